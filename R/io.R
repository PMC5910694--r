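# Text-format round-tripping for streamlines, fascicle tables and
# digitised cadaver polylines.

#' Write streamlines as CSV
#'
#' Long format: `streamline_id`, `point_index` (0-based), `x`, `y`, `z`
#' (mm, world frame).
#'
#' @param streamlines list of `myo_streamline` or point matrices
#' @param path output path
#' @return `path`, invisibly
#' @export
write_streamlines_csv <- function(streamlines, path) {
  rows <- lapply(seq_along(streamlines), function(i) {
    p <- if (inherits(streamlines[[i]], "myo_streamline"))
      streamlines[[i]]$points else streamlines[[i]]
    data.frame(streamline_id = i, point_index = seq_len(nrow(p)) - 1L,
               x = p[, 1], y = p[, 2], z = p[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read streamlines from CSV
#'
#' @param path CSV written by [write_streamlines_csv()]
#' @return list of point matrices, ordered by `streamline_id` and
#'   `point_index`
#' @export
read_streamlines_csv <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$streamline_id, df$point_index), ]
  lapply(split(df, df$streamline_id), function(d) {
    unname(as.matrix(d[, c("x", "y", "z")]))
  })
}

#' Write streamlines as legacy ASCII VTK polylines
#'
#' @param streamlines list of `myo_streamline` or point matrices
#' @param path output path (`.vtk`)
#' @return `path`, invisibly
#' @export
write_streamlines_vtk <- function(streamlines, path) {
  pts_list <- lapply(streamlines, function(s) {
    if (inherits(s, "myo_streamline")) s$points else matrix(s, ncol = 3)
  })
  npts <- vapply(pts_list, nrow, integer(1))
  all_pts <- do.call(rbind, pts_list)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0", "myotract streamlines", "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d double", nrow(all_pts))
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g", all_pts[, 1], all_pts[, 2], all_pts[, 3]),
             con)
  writeLines(sprintf("LINES %d %d", length(pts_list), length(pts_list) + sum(npts)),
             con)
  off <- c(0, cumsum(npts))
  for (i in seq_along(pts_list)) {
    writeLines(paste(c(npts[i], seq(off[i], off[i + 1] - 1)), collapse = " "),
               con)
  }
  invisible(path)
}

#' Read legacy ASCII VTK polylines
#'
#' @param path `.vtk` file written by [write_streamlines_vtk()]
#' @return list of point matrices
#' @export
read_streamlines_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  npts <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  coords <- scan(text = paste(lines[(ip + 1):length(lines)][
    seq_len(grep("^LINES", lines[(ip + 1):length(lines)])[1] - 1)
  ], collapse = "\n"), quiet = TRUE)
  pts <- matrix(coords[seq_len(3 * npts)], ncol = 3, byrow = TRUE)
  il <- grep("^LINES", lines)[1]
  nlines <- as.integer(strsplit(lines[il], "\\s+")[[1]][2])
  out <- vector("list", nlines)
  for (i in seq_len(nlines)) {
    rec <- as.integer(strsplit(trimws(lines[il + i]), "\\s+")[[1]])
    out[[i]] <- pts[rec[-1] + 1L, , drop = FALSE]
  }
  out
}

#' Read digitised cadaver fascicle polylines
#'
#' CSV with columns `fascicle_id`, `point_index`, `x`, `y`, `z` (mm), one
#' row per digitised point, emulating a 3D-digitiser export.
#'
#' @param path CSV file path
#' @return named list of point matrices, one per fascicle
#' @export
read_digitised_polylines <- function(path) {
  df <- utils::read.csv(path)
  need <- c("fascicle_id", "point_index", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("digitised polyline CSV must have columns: ",
         paste(need, collapse = ", "))
  }
  df <- df[order(df$fascicle_id, df$point_index), ]
  lapply(split(df, df$fascicle_id), function(d) {
    unname(as.matrix(d[, c("x", "y", "z")]))
  })
}
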