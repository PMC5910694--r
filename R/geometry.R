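# Segmentation-derived geometry: label volumes, surface models, muscle
# length and long axis, seed/boundary masks on the DTI grid, and
# segmentation-reliability metrics.

#' Construct a label volume
#'
#' @param data 3D integer array (0 = background, positive labels =
#'   compartments)
#' @param affine 4x4 voxel-to-world matrix (mm)
#' @return object of class `myo_label_volume`
#' @export
label_volume <- function(data, affine) {
  stopifnot(length(dim(data)) == 3)
  if (any(data < 0)) stop("labels must be non-negative")
  structure(list(data = data, affine = affine), class = "myo_label_volume")
}

#' @export
print.myo_label_volume <- function(x, ...) {
  labs <- sort(unique(as.vector(x$data)))
  labs <- labs[labs > 0]
  cat(sprintf("<myo_label_volume> %s; labels: %s\n",
              paste(dim(x$data), collapse = " x "),
              paste(labs, collapse = ", ")))
  invisible(x)
}

# 6-connected component count via label propagation (vectorised flood)
count_connected_components <- function(mask) {
  if (!any(mask)) return(0L)
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nxt <- lab
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      sh <- shift3(lab, s[1], s[2], s[3], fill = 0)
      nxt <- pmax(nxt, sh * mask)
    }
    nxt[!mask] <- 0
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  length(unique(lab[mask]))
}

#' Build a compartment surface model
#'
#' Extracts the closed, outward-oriented boundary surface of one label in
#' world mm. The enclosed volume of the returned mesh equals the
#' voxel-count volume of the label exactly. Warns when the label is not a
#' single 6-connected component.
#'
#' @param labels a [label_volume()]
#' @param label the compartment label to extract
#' @return a closed `myo_mesh`
#' @export
build_surface <- function(labels, label) {
  stopifnot(inherits(labels, "myo_label_volume"))
  mask <- labels$data == label
  if (!any(mask)) stop("label ", label, " is empty in the label volume")
  if (count_connected_components(mask) > 1L) {
    warning("label ", label, " has more than one connected component")
  }
  surface_from_mask(mask, labels$affine, label = as.integer(label))
}

#' Define the muscle long axis
#'
#' @param proximal,distal two distinct world points (mm)
#' @return object of class `myo_long_axis` with unit `direction`
#'   (distal to proximal)
#' @export
long_axis <- function(proximal, distal) {
  if (vnorm(proximal - distal) < 1e-9) stop("long-axis points must be distinct")
  structure(list(
    proximal = as.numeric(proximal), distal = as.numeric(distal),
    direction = unit(proximal - distal)
  ), class = "myo_long_axis")
}

#' Long axis from the principal axis of combined mesh vertices
#'
#' Automated fallback for the manually picked anterior-surface points: the
#' first principal component of the pooled compartment vertices, oriented
#' distal to proximal (increasing projection).
#'
#' @param meshes list of `myo_mesh`
#' @return a [long_axis()]
#' @export
long_axis_auto <- function(meshes) {
  v <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  dir <- pc$rotation[, 1]
  proj <- as.vector(v %*% dir)
  centre <- colMeans(v)
  long_axis(
    proximal = centre + dir * (max(proj) - mean(proj)),
    distal = centre + dir * (min(proj) - mean(proj))
  )
}

#' Muscle length along the long axis
#'
#' Distance between the most proximal and most distal vertex of all
#' compartment surface models combined, projected on the long axis.
#'
#' @param meshes list of `myo_mesh` (>= 1)
#' @param axis a [long_axis()]
#' @return length in mm
#' @export
muscle_length <- function(meshes, axis) {
  stopifnot(length(meshes) >= 1, inherits(axis, "myo_long_axis"))
  proj <- unlist(lapply(meshes, function(m) m$vertices %*% axis$direction))
  max(proj) - min(proj)
}

#' Resample a label volume to another grid (nearest neighbour)
#'
#' @param labels a [label_volume()]
#' @param dst_affine 4x4 voxel-to-world matrix of the destination grid
#' @param dst_shape destination grid shape (length 3)
#' @return a [label_volume()] on the destination grid
#' @export
resample_labels <- function(labels, dst_affine, dst_shape) {
  stopifnot(inherits(labels, "myo_label_volume"))
  centres <- grid_centres(dst_shape, dst_affine)
  src_idx <- containing_voxel(labels$affine, centres)
  d <- dim(labels$data)
  inb <- src_idx[, 1] >= 1 & src_idx[, 1] <= d[1] &
    src_idx[, 2] >= 1 & src_idx[, 2] <= d[2] &
    src_idx[, 3] >= 1 & src_idx[, 3] <= d[3]
  out <- integer(nrow(centres))
  out[inb] <- labels$data[src_idx[inb, , drop = FALSE]]
  label_volume(array(out, dst_shape), dst_affine)
}

#' Seed and boundary masks on the DTI grid
#'
#' Resamples the compartment masks to the DTI grid (nearest neighbour),
#' then splits each compartment into a boundary layer (in-mask voxels
#' within `n_boundary` voxels, Chebyshev distance in voxel units, of any
#' out-of-mask voxel) and a seed region (the remainder). Seeds are thus at
#' least `n_boundary` voxels away from the muscle surface.
#'
#' @param labels a [label_volume()] (anatomical grid)
#' @param dti_affine 4x4 voxel-to-world matrix of the DTI grid
#' @param dti_shape DTI grid shape (length 3)
#' @param n_boundary boundary-layer thickness in voxels (default 2)
#' @return named list per label: list with logical arrays `compartment`,
#'   `seed`, `boundary` on the DTI grid
#' @export
make_seed_and_boundary_masks <- function(labels, dti_affine, dti_shape,
                                         n_boundary = 2L) {
  res <- resample_labels(labels, dti_affine, dti_shape)
  labs <- sort(unique(as.vector(res$data)))
  labs <- labs[labs > 0]
  out <- list()
  for (lb in labs) {
    comp <- res$data == lb
    outside <- !comp
    grown <- outside
    for (i in seq_len(n_boundary)) grown <- dilate_chebyshev1(grown)
    boundary <- comp & grown
    seed <- comp & !boundary
    if (!any(seed)) {
      stop("empty seed mask for label ", lb,
           " after a ", n_boundary, "-voxel boundary layer; ",
           "the compartment is too thin on the DTI grid")
    }
    out[[as.character(lb)]] <- list(compartment = comp, seed = seed,
                                    boundary = boundary)
  }
  out
}

#' Segmentation reliability from repeated volumes
#'
#' Root-mean-squared difference between compartment volumes measured at
#' short and long muscle lengths, absolute and as a percentage of the mean
#' of all paired volumes.
#'
#' @param volumes_short,volumes_long named numeric vectors (cm^3), paired
#'   by name
#' @return list with `rms_cm3` and `rms_pct`
#' @export
volume_reliability <- function(volumes_short, volumes_long) {
  if (is.null(names(volumes_short)) || is.null(names(volumes_long))) {
    if (length(volumes_short) != length(volumes_long)) {
      stop("unpaired volumes: lengths differ and no names given")
    }
  } else {
    if (!setequal(names(volumes_short), names(volumes_long))) {
      stop("unpaired labels: ",
           paste(symdiff_chr(names(volumes_short), names(volumes_long)),
                 collapse = ", "))
    }
    volumes_long <- volumes_long[names(volumes_short)]
  }
  d <- volumes_short - volumes_long
  rms <- sqrt(mean(d^2))
  list(rms_cm3 = rms, rms_pct = 100 * rms / mean(c(volumes_short, volumes_long)))
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))
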