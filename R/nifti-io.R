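# Minimal NIfTI-1 single-file (.nii) I/O.
#
# No NIfTI reader is available in the supported dependency set, so the
# subset of the format this pipeline round-trips is implemented here:
# 3D/4D volumes, little-endian, dtypes uint8/int16/int32/float32/float64,
# sform affine (0-based voxel-centre convention, world in mm).

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

#' Write a volume as NIfTI-1
#'
#' Writes a single-file little-endian `.nii` with the affine stored in the
#' sform (code 1). `data` may be a 3D or 4D array.
#'
#' @param data numeric 3D or 4D array
#' @param path output file path (`.nii`)
#' @param affine 4x4 voxel-to-world matrix (mm, voxel-centre convention)
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`
#' @return `path`, invisibly
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = "float32") {
  dt <- NIFTI_DTYPES[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("data must be a 3D or 4D array")
  }
  ndim <- length(d)
  dim8 <- c(ndim, d, rep(1L, 7 - length(d)))
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size = 4L) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s[seq_len(min(length(raw_s), n))], raw(max(0L, n - length(raw_s)))), con)
  }

  wi(348L)                      # sizeof_hdr
  wc("", 10L); wc("", 18L)      # data_type, db_name (unused)
  wi(0L); wi(0L, 2L)            # extents, session_error
  writeBin(charToRaw("r"), con) # regular
  writeBin(raw(1L), con)        # dim_info
  wi(dim8, 2L)                  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)    # intent_p1..3, intent_code
  wi(dt$code, 2L); wi(dt$bitpix, 2L); wi(0L, 2L)  # datatype, bitpix, slice_start
  wf(c(0, spacing, rep(1, 4)))  # pixdim[8] (qfac 0)
  wf(352); wf(1); wf(0)         # vox_offset, scl_slope, scl_inter
  wi(0L, 2L); writeBin(raw(2L), con)  # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L))                 # glmax, glmin
  wc("myotract", 80L); wc("", 24L)    # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)        # qform_code 0, sform_code 1
  wf(c(0, 0, 0, 0, 0, 0))       # quaternions + qoffset (unused)
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])  # srow_x/y/z
  wc("", 16L)                   # intent_name
  wc("n+1", 4L)                 # magic
  writeBin(raw(4L), con)        # extension flag -> offset 352

  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the subset written by [write_nifti()]: single-file little-endian
#' `.nii`, 3D/4D, sform affine preferred (falls back to a diagonal pixdim
#' affine when no sform is present). Applies `scl_slope`/`scl_inter`.
#'
#' @param path `.nii` file path
#' @return list with `data` (array), `affine` (4x4) and `datatype`
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file: ", path)
  readBin(con, "raw", 10L + 18L + 4L + 2L + 1L + 1L)
  dim8 <- readBin(con, "integer", 8L, size = 2L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "integer", 1L, size = 2L, endian = "little")
  dtcode <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "integer", 2L, size = 2L, endian = "little")  # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = "little")
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  readBin(con, "raw", 2L + 1L + 1L)
  readBin(con, "numeric", 4L, size = 4L, endian = "little")
  readBin(con, "integer", 2L, size = 4L, endian = "little")
  readBin(con, "raw", 80L + 24L)
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # qform_code
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "numeric", 6L, size = 4L, endian = "little")
  srow <- matrix(readBin(con, "numeric", 12L, size = 4L, endian = "little"),
                 nrow = 3, byrow = TRUE)

  idx <- match(dtcode, vapply(NIFTI_DTYPES, function(x) x$code, integer(1)))
  if (is.na(idx)) stop("unsupported NIfTI datatype code: ", dtcode)
  dt <- NIFTI_DTYPES[[idx]]

  ndim <- dim8[1]
  d <- dim8[2:(1 + ndim)]
  n <- prod(d)
  seek(con, where = vox_offset, origin = "start")
  vals <- readBin(con, dt$what, n, size = dt$size, endian = "little",
                  signed = dt$signed)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- diag(4)
  if (sform_code > 0) {
    affine[1:3, ] <- srow
  } else {
    affine[1:3, 1:3] <- diag(pixdim[2:4])
  }
  list(data = array(vals, dim = d), affine = affine,
       datatype = names(NIFTI_DTYPES)[idx])
}

#' Write FSL-dialect bval/bvec sidecar files
#'
#' One row of b-values; three rows (x, y, z) of unit direction components.
#' The b0 volume is included as the first column with b = 0.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume
#' @param bvecs matrix of directions, one row per volume (zero row for b0)
#' @param stem output path stem; writes `<stem>.bval` and `<stem>.bvec`
#' @return character vector of the two paths, invisibly
#' @export
write_bval_bvec <- function(bvals, bvecs, stem) {
  bvecs <- matrix(bvecs, ncol = 3)
  stopifnot(length(bvals) == nrow(bvecs))
  bval_path <- paste0(stem, ".bval")
  bvec_path <- paste0(stem, ".bvec")
  writeLines(paste(format(bvals, scientific = FALSE, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(bvecs), 1, function(r) {
    paste(sprintf("%.10f", r), collapse = " ")
  }), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read FSL-dialect bval/bvec sidecar files
#'
#' @param stem path stem as used by [write_bval_bvec()]
#' @return list with `bvals` (vector) and `bvecs` (n x 3 matrix)
#' @export
read_bval_bvec <- function(stem) {
  bvals <- scan(paste0(stem, ".bval"), quiet = TRUE)
  rows <- lapply(readLines(paste0(stem, ".bvec"))[1:3],
                 function(l) scan(text = l, quiet = TRUE))
  bvecs <- t(do.call(rbind, rows))
  stopifnot(length(bvals) == nrow(bvecs))
  list(bvals = bvals, bvecs = bvecs)
}
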