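#' Minimal NIfTI-1 input/output
#'
#' The pipeline exchanges 3D/4D images as single-file NIfTI-1 (`.nii`, or
#' `.nii.gz` via R's built-in gzip connections). Only the subset needed here
#' is supported: float32 or float64 data, an optional 4x4 affine stored in
#' the sform, and up to 7 dimensions (we use 3 or 4). This is deliberately
#' not a general NIfTI library; headers produced by mainstream tools
#' (nibabel, FSL) for plain scalar images read back correctly.
#'
#' @param x numeric array (3D or 4D).
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param pixdim voxel sizes, one per dimension of `x` (mm for the first
#'   three, seconds for the fourth).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity built from `pixdim`.
#' @param description free-text tag stored in the 80-byte `descrip` field
#'   (truncated); used for provenance (seed, config hash).
#' @return `write_nifti` returns `path` invisibly. `read_nifti` returns the
#'   array with attributes `pixdim`, `affine` and `description`.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_nifti(array(rnorm(24), c(2, 3, 4)), f)
#' img <- read_nifti(f)
#' @export
write_nifti <- function(x, path, pixdim = rep(1, length(dim(x))),
                        affine = NULL, description = "") {
  stopifnot(is.array(x), length(dim(x)) %in% 2:7, is.numeric(x))
  nd <- length(dim(x))
  stopifnot(length(pixdim) == nd)
  dims <- c(nd, dim(x), rep(1L, 7 - nd))
  pd <- c(1, pixdim, rep(1, 7 - nd))
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- pd[2:4]
  }
  stopifnot(identical(dim(affine), c(4L, 4L)))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4, endian = "little")
  wc <- function(s, width) {
    raw <- charToRaw(substr(s, 1, width))
    writeBin(c(raw, raw(width - length(raw))), con)
  }

  wi(348, 4)                               # sizeof_hdr
  wc("", 10); wc("", 18)                   # data_type, db_name (unused)
  wi(0, 4); wi(0, 2); wc("", 1); wc("r", 1)  # extents, session_error, regular, dim_info
  wi(dims, 2)                              # dim[8]
  wf(c(0, 0, 0))                           # intent_p1..3
  wi(0, 2)                                 # intent_code
  wi(64, 2); wi(64, 2)                     # datatype (64 = float64), bitpix
  wi(0, 2)                                 # slice_start
  wf(pd)                                   # pixdim[8]
  wf(352)                                  # vox_offset
  wf(c(1, 0))                              # scl_slope, scl_inter
  wi(0, 2); wc("", 1); wc("", 1)           # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                           # cal_max, cal_min, slice_duration
  wf(0)                                    # toffset
  wi(c(0, 0), 4)                           # glmax, glmin
  wc(description, 80)                      # descrip
  wc("", 24)                               # aux_file
  wi(0, 2); wi(2, 2)                       # qform_code = 0, sform_code = 2
  wf(rep(0, 6))                            # quatern b,c,d + qoffset x,y,z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])
  wc("", 16)                               # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)  # magic
  writeBin(raw(4), con)                    # extension flag
  writeBin(as.double(x), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4, endian = "little")

  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", n = 36))   # through dim_info
  dims <- ri(8, 2)
  invisible(rf(3)); intent_code <- ri(1, 2)
  datatype <- ri(1, 2); bitpix <- ri(1, 2); invisible(ri(1, 2))
  pd <- rf(8)
  vox_offset <- rf(1)
  scl <- rf(2)
  invisible(readBin(con, "raw", n = 2 + 1 + 1)); invisible(rf(3)); invisible(rf(1))
  invisible(ri(2, 4))
  descrip <- readBin(con, "raw", n = 80)
  invisible(readBin(con, "raw", n = 24))
  invisible(ri(2, 2))                      # qform, sform codes
  invisible(rf(6))
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  invisible(readBin(con, "raw", n = 16 + 4))

  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  nvox <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) invisible(readBin(con, "raw", n = skip))
  dat <- switch(as.character(datatype),
    "2"  = readBin(con, "integer", n = nvox, size = 1, signed = FALSE, endian = "little"),
    "4"  = readBin(con, "integer", n = nvox, size = 2, endian = "little"),
    "8"  = readBin(con, "integer", n = nvox, size = 4, endian = "little"),
    "16" = readBin(con, "double", n = nvox, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = nvox, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) dat <- dat * scl[1] + scl[2]
  out <- array(dat, dim = shape)
  attr(out, "pixdim") <- pd[2:(1 + nd)]
  attr(out, "affine") <- rbind(srow, c(0, 0, 0, 1))
  dtxt <- rawToChar(descrip[seq_len(max(0, which(descrip != 0)))])
  attr(out, "description") <- dtxt
  out
}
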