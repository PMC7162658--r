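# Minimal NIfTI-1 volume IO. No NIfTI package ships with this R stack, so
# the single-file (.nii / .nii.gz) format is read and written here directly:
# 348-byte header, data at vox_offset, sform affine, the numeric datatypes
# this pipeline emits. Not a general-purpose implementation.

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, r = "uint8"),
  `4`  = list(what = "integer", size = 2L, signed = TRUE, r = "int16"),
  `8`  = list(what = "integer", size = 4L, signed = TRUE, r = "int32"),
  `16` = list(what = "double", size = 4L, signed = TRUE, r = "float32"),
  `64` = list(what = "double", size = 8L, signed = TRUE, r = "float64"))

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file `.nii` or `.nii.gz` images (3D or 4D, the common
#' numeric datatypes), applying `scl_slope`/`scl_inter` when set.
#'
#' @param path file path.
#' @return A `nifti_volume`: list with `data` (3D/4D array), `affine`
#'   (4x4 voxel-to-world matrix), `pixdim`, `datatype`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348)
    stop(sprintf("malformed NIfTI header in %s: only %d bytes before offset 348",
                 path, length(hdr)), call. = FALSE)
  field <- function(offset, what, n, size, endian) {
    readBin(hdr[seq(offset + 1L, offset + n * size)], what, n, size,
            signed = TRUE, endian = endian)
  }
  endian <- .Platform$endian
  if (field(0, "integer", 1, 4, endian) != 348L) {
    endian <- if (endian == "little") "big" else "little"
    if (field(0, "integer", 1, 4, endian) != 348L)
      stop(sprintf("malformed NIfTI header in %s: sizeof_hdr at offset 0 is not 348 in either byte order",
                   path), call. = FALSE)
  }
  dims <- field(40, "integer", 8, 2, endian)
  datatype <- field(70, "integer", 1, 2, endian)
  pixdim <- field(76, "double", 8, 4, endian)
  vox_offset <- field(108, "double", 1, 4, endian)
  scl_slope <- field(112, "double", 1, 4, endian)
  scl_inter <- field(116, "double", 1, 4, endian)
  sform_code <- field(254, "integer", 1, 2, endian)
  srow <- matrix(field(280, "double", 12, 4, endian), 3, 4, byrow = TRUE)
  magic <- rawToChar(hdr[345:347])
  if (!identical(magic, "n+1"))
    stop(sprintf("malformed NIfTI header in %s: magic at offset 344 is '%s'",
                 path, magic), call. = FALSE)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop(sprintf("unsupported NIfTI datatype %d in %s", datatype, path),
         call. = FALSE)
  ndim <- dims[1]
  shape <- dims[seq(2, 1 + max(ndim, 3))]
  shape[shape == 0] <- 1L
  n <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n)
    stop(sprintf("truncated NIfTI data in %s at offset %d: expected %d values, got %d",
                 path, as.integer(vox_offset), n, length(vals)), call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1)) else
    diag(c(pixdim[2:4], 1))
  structure(list(data = array(vals, shape), affine = affine,
                 pixdim = pixdim[2:5], datatype = dt$r),
            class = "nifti_volume")
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file `.nii` (or `.nii.gz`) image with an sform affine.
#'
#' @param image 3D/4D array or `nifti_volume`.
#' @param path output path (gzipped when it ends in `.gz`).
#' @param affine 4x4 voxel-to-world matrix (default identity).
#' @param tr_seconds 4th pixdim entry (default 1).
#' @param datatype `"float64"` (default, lossless for R doubles),
#'   `"float32"`, or `"int32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path, affine = NULL, tr_seconds = 1,
                         datatype = c("float64", "float32", "int32")) {
  datatype <- match.arg(datatype)
  if (inherits(image, "nifti_volume")) {
    affine <- affine %||% image$affine
    image <- image$data
  }
  affine <- affine %||% diag(4)
  data <- as.array(image)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop_invalid("image", "must be a 3D or 4D array")
  dims <- integer(8)
  dims[1] <- nd
  dims[seq(2, 1 + nd)] <- dim(data)
  dims[dims == 0] <- 1L
  code <- switch(datatype, float64 = 64L, float32 = 16L, int32 = 8L)
  bitpix <- switch(datatype, float64 = 64L, float32 = 32L, int32 = 32L)
  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  w_i4 <- function(x) writeBin(as.integer(x), con, 4)
  w_i2 <- function(x) writeBin(as.integer(x), con, 2)
  w_f4 <- function(x) writeBin(as.double(x), con, 4)
  w_raw <- function(n) writeBin(raw(n), con)
  w_i4(348); w_raw(36)
  w_i2(dims)                                   # dim[8]
  w_raw(14)                                    # intent fields
  w_i2(code); w_i2(bitpix); w_i2(0)            # datatype, bitpix, slice_start
  w_f4(c(1, sqrt(colSums(affine[1:3, 1:3]^2)), tr_seconds, 0, 0, 0)) # pixdim
  w_f4(352)                                    # vox_offset
  w_f4(1); w_f4(0)                             # scl_slope, scl_inter
  w_i2(0)                                      # slice_end
  writeBin(as.raw(c(0L, 10L)), con)            # slice_code, xyzt_units mm|sec
  w_f4(0); w_f4(0); w_f4(0)                    # cal_max, cal_min, slice_dur
  w_f4(0); w_i4(0); w_i4(0)                    # toffset, glmax, glmin
  w_raw(80 + 24)                               # descrip, aux_file
  w_i2(0); w_i2(1)                             # qform_code 0, sform_code 1
  w_f4(numeric(6))                             # quaternion + qoffsets
  w_f4(as.vector(t(affine[1:3, ])))            # srow_x/y/z
  w_raw(16)                                    # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  w_raw(4)                                     # extender: data at vox_offset 352
  vals <- as.vector(data)
  switch(datatype,
    float64 = writeBin(as.double(vals), con, 8),
    float32 = writeBin(as.double(vals), con, 4),
    int32 = writeBin(as.integer(round(vals)), con, 4))
  invisible(path)
}

#' Check that two volumes share a grid
#'
#' @param a,b `nifti_volume`s (or arrays, in which case only shape is
#'   checked).
#' @param tol affine comparison tolerance.
#' @return TRUE invisibly; errors on mismatch.
#' @export
check_same_grid <- function(a, b, tol = 1e-5) {
  da <- if (inherits(a, "nifti_volume")) dim(a$data) else dim(a)
  db <- if (inherits(b, "nifti_volume")) dim(b$data) else dim(b)
  if (!identical(da[1:3], db[1:3]))
    stop("volumes have different grid shapes", call. = FALSE)
  if (inherits(a, "nifti_volume") && inherits(b, "nifti_volume") &&
      max(abs(a$affine - b$affine)) > tol)
    stop("volumes have mismatched affines; resample upstream", call. = FALSE)
  invisible(TRUE)
}
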