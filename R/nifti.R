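# Minimal NIfTI-1 I/O (single-file .nii / .nii.gz, float32, RAS+ diagonal
# affine). No NIfTI package is available in this stack, so the subset of the
# format this package needs is read and written directly. Little-endian only.

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D volume as NIfTI-1
#'
#' Writes a single-file NIfTI-1 image (float32, little-endian) with a
#' diagonal RAS+ affine carrying the voxel size. Paths ending in .gz are
#' gzip-compressed.
#'
#' @param data 3D numeric array
#' @param path output path (.nii or .nii.gz)
#' @param voxel_size voxel edge lengths in mm, length 3 (or 1, recycled)
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  d <- dim(data)
  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  writeBin(raw(36), con)                                    # unused fields
  writeBin(as.integer(c(3, d, 1, 1, 1, 1)), con, size = 2,  # dim[8]
           endian = "little")
  writeBin(raw(14), con)                                    # intent fields
  writeBin(c(16L, 32L), con, size = 2, endian = "little")   # datatype, bitpix
  writeBin(0L, con, size = 2, endian = "little")            # slice_start
  writeBin(c(0, voxel_size, rep(0, 4)), con, size = 4,      # pixdim[8]
           endian = "little")
  writeBin(352, con, size = 4, endian = "little")           # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")       # scl_slope/inter
  writeBin(raw(4), con)                                     # slice_end..xyzt_units
  writeBin(c(0, 0, 0, 0), con, size = 4, endian = "little") # cal_max..toffset
  writeBin(raw(8), con)
  writeBin(raw(80 + 24), con)                               # descrip, aux_file
  writeBin(c(0L, 1L), con, size = 2, endian = "little")     # qform, sform codes
  writeBin(rep(0, 6), con, size = 4, endian = "little")     # quaternion
  srow <- rbind(c(voxel_size[1], 0, 0, 0),
                c(0, voxel_size[2], 0, 0),
                c(0, 0, voxel_size[3], 0))
  writeBin(as.numeric(t(srow)), con, size = 4, endian = "little")
  writeBin(raw(16), con)                                    # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)
  writeBin(raw(4), con)                                     # extension flag
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package
#'
#' Supports single-file little-endian NIfTI-1 with float32 (16), int16 (4),
#' uint8 (2) or float64 (64) data.
#'
#' @param path .nii or .nii.gz path
#' @return list with \code{data} (3D array) and \code{voxel_size} (length 3)
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sizeof_hdr <- readBin(hdr[1:4], "integer", 1, size = 4, endian = "little")
  if (sizeof_hdr != 348) stop("not a little-endian NIfTI-1 file", call. = FALSE)
  dims <- readBin(hdr[41:56], "integer", 8, size = 2, endian = "little")
  if (dims[1] < 3) stop("expected a 3D image", call. = FALSE)
  d <- dims[2:4]
  datatype <- readBin(hdr[71:72], "integer", 1, size = 2, endian = "little")
  pixdim <- readBin(hdr[77:108], "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(hdr[109:112], "numeric", 1, size = 4,
                        endian = "little")
  n <- prod(d)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  vals <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype ", datatype, call. = FALSE))
  list(data = array(vals, dim = d), voxel_size = abs(pixdim[2:4]))
}
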