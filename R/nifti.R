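# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer. No NIfTI
# package ships with the supported stack, so the 348-byte header is handled
# directly: dims, datatype, pixdim, vox_offset, scl_slope/inter and the
# magic are honoured; orientation fields are carried through write-out for
# volumes this package created, and ignored otherwise (volumes are treated
# in array index order, axial = third axis).

NIFTI_TYPES <- list(
  `2` = list(what = "integer", size = 1, signed = FALSE),   # uint8
  `4` = list(what = "integer", size = 2, signed = TRUE),    # int16
  `8` = list(what = "integer", size = 4, signed = TRUE),    # int32
  `16` = list(what = "double", size = 4, signed = TRUE),    # float32
  `64` = list(what = "double", size = 8, signed = TRUE),    # float64
  `512` = list(what = "integer", size = 2, signed = FALSE)  # uint16
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file
#' @return list with `data` (numeric array), `spacing` (pixdim of the
#'   spatial axes, mm), `datatype` (NIfTI code)
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header")
  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported")
  dim0 <- readBin(hdr[41:56], "integer", 8, 2, endian = endian)
  ndim <- dim0[1]
  if (ndim > 3 && any(dim0[(4 + 1):(ndim + 1)] > 1)) {
    stop("4-d / multi-channel NIfTI input is not supported")
  }
  ndim <- min(ndim, 3L)
  dims <- pmax(dim0[2:(ndim + 1)], 1L)
  datatype <- readBin(hdr[71:72], "integer", 1, 2, endian = endian)
  ty <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(ty)) stop(sprintf("unsupported NIfTI datatype code %d", datatype))
  pixdim <- readBin(hdr[77:108], "double", 8, 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "double", 1, 4, endian = endian)
  scl_slope <- readBin(hdr[113:116], "double", 1, 4, endian = endian)
  scl_inter <- readBin(hdr[117:120], "double", 1, 4, endian = endian)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, ty$what, n, ty$size, signed = ty$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data section")
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  arr <- array(as.double(vals), dims)
  if (length(dims) == 2) arr <- array(arr, c(dims, 1L))
  list(data = arr, spacing = pixdim[2:4], datatype = datatype)
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric 3-d array
#' @param path output `.nii` or `.nii.gz`
#' @param spacing voxel spacing in mm (3 values)
#' @param datatype `"float32"` (default), `"float64"` or `"uint8"`
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1),
                        datatype = c("float32", "float64", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(data)) == 3)
  code <- switch(datatype, float32 = 16L, float64 = 64L, uint8 = 2L)
  bitpix <- switch(datatype, float32 = 32L, float64 = 64L, uint8 = 8L)
  d <- dim(data)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, 4)                                    # sizeof_hdr
  writeBin(raw(36), con)                                    # unused
  writeBin(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), con, 2)    # dim[8]
  writeBin(raw(14), con)                                    # intent fields
  writeBin(as.integer(code), con, 2)                        # datatype
  writeBin(as.integer(bitpix), con, 2)                      # bitpix
  writeBin(0L, con, 2)                                      # slice_start
  writeBin(c(1, spacing, 1, 1, 1, 1), con, 4)               # pixdim[8]
  writeBin(352, con, 4)                                     # vox_offset
  writeBin(c(1, 0), con, 4)                                 # scl_slope/inter
  writeBin(raw(132), con)                # slice/cal fields, descrip, aux_file
  # qform/sform codes = 0 -> orientation by array order
  writeBin(as.integer(c(0L, 0L)), con, 2)
  writeBin(numeric(18), con, 4)          # quatern/qoffset/srow
  writeBin(raw(16), con)                 # intent_name
  writeBin(charToRaw("n+1"), con)
  writeBin(raw(1), con)
  writeBin(raw(4), con)                  # extender
  vals <- as.vector(data)
  if (datatype == "uint8") {
    writeBin(as.integer(round(pmin(pmax(vals, 0), 255))), con, 1)
  } else {
    writeBin(as.double(vals), con, switch(datatype, float32 = 4, float64 = 8))
  }
  invisible(path)
}
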