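# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz, float32 or common
# integer datatypes, little-endian). No R NIfTI package is assumed available;
# only the subset of the format the pipeline touches is supported.

NIFTI_HDR_SIZE <- 348L

#' Write a 3D or 4D array as a NIfTI-1 volume
#'
#' Writes a single-file NIfTI-1 image (magic `n+1`) with the data stored as
#' float32, a diagonal sform built from `voxel_size`, and RAS+ axis order
#' assumed (dim 1 = left-right, dim 2 = posterior-anterior, dim 3 =
#' inferior-superior). Files ending in `.gz` are gzip-compressed.
#'
#' @param x numeric array, 3D or 4D.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param description free-text tag stored in the header (max 79 chars).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size = c(1, 1, 1), description = "hemidti") {
  stopifnot(is.array(x), length(dim(x)) %in% c(3L, 4L), length(voxel_size) == 3L)
  dm <- dim(x)
  ndim <- length(dm)
  dim_field <- rep(1L, 8L)
  dim_field[1L] <- ndim
  dim_field[seq_len(ndim) + 1L] <- as.integer(dm)
  pixdim <- rep(0, 8)
  pixdim[1L] <- 1              # qfac
  pixdim[2:4] <- voxel_size
  if (ndim == 4L) pixdim[5L] <- 1

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)

  wi <- function(v, size = 4L) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    raw <- raw[seq_len(min(length(raw), n))]
    writeBin(c(raw, raw(n - length(raw))), con)
  }

  wi(NIFTI_HDR_SIZE)                       # sizeof_hdr
  wc("", 10L)                              # data_type (unused)
  wc("", 18L)                              # db_name (unused)
  wi(0L); wi(0L, 2L); wc("r", 1L)          # extents, session_error, regular
  writeBin(as.raw(0L), con)                # dim_info
  wi(dim_field, 2L)                        # dim[8]
  wf(c(0, 0, 0))                           # intent_p1..p3
  wi(0L, 2L)                               # intent_code
  wi(16L, 2L)                              # datatype = NIFTI_TYPE_FLOAT32
  wi(32L, 2L)                              # bitpix
  wi(0L, 2L)                               # slice_start
  wf(pixdim)                               # pixdim[8]
  wf(352)                                  # vox_offset
  wf(1); wf(0)                             # scl_slope, scl_inter
  wi(0L, 2L); writeBin(as.raw(c(0L, 0L)), con)   # slice_end, slice_code, xyzt_units
  wf(0); wf(0); wf(0)                      # cal_max, cal_min, slice_duration
  wf(0)                                    # toffset
  wi(0L); wi(0L)                           # glmax, glmin (unused)
  wc(description, 80L)                     # descrip
  wc("", 24L)                              # aux_file
  wi(0L, 2L); wi(1L, 2L)                   # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                  # quatern b,c,d + qoffset x,y,z
  wf(c(voxel_size[1], 0, 0, 0))            # srow_x
  wf(c(0, voxel_size[2], 0, 0))            # srow_y
  wf(c(0, 0, voxel_size[3], 0))            # srow_z
  wc("", 16L)                              # intent_name
  wc("n+1", 4L)                            # magic
  writeBin(raw(4L), con)                   # extension flag
  wf(as.vector(x))
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file NIfTI-1 images written by [write_nifti()] or other tools,
#' supporting datatypes uint8/int16/int32/float32/float64 and gzip compression.
#' Applies `scl_slope`/`scl_inter` when set.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array), `voxel_size` (mm, length 3) and
#'   `dim` (integer vector).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)

  ri <- function(n, size = 4L) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n, size = 4L) readBin(con, "double", n = n, size = size, endian = "little")

  sizeof_hdr <- ri(1L)
  if (!identical(sizeof_hdr, NIFTI_HDR_SIZE))
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, "): ", path)
  invisible(readBin(con, "raw", n = 36L))        # data_type..dim_info
  dim_field <- ri(8L, 2L)
  invisible(rf(3L))                              # intent params
  invisible(ri(1L, 2L))                          # intent_code
  datatype <- ri(1L, 2L)
  invisible(ri(1L, 2L))                          # bitpix
  invisible(ri(1L, 2L))                          # slice_start
  pixdim <- rf(8L)
  vox_offset <- rf(1L)
  scl_slope <- rf(1L)
  scl_inter <- rf(1L)
  invisible(readBin(con, "raw", n = 348L - 120L))  # rest of the header

  ndim <- dim_field[1L]
  if (!ndim %in% c(2L, 3L, 4L)) stop("unsupported number of dimensions: ", ndim)
  dm <- dim_field[seq_len(ndim) + 1L]
  n <- prod(dm)
  # skip from end of header to vox_offset
  skip <- as.integer(round(vox_offset)) - NIFTI_HDR_SIZE
  if (skip > 0L) invisible(readBin(con, "raw", n = skip))

  vals <- switch(as.character(datatype),
    "2"  = as.double(readBin(con, "integer", n = n, size = 1L, signed = FALSE)),
    "4"  = as.double(readBin(con, "integer", n = n, size = 2L, endian = "little")),
    "8"  = as.double(readBin(con, "integer", n = n, size = 4L, endian = "little")),
    "16" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype)
  )
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dm),
       voxel_size = pixdim[2:4],
       dim = as.integer(dm))
}

#' Read and write FSL-dialect gradient tables
#'
#' The b-value file is a single whitespace-separated row, one value per
#' volume; the b-vector file has three rows (x, y, z direction cosines), one
#' column per volume.
#'
#' @param scheme a [make_gradient_scheme()] object.
#' @param bval_path,bvec_path output/input paths.
#' @return `write_gradient_table()` returns the paths invisibly;
#'   `read_gradient_table()` returns a `gradient_scheme`.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(format(scheme$bvalues, trim = TRUE), collapse = " "), bval_path)
  rows <- apply(scheme$directions, 2L, function(v)
    paste(format(v, digits = 10, trim = TRUE), collapse = " "))
  writeLines(rows, bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_gradient_table
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  vecs <- do.call(rbind, lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE)))
  if (nrow(vecs) != 3L) stop("bvec file must have exactly 3 rows")
  if (ncol(vecs) != length(bvals)) stop("bvec/bval volume counts differ")
  new_gradient_scheme(directions = t(vecs), bvalues = bvals)
}
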