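# NIfTI-1 read/write over base-R binary connections (gzip transparent).
# The environment ships no R NIfTI package, so the format is implemented
# here directly against the NIfTI-1 standard; a nibabel cross-check lives in
# the test suite.  Only the fields this pipeline needs are honored: dims,
# datatype, pixdim, scl_slope/inter, qform/sform orientation.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L,
                 uint16 = 512L)

open_bin <- function(path, mode) {
  if (grepl("\\.gz$", path) || mode == "rb") gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI volume
#'
#' Parses NIfTI-1 or NIfTI-2 (`.nii` / `.nii.gz`), applies any scale
#' slope/intercept, reorients the data to the package's canonical internal
#' (z, y, x) axis convention using the sform (preferred) or qform, and
#' records the reorientation in the geometry log.
#'
#' @param path file path.
#' @param as_label if `TRUE`, return a [label_volume()] (values validated
#'   against \{0,1,2\}).
#' @param case_id identifier; defaults to the file name.
#' @return a [ct_volume()] or [label_volume()].
#' @export
read_volume <- function(path, as_label = FALSE, case_id = NULL) {
  if (!file.exists(path)) stop("cannot read NIfTI file (no such file): ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (!hdr_size %in% c(348L, 540L)) {
    close(con); con <- gzfile(path, "rb")
    hdr_size <- readBin(con, "integer", 1, size = 4, endian = "big")
    endian <- "big"
    if (!hdr_size %in% c(348L, 540L))
      stop("not a parseable NIfTI-1/NIfTI-2 file: ", path)
  }

  if (hdr_size == 348L) h <- read_n1_header(con, endian)
  else h <- read_n2_header(con, endian)

  ndim <- h$dim[1]
  extra <- if (ndim > 3) h$dim[(4 + 1):(ndim + 1)] else integer(0)
  if (ndim > 3 && any(extra > 1))
    stop(sprintf("expected a 3D image, got %dD (dim = %s): %s",
                 ndim, paste(h$dim[2:(ndim + 1)], collapse = "x"), path))
  if (ndim < 3) stop("expected a 3D image, got ", ndim, "D: ", path)
  nx <- h$dim[2]; ny <- h$dim[3]; nz <- h$dim[4]
  nvox <- as.numeric(nx) * ny * nz

  dt <- h$datatype
  rd <- switch(as.character(dt),
    "2"   = function(n) readBin(con, "integer", n, size = 1, signed = FALSE, endian = endian),
    "4"   = function(n) readBin(con, "integer", n, size = 2, endian = endian),
    "8"   = function(n) readBin(con, "integer", n, size = 4, endian = endian),
    "16"  = function(n) readBin(con, "double",  n, size = 4, endian = endian),
    "64"  = function(n) readBin(con, "double",  n, size = 8, endian = endian),
    "512" = function(n) readBin(con, "integer", n, size = 2, signed = FALSE, endian = endian),
    stop("unsupported NIfTI datatype code ", dt, ": ", path))

  # skip from end of header to vox_offset
  skip <- h$vox_offset - h$hdr_bytes_read
  if (skip > 0) readBin(con, "raw", skip)
  vals <- rd(nvox)
  if (length(vals) < nvox) stop("truncated NIfTI data: ", path)

  if (!is.na(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter

  arr <- array(vals, dim = c(nx, ny, nz))       # file order: x fastest
  sp_file <- h$pixdim[2:4]
  if (any(sp_file <= 0)) sp_file[sp_file <= 0] <- 1

  ori <- closest_canonical(h$affine)
  # permute file axes into world order (x, y, z), flipping negatives
  arr <- aperm(arr, ori$order)
  sp_ras <- sp_file[ori$order]
  for (ax in 1:3) if (ori$flip[ax]) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[ax]] <- dim(arr)[ax]:1
    arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  # world (x, y, z) -> internal (z, y, x)
  arr <- aperm(arr, c(3, 2, 1))
  spacing <- sp_ras[c(3, 2, 1)]

  gl <- list(list(type = "reorient", perm = ori$order, flip = ori$flip,
                  dim = dim(arr), affine = h$affine))
  cid <- if (is.null(case_id)) sub("\\.nii(\\.gz)?$", "", basename(path)) else case_id
  if (as_label) {
    label_volume(array(as.integer(round(arr)), dim(arr)), spacing, cid, gl)
  } else {
    ct_volume(arr, spacing, cid, gl)
  }
}

read_n1_header <- function(con, endian) {
  r_i16 <- function(n) readBin(con, "integer", n, size = 2, endian = endian)
  r_i32 <- function(n) readBin(con, "integer", n, size = 4, endian = endian)
  r_f32 <- function(n) readBin(con, "double", n, size = 4, endian = endian)
  readBin(con, "raw", 36)                        # data_type..dim_info (offsets 4..39)
  dm <- r_i16(8)                                 # offset 40
  r_f32(3); r_i16(1)                             # intent_p1-3, intent_code
  datatype <- r_i16(1); bitpix <- r_i16(1); r_i16(1)
  pixdim <- r_f32(8)                             # offset 76
  vox_offset <- r_f32(1)
  scl_slope <- r_f32(1); scl_inter <- r_f32(1)
  r_i16(1); readBin(con, "raw", 2)               # slice_end, slice_code, xyzt_units
  r_f32(4)                                       # cal_max..toffset
  r_i32(2)                                       # glmax, glmin
  readBin(con, "raw", 104)                       # descrip + aux_file
  qform_code <- r_i16(1); sform_code <- r_i16(1)
  quat <- r_f32(6)                               # b, c, d, qoffset x/y/z
  srow <- matrix(r_f32(12), nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16)                        # intent_name
  magic <- readBin(con, "raw", 4)

  affine <- build_affine(sform_code, srow, qform_code, quat, pixdim)
  list(dim = dm, datatype = datatype, bitpix = bitpix, pixdim = pixdim,
       vox_offset = round(vox_offset), scl_slope = scl_slope, scl_inter = scl_inter,
       affine = affine, hdr_bytes_read = 348L)
}

read_n2_header <- function(con, endian) {
  r_i16 <- function(n) readBin(con, "integer", n, size = 2, endian = endian)
  r_f64 <- function(n) readBin(con, "double", n, size = 8, endian = endian)
  r_i32 <- function(n) readBin(con, "integer", n, size = 4, endian = endian)
  r_i64 <- function(n) {                         # int64 via two int32 words
    w <- r_i32(2 * n)
    lo <- w[seq(1, 2 * n, 2)]; hi <- w[seq(2, 2 * n, 2)]
    if (endian == "big") { tmp <- lo; lo <- hi; hi <- tmp }
    lo <- ifelse(lo < 0, lo + 2^32, lo)
    hi * 2^32 + lo
  }
  readBin(con, "raw", 8)                         # magic
  datatype <- r_i16(1); bitpix <- r_i16(1)
  dm <- as.integer(r_i64(8))
  r_f64(3)                                       # intent_p1..p3
  pixdim <- r_f64(8)
  vox_offset <- r_i64(1)
  scl_slope <- r_f64(1); scl_inter <- r_f64(1)
  r_f64(3)                                       # cal_max, cal_min, slice_duration
  r_f64(1); r_i64(2)                             # toffset, slice_start, slice_end
  readBin(con, "raw", 104)                       # descrip + aux_file
  qform_code <- r_i32(1); sform_code <- r_i32(1)
  quat <- r_f64(6)
  srow <- matrix(r_f64(12), nrow = 3, byrow = TRUE)
  affine <- build_affine(sform_code, srow, qform_code, quat, pixdim)
  list(dim = dm, datatype = datatype, bitpix = bitpix, pixdim = pixdim,
       vox_offset = round(vox_offset), scl_slope = scl_slope, scl_inter = scl_inter,
       affine = affine, hdr_bytes_read = 496L)
}

build_affine <- function(sform_code, srow, qform_code, quat, pixdim) {
  if (!is.na(sform_code) && sform_code > 0) return(srow[, 1:3, drop = FALSE])
  if (!is.na(qform_code) && qform_code > 0) {
    b <- quat[1]; c_ <- quat[2]; d <- quat[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
                  2 * (b * c_ + a * d), a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
                  2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 + d^2 - b^2 - c_^2),
                nrow = 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    sp <- abs(pixdim[2:4]); sp[sp == 0] <- 1
    return(R %*% diag(c(sp[1], sp[2], qfac * sp[3])))
  }
  diag(abs(pixdim[2:4]) + (pixdim[2:4] == 0))
}

# For each world axis k, find the file axis most aligned with it.
closest_canonical <- function(affine) {
  M <- affine
  order <- integer(3); flip <- logical(3); used <- logical(3)
  for (k in 1:3) {
    cand <- abs(M[k, ]); cand[used] <- -Inf
    j <- which.max(cand)
    order[k] <- j; used[j] <- TRUE
    flip[k] <- M[k, j] < 0
  }
  list(order = order, flip = flip)
}

#' Write a volume as NIfTI-1
#'
#' Writes the canonical internal layout back to disk: file axes (x, y, z)
#' with an axis-aligned sform affine built from the voxel spacing.  Labels
#' are always written as an integer type.
#'
#' @param volume a [ct_volume()] or [label_volume()].
#' @param path output path; `.gz` suffix selects gzip compression.
#' @param dtype_policy `"auto"` (labels uint8, images float32), `"int16"`
#'   (HU images), `"float32"`, `"uint8"`, or `"int32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, dtype_policy = "auto") {
  v <- volume$voxels
  if (is_label(volume)) {
    vals <- unique(as.vector(v))
    if (!all(vals %in% 0:2))
      stop("label volume contains values outside {0,1,2}: ",
           paste(utils::head(setdiff(vals, 0:2), 5), collapse = ", "))
    if (dtype_policy == "auto") dtype_policy <- "uint8"
    if (!dtype_policy %in% c("uint8", "int16", "int32"))
      stop("labels must be written with an integral dtype, not ", dtype_policy)
  } else if (dtype_policy == "auto") {
    dtype_policy <- "float32"
  }
  dt_code <- NIFTI_DT[[dtype_policy]]
  if (is.null(dt_code)) stop("unknown dtype_policy: ", dtype_policy)
  size <- switch(dtype_policy, uint8 = 1L, int16 = 2L, int32 = 4L, float32 = 4L,
                 float64 = 8L)

  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  d <- dim(v)                    # (z, y, x)
  sp <- volume$spacing           # (z, y, x)
  arr <- aperm(v, c(3, 2, 1))    # file order x fastest
  if (dtype_policy %in% c("uint8", "int16", "int32")) {
    lim <- switch(dtype_policy, uint8 = c(0, 255), int16 = c(-32768, 32767),
                  int32 = c(-2^31, 2^31 - 1))
    arr <- pmin(pmax(round(arr), lim[1]), lim[2])
    storage.mode(arr) <- "integer"
  }

  con <- open_bin(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                                   # sizeof_hdr
  w_raw(36)                                     # data_type..dim_info
  w_i16(c(3L, d[3], d[2], d[1], 1L, 1L, 1L, 1L))  # dim
  w_f32(c(0, 0, 0)); w_i16(0L)                  # intent
  w_i16(dt_code); w_i16(size * 8L); w_i16(0L)   # datatype, bitpix, slice_start
  w_f32(c(1, sp[3], sp[2], sp[1], 0, 0, 0, 0))  # pixdim
  w_f32(352)                                    # vox_offset
  w_f32(1); w_f32(0)                            # scl_slope, scl_inter
  w_i16(0L); w_raw(2)                           # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                          # cal_max..toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  desc <- charToRaw(sprintf("nephroseg %s", volume$case_id))
  writeBin(c(desc, raw(80 - length(desc)))[1:80], con)
  w_raw(24)                                     # aux_file
  w_i16(0L); w_i16(1L)                          # qform_code, sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))                    # quatern + qoffset
  w_f32(c(sp[3], 0, 0, 0))                      # srow_x
  w_f32(c(0, sp[2], 0, 0))                      # srow_y
  w_f32(c(0, 0, sp[1], 0))                      # srow_z
  w_raw(16)                                     # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  w_raw(4)                                      # extension flag
  if (is.integer(arr)) {
    writeBin(as.vector(arr), con, size = size, endian = "little")
  } else {
    writeBin(as.vector(arr), con, size = size, endian = "little")
  }
  invisible(path)
}
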