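# Crop / clip / stitch geometry.
#
# Stage 1 tiles the center-cropped low-resolution volume into overlapping
# z-cubes (length 96, stride 48 at paper scale); stage 2 does the same
# inside per-kidney ROIs (length 64, stride 32).  Stitching fuses overlap by
# score averaging; cube starts are end-aligned so every z slice is covered.

#' Patch specification
#'
#' @param crop_xy length-2 integer in-plane crop size (y, x).
#' @param cube_len cube length along z.
#' @param stride z step between cube starts; `0 < stride <= cube_len`.
#' @return object of class `patch_spec`.
#' @export
patch_spec <- function(crop_xy, cube_len, stride) {
  crop_xy <- as.integer(crop_xy); cube_len <- as.integer(cube_len)
  stride <- as.integer(stride)
  if (any(crop_xy <= 0)) stop("crop_xy components must be > 0")
  if (stride <= 0 || stride > cube_len) stop("require 0 < stride <= cube_len")
  structure(list(crop_xy = crop_xy, cube_len = cube_len, stride = stride),
            class = "patch_spec")
}

#' Paper-scale stage geometries
#' @param stage 1 or 2.
#' @return a [patch_spec()]: stage 1 = crop (192,192), cubes 96/48;
#'   stage 2 = ROI (160,160), cubes 64/32.
#' @export
default_patch_spec <- function(stage) {
  if (stage == 1) patch_spec(c(192L, 192L), 96L, 48L)
  else patch_spec(c(160L, 160L), 64L, 32L)
}

#' Center crop (or pad) the in-plane axes
#'
#' Output in-plane shape equals `size`.  When the input is larger, the crop
#' offset is `floor((dim - size)/2)` per axis; when smaller, the volume is
#' zero-padded symmetrically and the recorded offset is negative, so the
#' inverse placement is still exact.
#'
#' @param v a [ct_volume()] or [label_volume()].
#' @param size length-2 integer (y, x).
#' @return list with `volume` and `offset` (length-2 integer, 0-based).
#' @export
center_crop_xy <- function(v, size) {
  d <- dim(v$voxels)
  size <- as.integer(size)
  off <- as.integer(floor((d[2:3] - size) / 2))   # negative => padding
  out <- extract_box(v$voxels, c(0L, off), c(d[1], size),
                     fill = if (is_label(v)) 0L else 0)
  vol <- rewrap(v, out, log_entry = list(type = "crop", offset = c(0L, off)))
  list(volume = vol, offset = off)
}

# Extract a (possibly out-of-bounds) box from a 3D array with zero fill.
# start is 0-based per axis; shape is the box size.
extract_box <- function(arr, start, shape, fill = 0) {
  d <- dim(arr)
  out <- array(fill, dim = shape)
  src_lo <- pmax(start, 0L)                 # 0-based inclusive
  src_hi <- pmin(start + shape, d)          # 0-based exclusive
  if (any(src_hi <= src_lo)) return(out)
  dst_lo <- src_lo - start
  out[(dst_lo[1] + 1):(dst_lo[1] + src_hi[1] - src_lo[1]),
      (dst_lo[2] + 1):(dst_lo[2] + src_hi[2] - src_lo[2]),
      (dst_lo[3] + 1):(dst_lo[3] + src_hi[3] - src_lo[3])] <-
    arr[(src_lo[1] + 1):src_hi[1], (src_lo[2] + 1):src_hi[2],
        (src_lo[3] + 1):src_hi[3]]
  out
}

#' Enumerate end-aligned z cube start offsets
#'
#' Starts are `0, stride, 2*stride, ...`; a final cube that would overrun is
#' replaced by one end-aligned cube at `Z - cube_len`; if `Z < cube_len`
#' there is a single cube at 0 (the volume is padded at extraction time).
#'
#' @param Z number of z slices.
#' @param cube_len,stride cube geometry.
#' @return integer vector of 0-based start offsets.
#' @export
cube_offsets <- function(Z, cube_len, stride) {
  if (Z <= cube_len) return(0L)
  starts <- seq(0L, Z - cube_len, by = stride)
  if (utils::tail(starts, 1) + cube_len < Z)
    starts <- c(starts, Z - cube_len)
  as.integer(starts)
}

#' Clip a volume into overlapping z cubes
#'
#' @param v a [ct_volume()] or [label_volume()].
#' @param spec a [patch_spec()]; the in-plane shape of `v` must already be
#'   `spec$crop_xy` (apply [center_crop_xy()] first).
#' @return a `patch_grid`: list with `cubes` (list of 3D arrays of shape
#'   `(cube_len, crop_xy)`), `offsets` (0-based z starts), `source_shape`.
#' @export
clip_z_cubes <- function(v, spec) {
  d <- dim(v$voxels)
  offs <- cube_offsets(d[1], spec$cube_len, spec$stride)
  cubes <- lapply(offs, function(o)
    extract_box(v$voxels, c(o, 0L, 0L), c(spec$cube_len, d[2], d[3]),
                fill = if (is_label(v)) 0L else 0))
  structure(list(cubes = cubes, offsets = offs, source_shape = d,
                 cube_len = spec$cube_len, is_label = is_label(v)),
            class = "patch_grid")
}

#' Stitch per-cube class scores back into a full volume
#'
#' Each voxel's score is the mean over all cubes covering it; slices beyond
#' the source extent (possible only for padded short volumes) are dropped.
#'
#' @param score_cubes list of 4D arrays `(cube_len, Y, X, K)` aligned with
#'   `offsets`.
#' @param offsets 0-based z starts (from [clip_z_cubes()]).
#' @param source_shape length-3 (Z, Y, X) of the tiled volume.
#' @return 4D array `(Z, Y, X, K)` of averaged scores.
#' @export
stitch_cubes <- function(score_cubes, offsets, source_shape) {
  Z <- source_shape[1]
  K <- dim(score_cubes[[1]])[4]
  L <- dim(score_cubes[[1]])[1]
  acc <- array(0, c(Z, source_shape[2], source_shape[3], K))
  cnt <- numeric(Z)
  for (i in seq_along(score_cubes)) {
    o <- offsets[i]
    zr <- (o + 1):min(o + L, Z)          # in-source slices of this cube
    acc[zr, , , ] <- acc[zr, , , , drop = FALSE] +
      score_cubes[[i]][seq_along(zr), , , , drop = FALSE]
    cnt[zr] <- cnt[zr] + 1
  }
  if (any(cnt == 0)) stop("internal error: uncovered z slice in stitch_cubes")
  sweep(acc, 1, cnt, "/")
}

#' Per-kidney ROI box
#'
#' @param start,stop 0-based inclusive/exclusive voxel bounds per (z, y, x)
#'   axis in the working frame (y/x may extend beyond the image; cropping
#'   zero-pads).
#' @param component_id connected-component id the box derives from.
#' @param voxel_count component size in voxels.
#' @return object of class `roi_box`.
#' @export
roi_box <- function(start, stop, component_id = NA_integer_,
                    voxel_count = NA_integer_) {
  start <- as.integer(start); stop <- as.integer(stop)
  if (any(stop <= start)) stop("roi_box requires start < stop on all axes")
  structure(list(start = start, stop = stop, component_id = component_id,
                 voxel_count = voxel_count), class = "roi_box")
}

#' Derive per-kidney ROI boxes from a coarse kidney mask
#'
#' Connected components (26-connectivity) of the binary mask are filtered by
#' a minimum physical volume, the two largest survivors are kept, and each
#' yields a box centered in-plane on the component centroid with shape
#' `roi_xy`, spanning the component's full z extent.
#'
#' @param coarse_mask a binary [label_volume()] in the working frame.
#' @param roi_xy length-2 integer in-plane ROI shape (default (160, 160)).
#' @param min_volume_mm3 components smaller than this are discarded
#'   (default 2000 mm3 = 2 cm3).
#' @return list of [roi_box()]; empty when no component survives (a stage-1
#'   failure, reported — never an exception).
#' @export
find_kidney_rois <- function(coarse_mask, roi_xy = c(160L, 160L),
                             min_volume_mm3 = 2000) {
  m <- coarse_mask$voxels > 0L
  if (!any(m)) return(list())
  lab <- cpp_label_components(array(as.integer(m), dim(m)))
  ncomp <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  vox_mm3 <- vox_volume_mm3(coarse_mask)
  keep <- which(sizes * vox_mm3 >= min_volume_mm3)
  if (!length(keep)) return(list())
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  keep <- utils::head(keep, 2)
  d <- dim(m)
  lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    zr <- range(idx[, 1]); cy <- mean(idx[, 2]); cx <- mean(idx[, 3])
    sy <- as.integer(round(cy - roi_xy[1] / 2))   # 0-based start
    sx <- as.integer(round(cx - roi_xy[2] / 2))
    # clamp inside the image when it fits; pad symmetrically when it doesn't
    if (d[2] >= roi_xy[1]) sy <- min(max(sy, 0L), d[2] - roi_xy[1])
    if (d[3] >= roi_xy[2]) sx <- min(max(sx, 0L), d[3] - roi_xy[2])
    roi_box(start = c(zr[1] - 1L, sy, sx),
            stop = c(zr[2], sy + roi_xy[1], sx + roi_xy[2]),
            component_id = k, voxel_count = sizes[k])
  })
}

#' Crop a ROI box out of a volume
#'
#' Zero-padded where the box leaves the image; the geometry log records the
#' placement so [restore_roi()] and [replay_geometry()] are exact inverses
#' on in-image voxels.
#'
#' @param v a [ct_volume()] or [label_volume()] in the working frame.
#' @param box a [roi_box()].
#' @return cropped volume of the same type.
#' @export
crop_roi <- function(v, box) {
  shape <- box$stop - box$start
  out <- extract_box(v$voxels, box$start, shape,
                     fill = if (is_label(v)) 0L else 0)
  rewrap(v, out, log_entry = list(type = "crop", offset = box$start))
}

#' Place a ROI prediction back on the full frame
#'
#' Voxels outside every ROI stay background; overlapping ROIs are resolved
#' by label precedence stone > kidney > background (numeric max).
#'
#' @param pred [label_volume()] on the ROI frame.
#' @param box the [roi_box()] the prediction belongs to.
#' @param canvas either a length-3 full shape (a fresh all-background canvas
#'   is created) or an existing full-frame integer array to overlay onto.
#' @return full-frame integer array of labels.
#' @export
restore_roi <- function(pred, box, canvas) {
  if (is.numeric(canvas) && is.null(dim(canvas)))
    canvas <- array(0L, dim = as.integer(canvas))
  d <- dim(canvas)
  shape <- box$stop - box$start
  if (any(dim(pred$voxels) != shape))
    stop("prediction shape does not match roi_box")
  if (any(box$start >= d))
    stop("roi_box inconsistent with full shape")
  src_lo <- pmax(box$start, 0L); src_hi <- pmin(box$stop, d)
  if (any(src_hi <= src_lo)) return(canvas)
  dst <- lapply(1:3, function(a) (src_lo[a] + 1):src_hi[a])
  insrc <- lapply(1:3, function(a)
    (src_lo[a] - box$start[a] + 1):(src_hi[a] - box$start[a]))
  sub <- pred$voxels[insrc[[1]], insrc[[2]], insrc[[3]], drop = FALSE]
  canvas[dst[[1]], dst[[2]], dst[[3]]] <-
    pmax(canvas[dst[[1]], dst[[2]], dst[[3]]], sub)
  canvas
}

#' Undo a center crop: place a cropped array back on the pre-crop frame
#'
#' @param arr 3D array (cropped frame).
#' @param offset length-2 (y, x) 0-based offset from [center_crop_xy()].
#' @param full_shape length-3 target shape.
#' @param fill background fill value.
#' @return 3D array of shape `full_shape`.
#' @export
uncrop_xy <- function(arr, offset, full_shape, fill = 0L) {
  out <- array(fill, dim = full_shape)
  d <- dim(arr)
  src_lo <- pmax(c(0L, offset), 0L)
  src_hi <- pmin(c(0L, offset) + d, full_shape)
  dst_lo <- src_lo; in_lo <- src_lo - c(0L, offset)
  out[(dst_lo[1] + 1):src_hi[1],
      (dst_lo[2] + 1):src_hi[2],
      (dst_lo[3] + 1):src_hi[3]] <-
    arr[(in_lo[1] + 1):(in_lo[1] + src_hi[1] - src_lo[1]),
        (in_lo[2] + 1):(in_lo[2] + src_hi[2] - src_lo[2]),
        (in_lo[3] + 1):(in_lo[3] + src_hi[3] - src_lo[3])]
  out
}
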