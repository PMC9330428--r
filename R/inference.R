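# Two-stage ("dependent") inference and the one-stage ("independent")
# baseline.
#
# Two-stage: preprocess to the working frame -> stage-1 resize + center
# crop -> z cubes -> coarse kidney scores -> stitch -> argmax -> restore to
# working resolution -> per-kidney ROIs -> stage-2 cubes inside each ROI ->
# fine kidney+stone scores -> stitch -> argmax -> overlay (stone > kidney >
# background) -> resample back to the input grid.

#' Bundle the two trained stages with their geometry
#'
#' @param stage1_net,stage2_net backbones (stage 1: 2 classes; stage 2: 3).
#' @param pipe a [pipeline_geometry()].
#' @param version free-form tag.
#' @return object of class `pipeline_bundle`.
#' @export
pipeline_bundle <- function(stage1_net, stage2_net, pipe, version = "0") {
  k1 <- stage1_net$cpp_cfg$out_classes %||% 2L
  k2 <- stage2_net$cpp_cfg$out_classes %||% 3L
  if (!is.null(stage1_net$cpp_cfg) && k1 != 2L)
    stop("stage-1 backbone must have 2 output classes")
  if (!is.null(stage2_net$cpp_cfg) && k2 != 3L)
    stop("stage-2 backbone must have 3 output classes")
  structure(list(stage1 = stage1_net, stage2 = stage2_net, pipe = pipe,
                 version = version),
            class = "pipeline_bundle")
}

# Run a backbone over a clipped grid and return stitched probabilities.
score_volume <- function(net, vol, spec) {
  grid <- clip_z_cubes(vol, spec)
  scores <- lapply(grid$cubes, function(cb) predict_cube(net, cb, normalize = TRUE))
  stitch_cubes(scores, grid$offsets, grid$source_shape)
}

argmax4 <- function(p) {
  K <- dim(p)[4]
  out <- array(0L, dim(p)[1:3])
  best <- p[, , , 1]
  for (k in 2:K) {
    sel <- p[, , , k] > best
    best[sel] <- p[, , , k][sel]
    out[sel] <- k - 1L
  }
  out
}

#' Two-stage (dependent) segmentation of one CT volume
#'
#' @param v a raw-HU [ct_volume()].
#' @param bundle a [pipeline_bundle()].
#' @return [label_volume()] on the input grid (labels 0/1/2), with
#'   attribute `info`: list with `failed` (stage-1 found no kidney — never
#'   an exception), `n_rois`, and the ROI boxes.
#' @export
segment_case_two_stage <- function(v, bundle) {
  pipe <- bundle$pipe
  pcfg <- pipe$preprocess_cfg
  d_in <- dim(v$voxels)

  w <- preprocess_working(v, pcfg)
  d_work <- dim(w$voxels)

  # ---- stage 1: coarse kidney at reduced resolution ----
  s1 <- resize_xy(w, pcfg$stage1_xy)
  cc <- center_crop_xy(s1, pipe$spec1$crop_xy)
  prob1 <- score_volume(bundle$stage1, cc$volume, pipe$spec1)
  mask_crop <- argmax4(prob1)
  mask_s1 <- uncrop_xy(mask_crop, cc$offset, dim(s1$voxels))
  # restore to working (native in-plane) resolution, nearest neighbor
  mask_work <- resize_xy(label_volume(mask_s1, s1$spacing, v$case_id),
                         d_work[2:3])$voxels

  rois <- find_kidney_rois(label_volume(mask_work, w$spacing, v$case_id),
                           roi_xy = pipe$spec2$crop_xy,
                           min_volume_mm3 = pipe$min_volume_mm3)
  if (!length(rois)) {
    out <- label_volume(array(0L, d_in), v$spacing, v$case_id)
    attr(out, "info") <- list(failed = TRUE, n_rois = 0L, rois = list())
    return(out)
  }

  # ---- stage 2: fine kidney + stone inside each ROI ----
  canvas <- array(0L, d_work)
  for (box in rois) {
    roi_img <- crop_roi(w, box)
    prob2 <- score_volume(bundle$stage2, roi_img, pipe$spec2)
    pred <- argmax4(prob2)
    canvas <- restore_roi(label_volume(pred, w$spacing, v$case_id), box, canvas)
  }

  out_vox <- resample_labels_z(canvas, d_in[1])
  out <- label_volume(out_vox, v$spacing, v$case_id)
  attr(out, "info") <- list(failed = FALSE, n_rois = length(rois), rois = rois)
  out
}

#' One-stage (independent) baseline segmentation
#'
#' A single 3-class network on the stage-1 geometry predicts background,
#' kidney and stone directly; same output frame contract as
#' [segment_case_two_stage()].
#'
#' @param v a raw-HU [ct_volume()].
#' @param net a 3-class backbone.
#' @param pipe a [pipeline_geometry()].
#' @return [label_volume()] on the input grid with an `info` attribute.
#' @export
segment_case_one_stage <- function(v, net, pipe) {
  pcfg <- pipe$preprocess_cfg
  d_in <- dim(v$voxels)
  w <- preprocess_working(v, pcfg)
  d_work <- dim(w$voxels)
  s1 <- resize_xy(w, pcfg$stage1_xy)
  cc <- center_crop_xy(s1, pipe$spec1$crop_xy)
  prob <- score_volume(net, cc$volume, pipe$spec1)
  mask_crop <- argmax4(prob)
  mask_s1 <- uncrop_xy(mask_crop, cc$offset, dim(s1$voxels))
  mask_work <- resize_xy(label_volume(mask_s1, s1$spacing, v$case_id),
                         d_work[2:3])$voxels
  out_vox <- resample_labels_z(mask_work, d_in[1])
  out <- label_volume(out_vox, v$spacing, v$case_id)
  attr(out, "info") <- list(failed = !any(out_vox > 0L), n_rois = NA_integer_,
                            rois = list())
  out
}

# Nearest-neighbor z resampling of an integer label array to a target slice
# count (inverse of the working-frame z harmonization).
resample_labels_z <- function(arr, n_target) {
  n <- dim(arr)[1]
  if (n == n_target) return(arr)
  src <- pmin(pmax(round((seq_len(n_target) - 0.5) * n / n_target + 0.5), 1L), n)
  arr[src, , , drop = FALSE]
}
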