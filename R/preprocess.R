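# Stage-independent CT preprocessing: HU windowing, z-spacing
# harmonization, per-volume min-max normalization, stage-1 in-plane resize,
# and kidney/stone label merging for coarse-stage targets.
#
# Fixed order of operations: window -> resample_z -> normalize ->
# (stage 1 only) resize_xy.  Normalization runs after any interpolation so
# outputs stay in [0, 1].

#' Preprocessing configuration
#'
#' Defaults are the standard unenhanced-CT soft-tissue settings used
#' throughout the pipeline: HU window \[-135, 215\], harmonized z spacing
#' 1.25 mm, stage-1 in-plane size (256, 256).
#'
#' @param hu_low,hu_high window bounds in HU.
#' @param target_z_spacing harmonized z spacing, mm.
#' @param stage1_xy length-2 integer, stage-1 in-plane (y, x) size.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(hu_low = -135, hu_high = 215,
                              target_z_spacing = 1.25, stage1_xy = c(256L, 256L)) {
  if (hu_low >= hu_high) stop("hu_low must be < hu_high")
  if (target_z_spacing <= 0) stop("target_z_spacing must be > 0")
  structure(list(hu_low = hu_low, hu_high = hu_high,
                 target_z_spacing = target_z_spacing,
                 stage1_xy = as.integer(stage1_xy)),
            class = "preprocess_config")
}

#' Clamp HU intensities to the soft-tissue window
#'
#' Total and idempotent: every voxel is clamped to `[hu_low, hu_high]`.
#'
#' @param v a [ct_volume()] in HU.
#' @param cfg a [preprocess_config()].
#' @return windowed `ct_volume`, same shape.
#' @export
window_hu <- function(v, cfg = preprocess_config()) {
  rewrap(v, pmin(pmax(v$voxels, cfg$hu_low), cfg$hu_high))
}

#' Per-volume min-max normalization
#'
#' Maps intensities to \[0, 1\] via `(x - min) / (max - min)`.  A constant
#' volume (max == min, e.g. a blank padding cube) returns all zeros with a
#' warning rather than erroring.
#'
#' @param v a windowed [ct_volume()].
#' @return normalized `ct_volume`.
#' @export
minmax_normalize <- function(v) {
  lo <- min(v$voxels); hi <- max(v$voxels)
  if (hi == lo) {
    warning("constant volume in minmax_normalize; returning all zeros")
    return(rewrap(v, array(0, dim(v$voxels))))
  }
  rewrap(v, (v$voxels - lo) / (hi - lo))
}

#' Harmonize z-axis spacing
#'
#' Resamples along z to `target_z_spacing` (default 1.25 mm).  The new slice
#' count is `round(n * spacing_z / target)`.  Images are interpolated
#' linearly, labels nearest-neighbor (value set preserved).  No-op when the
#' spacing already matches.
#'
#' @param v a [ct_volume()] or [label_volume()].
#' @param cfg a [preprocess_config()].
#' @return resampled volume of the same type.
#' @export
resample_z <- function(v, cfg = preprocess_config()) {
  sp <- v$spacing
  if (sp[1] <= 0) stop("non-positive z spacing")
  tz <- cfg$target_z_spacing
  n <- dim(v$voxels)[1]
  n_new <- max(1L, as.integer(round(n * sp[1] / tz)))
  if (n_new == n && isTRUE(all.equal(sp[1], tz))) return(v)
  f <- n_new / n
  # voxel-center mapping: src = (dst - 0.5) / f + 0.5
  src <- (seq_len(n_new) - 0.5) / f + 0.5
  if (is_label(v)) {
    idx <- pmin(pmax(round(src), 1L), n)
    out <- v$voxels[idx, , , drop = FALSE]
  } else {
    lo <- pmin(pmax(floor(src), 1L), n)
    hi <- pmin(lo + 1L, n)
    w <- pmin(pmax(src - lo, 0), 1)
    out <- v$voxels[lo, , , drop = FALSE] * (1 - w) +
           v$voxels[hi, , , drop = FALSE] * w
  }
  rewrap(v, out, spacing = c(tz, sp[2], sp[3]),
         log_entry = list(type = "scale", factor = c(f, 1, 1)))
}

#' Resize the in-plane (y, x) axes
#'
#' Bilinear for images, nearest-neighbor for labels.  Used to shrink volumes
#' to the stage-1 working size; identity when the shape already matches.
#'
#' @param v a [ct_volume()] or [label_volume()].
#' @param target length-2 integer (y, x) size.
#' @return resized volume of the same type.
#' @export
resize_xy <- function(v, target = c(256L, 256L)) {
  d <- dim(v$voxels)
  ty <- as.integer(target[1]); tx <- as.integer(target[2])
  if (ty == d[2] && tx == d[3]) return(v)
  fy <- ty / d[2]; fx <- tx / d[3]
  if (is_label(v)) {
    iy <- pmin(pmax(round((seq_len(ty) - 0.5) / fy + 0.5), 1L), d[2])
    ix <- pmin(pmax(round((seq_len(tx) - 0.5) / fx + 0.5), 1L), d[3])
    out <- v$voxels[, iy, ix, drop = FALSE]
  } else {
    Ay <- interp_matrix(d[2], ty)
    Ax <- interp_matrix(d[3], tx)
    out <- array(0, c(d[1], ty, tx))
    for (z in seq_len(d[1]))
      out[z, , ] <- Ay %*% v$voxels[z, , ] %*% t(Ax)
  }
  rewrap(v, out, spacing = c(v$spacing[1], v$spacing[2] / fy, v$spacing[3] / fx),
         log_entry = list(type = "scale", factor = c(1, fy, fx)))
}

# Dense 1D linear-interpolation matrix mapping n source samples to m targets
# (voxel-center convention, clamped at the edges).
interp_matrix <- function(n, m) {
  src <- (seq_len(m) - 0.5) / (m / n) + 0.5  # voxel-center mapping
  lo <- pmin(pmax(floor(src), 1L), n)
  hi <- pmin(lo + 1L, n)
  w <- pmin(pmax(src - lo, 0), 1)
  A <- matrix(0, m, n)
  A[cbind(seq_len(m), lo)] <- A[cbind(seq_len(m), lo)] + (1 - w)
  A[cbind(seq_len(m), hi)] <- A[cbind(seq_len(m), hi)] + w
  A
}

#' Merge kidney and stone labels into a single foreground class
#'
#' Stage-1 targets: every nonzero voxel becomes 1.  Foreground voxel count
#' is conserved exactly.
#'
#' @param l a [label_volume()].
#' @return binary `label_volume`.
#' @export
merge_kidney_labels <- function(l) {
  stopifnot(is_label(l))
  rewrap(l, array(as.integer(l$voxels > 0L), dim(l$voxels)))
}

#' Full working-frame preprocessing
#'
#' Applies window -> resample_z -> normalize (native in-plane resolution).
#' This is the frame stage-2 operates in; stage 1 additionally applies
#' [resize_xy()] to `cfg$stage1_xy`.
#'
#' @param v a [ct_volume()] in HU.
#' @param cfg a [preprocess_config()].
#' @return normalized working-frame `ct_volume`.
#' @export
preprocess_working <- function(v, cfg = preprocess_config()) {
  minmax_normalize(resample_z(window_hu(v, cfg), cfg))
}
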