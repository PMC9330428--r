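#' @useDynLib nephroseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd
#' @importFrom utils read.csv write.csv modifyList
NULL

# Internal axis convention: every volume array has dim (z, y, x).  All
# geometry code in the package assumes this order; "horizontal" flips act on
# the last (x) axis.

#' CT volume container
#'
#' A 3D scalar image (Hounsfield units, or normalized units after
#' preprocessing) plus per-axis voxel spacing and a geometry log recording
#' every crop/pad/resample applied, so that any internal voxel coordinate can
#' be mapped back to the original frame.
#'
#' @param voxels numeric 3D array, dim order (z, y, x).
#' @param spacing numeric length-3, voxel size in mm per (z, y, x) axis.
#' @param case_id opaque identifier string.
#' @param geometry_log list of geometry operations (internal format; see
#'   [replay_geometry()]).
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, case_id = "case", geometry_log = list()) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (z, y, x)")
  structure(list(voxels = voxels, spacing = spacing, case_id = case_id,
                 geometry_log = geometry_log),
            class = "ct_volume")
}

#' Label volume container
#'
#' Integer mask aligned to a [ct_volume()]: 0 background, 1 kidney, 2 stone.
#'
#' @inheritParams ct_volume
#' @return object of class `label_volume` (also inherits `ct_volume`).
#' @export
label_volume <- function(voxels, spacing, case_id = "case", geometry_log = list()) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  vals <- unique(as.vector(voxels))
  if (!all(vals %in% c(0, 1, 2)))
    stop("label values must be within {0, 1, 2}; found: ",
         paste(utils::head(setdiff(vals, 0:2), 5), collapse = ", "))
  storage.mode(voxels) <- "integer"
  v <- ct_volume(voxels, spacing, case_id, geometry_log)
  class(v) <- c("label_volume", "ct_volume")
  v
}

is_label <- function(v) inherits(v, "label_volume")

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<%s> %s  dim (z,y,x) = %d x %d x %d  spacing = %.3f/%.3f/%.3f mm  [%d geometry ops]\n",
              class(x)[1], x$case_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3], length(x$geometry_log)))
  invisible(x)
}

# Rebuild a volume around new voxels, keeping metadata, appending a geometry
# record. Used by every geometry-editing operation.
rewrap <- function(v, voxels, spacing = v$spacing, log_entry = NULL) {
  gl <- v$geometry_log
  if (!is.null(log_entry)) gl <- c(gl, list(log_entry))
  if (is_label(v)) {
    storage.mode(voxels) <- "integer"
    out <- v
    out$voxels <- voxels
    out$spacing <- spacing
    out$geometry_log <- gl
    out
  } else {
    out <- v
    out$voxels <- voxels
    out$spacing <- spacing
    out$geometry_log <- gl
    out
  }
}

vox_volume_mm3 <- function(v) prod(v$spacing)

#' Map internal voxel coordinates back to the original frame
#'
#' Replays the geometry log in reverse, composing the per-axis affine maps
#' recorded by crops, pads, resamplings and resizes, and returns continuous
#' (z, y, x) coordinates in the frame of the volume as it was first created
#' or read.
#'
#' @param v a `ct_volume` / `label_volume`.
#' @param zyx numeric matrix (n x 3) or length-3 vector of 1-based voxel
#'   coordinates in the current frame.
#' @return numeric matrix (n x 3) of coordinates in the original frame.
#' @export
replay_geometry <- function(v, zyx) {
  if (is.null(dim(zyx))) zyx <- matrix(zyx, nrow = 1)
  co <- zyx
  for (op in rev(v$geometry_log)) {
    co <- switch(op$type,
      crop = sweep(co, 2, op$offset, "+"),
      scale = {
        # voxel-center convention: new = (old - 0.5) * factor + 0.5
        for (ax in 1:3) co[, ax] <- (co[, ax] - 0.5) / op$factor[ax] + 0.5
        co
      },
      reorient = {
        # op$perm maps original axes -> current axes; op$flip acts in current
        out <- co
        for (ax in 1:3) {
          val <- co[, ax]
          if (op$flip[ax]) val <- op$dim[ax] + 1 - val
          out[, op$perm[ax]] <- val
        }
        out
      },
      co)
  }
  co
}
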