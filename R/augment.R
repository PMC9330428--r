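# Labeled-cube augmentation: random in-plane affine rotation (0 +/- 10
# degrees), horizontal inversion (probability 1 within its modes), and their
# composition.  Image and label always receive the identical spatial
# transform; images are interpolated linearly, labels nearest-neighbor.

#' Augmentation policy
#'
#' @param affine_angle_deg maximum absolute rotation angle; draws are
#'   uniform on `[-a, a]` (default 10).
#' @param flip_axis which internal axis "horizontal" refers to; `"x"`
#'   (default) or `"y"`.
#' @param on_the_fly if `TRUE` (default) training applies one randomly
#'   chosen variant per labeled cube per epoch; if `FALSE` the expanded
#'   four-variant set is materialized via [make_augmented_set()].
#' @param seed integer seed used when the policy drives a materialized set.
#' @return object of class `augment_policy`.
#' @export
augment_policy <- function(affine_angle_deg = 10, flip_axis = "x",
                           on_the_fly = TRUE, seed = 1L) {
  stopifnot(affine_angle_deg >= 0, flip_axis %in% c("x", "y"))
  structure(list(modes = c("affine", "hflip", "hflip_affine"),
                 affine_angle_deg = affine_angle_deg, flip_axis = flip_axis,
                 on_the_fly = on_the_fly, seed = as.integer(seed)),
            class = "augment_policy")
}

#' Horizontal inversion of an image/label cube pair
#'
#' Mirrors both cubes along the chosen axis (default internal x).  An exact
#' involution; label voxel counts per class are unchanged.
#'
#' @param image,label 3D arrays, dim (z, y, x); `label` may be `NULL`.
#' @param axis `"x"` or `"y"`.
#' @return list with `image` and `label`.
#' @export
hflip <- function(image, label = NULL, axis = "x") {
  fl <- function(a) {
    if (is.null(a)) return(NULL)
    d <- dim(a)
    if (axis == "x") a[, , d[3]:1, drop = FALSE] else a[, d[2]:1, , drop = FALSE]
  }
  list(image = fl(image), label = fl(label))
}

#' Random in-plane affine rotation of an image/label cube pair
#'
#' Rotates every z slice by the same angle about the slice center; image
#' bilinear, label nearest-neighbor, edges zero-filled.  The angle is either
#' supplied (`angle_deg`) or drawn uniformly from `[-max, +max]` under
#' `seed`, making the call deterministic.
#'
#' @param image,label 3D arrays (z, y, x); `label` may be `NULL`.
#' @param angle_deg fixed angle; if `NULL`, drawn under `seed`.
#' @param max_angle_deg bound for the random draw.
#' @param seed integer seed for the draw (ignored when `angle_deg` given).
#' @return list with `image`, `label`, `angle_deg`.
#' @export
random_affine <- function(image, label = NULL, angle_deg = NULL,
                          max_angle_deg = 10, seed = 1L) {
  if (is.null(angle_deg)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    angle_deg <- runif(1, -max_angle_deg, max_angle_deg)
  }
  if (abs(angle_deg) > max_angle_deg + 1e-9)
    stop("|angle| must be <= ", max_angle_deg, " degrees")
  if (angle_deg == 0) return(list(image = image, label = label, angle_deg = 0))

  d <- dim(image)
  th <- angle_deg * pi / 180
  cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
  # destination grid -> source coordinates (inverse rotation)
  gy <- rep(seq_len(d[2]), times = d[3]) - cy
  gx <- rep(seq_len(d[3]), each = d[2]) - cx
  sy <- cos(th) * gy + sin(th) * gx + cy
  sx <- -sin(th) * gy + cos(th) * gx + cx

  rot_lin <- function(a) {
    y0 <- floor(sy); x0 <- floor(sx)
    wy <- sy - y0; wx <- sx - x0
    out <- array(0, d)
    ok <- function(yy, xx) yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    cells <- list(list(y0, x0, (1 - wy) * (1 - wx)),
                  list(y0 + 1, x0, wy * (1 - wx)),
                  list(y0, x0 + 1, (1 - wy) * wx),
                  list(y0 + 1, x0 + 1, wy * wx))
    for (z in seq_len(d[1])) {
      sl <- a[z, , ]
      acc <- numeric(d[2] * d[3])
      for (cl in cells) {
        m <- ok(cl[[1]], cl[[2]])
        if (any(m))
          acc[m] <- acc[m] + cl[[3]][m] * sl[cbind(cl[[1]][m], cl[[2]][m])]
      }
      out[z, , ] <- acc
    }
    out
  }
  rot_nn <- function(a) {
    yn <- round(sy); xn <- round(sx)
    m <- yn >= 1 & yn <= d[2] & xn >= 1 & xn <= d[3]
    out <- array(0L, d)
    for (z in seq_len(d[1])) {
      sl <- a[z, , ]
      acc <- integer(d[2] * d[3])
      acc[m] <- sl[cbind(yn[m], xn[m])]
      out[z, , ] <- acc
    }
    out
  }
  list(image = rot_lin(image),
       label = if (is.null(label)) NULL else rot_nn(label),
       angle_deg = angle_deg)
}

# Apply one named augmentation mode to a cube pair.
apply_augment_mode <- function(image, label, mode, policy, seed) {
  if (mode == "none") return(list(image = image, label = label))
  out <- list(image = image, label = label)
  if (mode %in% c("hflip", "hflip_affine"))
    out <- hflip(out$image, out$label, axis = policy$flip_axis)
  if (mode %in% c("affine", "hflip_affine")) {
    r <- random_affine(out$image, out$label,
                       max_angle_deg = policy$affine_angle_deg, seed = seed)
    out <- list(image = r$image, label = r$label)
  }
  out
}

#' Expand labeled cubes with the three augmentation modes
#'
#' Each labeled cube (>= 1 foreground voxel) yields the original plus three
#' variants (affine, hflip, hflip+affine); unlabeled cubes pass through
#' unchanged, so the output count is `n_labeled * 4 + n_unlabeled`.
#'
#' @param cubes list of `list(image=, label=)` cube pairs.
#' @param policy an [augment_policy()].
#' @return expanded list of cube pairs; each element gains an `augmented`
#'   field naming the mode applied.
#' @export
make_augmented_set <- function(cubes, policy = augment_policy()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(policy$seed)
  out <- list()
  for (cb in cubes) {
    labeled <- !is.null(cb$label) && any(cb$label > 0L)
    cb$augmented <- "none"
    out[[length(out) + 1]] <- cb
    if (!labeled) next
    for (mode in policy$modes) {
      sd_ <- sample.int(2^30, 1)
      a <- apply_augment_mode(cb$image, cb$label, mode, policy, sd_)
      out[[length(out) + 1]] <- list(image = a$image, label = a$label,
                                     augmented = mode)
    }
  }
  out
}
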