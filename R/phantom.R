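# Synthetic abdominal-CT phantom generator.
#
# The phantoms emulate the geometry the two-stage pipeline exercises on real
# unenhanced CT: a soft-tissue body oval surrounded by air, two kidney-like
# ellipsoids at lateral offsets from the midline, and 0..n hyperdense
# spherical stones strictly inside the kidneys.  The "paper" profile mirrors
# the source dataset dimensions (512 x 512 in-plane, anisotropic spacing);
# the "desk" profile is the CI-sized stated world used by the test suite.

#' Phantom specification
#'
#' @param shape integer length-3, voxel counts (z, y, x); each >= 16.
#' @param spacing numeric length-3, voxel size mm (z, y, x).
#' @param kidney_axes_mm list with `z`, `y`, `x`: each a length-2 range (mm)
#'   for the ellipsoid semi-axes.
#' @param kidney_offset_mm lateral distance of each kidney center from the
#'   body midline, mm.
#' @param kidney_hu,background_hu,stone_hu,air_hu mean HU of kidney tissue,
#'   surrounding (retroperitoneal fat-like) tissue, stones, and air.
#' @param stone_diameters_mm numeric vector of requested stone diameters
#'   (mm); may be empty.
#' @param noise_sd_hu standard deviation of additive Gaussian HU noise.
#' @param n_distractors number of extra soft-tissue blobs outside the
#'   kidneys (background clutter); 0 by default.
#' @param seed integer seed; the generator is a pure function of spec + seed.
#' @param profile `"desk"` (default) or `"paper"`; sets the default shape,
#'   spacing and kidney size to the CI-sized or dataset-sized world.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(profile = c("desk", "paper"),
                         shape = NULL, spacing = NULL,
                         kidney_axes_mm = NULL, kidney_offset_mm = NULL,
                         kidney_hu = 35, background_hu = -80, stone_hu = 600,
                         air_hu = -1000, stone_diameters_mm = c(3, 6, 9),
                         noise_sd_hu = 10, n_distractors = 0, seed = 1L) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    if (is.null(shape)) shape <- c(64L, 96L, 96L)
    if (is.null(spacing)) spacing <- c(1.25, 1.0, 1.0)
    if (is.null(kidney_axes_mm))
      kidney_axes_mm <- list(z = c(14, 18), y = c(10, 13), x = c(10, 13))
    if (is.null(kidney_offset_mm)) kidney_offset_mm <- 16
  } else {
    if (is.null(shape)) shape <- c(120L, 512L, 512L)
    if (is.null(spacing)) spacing <- c(1.25, 0.7, 0.7)
    if (is.null(kidney_axes_mm))
      kidney_axes_mm <- list(z = c(40, 55), y = c(22, 32), x = c(22, 32))
    if (is.null(kidney_offset_mm)) kidney_offset_mm <- 60
  }
  spec <- structure(list(
    shape = as.integer(shape), spacing = as.numeric(spacing),
    kidney_axes_mm = kidney_axes_mm, kidney_offset_mm = kidney_offset_mm,
    kidney_hu = kidney_hu, background_hu = background_hu,
    stone_hu = stone_hu, air_hu = air_hu,
    stone_diameters_mm = as.numeric(stone_diameters_mm),
    noise_sd_hu = noise_sd_hu, n_distractors = as.integer(n_distractors),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$shape < 16L)) stop("all shape components must be >= 16")
  if (any(spec$spacing <= 0)) stop("all spacing components must be > 0")
  if (length(spec$stone_diameters_mm) && any(spec$stone_diameters_mm <= 0))
    stop("all stone diameters must be > 0")
  if (spec$stone_hu <= spec$kidney_hu)
    stop("stone_hu must exceed kidney_hu (stones are hyperdense on unenhanced CT)")
  if (spec$noise_sd_hu < 0) stop("noise_sd_hu must be >= 0")
  invisible(spec)
}

# Voxel-center physical coordinates along one axis, mm.
axis_mm <- function(n, sp) (seq_len(n) - 0.5) * sp

#' Generate one labeled phantom
#'
#' Builds the HU image (tissue means + Gaussian noise), the label volume
#' (0 background, 1 kidney, 2 stone), and a ground-truth record per stone and
#' per kidney.  Identical spec + seed give bit-identical output.  Stones are
#' rasterized spheres on the voxel grid; their truth volume is voxel count x
#' voxel volume (not the analytic sphere volume), and their size class is
#' derived from that rasterized volume via [classify_stone_size()].
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` ([ct_volume()]), `label` ([label_volume()]) and
#'   `truth` (list with `stones` and `kidneys` data frames).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  d <- spec$shape; sp <- spec$spacing
  zmm <- axis_mm(d[1], sp[1]); ymm <- axis_mm(d[2], sp[2]); xmm <- axis_mm(d[3], sp[3])
  ext <- c(d[1] * sp[1], d[2] * sp[2], d[3] * sp[3])

  img <- array(spec$air_hu, dim = d)
  lab <- array(0L, dim = d)

  # body: elliptic cylinder filling most of the in-plane field of view
  by <- 0.46 * ext[2]; bx <- 0.48 * ext[3]
  yc <- ext[2] / 2; xc <- ext[3] / 2
  body2d <- outer(((ymm - yc) / by)^2, ((xmm - xc) / bx)^2, "+") <= 1
  body <- aperm(array(body2d, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  img[body] <- spec$background_hu

  # two kidneys: axis-aligned ellipsoids left/right of the midline; jitter
  # draws are retried until the pair is disjoint (deterministic per seed)
  kid <- vector("list", 2)
  kcent <- matrix(0, 2, 3); kax <- matrix(0, 2, 3)
  for (attempt in 1:50) {
    for (k in 1:2) {
      ax <- c(runif(1, spec$kidney_axes_mm$z[1], spec$kidney_axes_mm$z[2]),
              runif(1, spec$kidney_axes_mm$y[1], spec$kidney_axes_mm$y[2]),
              runif(1, spec$kidney_axes_mm$x[1], spec$kidney_axes_mm$x[2]))
      side <- if (k == 1) -1 else 1
      cen <- c(ext[1] / 2 + runif(1, -2, 2) * sp[1],
               yc + runif(1, -3, 3),
               xc + side * spec$kidney_offset_mm + runif(1, -2, 2))
      kid[[k]] <- ellipsoid_mask(zmm, ymm, xmm, cen, ax)
      kcent[k, ] <- cen; kax[k, ] <- ax
    }
    if (!any(kid[[1]] & kid[[2]])) break
    if (attempt == 50)
      stop("cannot place disjoint kidneys; widen kidney_offset_mm or shrink kidney_axes_mm")
  }
  for (k in 1:2) {
    img[kid[[k]]] <- spec$kidney_hu
    lab[kid[[k]]] <- 1L
  }

  # optional distractor blobs in the body, never touching kidneys
  if (spec$n_distractors > 0) {
    for (i in seq_len(spec$n_distractors)) {
      r <- runif(1, 4, 8)
      cen <- c(runif(1, r, ext[1] - r), yc + runif(1, -0.3, 0.3) * by,
               xc + runif(1, -0.3, 0.3) * bx)
      m <- ellipsoid_mask(zmm, ymm, xmm, cen, rep(r, 3))
      m <- m & body & lab == 0L
      img[m] <- spec$kidney_hu + runif(1, -15, 15)
    }
  }

  # stones: rasterized spheres strictly inside a kidney, pairwise separated
  # by at least one voxel so each remains its own 26-connected component
  # (required for truth/inventory agreement)
  stones <- list()
  occupied <- array(FALSE, dim = d)   # stones inflated by one voxel margin
  for (i in seq_along(spec$stone_diameters_mm)) {
    dia <- spec$stone_diameters_mm[i]
    r <- dia / 2
    placed <- FALSE
    for (attempt in 1:200) {
      k <- sample.int(2, 1)
      # admissible centers: inside the ellipsoid shrunk by r + half max voxel
      margin <- r + max(sp) / 2
      shr <- kax[k, ] - margin
      if (any(shr <= 0)) next
      u <- runif(3, -1, 1)
      if (sum(u^2) > 1) next
      cen <- kcent[k, ] + u * shr
      m <- ellipsoid_mask(zmm, ymm, xmm, cen, rep(r, 3))
      if (!any(m)) next                      # sphere smaller than a voxel at this spot
      if (any(m & !kid[[k]])) next           # must be strictly inside the kidney
      if (any(m & occupied)) next            # keep a gap to earlier stones
      occupied <- occupied |
        ellipsoid_mask(zmm, ymm, xmm, cen, r + 2 * sp)  # 2-voxel exclusion margin
      img[m] <- spec$stone_hu
      lab[m] <- 2L
      cenvox <- round((cen / sp) + 0.5)
      stones[[length(stones) + 1]] <- data.frame(
        stone_id = length(stones) + 1L,
        center_z = cenvox[1], center_y = cenvox[2], center_x = cenvox[3],
        diameter_mm = dia, voxel_count = sum(m),
        volume_mm3 = sum(m) * prod(sp), kidney = k)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("stone %d (diameter %.1f mm) does not fit inside a kidney for this spec",
                   i, dia))
  }

  if (spec$noise_sd_hu > 0)
    img <- img + array(rnorm(prod(d), 0, spec$noise_sd_hu), dim = d)

  st <- if (length(stones)) do.call(rbind, stones) else
    data.frame(stone_id = integer(), center_z = numeric(), center_y = numeric(),
               center_x = numeric(), diameter_mm = numeric(), voxel_count = integer(),
               volume_mm3 = numeric(), kidney = integer())
  if (nrow(st)) st$size_class <- classify_stone_size(st$volume_mm3)
  else st$size_class <- character()

  kd <- data.frame(kidney = 1:2,
                   centroid_z = kcent[, 1] / sp[1] + 0.5,
                   centroid_y = kcent[, 2] / sp[2] + 0.5,
                   centroid_x = kcent[, 3] / sp[3] + 0.5,
                   voxel_count = c(sum(kid[[1]]), sum(kid[[2]])))

  cid <- sprintf("phantom_%06d", spec$seed)
  list(image = ct_volume(img, sp, cid),
       label = label_volume(lab, sp, cid),
       truth = list(stones = st, kidneys = kd))
}

ellipsoid_mask <- function(zmm, ymm, xmm, center, semi) {
  dz2 <- ((zmm - center[1]) / semi[1])^2
  dy2 <- ((ymm - center[2]) / semi[2])^2
  dx2 <- ((xmm - center[3]) / semi[3])^2
  # outer sum over three axes, laid out (z, y, x)
  plane <- outer(dy2, dx2, "+")
  arr <- outer(dz2, plane, "+")
  arr <= 1
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a seeded cohort of phantoms
#'
#' Draws `n_cases` independent phantoms from ranges over the spec fields.
#' Stone-free cases (mirroring scans without stones in a clinical cohort) are
#' allocated deterministically: `round(stone_free_fraction * n_cases)` cases,
#' chosen as a seeded subset, receive no stones.
#'
#' @param n_cases number of phantoms (>= 1).
#' @param base a [phantom_spec()] providing all fixed fields.
#' @param stone_count_range integer range (length 2) of stones per
#'   stone-bearing case; per-case count drawn uniformly.
#' @param diameter_range_mm numeric length-2; per-stone diameters drawn
#'   uniformly from this range.
#' @param stone_free_fraction optional fraction in \[0,1\]; if `NULL`, cases
#'   with zero stones arise only when `stone_count_range` includes 0.
#' @param seed cohort seed; case seeds are derived from it.
#' @return list with `cases` (list of [generate_phantom()] outputs) and
#'   `truth` (data frame, one row per stone across the cohort).
#' @export
generate_cohort <- function(n_cases, base = phantom_spec(),
                            stone_count_range = c(1L, 3L),
                            diameter_range_mm = c(3, 9),
                            stone_free_fraction = NULL, seed = 1L) {
  if (n_cases < 1) stop("n_cases must be >= 1")
  if (length(stone_count_range) != 2L || any(stone_count_range < 0) ||
      stone_count_range[1] > stone_count_range[2])
    stop("stone_count_range must be a non-empty non-negative range")
  if (diameter_range_mm[1] > diameter_range_mm[2] || diameter_range_mm[1] <= 0)
    stop("diameter_range_mm must be a positive non-empty range")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  free <- rep(FALSE, n_cases)
  if (!is.null(stone_free_fraction)) {
    nf <- round(stone_free_fraction * n_cases)
    if (nf > 0) free[sample.int(n_cases, nf)] <- TRUE
  }
  case_seeds <- sample.int(2^30, n_cases)
  counts <- sample(seq(stone_count_range[1], stone_count_range[2]),
                   n_cases, replace = TRUE)
  dias <- lapply(seq_len(n_cases), function(i) {
    if (free[i] || counts[i] == 0) numeric(0)
    else round(runif(counts[i], diameter_range_mm[1], diameter_range_mm[2]), 1)
  })

  cases <- vector("list", n_cases)
  rows <- list()
  for (i in seq_len(n_cases)) {
    spec_i <- base
    spec_i$stone_diameters_mm <- dias[[i]]
    spec_i$seed <- case_seeds[i]
    cases[[i]] <- generate_phantom(spec_i)
    st <- cases[[i]]$truth$stones
    if (nrow(st)) {
      st$case_id <- cases[[i]]$image$case_id
      rows[[length(rows) + 1]] <- st
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    cbind(cases[[1]]$truth$stones[0, ], case_id = character())
  list(cases = cases, truth = truth)
}

#' Write a cohort to disk as NIfTI pairs plus a truth CSV
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return invisibly, a data frame listing the files written.
#' @export
write_cohort <- function(cohort, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  files <- lapply(cohort$cases, function(cs) {
    ip <- file.path(dir, paste0(cs$image$case_id, "_image", ext))
    lp <- file.path(dir, paste0(cs$image$case_id, "_label", ext))
    write_volume(cs$image, ip, dtype_policy = "int16")
    write_volume(cs$label, lp)
    data.frame(case_id = cs$image$case_id, image = ip, label = lp)
  })
  files <- do.call(rbind, files)
  tt <- cohort$truth
  cols <- c("case_id", "center_z", "center_y", "center_x",
            "diameter_mm", "volume_mm3", "size_class")
  write.csv(tt[, intersect(cols, names(tt)), drop = FALSE],
            file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(files)
}
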