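# Training recipe: case-level 7:3 split with k-fold cross-validation,
# AdamW (decoupled weight decay on conv weights), ReduceLROnPlateau on the
# validation loss, combined soft-Dice + cross-entropy objective, best model
# by minimum validation loss.

#' Training configuration
#'
#' Defaults are the at-scale recipe: 200 epochs, AdamW, batch 8, initial
#' learning rate 0.001, weight decay 0.001, ReduceLROnPlateau, 7:3
#' train/test split with 5-fold cross-validation.  The desk profile (see
#' [default_config()]) shrinks epochs and batch for CPU-scale runs.
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size cubes per optimizer step (gradient accumulation).
#' @param lr initial learning rate.
#' @param weight_decay decoupled weight decay applied to conv weights.
#' @param folds cross-validation folds (>= 2).
#' @param test_fraction held-out fraction (0.3 = the 7:3 split).
#' @param plateau_factor,plateau_patience,min_lr ReduceLROnPlateau settings.
#' @param val_fraction fraction of training cases used for validation when
#'   no explicit fold is supplied to [train_stage()].
#' @param seed training seed.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 8L, lr = 1e-3,
                         weight_decay = 1e-3, folds = 5L, test_fraction = 0.3,
                         plateau_factor = 0.1, plateau_patience = 10L,
                         min_lr = 1e-5, val_fraction = 0.2, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  if (folds < 2) stop("folds must be >= 2")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, folds = as.integer(folds),
                 test_fraction = test_fraction, plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience), min_lr = min_lr,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Case-level train/test split with cross-validation folds
#'
#' The held-out test set is `round(test_fraction * n)` cases; the remaining
#' pool is partitioned into `folds` validation folds.  The split is always
#' at case level (never cube level), so no case can leak cubes across sets.
#'
#' @param case_ids vector of case identifiers.
#' @param test_fraction held-out fraction (default 0.3).
#' @param folds number of folds (default 5).
#' @param seed split seed.
#' @return list with `test` (ids) and `folds` — a list of
#'   `list(train=, val=)` id vectors partitioning the training pool.
#' @export
split_cases <- function(case_ids, test_fraction = 0.3, folds = 5L, seed = 1L) {
  n <- length(case_ids)
  if (n < folds + 1) stop("need at least folds + 1 cases, got ", n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample(case_ids)
  n_test <- round(test_fraction * n)
  test <- perm[seq_len(n_test)]
  pool <- perm[setdiff(seq_len(n), seq_len(n_test))]
  fold_id <- rep_len(seq_len(folds), length(pool))
  fl <- lapply(seq_len(folds), function(f)
    list(train = pool[fold_id != f], val = pool[fold_id == f]))
  list(test = test, folds = fl, pool = pool)
}

# ---- AdamW ----

adamw_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(opt, params, grads, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (k in names(params)) {
    g <- grads[[k]]
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g^2
    mh <- opt$m[[k]] / bc1
    vh <- opt$v[[k]] / bc2
    wd <- if (grepl("\\.W$", k)) weight_decay else 0
    params[[k]] <- params[[k]] - lr * (mh / (sqrt(vh) + eps) + wd * params[[k]])
  }
  list(opt = opt, params = params)
}

# ---- cube dataset construction ----

# Stage-1 cubes for one case: working frame -> stage-1 resize -> merged
# labels -> center crop -> z cubes.  With merge = FALSE this doubles as the
# dataset of the one-stage (independent) baseline: same geometry, 3-class
# targets.
stage1_case_cubes <- function(case, cfg, merge = TRUE) {
  pcfg <- cfg$preprocess_cfg
  spec <- cfg$spec1
  w <- preprocess_working(case$image, pcfg)
  wl <- resample_z(case$label, pcfg)
  s1i <- resize_xy(w, pcfg$stage1_xy)
  s1l <- resize_xy(wl, pcfg$stage1_xy)
  if (merge) s1l <- merge_kidney_labels(s1l)
  ci <- center_crop_xy(s1i, spec$crop_xy)$volume
  cl <- center_crop_xy(s1l, spec$crop_xy)$volume
  gi <- clip_z_cubes(ci, spec)
  gl <- clip_z_cubes(cl, spec)
  lapply(seq_along(gi$cubes), function(i)
    list(image = gi$cubes[[i]], label = gl$cubes[[i]],
         labeled = any(gl$cubes[[i]] > 0L)))
}

# Stage-2 cubes for one case: ground-truth kidney ROIs from the working
# frame (training-time decision; inference uses stage-1 predicted ROIs).
stage2_case_cubes <- function(case, cfg) {
  pcfg <- cfg$preprocess_cfg
  spec <- cfg$spec2
  w <- preprocess_working(case$image, pcfg)
  wl <- resample_z(case$label, pcfg)
  rois <- find_kidney_rois(merge_kidney_labels(wl), roi_xy = spec$crop_xy,
                           min_volume_mm3 = cfg$min_volume_mm3)
  out <- list()
  for (box in rois) {
    ri <- crop_roi(w, box)
    rl <- crop_roi(wl, box)
    gi <- clip_z_cubes(ri, spec)
    gl <- clip_z_cubes(rl, spec)
    for (i in seq_along(gi$cubes))
      out[[length(out) + 1]] <- list(image = gi$cubes[[i]],
                                     label = gl$cubes[[i]],
                                     labeled = any(gl$cubes[[i]] > 0L))
  }
  out
}

build_stage_dataset <- function(stage, cases, cfg) {
  fn <- if (identical(stage, "one"))
    function(case, cfg) stage1_case_cubes(case, cfg, merge = FALSE)
  else if (stage == 1) stage1_case_cubes
  else stage2_case_cubes
  unlist(lapply(cases, fn, cfg = cfg), recursive = FALSE)
}

#' Train one segmentation stage
#'
#' Builds the per-stage cube dataset (stage 1: merged-label coarse targets
#' at the stage-1 working geometry; stage 2: three-class targets inside
#' ground-truth kidney ROIs), then optimizes the backbone with AdamW on the
#' combined soft-Dice + cross-entropy loss, applying on-the-fly labeled-cube
#' augmentation, and returns the checkpoint with minimal validation loss
#' plus the per-epoch loss history.
#'
#' @param stage 1 (coarse kidney), 2 (fine kidney + stone), or `"one"` (the
#'   independent one-stage baseline: stage-1 geometry, 3 classes).
#' @param cases list of `list(image=, label=)` volumes (e.g. phantom cohort
#'   cases).
#' @param train_idx,val_idx integer indices into `cases`.
#' @param backbone_cfg a [backbone_config()] (out_classes forced to the
#'   stage's class count).
#' @param tcfg a [train_config()].
#' @param pipe pipeline geometry: list with `preprocess_cfg`, `spec1`,
#'   `spec2`, `min_volume_mm3` (see [pipeline_geometry()]).
#' @param augment an [augment_policy()] or `NULL` to disable augmentation.
#' @param verbose print per-epoch losses.
#' @return list with `net` (best backbone), `history` (data frame epoch /
#'   train_loss / val_loss / lr), `best_epoch`.
#' @export
train_stage <- function(stage, cases, train_idx, val_idx, backbone_cfg, tcfg,
                        pipe, augment = augment_policy(), verbose = FALSE) {
  backbone_cfg$out_classes <- if (identical(stage, 1) || identical(stage, 1L)) 2L else 3L
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(tcfg$seed)

  train_data <- build_stage_dataset(stage, cases[train_idx], pipe)
  val_data <- build_stage_dataset(stage, cases[val_idx], pipe)
  if (!length(train_data)) stop("empty training set")
  cube_dim <- dim(train_data[[1]]$image)
  check_divisible(cube_dim, backbone_cfg$depth)

  net <- build_backbone(backbone_cfg, seed = sample.int(2^30, 1))
  if (is.null(net$params)) stop("backbone '", backbone_cfg$name, "' is not trainable")
  opt <- adamw_init(net$params)
  lr <- tcfg$lr
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  best <- list(val = Inf, params = net$params, state = net$state, epoch = 0L)
  bad_epochs <- 0L

  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample(length(train_data))
    ep_loss <- 0
    acc <- NULL; acc_n <- 0L
    for (j in ord) {
      cb <- train_data[[j]]
      img <- cb$image; lb <- cb$label
      if (!is.null(augment) && cb$labeled) {
        mode <- sample(c("none", augment$modes), 1)
        if (mode != "none") {
          a <- apply_augment_mode(img, lb, mode, augment, sample.int(2^30, 1))
          img <- a$image; lb <- a$label
        }
      }
      g <- cpp_net_grad(img, as.integer(lb), net$params, net$state, net$cpp_cfg)
      net$state <- g$state
      ep_loss <- ep_loss + g$loss
      acc <- if (is.null(acc)) g$grads
             else mapply(`+`, acc, g$grads, SIMPLIFY = FALSE)
      acc_n <- acc_n + 1L
      if (acc_n >= tcfg$batch_size || j == ord[length(ord)]) {
        acc <- lapply(acc, function(x) x / acc_n)
        st <- adamw_step(opt, net$params, acc, lr, tcfg$weight_decay)
        opt <- st$opt; net$params <- st$params
        acc <- NULL; acc_n <- 0L
      }
    }
    ep_loss <- ep_loss / length(train_data)

    val_loss <- if (length(val_data)) {
      mean(vapply(val_data, function(cb)
        cpp_net_loss(cb$image, as.integer(cb$label), net$params, net$state,
                     net$cpp_cfg)$loss, numeric(1)))
    } else ep_loss
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_loss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("stage %d epoch %3d  train %.4f  val %.4f  lr %.2e",
                      stage, epoch, ep_loss, val_loss, lr))
    if (!is.finite(ep_loss) || !is.finite(val_loss))
      stop("non-finite loss at epoch ", epoch)

    if (val_loss < best$val - 1e-9) {
      best <- list(val = val_loss, params = net$params, state = net$state,
                   epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= tcfg$plateau_patience) {
        lr <- max(lr * tcfg$plateau_factor, tcfg$min_lr)
        bad_epochs <- 0L
      }
    }
  }
  net$params <- best$params
  net$state <- best$state
  list(net = net, history = hist, best_epoch = best$epoch)
}
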