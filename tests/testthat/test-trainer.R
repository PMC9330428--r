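test_that("split_cases follows the 7:3 arithmetic at case level", {
  sp <- split_cases(sprintf("c%03d", 1:260), seed = 1)
  expect_length(sp$test, 78L)               # round(0.3 * 260)
  expect_length(sp$pool, 182L)
  sp10 <- split_cases(paste0("c", 1:10), seed = 2)
  expect_length(sp10$test, 3L)
  expect_length(sp10$pool, 7L)
  expect_error(split_cases(paste0("c", 1:4), folds = 5), "folds \\+ 1")
})

test_that("folds partition the training pool with no overlap or leakage", {
  ids <- sprintf("case%02d", 1:23)
  for (seed in 1:3) {
    sp <- split_cases(ids, folds = 5, seed = seed)
    expect_length(intersect(sp$test, sp$pool), 0L)
    expect_setequal(c(sp$test, sp$pool), ids)
    all_val <- unlist(lapply(sp$folds, `[[`, "val"))
    expect_setequal(all_val, sp$pool)       # vals partition the pool
    expect_equal(anyDuplicated(all_val), 0L)
    for (f in sp$folds) {
      expect_length(intersect(f$train, f$val), 0L)
      expect_setequal(c(f$train, f$val), sp$pool)
      expect_length(intersect(f$val, sp$test), 0L)
    }
  }
})

test_that("train_config and backbone_config validate their invariants", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(lr = 0), "lr")
  expect_error(train_config(folds = 1), "folds")
  expect_error(backbone_config(out_classes = 4), "out_classes")
})

test_that("a short training run learns, selects by validation loss, and is reproducible", {
  setup <- tiny_experiment_setup(epochs = 3L)
  obj <- nephroseg:::config_objects(setup$config)
  cohort <- generate_cohort(5, base = setup$phantom_base,
                            stone_count_range = c(1L, 2L),
                            diameter_range_mm = c(3, 6), seed = 31)
  tcfg <- obj$tcfg; tcfg$seed <- 31L
  bb <- obj$backbone_cfg; bb$base_channels <- 4L
  f <- train_stage(1, cohort$cases, 1:4, 5L, bb, tcfg, obj$pipe, obj$augment)
  h <- f$history
  expect_equal(nrow(h), 3L)
  expect_true(all(is.finite(h$train_loss)) && all(is.finite(h$val_loss)))
  expect_lt(h$train_loss[3], h$train_loss[1])        # smoke: loss decreases
  expect_equal(f$best_epoch, which.min(h$val_loss))  # selection rule

  # determinism: identical seed, identical loss history and parameters
  f2 <- train_stage(1, cohort$cases, 1:4, 5L, bb, tcfg, obj$pipe, obj$augment)
  expect_identical(f$history, f2$history)
  expect_identical(f$net$params, f2$net$params)

  # stage "one" builds 3-class targets on stage-1 geometry
  d1 <- nephroseg:::build_stage_dataset("one", cohort$cases[1], obj$pipe)
  expect_true(any(vapply(d1, function(cb) any(cb$label == 2L), logical(1))))
  expect_error(train_stage(1, cohort$cases, integer(0), 5L, bb, tcfg,
                           obj$pipe), "empty training set")
})

test_that("stage-2 datasets are ROI-shaped with three classes", {
  setup <- tiny_experiment_setup()
  obj <- nephroseg:::config_objects(setup$config)
  cohort <- generate_cohort(2, base = setup$phantom_base,
                            stone_count_range = c(1L, 2L),
                            diameter_range_mm = c(3, 6), seed = 32)
  d2 <- nephroseg:::build_stage_dataset(2, cohort$cases, obj$pipe)
  expect_gt(length(d2), 0)
  dims <- dim(d2[[1]]$image)
  expect_equal(dims[2:3], setup$config$stage2$roi_xy)
  expect_equal(dims[1], setup$config$stage2$cube_len)
  expect_true(any(vapply(d2, function(cb) any(cb$label == 2L), logical(1))))
})

test_that("AdamW decays only convolution weights", {
  params <- list(`a.W` = matrix(1, 2, 2), `a.g` = rep(1, 2))
  grads <- list(`a.W` = matrix(0, 2, 2), `a.g` = rep(0, 2))
  opt <- nephroseg:::adamw_init(params)
  st <- nephroseg:::adamw_step(opt, params, grads, lr = 0.1, weight_decay = 0.5)
  expect_true(all(st$params$a.W < 1))     # decayed
  expect_true(all(st$params$a.g == 1))    # not decayed
})
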