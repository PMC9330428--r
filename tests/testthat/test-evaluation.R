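test_that("confusion counts and metrics match the brute-force oracle", {
  set.seed(10)
  for (i in 1:30) {
    d <- c(16L, 16L, 16L)
    pred <- array(sample(0:2, prod(d), TRUE), d)
    truth <- array(sample(0:2, prod(d), TRUE), d)
    for (cls in 1:2) {
      got <- confusion_counts(pred, truth, cls)
      want <- oracle_confusion(pred, truth, cls)
      expect_identical(got, want)
      expect_equal(metrics_from_counts(got), oracle_metrics(want))
      expect_equal(got$TP + got$FP + got$TN + got$FN, prod(d))
    }
  }
})

test_that("metric formulas on worked examples and degenerate conventions", {
  expect_equal(metrics_from_counts(list(TP = 2, FP = 2, TN = 0, FN = 2))$dice, 0.5)
  perfect <- metrics_from_counts(list(TP = 10, FP = 0, TN = 90, FN = 0))
  expect_true(all(unlist(perfect) == 1))
  # pred == truth -> FP = FN = 0
  a <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
  cc <- confusion_counts(a, a, 1L)
  expect_equal(cc$FP, 0L); expect_equal(cc$FN, 0L)
  # pred = complement of binary truth -> TP = TN = 0
  cc2 <- confusion_counts(1L - a, a, 1L)
  expect_equal(cc2$TP, 0L); expect_equal(cc2$TN, 0L)
  # empty truth & empty pred: dice and specificity = 1 by convention
  z <- array(0L, c(4, 4, 4))
  m <- metrics_from_counts(confusion_counts(z, z, 2L))
  expect_equal(m$dice, 1.0)
  expect_equal(m$specificity, 1.0)
  expect_error(confusion_counts(z, array(0L, c(4, 4, 5)), 1L), "differ")
})

test_that("dice is symmetric and accuracy invariant under pred/truth swap", {
  set.seed(11)
  for (i in 1:20) {
    p <- array(sample(0:1, 216, TRUE), c(6, 6, 6))
    t <- array(sample(0:1, 216, TRUE), c(6, 6, 6))
    m1 <- metrics_from_counts(confusion_counts(p, t, 1L))
    m2 <- metrics_from_counts(confusion_counts(t, p, 1L))
    expect_equal(m1$dice, m2$dice)
    expect_equal(m1$accuracy, m2$accuracy)
    # set-based dice identity
    inter <- sum(p == 1L & t == 1L)
    expect_equal(m1$dice, 2 * inter / (sum(p == 1L) + sum(t == 1L)))
  }
})

test_that("stone size classes follow the half-open volume thresholds", {
  expect_equal(classify_stone_size(c(20, 100, 27.999, 28, 314.9, 315, 1000)),
               c("small", "medium", "small", "medium", "medium", "large", "large"))
  expect_error(classify_stone_size(-1), ">= 0")
})

test_that("stone_inventory reproduces generator truth exactly", {
  ph <- generate_phantom(phantom_spec("desk", seed = 13,
                                      stone_diameters_mm = c(3, 6, 9)))
  inv <- stone_inventory(ph$label)
  st <- ph$truth$stones
  expect_equal(nrow(inv), nrow(st))
  expect_equal(sort(inv$voxel_count), sort(st$voxel_count))
  expect_equal(sort(inv$volume_mm3), sort(st$volume_mm3))
  expect_equal(sort(inv$size_class), sort(st$size_class))
  # empty label -> empty inventory
  expect_equal(nrow(stone_inventory(label_volume(array(0L, c(4, 4, 4)),
                                                 c(1, 1, 1)))), 0L)
})

test_that("two corner-touching voxels form one 26-connected component", {
  m <- array(0L, c(4, 4, 4))
  m[2, 2, 2] <- 2L
  m[3, 3, 3] <- 2L
  inv <- stone_inventory(label_volume(m, c(1, 1, 1)))
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$voxel_count, 2L)
})

test_that("compiled component labeling matches the BFS oracle", {
  set.seed(12)
  for (i in 1:5) {
    m <- array(runif(10 * 10 * 10) < 0.25, c(10, 10, 10))
    got <- nephroseg:::cpp_label_components(array(as.integer(m), dim(m)))
    want <- oracle_label_components(m)
    expect_equal(max(got), max(want))
    # label ids may differ; partitions must agree
    if (max(got) > 0)
      expect_equal(length(unique(paste(got[m], want[m]))), max(got))
  }
})

test_that("success_rate counts cases at or above the threshold", {
  expect_equal(success_rate(rep(0.9, 5), 0.5)$rate, 1.0)
  expect_equal(success_rate(rep(0.1, 5), 0.5)$rate, 0.0)
  vals <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.51, 0.5, 0.4, 0.3, 0.2)
  sr <- success_rate(vals, 0.5)
  expect_equal(sr$rate, 0.7)
  expect_equal(sr$threshold, 0.5)
})

test_that("size-stratified dice matches hand computation per stratum", {
  d <- c(12L, 20L, 20L)
  truth <- array(0L, d)
  truth[2:3, 2:3, 2:3] <- 2L            # 8 voxels = 8 mm3 -> small
  truth[6:9, 5:8, 5:8] <- 2L            # 64 voxels -> medium
  truth[2:11, 12:19, 12:19] <- 2L       # 640 voxels -> large
  pred <- array(0L, d)
  pred[6:9, 5:8, 5:8] <- 2L             # medium matched exactly
  pred[2:11, 12:18, 12:19] <- 2L        # large partly matched (560 voxels)
  sd_ <- size_stratified_dice(label_volume(pred, c(1, 1, 1)),
                              label_volume(truth, c(1, 1, 1)))
  by <- sd_$by_class
  expect_equal(by$mean_dice[by$size_class == "small"], 0)
  expect_equal(by$mean_dice[by$size_class == "medium"], 1)
  expect_equal(by$mean_dice[by$size_class == "large"],
               2 * 560 / (560 + 640))
  # perfect prediction -> every stratum 1.0
  sp <- size_stratified_dice(label_volume(truth, c(1, 1, 1)),
                             label_volume(truth, c(1, 1, 1)))
  expect_true(all(sp$by_class$mean_dice == 1))
  # no truth stones -> empty result
  e <- size_stratified_dice(label_volume(pred, c(1, 1, 1)),
                            label_volume(array(0L, d), c(1, 1, 1)))
  expect_equal(nrow(e$by_class), 0L)
})

test_that("evaluate_cohort aggregates per-case metrics and success rates", {
  ph <- tiny_phantom(seed = 14)
  ev <- evaluate_cohort(list(ph$label), list(ph$label))
  expect_true(all(ev$per_case$dice == 1))
  expect_true(all(ev$success$success_rate == 1))
  expect_equal(sort(unique(ev$per_case$class)), c("kidney", "stone"))
})
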