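test_that("generate_phantom builds the requested stones as distinct components", {
  ph <- tiny_phantom(seed = 3, stones = c(3, 6))
  lab <- ph$label$voxels
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 2L))
  comp <- nephroseg:::cpp_label_components(array(as.integer(lab == 2L), dim(lab)))
  expect_equal(max(comp), 2L)
  expect_equal(nrow(ph$truth$stones), 2L)
})

test_that("identical spec and seed give bit-identical phantoms", {
  spec <- phantom_spec("desk", seed = 11, stone_diameters_mm = c(4, 7))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$label$voxels, b$label$voxels)
  expect_identical(a$truth$stones, b$truth$stones)
})

test_that("stones are hyperdense relative to kidney tissue in the image", {
  ph <- tiny_phantom(seed = 5, stones = c(6, 9))
  img <- ph$image$voxels; lab <- ph$label$voxels
  expect_gt(mean(img[lab == 2L]), mean(img[lab == 1L]))
})

test_that("noiseless phantoms carry exact tissue means under their labels", {
  spec <- phantom_spec("desk", seed = 2, stone_diameters_mm = c(5),
                       noise_sd_hu = 0)
  ph <- generate_phantom(spec)
  img <- ph$image$voxels; lab <- ph$label$voxels
  expect_true(all(img[lab == 2L] == spec$stone_hu))
  expect_true(all(img[lab == 1L] == spec$kidney_hu))
})

test_that("truth volumes are the rasterized volumes and classes are consistent", {
  ph <- generate_phantom(phantom_spec("desk", seed = 9,
                                      stone_diameters_mm = c(3, 6, 9)))
  st <- ph$truth$stones
  expect_true(all(st$voxel_count > 0))
  expect_equal(st$volume_mm3, st$voxel_count * prod(ph$label$spacing))
  expect_equal(st$size_class, classify_stone_size(st$volume_mm3))
  # volume accounting against the label volume itself, zero tolerance
  expect_equal(sum(st$voxel_count), sum(ph$label$voxels == 2L))
})

test_that("an oversized stone raises an explicit error naming the stone", {
  spec <- phantom_spec("desk", seed = 1, stone_diameters_mm = c(40))
  expect_error(generate_phantom(spec), "stone 1.*40\\.0 mm")
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec("desk", shape = c(8, 96, 96)), ">= 16")
  expect_error(phantom_spec("desk", spacing = c(0, 1, 1)), "spacing")
  expect_error(phantom_spec("desk", stone_diameters_mm = c(-1)), "> 0")
  expect_error(phantom_spec("desk", stone_hu = 30, kidney_hu = 35), "hyperdense")
})

test_that("cohort generation is deterministic and respects stone-count ranges", {
  a <- generate_cohort(5, stone_count_range = c(0L, 3L), seed = 21)
  b <- generate_cohort(5, stone_count_range = c(0L, 3L), seed = 21)
  expect_identical(a$truth, b$truth)
  counts <- vapply(a$cases, function(cs) nrow(cs$truth$stones), integer(1))
  expect_true(all(counts >= 0 & counts <= 3))
  expect_error(generate_cohort(0), "n_cases")
  expect_error(generate_cohort(3, stone_count_range = c(2L, 1L)), "range")
})

test_that("stone-free fraction allocates exactly round(frac * n) cases", {
  co <- generate_cohort(10, stone_free_fraction = 0.2, seed = 4)
  free <- vapply(co$cases, function(cs) !any(cs$label$voxels == 2L), logical(1))
  expect_equal(sum(free), 2L)
  # truth table row count equals total stones
  expect_equal(nrow(co$truth),
               sum(vapply(co$cases, function(cs) nrow(cs$truth$stones), integer(1))))
})

test_that("write_cohort produces NIfTI pairs and a truth CSV", {
  co <- generate_cohort(2, seed = 6)
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files$image)))
  expect_true(all(file.exists(files$label)))
  tt <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(tt), nrow(co$truth))
  # round trip one label and compare
  l <- read_volume(files$label[1], as_label = TRUE)
  expect_identical(l$voxels, co$cases[[1]]$label$voxels)
})
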