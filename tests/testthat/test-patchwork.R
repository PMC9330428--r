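test_that("center_crop_xy computes floor((dim-size)/2) offsets and pads small inputs", {
  v <- ct_volume(array(rnorm(2 * 256 * 256), c(2, 256, 256)), c(1, 1, 1))
  cc <- center_crop_xy(v, c(192L, 192L))
  expect_equal(cc$offset, c(32L, 32L))
  expect_equal(dim(cc$volume$voxels), c(2L, 192L, 192L))
  expect_equal(cc$volume$voxels[1, , ], v$voxels[1, 33:224, 33:224])

  # identity when size equals input
  ci <- center_crop_xy(v, c(256L, 256L))
  expect_equal(ci$offset, c(0L, 0L))
  expect_identical(ci$volume$voxels, v$voxels)

  # smaller input: symmetric zero-pad, negative offsets, invertible placement
  vs <- ct_volume(array(rnorm(2 * 160 * 160), c(2, 160, 160)), c(1, 1, 1))
  cp <- center_crop_xy(vs, c(192L, 192L))
  expect_equal(cp$offset, c(-16L, -16L))
  expect_equal(dim(cp$volume$voxels), c(2L, 192L, 192L))
  expect_equal(cp$volume$voxels[, 17:176, 17:176], vs$voxels)
  back <- uncrop_xy(cp$volume$voxels, cp$offset, dim(vs$voxels), fill = 0)
  expect_equal(back, vs$voxels)
})

test_that("cube_offsets matches the worked examples", {
  expect_equal(cube_offsets(96, 96, 48), 0L)
  expect_equal(cube_offsets(144, 96, 48), c(0L, 48L))
  expect_equal(cube_offsets(100, 96, 48), c(0L, 4L))
})

test_that("every z slice is covered for any Z and valid spec", {
  for (Z in c(1, 5, 31, 32, 33, 64, 97, 200)) {
    offs <- cube_offsets(Z, 32L, 16L)
    covered <- sort(unique(unlist(lapply(offs, function(o) o + 1:32))))
    expect_true(all(seq_len(Z) %in% covered), info = paste("Z =", Z))
  }
})

test_that("stitching averages overlaps and inverts clipping exactly", {
  spec <- patch_spec(c(8L, 8L), 6L, 3L)
  v <- ct_volume(array(rnorm(14 * 8 * 8), c(14, 8, 8)), c(1, 1, 1))
  grid <- clip_z_cubes(v, spec)
  # identity "model": score = the cube itself, one class
  scores <- lapply(grid$cubes, function(cb) array(cb, c(dim(cb), 1)))
  st <- stitch_cubes(scores, grid$offsets, grid$source_shape)
  expect_equal(st[, , , 1], v$voxels)

  # constant cubes a and b overlapping -> (a+b)/2 on the overlap
  s2 <- list(array(1, c(6, 8, 8, 1)), array(3, c(6, 8, 8, 1)))
  st2 <- stitch_cubes(s2, c(0L, 3L), c(9L, 8L, 8L))
  expect_true(all(st2[1:3, , , 1] == 1))
  expect_true(all(st2[4:6, , , 1] == 2))
  expect_true(all(st2[7:9, , , 1] == 3))

  # random 3-cube grid against the brute-force averaging oracle
  set.seed(7)
  offs <- c(0L, 4L, 9L)
  cubes <- lapply(1:3, function(i) array(rnorm(6 * 4 * 4 * 2), c(6, 4, 4, 2)))
  expect_equal(stitch_cubes(cubes, offs, c(15L, 4L, 4L)),
               oracle_stitch(cubes, offs, c(15L, 4L, 4L)))
})

test_that("find_kidney_rois keeps the two largest components above threshold", {
  ph <- tiny_phantom(seed = 12)
  mask <- merge_kidney_labels(ph$label)
  rois <- find_kidney_rois(mask, roi_xy = c(64L, 64L), min_volume_mm3 = 2000)
  expect_length(rois, 2L)
  # each truth kidney centroid falls inside exactly one box
  for (k in 1:2) {
    cen <- unlist(ph$truth$kidneys[k, c("centroid_z", "centroid_y", "centroid_x")])
    inside <- vapply(rois, function(b)
      all(cen > b$start & cen <= b$stop), logical(1))
    expect_equal(sum(inside), 1L)
  }

  # one kidney plus a 3-voxel speck: the speck is discarded
  m <- array(0L, c(32, 48, 48))
  m[10:20, 10:25, 10:25] <- 1L
  m[30, 40, 40:42] <- 1L
  lv <- label_volume(m, c(1, 1, 1))
  rois2 <- find_kidney_rois(lv, roi_xy = c(32L, 32L), min_volume_mm3 = 100)
  expect_length(rois2, 1L)
  expect_equal(rois2[[1]]$voxel_count, 11L * 16L * 16L)

  # empty mask -> empty list, not an error
  expect_length(find_kidney_rois(label_volume(array(0L, c(8, 8, 8)),
                                              c(1, 1, 1))), 0L)
})

test_that("crop_roi and restore_roi are exact inverses on in-image voxels", {
  set.seed(3)
  arr <- array(sample(0:2, 20 * 30 * 30, TRUE), c(20, 30, 30))
  lv <- label_volume(arr, c(1, 1, 1))

  # interior box: voxel-exact
  b1 <- roi_box(c(4L, 5L, 6L), c(12L, 21L, 22L))
  cr <- crop_roi(lv, b1)
  expect_identical(cr$voxels, arr[5:12, 6:21, 7:22])

  # edge box: zero-padded, and restore re-places all in-image voxels
  b2 <- roi_box(c(-2L, 20L, 20L), c(6L, 36L, 36L))
  cr2 <- crop_roi(lv, b2)
  expect_equal(dim(cr2$voxels), c(8L, 16L, 16L))
  expect_true(all(cr2$voxels %in% 0:2))
  placed <- restore_roi(cr2, b2, dim(arr))
  inz <- 1:6; iny <- 21:30; inx <- 21:30   # box z -2..5 covers slices 1..6
  expect_identical(placed[inz, iny, inx], arr[inz, iny, inx])
  expect_true(all(placed[7:20, , ] == 0L))
  expect_true(all(placed[, 1:20, ] == 0L))

  # precedence: stone (2) wins over kidney (1) on overlap
  c1 <- label_volume(array(1L, c(4, 4, 4)), c(1, 1, 1))
  c2 <- label_volume(array(2L, c(4, 4, 4)), c(1, 1, 1))
  ba <- roi_box(c(0L, 0L, 0L), c(4L, 4L, 4L))
  bb <- roi_box(c(0L, 2L, 2L), c(4L, 6L, 6L))
  canvas <- restore_roi(c1, ba, c(4L, 8L, 8L))
  canvas <- restore_roi(c2, bb, canvas)
  expect_true(all(canvas[, 3:4, 3:4] == 2L))
  expect_true(all(canvas[, 1:2, 1:2] == 1L))
  # all-background restore stays background
  expect_true(all(restore_roi(label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1)),
                              ba, c(4L, 8L, 8L)) == 0L))
  # inconsistent box errors
  expect_error(restore_roi(c1, roi_box(c(10L, 0L, 0L), c(14L, 4L, 4L)),
                           c(4L, 8L, 8L)), "inconsistent")
})

test_that("patch_spec rejects invalid geometry", {
  expect_error(patch_spec(c(8L, 8L), 6L, 0L), "stride")
  expect_error(patch_spec(c(8L, 8L), 6L, 7L), "stride")
  expect_error(patch_spec(c(0L, 8L), 6L, 3L), "crop_xy")
})
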