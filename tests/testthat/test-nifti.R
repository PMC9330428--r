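make_vol <- function(d = c(10L, 12L, 14L), spacing = c(1.25, 0.8, 0.8),
                     seed = 1) {
  set.seed(seed)
  ct_volume(array(rnorm(prod(d), 40, 80), d), spacing, "t")
}

test_that("image volumes round trip through NIfTI (float32 and int16)", {
  v <- make_vol()
  tf <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, tf, dtype_policy = "float32")
  r1 <- read_volume(tf)
  expect_equal(dim(r1$voxels), dim(v$voxels))
  expect_equal(r1$voxels, v$voxels, tolerance = 1e-6)
  # a second trip is bit-exact: values are already float32-representable
  tf2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(r1, tf2, dtype_policy = "float32")
  expect_identical(read_volume(tf2)$voxels, r1$voxels)
  expect_equal(r1$spacing, v$spacing, tolerance = 1e-6)

  vi <- ct_volume(array(round(v$voxels), dim(v$voxels)), v$spacing)
  tfi <- withr::local_tempfile(fileext = ".nii")
  write_volume(vi, tfi, dtype_policy = "int16")
  expect_equal(read_volume(tfi)$voxels, vi$voxels)
})

test_that("label volumes round trip exactly and are stored as integers", {
  ph <- tiny_phantom(seed = 2)
  tf <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$label, tf)
  r <- read_volume(tf, as_label = TRUE)
  expect_identical(r$voxels, ph$label$voxels)
  # datatype code in the header must be integral (uint8=2, int16=4, int32=8)
  con <- gzfile(tf, "rb")
  readBin(con, "raw", 70)
  dt <- readBin(con, "integer", 1, size = 2, endian = "little")
  close(con)
  expect_true(dt %in% c(2L, 4L, 8L))
})

test_that("an all-zero volume round trips to all zeros", {
  v <- ct_volume(array(0, c(8, 8, 8)), c(1, 1, 1))
  tf <- withr::local_tempfile(fileext = ".nii")
  write_volume(v, tf)
  expect_true(all(read_volume(tf)$voxels == 0))
})

test_that("spacing is preserved through the header", {
  v <- make_vol(spacing = c(1.25, 0.8, 0.8))
  tf <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, tf)
  expect_equal(read_volume(tf)$spacing, c(1.25, 0.8, 0.8), tolerance = 1e-6)
})

test_that("4D images and missing files are rejected with clear errors", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "no such file")
  v <- make_vol(d = c(6L, 6L, 6L))
  tf <- withr::local_tempfile(fileext = ".nii")
  write_volume(v, tf, dtype_policy = "float32")
  # patch the header: dim[0] = 4, dim[4] (t) = 2
  raw <- readBin(tf, "raw", file.size(tf))
  raw[41:42] <- writeBin(4L, raw(), size = 2, endian = "little")
  raw[49:50] <- writeBin(2L, raw(), size = 2, endian = "little")
  tf4 <- withr::local_tempfile(fileext = ".nii")
  writeBin(raw, tf4)
  expect_error(read_volume(tf4), "3D")
})

test_that("labels with out-of-range values are refused on write", {
  ph <- tiny_phantom(seed = 3)
  bad <- ph$label
  bad$voxels[1] <- 7L
  tf <- withr::local_tempfile(fileext = ".nii")
  expect_error(write_volume(bad, tf), "outside \\{0,1,2\\}")
  expect_error(write_volume(ph$label, tf, dtype_policy = "float32"),
               "integral")
})

test_that("reader agrees with nibabel on data, spacing and orientation", {
  # nibabel (Python, same image) is the independent oracle: it writes a
  # volume with a negated-axis affine; our reader must reorient to match
  # nibabel's own closest-canonical view.
  py <- Sys.which("python")
  expect_true(nzchar(py))
  dir <- withr::local_tempdir()
  script <- file.path(dir, "mk.py")
  nii <- file.path(dir, "oracle.nii.gz")
  writeLines(c(
    "import numpy as np, nibabel as nib, json, sys",
    "rng = np.random.default_rng(0)",
    "arr = rng.integers(0, 100, size=(5, 6, 7)).astype(np.float32)",
    "aff = np.diag([-0.7, -0.9, 1.25, 1.0])",
    "img = nib.Nifti1Image(arr, aff)",
    sprintf("nib.save(img, %s)", shQuote(nii)),
    "can = nib.as_closest_canonical(img)",
    "a = np.asanyarray(can.dataobj)",
    "print(json.dumps({'shape': list(a.shape),",
    "  'zooms': [float(z) for z in can.header.get_zooms()],",
    "  'vals': a.ravel(order='F').tolist()}))"), script)
  out <- system2(py, script, stdout = TRUE)
  ref <- jsonlite::fromJSON(out[length(out)])
  canonical <- array(ref$vals, dim = ref$shape)   # file order (x, y, z)
  r <- read_volume(nii)
  expect_equal(dim(r$voxels), rev(ref$shape))
  expect_equal(r$spacing, rev(ref$zooms), tolerance = 1e-6)
  expect_equal(r$voxels, aperm(canonical, c(3, 2, 1)), tolerance = 1e-6)
})

test_that("geometry log replay maps cropped coordinates back to the source", {
  v <- make_vol(d = c(12L, 20L, 20L))
  cc <- center_crop_xy(v, c(10L, 10L))
  # voxel (3, 4, 5) in the crop came from (3, 4 + off_y, 5 + off_x)
  back <- replay_geometry(cc$volume, c(3, 4, 5))
  expect_equal(as.vector(back), c(3, 4 + cc$offset[1], 5 + cc$offset[2]))
})
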