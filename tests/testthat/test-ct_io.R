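test_that("grayscale conversion maps the HU range onto [0, 255]", {
  arr <- array(0L, dim = c(3, 3, 2))
  arr[1, 1, 1] <- -1000L; arr[3, 3, 2] <- 1000L
  vol <- hu_volume(arr)
  g <- to_grayscale(vol)
  expect_equal(unclass(g)[1, 1, 1], 0L)
  expect_equal(unclass(g)[3, 3, 2], 255L)
  # midpoint 0 HU rounds half-up to 128
  expect_equal(unclass(g)[2, 2, 1], 128L)
  expect_true(all(g >= 0L & g <= 255L))

  expect_error(to_grayscale(hu_volume(array(-500L, dim = c(2, 2, 2)))),
               "constant")
})

test_that("grayscale conversion is monotone and honors a fixed window", {
  set.seed(3)
  arr <- array(sample(-1000:1000, 4 * 4 * 3, replace = TRUE), dim = c(4, 4, 3))
  arr[1, 1, 1] <- 0L
  vol <- hu_volume(arr)
  g <- unclass(to_grayscale(vol))
  ord <- order(as.vector(arr))
  expect_true(all(diff(as.vector(g)[ord]) >= 0))

  gw <- unclass(to_grayscale(vol, window = c(-1000, 1000)))
  expect_equal(gw[arr == 0][1], 128L)
  # clamping: values outside the window saturate
  arr2 <- array(c(-2000L, 0L, 500L, 2000L), dim = c(2, 2, 1))
  vol2 <- hu_volume(array(pmax(pmin(arr2, 3071L), -1024L), dim = dim(arr2)))
  gw2 <- unclass(to_grayscale(vol2, window = c(-1000, 1000)))
  expect_equal(gw2[1, 1, 1], 0L)
  expect_equal(gw2[2, 2, 1], 255L)
})

test_that("trim keeps the first slices, clamps, and is idempotent", {
  arr <- array(seq_len(4 * 4 * 10), dim = c(4, 4, 10))
  arr <- (arr %% 2000L) - 1000L
  vol <- hu_volume(arr)
  t6 <- trim_volume(vol, 6)
  expect_equal(dim(t6$data)[3], 6)
  expect_identical(t6$data, vol$data[, , 1:6])
  expect_equal(dim(trim_volume(vol, 56)$data)[3], 10)  # clamps
  expect_identical(trim_volume(t6, 6), t6)             # idempotent
  t1 <- trim_volume(vol, 1)
  expect_identical(t1$data[, , 1], vol$data[, , 1])
})

test_that("DICOM series round trip reproduces the phantom exactly", {
  ph <- small_phantom(seed = 4)
  dir <- withr::local_tempdir()
  write_phantom_dicom(ph, dir)
  expect_length(list.files(dir, pattern = "\\.dcm$"), 3L)
  vol <- read_dicom_series(dir)
  expect_identical(vol$data, ph$hu$data)
  expect_equal(unname(vol$spacing[["dz"]]), 2.5)
  expect_error(read_dicom_series(withr::local_tempdir()), "no DICOM")
})

test_that("DICOM slices are ordered by z position, not file name", {
  dir <- withr::local_tempdir()
  # file names sort opposite to z
  m1 <- matrix(11L, 4, 4); m2 <- matrix(22L, 4, 4); m3 <- matrix(33L, 4, 4)
  heartseg:::dcm_write_slice(m3, file.path(dir, "a.dcm"), instance = 3, z = 5)
  heartseg:::dcm_write_slice(m1, file.path(dir, "b.dcm"), instance = 1, z = 0)
  heartseg:::dcm_write_slice(m2, file.path(dir, "c.dcm"), instance = 2, z = 2.5)
  vol <- read_dicom_series(dir)
  expect_equal(vol$data[1, 1, ], c(11L, 22L, 33L))
})

test_that("rescale slope and intercept give HU on read", {
  dir <- withr::local_tempdir()
  # stored value 1024 with intercept -1024, slope 1 reads back as 0 HU
  heartseg:::dcm_write_slice(matrix(0L, 4, 4), file.path(dir, "s.dcm"),
                             intercept = -1024, slope = 1)
  vol <- read_dicom_series(dir)
  expect_true(all(vol$data == 0L))
  raw <- heartseg:::dcm_read_file(file.path(dir, "s.dcm"))
  expect_equal(raw$intercept, -1024)
  expect_equal(raw$slope, 1)
})

test_that("mask writing round-trips through PNG and NIfTI", {
  set.seed(8)
  m <- random_mask(8, 8)
  p_png <- withr::local_tempfile(fileext = ".png")
  write_mask(m, p_png, format = "png")
  expect_identical(read_mask(p_png), m)

  z <- matrix(0L, 8, 8)
  p0 <- withr::local_tempfile(fileext = ".png")
  write_mask(z, p0)
  expect_identical(read_mask(p0), z)

  p_nii <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, p_nii, format = "nifti")
  expect_identical(read_mask(p_nii), m)

  # 3-D stack to PNG: one zero-padded file per slice
  st <- array(c(m, 1L - m, m), dim = c(8, 8, 3))
  base <- file.path(withr::local_tempdir(), "stack")
  paths <- write_mask(st, base, format = "png")
  expect_equal(basename(paths),
               c("stack_001.png", "stack_002.png", "stack_003.png"))
  expect_identical(read_mask(paths[2]), 1L - m)

  p_st <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(st, p_st, format = "nifti")
  expect_identical(read_mask(p_st), st)
})

test_that("HU volumes are validated and clamped", {
  expect_error(hu_volume(array(0L, dim = c(2, 2, 0))), "slice")
  expect_warning(v <- hu_volume(array(c(-2000L, 5000L, 0L, 0L),
                                      dim = c(2, 2, 1))), "clamped")
  expect_equal(range(v$data), c(-1024L, 3071L))
})
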