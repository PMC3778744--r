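test_that("a 4D NIfTI file reads back as a time-major float series", {
  f <- tempfile(fileext = ".nii.gz")
  write_test_nifti(array(as.integer(0:11), c(2, 2, 1, 3)), f, dt = 1.5)
  s <- read_series(f)
  expect_s3_class(s, "perfusion_series")
  expect_identical(unname(s$dims), c(2L, 2L, 1L, 3L))
  expect_identical(s$layout, "time_major")
  expect_equal(as.vector(s$data), as.numeric(0:11))
  expect_true(is.double(s$data))
  expect_equal(s$dt, 1.5)
})

test_that("dt precedence: override beats header; msec headers convert to seconds", {
  f <- tempfile(fileext = ".nii")
  write_test_nifti(array(0, c(2, 2, 1, 3)), f, dt = 1500, tunit = "ms")
  expect_equal(read_series(f)$dt, 1.5)
  expect_equal(read_series(f, dt_override = 2)$dt, 2)
})

test_that("a file without usable time information needs dt_override", {
  f <- tempfile(fileext = ".nii")
  write_test_nifti(array(0, c(2, 2, 1, 3)), f, dt = NULL)   # no declared time unit
  expect_error(read_series(f), class = "perfmap_config_error")
  expect_equal(read_series(f, dt_override = 1)$dt, 1)
})

test_that("non-4D input is rejected with a dimensionality error", {
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 2))), f)
  expect_error(read_series(f, dt_override = 1), class = "perfmap_dim_error")
})

test_that("NIfTI scale slope and intercept are applied on read", {
  skip_if_not_installed("oro.nifti")
  # independent writer: stored int16 value 5, slope 2, intercept 1 -> 11
  nim <- oro.nifti::nifti(array(5L, c(2, 2, 1, 3)), datatype = 4L)
  oro.nifti::scl_slope(nim) <- 2
  oro.nifti::scl_inter(nim) <- 1
  stem <- tempfile()
  oro.nifti::writeNIfTI(nim, stem, gzipped = FALSE)
  s <- read_series(paste0(stem, ".nii"), dt_override = 1)
  expect_equal(unique(as.vector(s$data)), 11)
})

test_that("reorganize places the labeled value at the predicted index", {
  # A[t][z][y][x] = 1000 t + 100 z + 10 y + x (0-based labels)
  dm <- c(2L, 2L, 2L, 3L)                     # (Dim1, Dim2, Dim3, Time)
  tm <- array(NA_real_, dm)
  for (t in 0:(dm[4] - 1)) for (z in 0:(dm[3] - 1))
    for (y in 0:(dm[2] - 1)) for (x in 0:(dm[1] - 1))
      tm[x + 1, y + 1, z + 1, t + 1] <- 1000 * t + 100 * z + 10 * y + x
  s <- perfusion_series(tm, dt = 1, layout = "time_major")
  v <- reorganize(s, "voxel_major")
  expect_identical(v$layout, "voxel_major")
  for (t in 0:(dm[4] - 1)) for (z in 0:(dm[3] - 1))
    for (y in 0:(dm[2] - 1)) for (x in 0:(dm[1] - 1))
      expect_identical(v$data[t + 1, x + 1, y + 1, z + 1],
                       1000 * t + 100 * z + 10 * y + x)
})

test_that("reorganize round trip is the elementwise identity and preserves values", {
  withr::with_seed(1, {
    for (dm in list(c(3L, 4L, 2L, 5L), c(1L, 1L, 1L, 6L), c(4L, 1L, 3L, 2L))) {
      s <- perfusion_series(array(rnorm(prod(dm)), dm), dt = 1, layout = "time_major")
      rt <- reorganize(reorganize(s, "voxel_major"), "time_major")
      expect_identical(rt$data, s$data)
      # bijection on positions: same multiset of values
      expect_identical(sort(as.vector(reorganize(s, "voxel_major")$data)),
                       sort(as.vector(s$data)))
      # same-layout call is the identity
      expect_identical(reorganize(s, "time_major"), s)
    }
  })
})

test_that("map write/read round trip preserves values under the mask and NaNs outside", {
  withr::with_seed(2, {
    ph <- tiny_phantom()
    sp <- dim(ph$truth$cbf)
    map <- array(rnorm(prod(sp)), sp)
    mask <- array(runif(prod(sp)) > 0.5, sp)
    f <- tempfile(fileext = ".nii.gz")
    write_map_nifti(map, mask, ph$series, f)
    back <- as.array(RNifti::readNifti(f))
    expect_equal(back[mask], map[mask], tolerance = 1e-7)  # float32 round trip
    expect_true(all(is.nan(back[!mask])))
    # all-false mask -> all NaN
    write_map_nifti(map, array(FALSE, sp), ph$series, f)
    expect_true(all(is.nan(as.array(RNifti::readNifti(f)))))
    # dimension mismatch is caught
    expect_error(write_map_nifti(map[-1, , , drop = FALSE], mask, ph$series, f),
                 class = "perfmap_dim_error")
  })
})

test_that("series write/read round trip keeps values, dt and affine", {
  ph <- tiny_phantom()
  f <- tempfile(fileext = ".nii.gz")
  write_series_nifti(ph$series, f)
  s2 <- read_series(f)
  expect_equal(s2$data, ph$series$data, tolerance = 1e-6)  # float32 on disk
  expect_equal(s2$dt, ph$series$dt)
  expect_identical(s2$dims, ph$series$dims)
})
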