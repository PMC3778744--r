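test_that("gamma-variate bolus: support, peak location, linear amplitude, positive floor", {
  p <- list(A = 2, t0 = 5, alpha = 2.5, beta = 1.2)
  times <- seq(0.5, 40, by = 0.5)
  a <- gamma_variate_aif(p, times)
  expect_true(all(a$values[times <= 5][-1] == 0))        # zero before arrival
  expect_equal(a$values[1], 1e-6 * p$A)                  # invertibility floor at t1
  # analytic peak at t0 + alpha*beta, within one grid step of dense argmax
  expect_lt(abs(times[which.max(a$values)] - (p$t0 + p$alpha * p$beta)), 0.5 + 1e-9)
  a2 <- gamma_variate_aif(modifyList(p, list(A = 4)), times)
  expect_equal(a2$values, 2 * a$values)
  expect_error(gamma_variate_aif(modifyList(p, list(alpha = -1)), times),
               class = "perfmap_config_error")
})

test_that("a noise-free simulated curve deconvolves back to its residue", {
  a <- gamma_variate_aif(list(A = 1, t0 = 0, alpha = 2, beta = 1), seq_len(30))
  ct <- simulate_voxel_curve(a, cbf = 0.8, mtt = 5, delay = 2)
  h <- deconvolve_voxel(ct, truncated_pseudoinverse(build_aif_matrix(a), 0))
  expect_equal(h, attr(ct, "h_true"), tolerance = 1e-8)
  # near-zero flow leaves only noise
  withr::with_seed(2, {
    ct2 <- simulate_voxel_curve(a, cbf = 1e-9, mtt = 5, noise_sigma = 0.1)
    expect_lt(max(abs(ct2)), 1)
  })
  # residue definition: zero before the delay, cbf at the arrival sample
  expect_equal(attr(ct, "h_true")[1], 0)
  expect_equal(attr(ct, "h_true")[2], 0.8)
})

test_that("the generator is bitwise deterministic under a fixed seed", {
  p1 <- build_phantom(phantom_preset("tiny", noise_frac = 0.05, seed = 33))
  p2 <- build_phantom(phantom_preset("tiny", noise_frac = 0.05, seed = 33))
  expect_identical(p1$series$data, p2$series$data)
  p3 <- build_phantom(phantom_preset("tiny", noise_frac = 0.05, seed = 34))
  expect_false(identical(p3$series$data, p1$series$data))
})

test_that("phantom construction: region curves, truth consistency, overlap rejection", {
  ph <- tiny_phantom()
  vm <- reorganize(ph$series, "voxel_major")
  m <- matrix(vm$data, nrow = vm$dims[["time"]])
  # noise-free: every voxel of a region carries the identical curve
  gray <- which(!is.na(ph$truth$cbf) & ph$truth$cbf == 0.6)
  expect_true(all(m[, gray] == m[, gray[1]]))
  # truth invariant: cbv = cbf * nominal mtt * recorded correction
  reg <- ph$truth$regions
  expect_equal(reg$cbv, reg$cbf_nominal * reg$mtt_nominal * reg$correction)
  # arterial voxels carry the 3x AIF
  expect_equal(m[, which(ph$truth$arterial)[1]], 3 * ph$truth$aif$values)
  # overlapping regions are rejected
  expect_error(
    phantom_spec(dims = c(8, 8, 1, 10), dt = 1,
                 aif_params = list(A = 1, t0 = 0, alpha = 2, beta = 1),
                 regions = list(
                   list(label = "a", box = c(1, 4, 1, 4, 1, 1), cbf = 1, mtt = 2),
                   list(label = "b", box = c(4, 6, 4, 6, 1, 1), cbf = 1, mtt = 2)),
                 arterial_box = c(7, 8, 7, 8, 1, 1)),
    class = "perfmap_config_error")
})

test_that("MTT truncation bias grows with the threshold once truncation engages", {
  # Noisy ill-posed phantom; over thresholds that actually truncate the
  # spectrum, increasing regularization biases MTT increasingly. (At
  # threshold 0 the estimate is instead dominated by rectified noise in
  # the CBV sum, so the untruncated point is not part of the trend.)
  ph <- build_phantom(phantom_preset("tiny-smooth", noise_frac = 0.05, seed = 19))
  tis <- !is.na(ph$truth$cbf)
  bias <- vapply(c(0.1, 0.2, 0.3), function(th) {
    m <- run_serial(ph$series, truth_aif_config(ph$truth, threshold = th))
    abs(median(m$mtt[tis & m$valid]) - median(ph$truth$mtt[tis]))
  }, numeric(1))
  expect_true(all(diff(bias) > 0))
})

test_that("phantom spec JSON round trip reproduces the phantom", {
  ph <- build_phantom(phantom_preset("tiny", noise_frac = 0.02, seed = 9))
  d <- tempfile()
  write_phantom(ph, d)
  expect_true(all(file.exists(file.path(d, c("series.nii.gz", "truth_cbf.nii.gz",
                                             "aif.txt", "spec.json")))))
  spec2 <- read_phantom_spec(file.path(d, "spec.json"))
  ph2 <- build_phantom(spec2)
  expect_equal(ph2$series$data, ph$series$data, tolerance = 1e-12)
  # AIF text file matches the truth AIF
  expect_equal(scan(file.path(d, "aif.txt"), quiet = TRUE), ph$truth$aif$values,
               tolerance = 1e-12)
})
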