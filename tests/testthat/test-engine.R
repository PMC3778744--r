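test_that("the full pipeline recovers phantom ground truth on noise-free input", {
  ph <- tiny_phantom()
  maps <- run_serial(ph$series, truth_aif_config(ph$truth))
  tis <- !is.na(ph$truth$cbf)
  expect_true(all(maps$valid[tis]))
  for (m in c("cbf", "cbv", "mtt"))
    expect_lt(max(abs(maps[[m]][tis] - ph$truth[[m]][tis]) / ph$truth[[m]][tis]),
              1e-6)
  # two tissue classes injected with CBF 0.6 and 0.3: class-mean ratio 2
  hi <- tis & ph$truth$cbf > 0.45
  lo <- tis & ph$truth$cbf < 0.45
  expect_equal(mean(maps$cbf[hi]) / mean(maps$cbf[lo]), 2, tolerance = 1e-6)
  # TA lands within one sampling interval of the injected delay
  expect_true(all(abs(maps$ta[tis] - ph$truth$ta[tis]) <= ph$series$dt + 1e-12))
  expect_identical(maps$n_svd, 1L)
})

test_that("an all-zero series yields no valid voxels", {
  z <- perfusion_series(array(0, c(4, 4, 2, 10)), dt = 1, layout = "time_major")
  maps <- run_serial(z, run_config(aif_mode = "file", aif = aif_vector(c(1, rep(0, 9)), 1)))
  expect_false(any(maps$valid))
  expect_true(all(is.nan(maps$cbf)))
})

test_that("mtt equals cbv/cbf elementwise wherever valid", {
  ph <- tiny_phantom(noise_frac = 0.05, seed = 23)
  maps <- run_serial(ph$series, run_config(svd_rel_threshold = 0.2))
  v <- maps$valid
  expect_true(any(v))
  expect_equal(maps$mtt[v], maps$cbv[v] / maps$cbf[v], tolerance = 1e-12)
  expect_true(all(maps$cbf[v] > 0) && all(maps$cbv[v] > 0))
  expect_true(all(is.nan(maps$cbf[!v])) && all(is.nan(maps$ta[!v])))
})

test_that("chunking is a partition of the voxels for slice and fixed-size chunks", {
  sp <- c(16L, 16L, 2L)
  for (chunk in list("slice", 7L, 1L, 512L, 1000L)) {
    ch <- perfmap:::chunk_indices(sp, chunk)
    flat <- unlist(ch)
    expect_identical(sort(flat), seq_len(prod(sp)))   # each voxel exactly once
    expect_identical(anyDuplicated(flat), 0L)
  }
  expect_length(perfmap:::chunk_indices(sp, "slice"), 2L)
})

test_that("parallel engine output is bit-identical to serial for any workers/chunk setting", {
  ph <- tiny_phantom(noise_frac = 0.05, seed = 41)
  cfg <- run_config(svd_rel_threshold = 0.2)
  ref <- run_serial(ph$series, cfg)
  for (setting in list(list(w = 1L, c = "slice"), list(w = 2L, c = "slice"),
                       list(w = 3L, c = 7L))) {
    got <- run_parallel(ph$series, run_config(svd_rel_threshold = 0.2,
                                              workers = setting$w,
                                              chunk = setting$c))
    for (m in c("cbf", "cbv", "mtt", "ttp", "ta", "valid"))
      expect_identical(got[[m]], ref[[m]],
                       info = sprintf("map %s, workers %d", m, setting$w))
  }
})

test_that("two identical runs produce identical bytes (no hidden state)", {
  ph <- tiny_phantom(noise_frac = 0.05, seed = 2)
  cfg <- run_config()
  a <- run_serial(ph$series, cfg)
  b <- run_serial(ph$series, cfg)
  for (m in c("cbf", "cbv", "mtt", "ttp", "ta", "valid"))
    expect_identical(a[[m]], b[[m]])
})

test_that("global mode computes one SVD; local mode computes one per in-mask voxel", {
  spec <- phantom_spec(
    dims = c(6L, 6L, 1L, 20L), dt = 1,
    aif_params = list(t0 = 0, alpha = 2, beta = 1, A = gamma_peak_amplitude(2, 1)),
    regions = list(list(label = "t", box = c(1, 4, 1, 6, 1, 1),
                        cbf = 0.5, mtt = 4, delay = 1)),
    arterial_box = c(6, 6, 1, 2, 1, 1), seed = 3)
  ph <- build_phantom(spec)
  g <- run_serial(ph$series, run_config(aif_mode = "global"))
  expect_identical(g$n_svd, 1L)
  l <- run_serial(ph$series, run_config(aif_mode = "local", local_radius = 2L,
                                        local_top_k = 2L))
  expect_identical(l$n_svd, sum(l$mask))
  # local engine is parallel-safe too
  lp <- run_parallel(ph$series, run_config(aif_mode = "local", local_radius = 2L,
                                           local_top_k = 2L, workers = 2L))
  expect_identical(lp$cbf, l$cbf)
  expect_identical(lp$n_svd, l$n_svd)
})

test_that("denoising and baseline options run inside the pipeline", {
  ph <- tiny_phantom(noise_frac = 0.05, seed = 15)
  cfg <- run_config(denoise = kernel_spec(3L, 1L), baseline_frames = 1L)
  maps <- run_serial(ph$series, cfg)
  expect_true(any(maps$valid))
  expect_false(identical(maps$cbf, run_serial(ph$series, run_config())$cbf))
})

test_that("weighted-mean filtering suppresses noise on a homogeneous signal", {
  clean <- tiny_phantom(noise_frac = 0)
  noisy <- tiny_phantom(noise_frac = 0.05, seed = 15)
  vm_c <- reorganize(clean$series, "voxel_major")
  vm_n <- reorganize(noisy$series, "voxel_major")
  den <- denoise_weighted_mean(vm_n, kernel_spec(3L, 1L))
  # strictly interior voxels of the homogeneous region: every spatial
  # neighbour shares the identical clean curve, so averaging can only
  # shrink the noise there
  sp <- dim(clean$truth$cbf)
  interior <- array(FALSE, sp)
  interior[3:6, 3:14, ] <- TRUE
  sub <- function(s) matrix(s$data, nrow = 40)[, which(as.vector(interior))]
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(sub(den), sub(vm_c)), rmse(sub(vm_n), sub(vm_c)))
})
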