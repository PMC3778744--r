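#' Amplitude giving a unit-peak gamma-variate bolus
#'
#' The gamma-variate `A (t-t0)^alpha exp(-(t-t0)/beta)` peaks at
#' `t = t0 + alpha*beta` with value `A (alpha*beta)^alpha exp(-alpha)`;
#' this returns the `A` that makes that peak 1.
#'
#' @param alpha,beta Shape and scale (seconds) of the bolus, both > 0.
#' @export
gamma_peak_amplitude <- function(alpha, beta) {
  1 / ((alpha * beta)^alpha * exp(-alpha))
}

#' Gamma-variate arterial bolus curve
#'
#' The standard parametric model of a first-pass contrast bolus:
#' `Ca(t) = A (t-t0)^alpha exp(-(t-t0)/beta)` for `t > t0`, 0 before.
#' The first sample is floored at `1e-6 * A` so the convolution matrix
#' built from the curve is never exactly singular.
#'
#' @param params List with `A` (amplitude), `t0` (bolus arrival,
#'   seconds), `alpha` (shape), `beta` (scale, seconds); `alpha`,
#'   `beta`, `A` must be positive.
#' @param times Regular sampling grid in seconds (`t1 ... tN`).
#' @return An [aif_vector()].
#' @export
gamma_variate_aif <- function(params, times) {
  with(params, {
    if (alpha <= 0 || beta <= 0 || A <= 0)
      stop_config("gamma-variate parameters A, alpha, beta must be positive")
    v <- ifelse(times > t0, A * (times - t0)^alpha * exp(-(times - t0) / beta), 0)
    v[1L] <- max(v[1L], 1e-6 * A)
    aif_vector(v, dt = times[2L] - times[1L])
  })
}

#' Exponential tissue residue function
#'
#' `h(t) = cbf * exp(-(t - delay)/mtt)` for `t >= delay`, zero before:
#' the simplest physiologically standard residue model, delayed by the
#' voxel's bolus arrival time.
#'
#' @param times Sampling grid in seconds.
#' @param cbf IRF amplitude (> 0).
#' @param mtt Mean transit time in seconds (> 0).
#' @param delay Arrival delay in seconds (>= 0).
#' @return Numeric vector over `times`.
#' @export
tissue_residue <- function(times, cbf, mtt, delay = 0) {
  if (cbf <= 0 || mtt <= 0) stop_config("cbf and mtt must be positive")
  ifelse(times < delay, 0, cbf * exp(-(times - delay) / mtt))
}

#' Simulate one tissue concentration curve
#'
#' Forms the discrete forward model: the AIF's convolution matrix
#' applied to an exponential residue, plus i.i.d. Gaussian noise drawn
#' from the current RNG state. Because the forward operator is the same
#' discrete convolution matrix the solver inverts, a noise-free curve
#' deconvolved at threshold 0 returns the residue exactly (to
#' floating-point precision) -- the package's strongest correctness
#' anchor.
#'
#' @param aif An [aif_vector()].
#' @param cbf,mtt,delay Residue parameters, see [tissue_residue()].
#' @param noise_sigma Standard deviation of additive Gaussian noise
#'   (>= 0).
#' @return Numeric concentration curve with attribute `"h_true"`, the
#'   noise-free residue.
#' @export
simulate_voxel_curve <- function(aif, cbf, mtt, delay = 0, noise_sigma = 0) {
  stopifnot(inherits(aif, "aif_vector"))
  nt <- length(aif$values)
  times <- aif$dt * seq_len(nt)
  h <- tissue_residue(times, cbf, mtt, delay)
  ct <- as.vector(build_aif_matrix(aif)$matrix %*% h)
  if (noise_sigma > 0) ct <- ct + rnorm(nt, 0, noise_sigma)
  attr(ct, "h_true") <- h
  ct
}

#' Digital perfusion phantom specification
#'
#' Describes a synthetic bolus-passage series: a gamma-variate arterial
#' curve, rectangular tissue regions with known CBF/MTT/delay carrying
#' exponential residues, an arterial region carrying the AIF at
#' vessel-like (3x) amplitude, and seeded additive Gaussian noise.
#'
#' @param dims Integer `(Dim1, Dim2, Dim3, Time)`.
#' @param dt Sampling interval in seconds.
#' @param aif_params List `(A, t0, alpha, beta)` for
#'   [gamma_variate_aif()]. The bolus peak `t0 + alpha*beta` must fall
#'   inside the acquisition window.
#' @param regions List of tissue regions, each a list with `label`,
#'   `box = c(x1, x2, y1, y2, z1, z2)` (1-based inclusive), `cbf`,
#'   `mtt` (s), and optional `delay` (s, default 0). Regions must be
#'   pairwise disjoint.
#' @param arterial_box Box (same format) of the designated arterial
#'   voxels; must not overlap any tissue region.
#' @param noise_sigma Absolute noise standard deviation; ignored when
#'   `noise_frac` is given.
#' @param noise_frac Noise standard deviation as a fraction of the peak
#'   noise-free tissue signal (e.g. 0.05 for 5%).
#' @param baseline Additive constant on every voxel (default 0).
#' @param seed RNG seed for the noise draw.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(dims, dt, aif_params, regions, arterial_box,
                         noise_sigma = 0, noise_frac = NULL,
                         baseline = 0, seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 4L || any(dims < 1L) || dims[4L] < 2L)
    stop_config("dims must be 4 positive integers with Time >= 2")
  if (dt <= 0) stop_config("dt must be positive")
  if (aif_params$t0 + aif_params$alpha * aif_params$beta >= dims[4L] * dt)
    stop_config("bolus peak t0 + alpha*beta must lie inside the acquisition window")
  sp <- dims[1:3]
  seen <- integer(0)
  for (r in c(regions, list(list(label = "arterial", box = arterial_box,
                                 cbf = 1, mtt = 1)))) {
    if (r$cbf <= 0 || r$mtt <= 0) stop_config("region cbf and mtt must be positive")
    idx <- box_indices(r$box, sp)
    if (length(intersect(idx, seen)))
      stop_config("phantom regions overlap at region '", r$label, "'")
    seen <- c(seen, idx)
  }
  if (noise_sigma < 0) stop_config("noise_sigma must be >= 0")
  structure(list(dims = dims, dt = dt, aif_params = aif_params,
                 regions = regions, arterial_box = arterial_box,
                 noise_sigma = noise_sigma, noise_frac = noise_frac,
                 baseline = baseline, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Linear voxel indices of a box c(x1,x2,y1,y2,z1,z2), clipped to volume.
box_indices <- function(box, sp) {
  b <- as.integer(box)
  if (length(b) != 6L || any(b[c(1, 3, 5)] > b[c(2, 4, 6)]))
    stop_config("box must be c(x1,x2,y1,y2,z1,z2) with lo <= hi")
  if (any(b[c(1, 3, 5)] < 1L) || any(b[c(2, 4, 6)] > sp))
    stop_config("box exceeds volume bounds")
  g <- expand.grid(x = b[1]:b[2], y = b[3]:b[4], z = b[5]:b[6])
  as.integer(g$x + sp[1L] * (g$y - 1L) + sp[1L] * sp[2L] * (g$z - 1L))
}

#' Built-in phantom presets
#'
#' * `"tiny"`: 16 x 16 x 2 x 40 at dt = 1 s with a sharp bolus
#'   (alpha = 2, beta = 1 s) whose discrete convolution matrix is
#'   well-conditioned -- the exact-recovery regime used as correctness
#'   anchor. Two tissue classes with a 2:1 CBF ratio plus a small
#'   arterial block.
#' * `"tiny-smooth"`: same geometry with a slow-rise bolus (alpha = 3,
#'   beta = 1.5 s) whose operator is severely ill-conditioned -- the
#'   regime in which SVD truncation earns its keep; used for
#'   noise/threshold studies.
#' * `"mr-paper"`: 128 x 128 x 22 x 80 at dt = 1.5 s (a typical MR
#'   perfusion size) for scale testing.
#' * `"ct-paper"`: 128 x 128 x 11 x 44 at dt = 1 s (a typical CT
#'   perfusion size).
#'
#' @param name Preset name.
#' @param noise_frac Noise SD as a fraction of peak tissue signal
#'   (default 0, noise-free).
#' @param seed RNG seed.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("tiny", "tiny-smooth", "mr-paper", "ct-paper"),
                           noise_frac = 0, seed = 1L) {
  name <- match.arg(name)
  sharp <- list(t0 = 0, alpha = 2, beta = 1, A = gamma_peak_amplitude(2, 1))
  smooth <- list(t0 = 0, alpha = 3, beta = 1.5, A = gamma_peak_amplitude(3, 1.5))
  tiny_geom <- function(aifp) phantom_spec(
    dims = c(16L, 16L, 2L, 40L), dt = 1, aif_params = aifp,
    regions = list(
      list(label = "gray",  box = c(2L, 7L, 2L, 15L, 1L, 2L),  cbf = 0.6, mtt = 4, delay = 1),
      list(label = "white", box = c(10L, 15L, 2L, 15L, 1L, 2L), cbf = 0.3, mtt = 8, delay = 2)),
    arterial_box = c(8L, 9L, 7L, 9L, 1L, 2L),
    noise_frac = if (noise_frac > 0) noise_frac else NULL, seed = seed)
  big_geom <- function(dims, dt) phantom_spec(
    dims = dims, dt = dt,
    aif_params = sharp,
    regions = list(
      list(label = "gray",  box = c(8L, 56L, 8L, 120L, 1L, dims[3L]),  cbf = 0.6, mtt = 4, delay = dt),
      list(label = "white", box = c(72L, 120L, 8L, 120L, 1L, dims[3L]), cbf = 0.3, mtt = 8, delay = 2 * dt)),
    arterial_box = c(60L, 67L, 56L, 71L, max(1L, dims[3L] %/% 2L), max(1L, dims[3L] %/% 2L) + 1L),
    noise_frac = if (noise_frac > 0) noise_frac else NULL, seed = seed)
  switch(name,
         "tiny" = tiny_geom(sharp),
         "tiny-smooth" = tiny_geom(smooth),
         "mr-paper" = big_geom(c(128L, 128L, 22L, 80L), 1.5),
         "ct-paper" = big_geom(c(128L, 128L, 11L, 44L), 1))
}

#' Build a digital perfusion phantom
#'
#' Generates the 4D series and its ground truth. Tissue voxels carry the
#' discrete forward model (convolution matrix times exponential
#' residue), arterial voxels carry the AIF scaled by 3 (vessel-like
#' amplitude), background voxels are baseline only; seeded Gaussian
#' noise is added everywhere. Truth maps record the *discrete* ground
#' truth the sampled residue attains: CBF is `max(h)` over the grid
#' (equal to the nominal cbf when the arrival delay is a positive
#' multiple of dt, as in all presets), CBV is `dt * sum(max(h, 0))` and
#' MTT their ratio. The pipeline recovers these exactly on noise-free
#' input at threshold 0. The ratio of discrete CBV to nominal
#' `cbf * mtt` is recorded per region in the `regions` table
#' (`correction` column).
#'
#' @param spec A [phantom_spec()].
#' @return List with `series` (a `time_major` [perfusion_series()]) and
#'   `truth` (3D `cbf`, `cbv`, `mtt`, `ta` arrays, NaN outside tissue
#'   regions; the `aif` as an [aif_vector()]; `arterial` logical array;
#'   `noise_sigma` actually applied; a per-region summary data frame).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$dims[1:3]
  nt <- spec$dims[4L]
  size <- prod(sp)
  times <- spec$dt * seq_len(nt)
  aif <- gamma_variate_aif(spec$aif_params, times)
  Cmat <- build_aif_matrix(aif)$matrix

  ctmat <- matrix(0, nt, size)
  truth <- list(cbf = array(NaN, sp), cbv = array(NaN, sp),
                mtt = array(NaN, sp), ta = array(NaN, sp))
  peak_tissue <- 0
  reg_rows <- list()
  for (r in spec$regions) {
    delay <- r$delay %||% 0
    h <- tissue_residue(times, r$cbf, r$mtt, delay)
    ct0 <- as.vector(Cmat %*% h)
    idx <- box_indices(r$box, sp)
    ctmat[, idx] <- ct0
    # Discrete ground truth: what the sampled residue actually attains.
    # When the arrival delay is a positive multiple of dt the grid hits
    # the residue peak and cbf_d equals the nominal cbf exactly.
    cbf_d <- max(h)
    cbv_d <- spec$dt * sum(pmax(h, 0))
    truth$cbf[idx] <- cbf_d
    truth$cbv[idx] <- cbv_d
    truth$mtt[idx] <- cbv_d / cbf_d
    truth$ta[idx] <- delay
    peak_tissue <- max(peak_tissue, max(ct0))
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      label = r$label, n_voxels = length(idx), cbf_nominal = r$cbf,
      cbf = cbf_d, mtt_nominal = r$mtt, mtt = cbv_d / cbf_d, cbv = cbv_d,
      delay = delay, correction = cbv_d / (r$cbf * r$mtt))
  }
  aidx <- box_indices(spec$arterial_box, sp)
  ctmat[, aidx] <- 3 * aif$values
  arterial <- array(FALSE, sp)
  arterial[aidx] <- TRUE

  sigma <- if (!is.null(spec$noise_frac)) spec$noise_frac * peak_tissue
           else spec$noise_sigma
  withr::with_seed(spec$seed, {
    if (sigma > 0) ctmat <- ctmat + rnorm(length(ctmat), 0, sigma)
  })
  if (spec$baseline != 0) ctmat <- ctmat + spec$baseline

  vm <- perfusion_series(array(ctmat, c(nt, sp)), dt = spec$dt,
                         layout = "voxel_major")
  list(series = reorganize(vm, "time_major"),
       truth = c(truth, list(aif = aif, arterial = arterial,
                             noise_sigma = sigma,
                             regions = do.call(rbind, reg_rows))),
       spec = spec)
}

#' Write a phantom to disk
#'
#' Writes the series (`series.nii.gz`), the four truth maps
#' (`truth_cbf.nii.gz`, ...), the AIF as plain text (`aif.txt`, one
#' value per line) and the resolved spec (`spec.json`).
#'
#' @param phantom Output of [build_phantom()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_series_nifti(phantom$series, file.path(dir, "series.nii.gz"))
  all_true <- array(TRUE, dim(phantom$truth$cbf))
  for (m in c("cbf", "cbv", "mtt", "ta"))
    write_map_nifti(phantom$truth[[m]], all_true, phantom$series,
                    file.path(dir, sprintf("truth_%s.nii.gz", m)))
  writeLines(format(phantom$truth$aif$values, digits = 17),
             file.path(dir, "aif.txt"))
  spec <- phantom$spec
  jsonlite::write_json(
    list(dims = spec$dims, dt = spec$dt, aif_params = spec$aif_params,
         regions = spec$regions, arterial_box = spec$arterial_box,
         noise_sigma = phantom$truth$noise_sigma, baseline = spec$baseline,
         seed = spec$seed),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom spec from JSON
#'
#' Accepts the format written by [write_phantom()] (absolute
#' `noise_sigma`) or a hand-written spec with `noise_frac`.
#'
#' @param path JSON file path.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- j$regions
  if (is.data.frame(regions)) {
    regions <- lapply(seq_len(nrow(regions)), function(i) {
      r <- as.list(regions[i, , drop = FALSE])
      r$box <- unlist(regions$box[i])
      r
    })
  }
  phantom_spec(dims = unlist(j$dims), dt = j$dt,
               aif_params = as.list(j$aif_params), regions = regions,
               arterial_box = unlist(j$arterial_box),
               noise_sigma = j$noise_sigma %||% 0,
               noise_frac = j$noise_frac,
               baseline = j$baseline %||% 0, seed = j$seed %||% 1L)
}
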