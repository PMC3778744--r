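# Shared fixtures: everything is generated in code at test time.

# A small, well-conditioned phantom (sharp bolus) and its truth.
tiny_phantom <- function(noise_frac = 0, seed = 7L) {
  build_phantom(phantom_preset("tiny", noise_frac = noise_frac, seed = seed))
}

# Config that pins the true AIF so recovery oracles are exact.
truth_aif_config <- function(truth, threshold = 0, ...) {
  run_config(svd_rel_threshold = threshold, aif_mode = "file",
             aif = truth$aif, ...)
}

# Random lower-triangular Toeplitz matrix with nonzero leading entry.
random_toeplitz <- function(n, dt = 1) {
  v <- c(runif(1, 0.5, 1.5), runif(n - 1))
  M <- matrix(0, n, n)
  lag <- row(M) - col(M) + 1L
  M[lag >= 1L] <- dt * v[lag[lag >= 1L]]
  list(M = M, v = v, dt = dt)
}

# A small voxel_major series filled with reproducible random values.
random_vm_series <- function(dims = c(5L, 5L, 3L), nt = 4L, dt = 1, seed = 42L) {
  withr::with_seed(seed, {
    perfusion_series(array(rnorm(nt * prod(dims)), c(nt, dims)),
                     dt = dt, layout = "voxel_major")
  })
}

# Write a minimal 4D NIfTI file with explicit time-step metadata.
write_test_nifti <- function(data4d, path, dt = NULL, tunit = "s") {
  img <- RNifti::asNifti(data4d)
  if (!is.null(dt)) {
    RNifti::pixdim(img) <- c(1, 1, 1, dt)
    RNifti::pixunits(img) <- c("mm", tunit)
  }
  RNifti::writeNifti(img, path)
  path
}
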