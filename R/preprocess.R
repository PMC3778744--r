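#' Weighted-mean denoising kernel
#'
#' Describes a 2D (in-slice spatial), 3D (spatial) or 4D (spatial +
#' time) weighted-mean filter window. Weight array axes are ordered
#' `(dim1, dim2[, dim3[, time]])` and must have extent `2*radius + 1`
#' along each axis.
#'
#' @param ndim 2, 3 or 4.
#' @param radius Nonnegative integer half-width of the window.
#' @param weights `"uniform"` or an explicit nonnegative array of dim
#'   `rep(2*radius + 1, ndim)` with positive sum.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(ndim, radius = 1L, weights = "uniform") {
  if (!ndim %in% 2:4) stop_config("kernel ndim must be 2, 3 or 4")
  radius <- as.integer(radius)
  if (radius < 0L) stop_config("kernel radius must be >= 0")
  side <- 2L * radius + 1L
  if (identical(weights, "uniform")) {
    weights <- array(1, dim = rep(side, ndim))
  } else {
    weights <- as.array(weights)
    if (ndim == 1L || is.null(dim(weights))) dim(weights) <- length(weights)
    if (!identical(as.integer(dim(weights)), rep(side, ndim)))
      stop_config("weights must have dim (", paste(rep(side, ndim), collapse = ","), ")")
    if (any(weights < 0) || any(!is.finite(weights)))
      stop_config("weights must be finite and nonnegative")
  }
  if (sum(weights) <= 0) stop_config("kernel weights must have positive sum")
  structure(list(ndim = as.integer(ndim), radius = radius, weights = weights),
            class = "kernel_spec")
}

#' Weighted-mean denoising of a perfusion series
#'
#' Replaces each value by the weight-normalised mean of its
#' neighbourhood: in-slice spatial (2D), spatial (3D), or spatial plus
#' time (4D). At the volume borders the window is truncated to the
#' in-bounds part and the weights renormalised over it, so edges are not
#' darkened. A constant field is preserved exactly by any kernel.
#'
#' @param series A `voxel_major` [perfusion_series()] (per-voxel
#'   processing layout; use [reorganize()] first).
#' @param kernel A [kernel_spec()].
#' @return The filtered series, same dims and layout.
#' @export
denoise_weighted_mean <- function(series, kernel) {
  stopifnot(inherits(series, "perfusion_series"), inherits(kernel, "kernel_spec"))
  if (series$layout != "voxel_major")
    stop_config("denoise_weighted_mean expects a voxel_major series")
  D <- series$data
  dm <- dim(D)
  r <- kernel$radius
  if (r == 0L) {
    # window is the voxel itself; normalisation makes this the identity
    return(series)
  }
  # data axes touched by the kernel, matching the weight-array axis order
  axes <- switch(as.character(kernel$ndim),
                 "2" = c(2L, 3L),
                 "3" = c(2L, 3L, 4L),
                 "4" = c(2L, 3L, 4L, 1L))
  num <- array(0, dm)
  den <- array(0, dm)
  offs <- as.matrix(do.call(expand.grid, rep(list(seq.int(-r, r)), kernel$ndim)))
  full <- lapply(dm, seq_len)
  for (k in seq_len(nrow(offs))) {
    wk <- kernel$weights[matrix(offs[k, ] + r + 1L, nrow = 1L)]
    if (wk == 0) next
    dst <- full
    src <- full
    ok <- TRUE
    for (a in seq_len(kernel$ndim)) {
      ax <- axes[a]; n <- dm[ax]; o <- offs[k, a]
      if (abs(o) >= n) { ok <- FALSE; break }
      if (o >= 0L) {          # neighbour at +o exists for positions 1..n-o
        dst[[ax]] <- seq_len(n - o); src[[ax]] <- seq.int(1L + o, n)
      } else {
        dst[[ax]] <- seq.int(1L - o, n); src[[ax]] <- seq_len(n + o)
      }
    }
    if (!ok) next
    num[dst[[1]], dst[[2]], dst[[3]], dst[[4]]] <-
      num[dst[[1]], dst[[2]], dst[[3]], dst[[4]]] +
      wk * D[src[[1]], src[[2]], src[[3]], src[[4]]]
    den[dst[[1]], dst[[2]], dst[[3]], dst[[4]]] <-
      den[dst[[1]], dst[[2]], dst[[3]], dst[[4]]] + wk
  }
  out <- num / den
  bad <- den == 0            # possible if every in-bounds weight is zero
  if (any(bad)) out[bad] <- D[bad]
  series$data <- out
  series
}

#' Subtract the pre-bolus baseline from every voxel curve
#'
#' Converts raw intensity curves to concentration-like signals by
#' subtracting, per voxel, the mean of the first `n_baseline` (pre-bolus)
#' frames. Results may be negative.
#'
#' @param series A [perfusion_series()] in either layout.
#' @param n_baseline Number of leading frames to average
#'   (`1 <= n_baseline < Time`).
#' @return The corrected series.
#' @export
baseline_correct <- function(series, n_baseline) {
  stopifnot(inherits(series, "perfusion_series"))
  nt <- series$dims[["time"]]
  n_baseline <- as.integer(n_baseline)
  if (is.na(n_baseline) || n_baseline < 1L || n_baseline >= nt)
    stop_config("n_baseline must be in [1, Time-1]; got ", n_baseline,
                " with Time = ", nt)
  d <- series$data
  dm <- dim(d)
  if (series$layout == "voxel_major") {
    m <- matrix(d, nrow = nt)
    base <- colMeans(m[seq_len(n_baseline), , drop = FALSE])
    m <- m - rep(base, each = nt)
    series$data <- array(m, dim = dm)
  } else {
    nv <- prod(dm[1:3])
    m <- matrix(d, nrow = nv)
    base <- rowMeans(m[, seq_len(n_baseline), drop = FALSE])
    m <- m - base
    series$data <- array(m, dim = dm)
  }
  series
}

#' Threshold-based brain mask
#'
#' A voxel is inside the mask iff its time-averaged intensity is at
#' least `frac` times the maximum time-averaged intensity anywhere in
#' the volume. Intended to exclude air/background before deconvolution.
#'
#' @param series A [perfusion_series()] in either layout.
#' @param frac Fraction of the maximum in (0, 1).
#' @return 3D logical array `(Dim1, Dim2, Dim3)`.
#' @export
compute_brain_mask <- function(series, frac) {
  stopifnot(inherits(series, "perfusion_series"))
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac >= 1)
    stop_config("frac must be in (0, 1)")
  avg <- time_avg_volume(series)
  avg >= frac * max(avg)
}
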