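#' Truncated singular value decomposition
#'
#' Factorises a square matrix as `U diag(W) V'` and records which
#' singular values survive relative truncation: values strictly smaller
#' than `rel_threshold * max(W)` are zeroed when the pseudoinverse is
#' formed (boundary values are kept). The discrete deconvolution problem
#' is ill-posed -- rows of the convolution matrix of a smooth bolus are
#' near-linear combinations -- and truncation is what keeps the solution
#' from amplifying measurement noise.
#'
#' @param x A square numeric matrix or an [build_aif_matrix()] result.
#' @param rel_threshold Fraction of the largest singular value in
#'   `[0, 1)`.
#' @return A `truncated_svd` object: fields `u`, `d` (descending), `v`,
#'   `rel_threshold`, `retained_rank`.
#' @export
truncated_svd <- function(x, rel_threshold = 0.2) {
  M <- if (inherits(x, "aif_matrix")) x$matrix else as.matrix(x)
  if (nrow(M) != ncol(M)) stop_dims("matrix must be square")
  if (!is.numeric(rel_threshold) || length(rel_threshold) != 1L ||
      rel_threshold < 0 || rel_threshold >= 1)
    stop_config("rel_threshold must be in [0, 1)")
  s <- svd(M)
  kept <- !(s$d < rel_threshold * s$d[1L])    # strict <: boundary kept
  if (s$d[1L] <= 0 || !any(kept))
    stop_config("all singular values truncated (zero matrix?)")
  structure(list(u = s$u, d = s$d, v = s$v,
                 rel_threshold = rel_threshold,
                 retained_rank = sum(kept)),
            class = "truncated_svd")
}

#' @export
print.truncated_svd <- function(x, ...) {
  cat(sprintf("<truncated_svd> %d x %d, rank %d/%d retained at threshold %g\n",
              nrow(x$u), ncol(x$u), x$retained_rank, length(x$d), x$rel_threshold))
  invisible(x)
}

#' Truncated-SVD pseudoinverse of an AIF matrix
#'
#' Computes the SVD of the convolution matrix, zeroes every singular
#' value below `rel_threshold` times the largest, and returns
#' `V diag(1/W or 0) U'`. At threshold 0 on an invertible matrix this is
#' the ordinary inverse (to floating-point accuracy); positive
#' thresholds trade bias for noise robustness.
#'
#' @param Ca An [build_aif_matrix()] result or a square numeric matrix.
#' @param rel_threshold Fraction of the largest singular value in
#'   `[0, 1)`; default 0.2, the customary value for perfusion SVD.
#' @return A Time x Time matrix; attribute `"retained_rank"` gives the
#'   number of singular values kept.
#' @export
truncated_pseudoinverse <- function(Ca, rel_threshold = 0.2) {
  ts <- truncated_svd(Ca, rel_threshold)
  dinv <- ifelse(ts$d < ts$rel_threshold * ts$d[1L], 0, 1 / ts$d)
  P <- ts$v %*% (dinv * t(ts$u))
  attr(P, "retained_rank") <- ts$retained_rank
  P
}

#' Deconvolve one voxel curve
#'
#' The impulse response function (IRF) of a voxel is the pseudoinverse
#' applied to its concentration curve: `h = V W^-1 (U' Ct)`, evaluated
#' as a single matrix-vector product with the precomputed pseudoinverse
#' (one pseudoinverse serves every voxel sharing the same AIF).
#'
#' @param Ct Numeric concentration curve of length `Time`.
#' @param Ca_pinv Time x Time pseudoinverse from
#'   [truncated_pseudoinverse()].
#' @return Numeric IRF of length `Time`.
#' @export
deconvolve_voxel <- function(Ct, Ca_pinv) {
  if (length(Ct) != ncol(Ca_pinv))
    stop_dims("curve length ", length(Ct), " does not match matrix size ",
              ncol(Ca_pinv))
  as.vector(Ca_pinv %*% Ct)
}
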