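#' Arterial input function vector
#'
#' The contrast concentration sampled in a feeding artery,
#' `Ca(t1) ... Ca(tN)`, on the same time grid as the tissue curves.
#'
#' @param values Numeric vector of length `Time` with at least one
#'   strictly positive value.
#' @param dt Sampling interval in seconds.
#' @return An `aif_vector` object.
#' @export
aif_vector <- function(values, dt) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop_config("AIF must have at least one sample")
  if (!any(values > 0)) stop_config("AIF must have at least one positive value")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop_config("`dt` must be a single positive number of seconds")
  structure(list(values = values, dt = as.numeric(dt)), class = "aif_vector")
}

#' @export
print.aif_vector <- function(x, ...) {
  cat(sprintf("<aif_vector> %d samples, dt = %g s, peak = %g at t = %g s\n",
              length(x$values), x$dt, max(x$values),
              x$dt * which.max(x$values)))
  invisible(x)
}

#' Read an AIF vector from a plain-text file
#'
#' One value per line.
#'
#' @param path Text file path.
#' @param dt Sampling interval in seconds.
#' @return An [aif_vector()].
#' @export
read_aif_text <- function(path, dt) {
  aif_vector(scan(path, what = numeric(), quiet = TRUE), dt)
}

#' Build the discrete convolution matrix of an AIF
#'
#' The convolution of the AIF with a tissue impulse response, sampled on
#' a regular grid, is the matrix product of a dt-scaled lower-triangular
#' Toeplitz matrix with the response vector: entry `(i, j)` is
#' `dt * Ca(t[i-j+1])` for `i >= j` and 0 above the diagonal. Its
#' determinant is `(dt * Ca(t1))^N`, so the matrix is invertible exactly
#' when the first AIF sample is nonzero.
#'
#' @param aif An [aif_vector()].
#' @return An `aif_matrix` object with fields `matrix` (Time x Time),
#'   `dt` and `source` (the input AIF).
#' @export
build_aif_matrix <- function(aif) {
  stopifnot(inherits(aif, "aif_vector"))
  v <- aif$values
  n <- length(v)
  M <- matrix(0, n, n)
  lag <- row(M) - col(M) + 1L
  lower <- lag >= 1L
  M[lower] <- aif$dt * v[lag[lower]]
  structure(list(matrix = M, dt = aif$dt, source = aif), class = "aif_matrix")
}

# Arterial-likeness score for candidate curves: high, early bolus.
# peak / (1 + zero-based time-to-peak index); computed column-wise.
aif_candidate_scores <- function(curves) {
  tp <- max.col(t(curves), ties.method = "first")      # 1-based argmax
  peak <- curves[cbind(tp, seq_len(ncol(curves)))]
  list(score = peak / tp, peak = peak, tp = tp)
}

# Average the top_k highest-scoring candidate columns. Ties broken by
# (score desc, linear voxel index asc) for determinism.
top_k_mean_curve <- function(curves, cand_idx, top_k) {
  sc <- aif_candidate_scores(curves)
  ord <- order(-sc$score, cand_idx)
  sel <- ord[seq_len(top_k)]
  list(values = rowMeans(curves[, sel, drop = FALSE]),
       selected = sort(cand_idx[sel]))
}

#' Select a global AIF from the full volume
#'
#' Scores every in-mask voxel curve by peak height divided by
#' `1 + (zero-based time-to-peak index)` -- encoding the "high, early
#' bolus" signature of arterial voxels -- and averages the `top_k`
#' highest-scoring curves. Ties are broken by ascending linear voxel
#' index so the selection is deterministic.
#'
#' @param series A `voxel_major` [perfusion_series()].
#' @param mask 3D logical array; `NULL` means all voxels.
#' @param top_k Number of curves to average (default 5).
#' @return An [aif_vector()] with attribute `"voxels"` giving the linear
#'   indices of the selected voxels.
#' @export
select_global_aif <- function(series, mask = NULL, top_k = 5L) {
  stopifnot(inherits(series, "perfusion_series"))
  if (series$layout != "voxel_major")
    stop_config("select_global_aif expects a voxel_major series")
  m <- voxel_matrix(series)
  cand <- if (is.null(mask)) seq_len(ncol(m)) else which(as.vector(mask))
  if (length(cand) < top_k)
    stop_config("mask has ", length(cand), " voxels; need at least top_k = ", top_k)
  res <- top_k_mean_curve(m[, cand, drop = FALSE], cand, top_k)
  out <- aif_vector(res$values, series$dt)
  attr(out, "voxels") <- res$selected
  out
}

#' Generate a local AIF for one voxel
#'
#' Applies the [select_global_aif()] scoring restricted to the in-mask
#' voxels of the cubic neighbourhood of side `2*radius + 1` centred on
#' `voxel` (clipped at the volume borders). If fewer than `top_k`
#' candidates have a strictly positive peak, the `fallback` AIF
#' (normally the global one) is returned instead, so a local AIF always
#' exists.
#'
#' @param series A `voxel_major` [perfusion_series()].
#' @param voxel Integer `(x, y, z)` position, 1-based.
#' @param radius Neighbourhood half-width in voxels (>= 1).
#' @param top_k Number of curves to average.
#' @param fallback An [aif_vector()] used when the neighbourhood has no
#'   usable arterial candidates.
#' @param mask Optional 3D logical array restricting candidates.
#' @return An [aif_vector()].
#' @export
generate_local_aif <- function(series, voxel, radius, top_k, fallback, mask = NULL) {
  stopifnot(inherits(series, "perfusion_series"), inherits(fallback, "aif_vector"))
  if (series$layout != "voxel_major")
    stop_config("generate_local_aif expects a voxel_major series")
  sp <- series$dims[c("dim1", "dim2", "dim3")]
  local_aif_curve(voxel_matrix(series), sp, voxel, radius, top_k, fallback,
                  if (is.null(mask)) NULL else as.vector(mask), series$dt)
}

# Workhorse behind generate_local_aif, on a precomputed Time x Size
# matrix so the per-voxel loop of the local-AIF engine mode does not
# re-copy the series.
local_aif_curve <- function(ctmat, sp, voxel, radius, top_k, fallback,
                            mask_vec = NULL, dt = fallback$dt) {
  if (radius < 1L) stop_config("local AIF radius must be >= 1")
  if (any(voxel < 1L) || any(voxel > sp))
    stop_dims("voxel (", paste(voxel, collapse = ","), ") outside volume")
  rng <- lapply(1:3, function(a) {
    seq.int(max(1L, voxel[a] - radius), min(sp[a], voxel[a] + radius))
  })
  grid <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  idx <- grid$x + sp[1L] * (grid$y - 1L) + sp[1L] * sp[2L] * (grid$z - 1L)
  if (!is.null(mask_vec)) idx <- idx[mask_vec[idx]]
  idx <- sort(idx)
  if (length(idx) == 0L) return(fallback)
  curves <- ctmat[, idx, drop = FALSE]
  sc <- aif_candidate_scores(curves)
  pos <- sc$peak > 0
  if (sum(pos) < top_k) return(fallback)
  res <- top_k_mean_curve(curves[, pos, drop = FALSE], idx[pos], top_k)
  out <- aif_vector(res$values, dt)
  attr(out, "voxels") <- res$selected
  out
}
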