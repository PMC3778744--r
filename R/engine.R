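#' Pipeline run configuration
#'
#' Collects every tunable of the quantification pipeline. Defaults
#' follow common perfusion-SVD practice; each field is documented with
#' its unit.
#'
#' @param dt Sampling interval in seconds; `NULL` uses the series' own.
#' @param svd_rel_threshold Relative SVD truncation threshold in
#'   `[0, 1)` (fraction of the largest singular value); default 0.2.
#' @param aif_mode `"global"` (one AIF selected from the volume),
#'   `"local"` (one AIF per voxel neighbourhood) or `"file"`
#'   (user-supplied vector).
#' @param aif An [aif_vector()], required for `aif_mode = "file"`
#'   unless `aif_file` is given.
#' @param aif_file Plain-text AIF file (one value per line).
#' @param global_top_k,local_top_k Curves averaged into the global /
#'   local AIF; defaults 5.
#' @param local_radius Half-width of the cubic local-AIF neighbourhood
#'   in voxels; default 5.
#' @param denoise Optional [kernel_spec()]; `NULL` disables denoising
#'   (inputs are usually already concentration curves).
#' @param baseline_frames Optional count of pre-bolus frames whose mean
#'   is subtracted per voxel; `NULL` disables.
#' @param mask_frac Brain-mask threshold as a fraction of the maximum
#'   time-averaged intensity; default 0.15.
#' @param workers Worker count for [run_parallel()]; default 2.
#' @param chunk `"slice"` (one axial slice per chunk, the default) or a
#'   positive integer giving voxels per chunk.
#' @param rise_frac Arrival threshold for the TA map; default 0.1.
#' @param lo_pct,hi_pct Display window percentiles for rendering.
#' @return A `run_config` object.
#' @export
run_config <- function(dt = NULL, svd_rel_threshold = 0.2,
                       aif_mode = c("global", "local", "file"),
                       aif = NULL, aif_file = NULL,
                       global_top_k = 5L, local_radius = 5L, local_top_k = 5L,
                       denoise = NULL, baseline_frames = NULL,
                       mask_frac = 0.15, workers = 2L, chunk = "slice",
                       rise_frac = 0.1, lo_pct = 2, hi_pct = 98) {
  aif_mode <- match.arg(aif_mode)
  if (!is.null(dt) && (!is.numeric(dt) || dt <= 0))
    stop_config("dt must be positive (seconds)")
  if (svd_rel_threshold < 0 || svd_rel_threshold >= 1)
    stop_config("svd_rel_threshold must be in [0, 1)")
  if (aif_mode == "file" && is.null(aif) && is.null(aif_file))
    stop_config("aif_mode 'file' needs `aif` or `aif_file`")
  if (aif_mode != "file" && (!is.null(aif) || !is.null(aif_file)))
    stop_config("`aif`/`aif_file` given but aif_mode is '", aif_mode,
                "'; use aif_mode = 'file'")
  if (!is.null(denoise) && !inherits(denoise, "kernel_spec"))
    stop_config("denoise must be NULL or a kernel_spec")
  if (mask_frac <= 0 || mask_frac >= 1) stop_config("mask_frac must be in (0, 1)")
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) stop_config("workers must be >= 1")
  if (!identical(chunk, "slice")) {
    chunk <- as.integer(chunk)
    if (is.na(chunk) || chunk < 1L) stop_config("chunk must be 'slice' or a positive integer")
  }
  if (rise_frac <= 0 || rise_frac >= 1) stop_config("rise_frac must be in (0, 1)")
  if (lo_pct < 0 || hi_pct > 100 || lo_pct >= hi_pct)
    stop_config("need 0 <= lo_pct < hi_pct <= 100")
  structure(list(dt = dt, svd_rel_threshold = svd_rel_threshold,
                 aif_mode = aif_mode, aif = aif, aif_file = aif_file,
                 global_top_k = as.integer(global_top_k),
                 local_radius = as.integer(local_radius),
                 local_top_k = as.integer(local_top_k),
                 denoise = denoise, baseline_frames = baseline_frames,
                 mask_frac = mask_frac, workers = workers, chunk = chunk,
                 rise_frac = rise_frac, lo_pct = lo_pct, hi_pct = hi_pct),
            class = "run_config")
}

# ---------------------------------------------------------------------
# Shared pipeline front end: denoise + reorganise, mask, baseline,
# AIF resolution. Returns the per-voxel processing context used by both
# engines; everything downstream of here is scheduling.
prepare_run <- function(series, config) {
  stopifnot(inherits(series, "perfusion_series"), inherits(config, "run_config"))
  dt <- config$dt %||% series$dt
  timings <- c()
  t0 <- proc.time()[["elapsed"]]
  vm <- reorganize(series, "voxel_major")
  if (!is.null(config$denoise)) vm <- denoise_weighted_mean(vm, config$denoise)
  timings["reorganize_denoise"] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  mask <- compute_brain_mask(vm, config$mask_frac)
  if (!is.null(config$baseline_frames))
    vm <- baseline_correct(vm, config$baseline_frames)
  nt <- vm$dims[["time"]]

  aif <- switch(config$aif_mode,
    file = {
      a <- config$aif %||% read_aif_text(config$aif_file, dt)
      if (length(a$values) != nt)
        stop_dims("AIF has ", length(a$values), " samples but series has Time = ", nt)
      aif_vector(a$values, dt)
    },
    global = ,
    local = {
      g <- select_global_aif(vm, mask, config$global_top_k)
      aif_vector(g$values, dt)
    })
  timings["mask_aif"] <- proc.time()[["elapsed"]] - t0

  n_svd <- 0L
  pinv <- NULL
  if (config$aif_mode != "local") {
    pinv <- truncated_pseudoinverse(build_aif_matrix(aif), config$svd_rel_threshold)
    n_svd <- 1L
  }
  sp <- unname(vm$dims[c("dim1", "dim2", "dim3")])
  list(ctmat = voxel_matrix(vm), mask_vec = as.vector(mask),
       mask = mask, sp = sp, dt = dt, nt = nt, aif = aif, pinv = pinv,
       n_svd_setup = n_svd, config = config, timings = timings)
}

# Partition the linear voxel indices 1..Size into chunks. "slice" gives
# one axial (dim3) slice per chunk -- contiguous because the linear
# index runs dim1 fastest; an integer gives consecutive blocks of that
# many voxels (the last may be short).
chunk_indices <- function(sp, chunk) {
  size <- prod(sp)
  if (identical(chunk, "slice")) {
    per <- prod(sp[1:2])
    lapply(seq_len(sp[3L]), function(z) seq.int((z - 1L) * per + 1L, z * per))
  } else {
    k <- as.integer(chunk)
    unname(split(seq_len(size), ceiling(seq_len(size) / k)))
  }
}

# One reusable deconvolution workspace per worker: holds the result
# buffer that is recycled across the worker's chunks instead of being
# reallocated per voxel (the scratch-pool contract of the parallel
# engine). `creations` is a diagnostic counter used by tests.
new_workspace <- function() {
  ws <- new.env(parent = emptyenv())
  ws$out <- NULL
  ws$chunks_seen <- 0L
  ws
}

workspace_buffer <- function(ws, n) {
  if (is.null(ws$out) || ncol(ws$out) < n) ws$out <- matrix(NA_real_, 6L, n)
  else ws$out[] <- NA_real_
  ws$chunks_seen <- ws$chunks_seen + 1L
  ws$out
}

# Per-voxel quantification of one chunk. This function is the *only*
# place voxel results are computed; serial and parallel engines differ
# purely in how chunks are scheduled, which is what guarantees
# bit-identical output.
process_chunk <- function(ct_sub, idx, ctx, ws) {
  n <- length(idx)
  out <- workspace_buffer(ws, n)
  nsvd <- 0L
  local_mode <- ctx$config$aif_mode == "local"
  thr <- ctx$config$svd_rel_threshold
  rise <- ctx$config$rise_frac
  dt <- ctx$dt
  pinv <- ctx$pinv
  for (k in seq_len(n)) {
    i <- idx[k]
    if (!ctx$mask_vec[i]) { out[6L, k] <- 0; next }
    ct <- ct_sub[, k]
    if (local_mode) {
      vox <- linear_to_xyz(i, ctx$sp)
      laif <- local_aif_curve(ctx$ctmat, ctx$sp, vox, ctx$config$local_radius,
                              ctx$config$local_top_k, ctx$aif, ctx$mask_vec, dt)
      pinv <- truncated_pseudoinverse(build_aif_matrix(laif), thr)
      nsvd <- nsvd + 1L
    }
    h <- deconvolve_voxel(ct, pinv)
    sm <- compute_scalar_maps(h, dt)
    if (sm$valid) {
      tm <- compute_timing_maps(ct, dt, rise)
      out[, k] <- c(sm$cbf, sm$cbv, sm$mtt, tm[[1L]], tm[[2L]], 1)
    } else {
      out[6L, k] <- 0
    }
  }
  list(res = out[, seq_len(n), drop = FALSE], nsvd = nsvd)
}

linear_to_xyz <- function(i, sp) {
  i0 <- i - 1L
  x <- i0 %% sp[1L]
  y <- (i0 %/% sp[1L]) %% sp[2L]
  z <- i0 %/% (sp[1L] * sp[2L])
  c(x, y, z) + 1L
}

assemble_maps <- function(results, chunks, ctx) {
  size <- prod(ctx$sp)
  flat <- matrix(NA_real_, 6L, size)
  nsvd <- ctx$n_svd_setup
  for (j in seq_along(chunks)) {
    flat[, chunks[[j]]] <- results[[j]]$res
    nsvd <- nsvd + results[[j]]$nsvd
  }
  valid <- array(flat[6L, ] == 1, dim = ctx$sp)
  shape <- function(r) {
    v <- flat[r, ]
    v[!valid] <- NaN
    array(v, dim = ctx$sp)
  }
  structure(list(cbf = shape(1L), cbv = shape(2L), mtt = shape(3L),
                 ttp = shape(4L), ta = shape(5L), valid = valid,
                 dt = ctx$dt, aif = ctx$aif, n_svd = nsvd,
                 mask = ctx$mask, config = ctx$config,
                 timings = ctx$timings),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("<parametric_maps> %s voxels, %d valid (%.1f%%), dt = %g s\n",
              paste(dim(x$valid), collapse = " x "), sum(x$valid),
              100 * mean(x$valid), x$dt))
  for (m in c("cbf", "cbv", "mtt", "ttp", "ta")) {
    v <- x[[m]][x$valid]
    v <- v[is.finite(v)]
    if (length(v))
      cat(sprintf("  %-3s median %.4g  [%.4g, %.4g]\n", m,
                  median(v), min(v), max(v)))
  }
  invisible(x)
}

#' Run the quantification pipeline serially
#'
#' Executes load - (denoise +) reorganise - AIF - per-voxel
#' deconvolution - map generation in order, one voxel at a time. This is
#' the reference engine: [run_parallel()] is required to reproduce its
#' output bit for bit.
#'
#' @param series A [perfusion_series()] (either layout).
#' @param config A [run_config()].
#' @return A `parametric_maps` object: 3D `cbf`, `cbv`, `mtt`, `ttp`,
#'   `ta` arrays (NaN at invalid voxels), logical `valid`, the AIF used,
#'   and the SVD call count `n_svd` (1 in global/file mode, one per
#'   in-mask voxel in local mode).
#' @export
run_serial <- function(series, config = run_config()) {
  ctx <- prepare_run(series, config)
  chunks <- chunk_indices(ctx$sp, config$chunk)
  ws <- new_workspace()
  t0 <- proc.time()[["elapsed"]]
  results <- lapply(chunks, function(idx) {
    process_chunk(ctx$ctmat[, idx, drop = FALSE], idx, ctx, ws)
  })
  ctx$timings["deconvolve"] <- proc.time()[["elapsed"]] - t0
  ctx$timings["workspaces"] <- 1
  assemble_maps(results, chunks, ctx)
}

#' Run the quantification pipeline on a worker pool
#'
#' Partitions the voxels into chunks (one axial slice each by default),
#' processes them on `config$workers` separate R worker processes --
#' each holding one reusable deconvolution workspace recycled across
#' its chunks -- and writes every result into the output volume at the
#' voxel's global index. Chunking is a partition (every voxel processed
#' exactly once) and per-voxel arithmetic is byte-identical to
#' [run_serial()]; only the scheduling differs, so the five maps and
#' the validity mask are bitwise equal to the serial engine's for every
#' workers/chunk setting.
#'
#' @inheritParams run_serial
#' @return A `parametric_maps` object, bit-identical to [run_serial()].
#' @export
run_parallel <- function(series, config = run_config()) {
  ctx <- prepare_run(series, config)
  chunks <- chunk_indices(ctx$sp, config$chunk)
  nw <- min(config$workers, length(chunks))
  if (nw <= 1L) {
    ws <- new_workspace()
    t0 <- proc.time()[["elapsed"]]
    results <- lapply(chunks, function(idx) {
      process_chunk(ctx$ctmat[, idx, drop = FALSE], idx, ctx, ws)
    })
    ctx$timings["deconvolve"] <- proc.time()[["elapsed"]] - t0
    ctx$timings["workspaces"] <- 1
    return(assemble_maps(results, chunks, ctx))
  }
  cl <- parallel::makePSOCKcluster(nw)
  on.exit(parallel::stopCluster(cl), add = TRUE)
  # Ship the shared context once per worker; chunk payloads carry only
  # their own curves. Workers keep one workspace for the whole run.
  # worker_init / worker_run_chunk are top-level namespace functions so
  # that only a namespace reference travels with each call, never the
  # engine's execution environment.
  wctx <- ctx
  if (config$aif_mode != "local") wctx$ctmat <- NULL   # not needed remotely
  parallel::clusterCall(cl, worker_init, wctx)
  tasks <- lapply(chunks, function(idx) {
    list(idx = idx, ct = ctx$ctmat[, idx, drop = FALSE])
  })
  t0 <- proc.time()[["elapsed"]]
  results <- parallel::clusterApply(cl, tasks, worker_run_chunk)
  ctx$timings["deconvolve"] <- proc.time()[["elapsed"]] - t0
  ctx$timings["workspaces"] <- nw
  assemble_maps(results, chunks, ctx)
}

# Runs once per PSOCK worker: installs the shared context and the
# worker's single reusable workspace in its global environment.
worker_init <- function(ctx) {
  assign(".perfmap_ctx", ctx, envir = globalenv())
  assign(".perfmap_ws", new_workspace(), envir = globalenv())
  NULL
}

worker_run_chunk <- function(task) {
  ctx <- get(".perfmap_ctx", envir = globalenv())
  if (is.null(ctx$ctmat)) ctx$ctmat <- task$ct   # only consulted in local mode
  process_chunk(task$ct, task$idx, ctx,
                get(".perfmap_ws", envir = globalenv()))
}
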