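#' Scalar hemodynamic parameters of one impulse response
#'
#' * CBF is the maximum of the IRF over time.
#' * CBV is the rectangle-rule time integral of the IRF,
#'   `dt * sum(max(h, 0))`; negative lobes (truncation ringing) are
#'   clipped to zero in the sum only, so CBV stays nonnegative without
#'   masking a genuine peak.
#' * MTT is CBV / CBF, the central volume theorem.
#'
#' A voxel is invalid (all parameters `NA`) when CBF or CBV is not
#' strictly positive.
#'
#' @param h Numeric IRF of length >= 1.
#' @param dt Sampling interval in seconds.
#' @return List with `cbf` (IRF-amplitude units), `cbv`
#'   (amplitude-seconds), `mtt` (seconds) and logical `valid`.
#' @export
compute_scalar_maps <- function(h, dt) {
  cbf <- max(h)
  cbv <- dt * sum(pmax.int(h, 0))
  if (!is.finite(cbf) || !is.finite(cbv) || cbf <= 0 || cbv <= 0)
    return(list(cbf = NA_real_, cbv = NA_real_, mtt = NA_real_, valid = FALSE))
  list(cbf = cbf, cbv = cbv, mtt = cbv / cbf, valid = TRUE)
}

#' Bolus timing parameters of one concentration curve
#'
#' TTP (time to peak) is `dt` times the zero-based index of the curve's
#' first maximum; TA (time of arrival) is `dt` times the zero-based
#' index of the first sample reaching `rise_frac` of the maximum. Both
#' are `NaN` when the curve never goes positive.
#'
#' @param Ct Numeric curve of length >= 2.
#' @param dt Sampling interval in seconds.
#' @param rise_frac Arrival threshold as a fraction of the peak,
#'   in (0, 1); default 0.1.
#' @return Named numeric `c(ttp, ta)` in seconds.
#' @export
compute_timing_maps <- function(Ct, dt, rise_frac = 0.1) {
  if (length(Ct) < 2L) stop_dims("curve must have at least two samples")
  if (!is.numeric(rise_frac) || rise_frac <= 0 || rise_frac >= 1)
    stop_config("rise_frac must be in (0, 1)")
  m <- max(Ct)
  if (!is.finite(m) || m <= 0) return(c(ttp = NaN, ta = NaN))
  c(ttp = dt * (which.max(Ct) - 1L),
    ta  = dt * (which(Ct >= rise_frac * m)[1L] - 1L))
}

#' The fixed blue-to-red colour lookup table
#'
#' 256 RGB rows (0..255) interpolated through
#' blue - cyan - green - yellow - red, the conventional perfusion-map
#' palette (low values cold, high values hot).
#'
#' @return 256 x 3 integer matrix, columns R, G, B.
#' @export
perfusion_lut <- function() {
  ramp <- colorRamp(c("#0000FF", "#00FFFF", "#00FF00", "#FFFF00", "#FF0000"))
  lut <- round(ramp(seq(0, 1, length.out = 256L)))
  storage.mode(lut) <- "integer"
  colnames(lut) <- c("R", "G", "B")
  lut
}

#' Render a parametric map as per-slice RGB images
#'
#' Valid voxel values are clipped to the `[lo_pct, hi_pct]` percentile
#' range of the valid voxels, mapped linearly to 0..255 and passed
#' through the fixed [perfusion_lut()]. Invalid voxels render black. A
#' degenerate range (constant map, or no valid voxels) maps to LUT index
#' 0 by convention.
#'
#' @param map3d 3D numeric array.
#' @param valid 3D logical array, same dims.
#' @param lo_pct,hi_pct Percentiles, `0 <= lo_pct < hi_pct <= 100`.
#' @return List of `Dim3` integer arrays of dim `(Dim1, Dim2, 3)` with
#'   byte values 0..255; attributes `"lo"`/`"hi"` record the window.
#' @export
render_colormap <- function(map3d, valid, lo_pct = 2, hi_pct = 98) {
  if (!identical(dim(map3d), dim(valid))) stop_dims("map and valid dims differ")
  if (lo_pct < 0 || hi_pct > 100 || lo_pct >= hi_pct)
    stop_config("need 0 <= lo_pct < hi_pct <= 100")
  lut <- perfusion_lut()
  ok <- valid & is.finite(map3d)
  vals <- map3d[ok]
  if (length(vals) == 0L) {
    lo <- hi <- NA_real_
    idx <- array(0L, dim(map3d))
  } else {
    lo <- quantile(vals, lo_pct / 100, names = FALSE, type = 7)
    hi <- quantile(vals, hi_pct / 100, names = FALSE, type = 7)
    if (hi - lo <= 0) {
      idx <- array(0L, dim(map3d))
    } else {
      sc <- pmin(pmax((map3d - lo) / (hi - lo), 0), 1)
      idx <- array(as.integer(round(sc * 255)), dim(map3d))
    }
  }
  nz <- dim(map3d)[3L]
  out <- vector("list", nz)
  for (z in seq_len(nz)) {
    iz <- idx[, , z]
    rgb <- array(0L, c(dim(map3d)[1:2], 3L))
    okz <- ok[, , z]
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[okz] <- lut[iz[okz] + 1L, ch]
      rgb[, , ch] <- plane
    }
    out[[z]] <- rgb
  }
  attr(out, "lo") <- lo
  attr(out, "hi") <- hi
  out
}

#' Write rendered slices as PNG files
#'
#' One file per axial slice, named `<prefix>_slice<zz>.png`. Rows run
#' top-to-bottom with increasing radiological `y` flipped for display,
#' columns are `x`.
#'
#' @param rendered Output of [render_colormap()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, e.g. `"cbf"`.
#' @return Character vector of file paths, invisibly.
#' @export
write_map_pngs <- function(rendered, dir, prefix) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(rendered))
  for (z in seq_along(rendered)) {
    rgb <- rendered[[z]]
    # (x, y, ch) -> image rows = y reversed, cols = x, scaled to [0,1]
    img <- aperm(rgb[, rev(seq_len(dim(rgb)[2L])), , drop = FALSE], c(2L, 1L, 3L)) / 255
    paths[z] <- file.path(dir, sprintf("%s_slice%02d.png", prefix, z))
    png::writePNG(img, paths[z])
  }
  invisible(paths)
}
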