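#' 4D perfusion series container
#'
#' A `perfusion_series` wraps a 4D numeric array together with its grid
#' metadata: voxel dimensions, sampling interval and storage layout. Two
#' layouts are supported, differing only in which axis varies slowest in
#' memory:
#'
#' * `time_major`: array dimensions `(Dim1, Dim2, Dim3, Time)`. With R's
#'   column-major storage this means the first spatial axis varies
#'   fastest and time slowest -- the order in which volumes arrive from a
#'   scanner (one complete 3D volume per time point).
#' * `voxel_major`: array dimensions `(Time, Dim1, Dim2, Dim3)`, so each
#'   voxel's full time curve is contiguous. All per-voxel processing
#'   (AIF selection, deconvolution) operates on this layout.
#'
#' @param data 4D numeric array, axis order per `layout`.
#' @param dt Sampling interval in seconds (> 0).
#' @param layout `"time_major"` or `"voxel_major"`.
#' @param affine 4x4 spatial transform carried through to any maps
#'   written from this series; defaults to `diag(4)`.
#' @param source_dtype Optional record of the on-disk numeric type.
#' @return An object of class `perfusion_series` with fields `data`,
#'   `dims` (always named `(dim1, dim2, dim3, time)` irrespective of
#'   layout), `dt`, `layout`, `affine`, `source_dtype`.
#' @seealso [read_series()], [reorganize()]
#' @export
perfusion_series <- function(data, dt, layout = c("time_major", "voxel_major"),
                             affine = NULL, source_dtype = NULL) {
  layout <- match.arg(layout)
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_dims("`data` must be a 4D array, got ", length(dim(data)), " dimension(s)")
  dm <- dim(data)
  dims <- if (layout == "time_major") c(dm[1:3], dm[4]) else c(dm[2:4], dm[1])
  names(dims) <- c("dim1", "dim2", "dim3", "time")
  if (dims[["time"]] < 2L)
    stop_dims("a perfusion series needs at least two time points")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop_config("`dt` must be a single positive number of seconds")
  # plain double array: drop any reader-specific attributes
  data <- array(as.double(data), dim = unname(dm))
  if (is.null(affine)) affine <- diag(4)
  structure(
    list(data = data, dims = dims, dt = as.numeric(dt), layout = layout,
         affine = affine, source_dtype = source_dtype),
    class = "perfusion_series"
  )
}

#' @export
print.perfusion_series <- function(x, ...) {
  d <- x$dims
  cat(sprintf("<perfusion_series> %d x %d x %d voxels, %d time points (dt = %g s, %s)\n",
              d[["dim1"]], d[["dim2"]], d[["dim3"]], d[["time"]], x$dt, x$layout))
  invisible(x)
}

#' Read a 4D NIfTI perfusion series
#'
#' Loads a 4D NIfTI-1 file as a `time_major` [perfusion_series()].
#' Stored integers are converted to 64-bit floating point, with the
#' NIfTI `scl_slope`/`scl_inter` scaling applied when the slope is
#' nonzero (the reader applies it on access). The sampling interval is
#' taken from `dt_override` if given; otherwise from the header time
#' step, which is only trusted when it is positive *and* the header
#' declares a real time unit (seconds, milliseconds or microseconds) --
#' an undeclared unit with the writer-default step of 1 is
#' indistinguishable from "no time information".
#'
#' @param path Path to a 4D `.nii` / `.nii.gz` file.
#' @param dt_override Optional sampling interval in seconds; takes
#'   precedence over the header.
#' @return A `time_major` [perfusion_series()].
#' @export
read_series <- function(path, dt_override = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop_dims("expected a 4D NIfTI volume, got ", length(dim(img)), "D: ", path)
  dt <- dt_override
  if (is.null(dt)) {
    pd <- RNifti::pixdim(img)
    unit <- RNifti::pixunits(img)
    tstep <- if (length(pd) >= 4L) pd[4L] else 0
    tunit <- intersect(unit, c("s", "ms", "us"))
    if (length(tunit) == 0L || !is.finite(tstep) || tstep <= 0)
      stop_config("no usable time step in NIfTI header of ", path,
                  " (need positive pixdim[4] with declared time units); pass dt_override")
    dt <- switch(tunit[1L], s = tstep, ms = tstep / 1000, us = tstep / 1e6)
  }
  hdr <- RNifti::niftiHeader(path)
  perfusion_series(as.array(img), dt = dt, layout = "time_major",
                   affine = unclass(RNifti::xform(img)),
                   source_dtype = hdr$datatype)
}

#' Change the storage layout of a perfusion series
#'
#' Permutes the data array between `time_major` and `voxel_major`
#' layouts. The value at any spatial index and time point is preserved;
#' only storage order changes. Calling with the series' current layout
#' is the identity.
#'
#' @param series A [perfusion_series()].
#' @param target_layout `"time_major"` or `"voxel_major"`.
#' @return The series in the requested layout.
#' @export
reorganize <- function(series, target_layout = c("voxel_major", "time_major")) {
  stopifnot(inherits(series, "perfusion_series"))
  target_layout <- match.arg(target_layout)
  if (series$layout == target_layout) return(series)
  perm <- if (target_layout == "voxel_major") c(4L, 1L, 2L, 3L) else c(2L, 3L, 4L, 1L)
  series$data <- aperm(series$data, perm)
  series$layout <- target_layout
  series
}

# Time x Size matrix view of a voxel_major series: one column per voxel,
# columns ordered dim1-fastest (the linear voxel index used throughout).
voxel_matrix <- function(series) {
  stopifnot(series$layout == "voxel_major")
  matrix(series$data, nrow = series$dims[["time"]])
}

# Per-voxel time average as a 3D volume, from either layout.
time_avg_volume <- function(series) {
  d <- series$dims
  sp <- d[c("dim1", "dim2", "dim3")]
  avg <- if (series$layout == "voxel_major") {
    colMeans(matrix(series$data, nrow = d[["time"]]))
  } else {
    rowMeans(matrix(series$data, nrow = prod(sp)))
  }
  array(avg, dim = unname(sp))
}

#' Write a 3D parametric map as NIfTI
#'
#' Writes `map3d` as a float32 NIfTI-1 volume reusing the affine of the
#' reference series; voxels where `mask` is `FALSE` are written as NaN.
#'
#' @param map3d 3D numeric array with the reference's spatial dims.
#' @param mask 3D logical array, same dims.
#' @param ref The [perfusion_series()] the map was computed from.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_map_nifti <- function(map3d, mask, ref, path) {
  stopifnot(inherits(ref, "perfusion_series"))
  sp <- ref$dims[c("dim1", "dim2", "dim3")]
  if (!identical(as.integer(dim(map3d)), as.integer(sp)))
    stop_dims("map dims (", paste(dim(map3d), collapse = "x"),
              ") do not match series spatial dims (", paste(sp, collapse = "x"), ")")
  if (!identical(dim(mask), dim(map3d)))
    stop_dims("mask dims do not match map dims")
  out <- map3d
  out[!mask] <- NaN
  img <- RNifti::asNifti(out)
  img <- RNifti::`sform<-`(img, structure(ref$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a perfusion series as 4D NIfTI
#'
#' Stores the series `time_major` (the on-disk axis convention) with its
#' sampling interval in the header (`pixdim[4]`, seconds).
#'
#' @param series A [perfusion_series()].
#' @param path Output path.
#' @param datatype On-disk type; `"float"` (float32, default) or
#'   `"short"` (int16, the raw-scanner convention; values are rounded).
#' @export
write_series_nifti <- function(series, path, datatype = "float") {
  series <- reorganize(series, "time_major")
  data <- series$data
  if (datatype == "short") data <- round(data)
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(series$affine, code = 2L))
  RNifti::pixdim(img) <- c(1, 1, 1, series$dt)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
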