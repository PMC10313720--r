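#' Sampled time-attenuation curve
#'
#' A `ct_curve` holds a sampled HU-vs-time function — an arterial input
#' function (AIF) or a tissue time-attenuation curve (TAC) — together with
#' its pre-enhancement baseline level.
#'
#' @param times sample times, seconds, strictly increasing.
#' @param values attenuation values, HU, same length as `times`.
#' @param baseline pre-enhancement attenuation, HU (finite scalar).
#' @return a `ct_curve` object.
#' @export
ct_curve <- function(times, values, baseline) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values must have equal length")
  if (length(times) < 1) stop("curve must have at least one sample")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(values))) stop("values must be finite")
  if (length(baseline) != 1 || !is.finite(baseline)) stop("baseline must be a finite scalar")
  structure(list(times = times, values = values, baseline = as.numeric(baseline)),
            class = "ct_curve")
}

#' @export
print.ct_curve <- function(x, ...) {
  cat(sprintf("<ct_curve> %d samples, t in [%g, %g] s, HU in [%g, %g], baseline %g\n",
              length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values), x$baseline))
  invisible(x)
}

#' @export
length.ct_curve <- function(x) length(x$times)

#' Enhancement of a curve above its baseline
#'
#' @param curve a [ct_curve()].
#' @return numeric vector `values - baseline` (HU).
#' @export
curve_enhancement <- function(curve) {
  stopifnot(inherits(curve, "ct_curve"))
  curve$values - curve$baseline
}

#' Region-of-interest mask
#'
#' A boolean grid matching the spatial shape of a [dynamic_series()].
#'
#' @param mask logical matrix (2D spatial grid), at least one voxel TRUE.
#' @param label region name, e.g. `"aorta"`, `"parenchyma_circ"`.
#' @param shape_kind `"circular"` or `"polygonal"`.
#' @return an `roi_mask` object.
#' @export
roi_mask <- function(mask, label, shape_kind = c("circular", "polygonal")) {
  shape_kind <- match.arg(shape_kind)
  if (!is.logical(mask) || is.null(dim(mask))) stop("mask must be a logical matrix")
  if (!any(mask)) stop("mask must contain at least one TRUE voxel")
  structure(list(mask = mask, label = label, shape_kind = shape_kind),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s' (%s), %d voxels on a %s grid\n",
              x$label, x$shape_kind, sum(x$mask),
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' Time-ordered dynamic HU series
#'
#' @param voxels numeric array ordered `(time, x, y)`; one 2D volume per frame.
#' @param times frame times, seconds, strictly increasing, one per volume.
#' @return a `dynamic_series` object.
#' @export
dynamic_series <- function(voxels, times) {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    stop("voxels must be a 3D array ordered (time, x, y)")
  }
  times <- as.numeric(times)
  if (dim(voxels)[1] != length(times)) stop("one volume per time point required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(voxels = voxels, times = times), class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_series> %d frames of %dx%d voxels, t in [%g, %g] s\n",
              d[1], d[2], d[3], min(x$times), max(x$times)))
  invisible(x)
}

#' Extract a mean time-attenuation curve over an ROI
#'
#' Averages HU over the mask at each frame. The curve baseline is the mean of
#' the frames strictly before `tbase` (the frame at which the bolus-tracking
#' trigger fires on the AIF, see [find_tbase()]); when `tbase` is `NULL` or
#' no frames precede it, the first frame's value is used.
#'
#' @param series a [dynamic_series()].
#' @param roi an [roi_mask()] matching the series' spatial grid.
#' @param tbase optional 1-based frame index of the trigger frame.
#' @return a [ct_curve()].
#' @export
extract_tac <- function(series, roi, tbase = NULL) {
  stopifnot(inherits(series, "dynamic_series"), inherits(roi, "roi_mask"))
  d <- dim(series$voxels)
  if (!identical(d[2:3], dim(roi$mask))) stop("mask does not match series spatial shape")
  nt <- d[1]
  flat <- matrix(series$voxels, nrow = nt)        # frames x voxels
  vals <- rowMeans(flat[, as.vector(roi$mask), drop = FALSE])
  baseline <- if (!is.null(tbase) && tbase > 1) mean(vals[seq_len(tbase - 1)]) else vals[1]
  ct_curve(series$times, vals, baseline)
}

#' Bolus-tracking trigger frame (t_base)
#'
#' First frame at which the AIF strictly exceeds the threshold, in absolute
#' HU — the frame at which the first FPA volume scan is acquired.
#'
#' @param aif a [ct_curve()] (aortic AIF).
#' @param threshold trigger threshold, absolute HU (default 120).
#' @return 1-based frame index.
#' @export
find_tbase <- function(aif, threshold = 120) {
  stopifnot(inherits(aif, "ct_curve"))
  idx <- which(aif$values > threshold)
  if (length(idx) == 0) {
    stop(sprintf("trigger never fired: no AIF sample exceeds %g HU (max %g HU)",
                 threshold, max(aif$values)))
  }
  idx[1]
}

#' AIF peak frame (t_max)
#'
#' Frame index of the global AIF maximum; ties resolve to the earliest frame.
#' This is FPA1's (retrospective) second-scan time.
#'
#' @param aif a [ct_curve()].
#' @return 1-based frame index.
#' @export
find_tmax <- function(aif) {
  stopifnot(inherits(aif, "ct_curve"))
  which.max(aif$values)
}
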