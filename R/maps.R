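#' Voxelwise blood-flow map
#'
#' Container for a perfusion map: `bf` is a spatial grid of blood flow in
#' ml/100 ml/min, floored at zero (the number of voxels clamped is kept in
#' `n_negative`), plus the method, the scan timing used (for FPA) and a
#' provenance snapshot of the configuration.
#'
#' @param bf numeric matrix of blood flow, ml/100 ml/min.
#' @param method `"MSM"`, `"FPA1"` or `"FPA2"`.
#' @param timing for FPA maps, integer `c(tbase_index, second_index)`;
#'   `NULL` for MSM.
#' @param provenance list snapshot of the generating configuration.
#' @param n_negative count of voxels whose raw estimate was negative.
#' @return a `perfusion_map` object.
#' @keywords internal
perfusion_map <- function(bf, method, timing = NULL, provenance = list(),
                          n_negative = 0L) {
  if (!all(is.finite(bf))) stop("bf must be finite")
  if (any(bf < 0)) stop("bf must be floored at >= 0")
  structure(list(bf = bf, method = method, timing = timing,
                 provenance = provenance, n_negative = as.integer(n_negative)),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  tim <- if (is.null(x$timing)) "" else
    sprintf(", frames %d->%d", x$timing[1], x$timing[2])
  cat(sprintf("<perfusion_map> %s%s: BF in [%.1f, %.1f] ml/100 ml/min (%d voxels clamped)\n",
              x$method, tim, min(x$bf), max(x$bf), x$n_negative))
  invisible(x)
}

# shared clamp: negative raw estimates floored to zero, count retained
clamp_bf <- function(bf_raw) {
  neg <- sum(bf_raw < 0)
  bf_raw[bf_raw < 0] <- 0
  list(bf = bf_raw, n_negative = as.integer(neg))
}

#' Mean and SD of blood flow over an ROI
#'
#' @param map a `perfusion_map`.
#' @param roi an [roi_mask()] on the same spatial grid.
#' @return named numeric `c(mean, sd)` (sample SD; `NA` for a single voxel).
#' @export
map_stats <- function(map, roi) {
  stopifnot(inherits(map, "perfusion_map"), inherits(roi, "roi_mask"))
  if (!identical(dim(map$bf), dim(roi$mask))) stop("mask does not match map shape")
  v <- map$bf[roi$mask]
  if (length(v) == 0) stop("empty mask")
  c(mean = mean(v), sd = stats::sd(v))
}
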