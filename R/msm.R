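#' Maximum slope model configuration
#'
#' The MSM blood-flow estimate is the maximum upslope of the tissue TAC
#' divided by the peak arterial enhancement and tissue density:
#' `BF = 6000 * max(dTAC/dt) / (AIF_ref * rho_t)`. The upslope is estimated
#' per voxel as the maximum over sliding windows of the least-squares line
#' slope of HU versus time.
#'
#' @param slope_window consecutive samples per sliding fit (>= 2, odd
#'   recommended; default 3). Wider windows suppress noise but smooth the
#'   peak slope downward.
#' @param rho_t tissue density, g/ml (default 1.0, i.e. per-volume flow).
#' @param aif_reference `"enhancement"` (peak AIF above baseline; default) or
#'   `"absolute"` (peak absolute HU).
#' @param fit `"slope"` (sliding-window least squares; default) or
#'   `"gammafit"` (each voxel TAC is first smoothed by a gamma-variate
#'   least-squares fit, then differentiated on a dense grid; much slower,
#'   intended for small ROIs or sensitivity analyses).
#' @return an `msm_config` object.
#' @export
msm_config <- function(slope_window = 3L, rho_t = 1.0,
                       aif_reference = c("enhancement", "absolute"),
                       fit = c("slope", "gammafit")) {
  if (slope_window < 2) stop("slope_window must be >= 2")
  if (rho_t <= 0) stop("rho_t must be > 0")
  structure(list(slope_window = as.integer(slope_window), rho_t = rho_t,
                 aif_reference = match.arg(aif_reference),
                 fit = match.arg(fit)),
            class = "msm_config")
}

# least-squares slope of every length-k window of each column of Y (T x V),
# returned as (T-k+1) x V. The LS slope is a fixed linear functional of the
# window samples, so all voxels are handled with one matrix product.
sliding_slopes <- function(times, Y, k) {
  nt <- length(times)
  if (k > nt) stop(sprintf("slope_window %d exceeds %d frames", k, nt))
  W <- matrix(0, nrow = nt - k + 1, ncol = nt)
  for (s in seq_len(nt - k + 1)) {
    tw <- times[s:(s + k - 1)]
    tc <- tw - mean(tw)
    W[s, s:(s + k - 1)] <- tc / sum(tc^2)
  }
  W %*% Y
}

# gamma-variate smooth of a single TAC; returns max derivative (HU/s).
# Falls back to the sliding-window estimate when nls fails to converge.
max_slope_gammafit <- function(times, y, k) {
  base <- y[1]
  start <- list(A = max(y - base, 1e-3), t0 = times[which.max(diff(y))],
                alpha = 3, beta = 2.5)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ base + A * pmax(times - t0, 0)^alpha *
                   exp(-pmax(times - t0, 0) / beta) / ((alpha * beta)^alpha * exp(-alpha)),
                 start = start,
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(max(sliding_slopes(times, matrix(y, ncol = 1), k)))
  }
  tt <- seq(min(times), max(times), length.out = 20 * length(times))
  yy <- stats::predict(fit, newdata = list(times = tt))
  max(diff(yy) / diff(tt))
}

#' Maximum slope model blood-flow map
#'
#' Per voxel, the maximum sliding-window least-squares slope of the TAC
#' (HU/s) is divided by the AIF reference (peak enhancement by default) and
#' tissue density, scaled to ml/100 ml/min. Negative estimates are floored
#' at zero and counted.
#'
#' @param series a [dynamic_series()].
#' @param aif the arterial input function as a [ct_curve()].
#' @param cfg an [msm_config()].
#' @return a `perfusion_map` with `method = "MSM"`.
#' @examples
#' # a pure 2 HU/s ramp against a 200 HU AIF peak gives 60 ml/100 ml/min
#' @export
msm_map <- function(series, aif, cfg = msm_config()) {
  stopifnot(inherits(series, "dynamic_series"), inherits(aif, "ct_curve"))
  d <- dim(series$voxels)
  nt <- d[1]
  if (nt < cfg$slope_window) stop("fewer frames than slope_window")
  aif_ref <- switch(cfg$aif_reference,
                    enhancement = max(curve_enhancement(aif)),
                    absolute = max(aif$values))
  if (aif_ref <= 0) stop("AIF reference must be > 0")

  Y <- matrix(series$voxels, nrow = nt)
  if (cfg$fit == "slope") {
    slopes <- sliding_slopes(series$times, Y, cfg$slope_window)
    max_slope <- apply(slopes, 2, max)
  } else {
    max_slope <- apply(Y, 2, max_slope_gammafit,
                       times = series$times, k = cfg$slope_window)
  }
  bf_raw <- HU_FLOW_SCALE * max_slope / (aif_ref * cfg$rho_t)
  cl <- clamp_bf(matrix(bf_raw, nrow = d[2], ncol = d[3]))
  perfusion_map(cl$bf, "MSM", timing = NULL,
                provenance = list(config = unclass(cfg), aif_ref = aif_ref),
                n_negative = cl$n_negative)
}
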