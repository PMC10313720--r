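#' First-pass analysis configuration
#'
#' FPA estimates blood flow from two volume scans: the first at the
#' bolus-tracking trigger frame `t_base` (AIF > `trigger_threshold`,
#' absolute HU), the second either at the retrospective AIF peak (`fpa1`) or
#' at the frame nearest `t_p = t_i/2 + dispersion_d` seconds after `t_base`
#' (`fpa2`), where `t_i` is the contrast injection duration.
#'
#' @param variant `"fpa1"` (second scan at the AIF peak) or `"fpa2"`
#'   (prospective timing by the temporal-center rule).
#' @param trigger_threshold bolus-tracking threshold, absolute HU (> 0).
#' @param t_i contrast injection duration, seconds (> 0); default 16.
#' @param dispersion_d dispersion delay `d`, seconds (>= 0); used by fpa2.
#' @param aif_reference `"enhancement"` (integrate AIF above baseline;
#'   default) or `"absolute"`.
#' @return an `fpa_config` object.
#' @export
fpa_config <- function(variant = c("fpa1", "fpa2"),
                       trigger_threshold = 120,
                       t_i = 16,
                       dispersion_d = 0,
                       aif_reference = c("enhancement", "absolute")) {
  variant <- match.arg(variant)
  if (trigger_threshold <= 0) stop("trigger_threshold must be > 0")
  if (t_i <= 0) stop("t_i must be > 0")
  if (dispersion_d < 0) stop("dispersion_d must be >= 0")
  structure(list(variant = variant, trigger_threshold = trigger_threshold,
                 t_i = t_i, dispersion_d = dispersion_d,
                 aif_reference = match.arg(aif_reference)),
            class = "fpa_config")
}

#' Temporal center of the contrast bolus
#'
#' The second FPA scan is placed at the approximate temporal center of the
#' bolus, `t_p = t_i/2 + d`: half the injection duration plus an
#' organ-dependent dispersion delay.
#'
#' @param t_i injection duration, seconds (> 0).
#' @param d dispersion delay, seconds (>= 0).
#' @return `t_p` in seconds.
#' @examples
#' compute_tp(16, 0)    # 8
#' compute_tp(16, 13.5) # 21.5
#' @export
compute_tp <- function(t_i, d) {
  if (t_i <= 0) stop("t_i must be > 0")
  if (d < 0) stop("d must be >= 0")
  t_i / 2 + d
}

#' Select the second FPA scan frame
#'
#' For `fpa1`, the AIF-peak frame; for `fpa2`, the frame whose time is
#' nearest to `time(t_base) + t_p` (earlier frame on ties). Errors when the
#' target time falls beyond the last acquired frame, or when the chosen
#' frame does not follow `t_base`.
#'
#' @param aif the AIF as a [ct_curve()].
#' @param cfg an [fpa_config()].
#' @return 1-based frame index (> t_base index).
#' @export
select_second_frame <- function(aif, cfg) {
  stopifnot(inherits(aif, "ct_curve"), inherits(cfg, "fpa_config"))
  tbase <- find_tbase(aif, cfg$trigger_threshold)
  if (cfg$variant == "fpa1") {
    idx <- find_tmax(aif)
  } else {
    target <- aif$times[tbase] + compute_tp(cfg$t_i, cfg$dispersion_d)
    if (target > aif$times[length(aif$times)] + 1e-9) {
      stop(sprintf("window exceeded: second scan at %.2f s is beyond the last frame (%.2f s)",
                   target, aif$times[length(aif$times)]))
    }
    idx <- which.min(abs(aif$times - target)) # ties: which.min takes the earlier
  }
  if (idx <= tbase) {
    stop(sprintf("second scan frame %d does not follow the trigger frame %d", idx, tbase))
  }
  idx
}

#' First-pass analysis blood-flow map
#'
#' Two-scan indicator-dilution estimate. Per voxel, the enhancement change
#' between the trigger frame and the second scan, `dHU`, is normalized by
#' the integrated arterial enhancement over the same interval:
#' \deqn{P_{FPA} = 6000\, \frac{\Delta HU}{\int_{t_{base}}^{t_2} AIF_{enh}\,dt}}
#' The compartment-average form `P_avg = 6000 * dHU_avg / integral` and the
#' voxelwise redistribution `P_FPA = P_avg * dHU / dHU_avg` are equivalent;
#' both are computed and the map records `p_avg`. By construction the
#' compartment mean of the raw voxelwise map equals `p_avg` exactly (checked
#' before the negative-value clamp).
#'
#' @param series a [dynamic_series()].
#' @param aif the AIF as a [ct_curve()]; its `baseline` is subtracted before
#'   integration when `aif_reference = "enhancement"`.
#' @param cfg an [fpa_config()].
#' @param compartment [roi_mask()] of the tissue compartment over which
#'   `dHU_avg` / `P_avg` are defined.
#' @return a `perfusion_map` (`method` `"FPA1"`/`"FPA2"`) with extra
#'   provenance fields `p_avg`, `dhu_avg` and `aif_integral`.
#' @export
fpa_map <- function(series, aif, cfg, compartment) {
  stopifnot(inherits(series, "dynamic_series"), inherits(aif, "ct_curve"),
            inherits(cfg, "fpa_config"), inherits(compartment, "roi_mask"))
  d <- dim(series$voxels)
  if (!identical(d[2:3], dim(compartment$mask))) {
    stop("compartment mask does not match series spatial shape")
  }
  if (!isTRUE(all.equal(series$times, aif$times))) {
    stop("mismatched time grids: AIF and series must share frame times")
  }
  tbase <- find_tbase(aif, cfg$trigger_threshold)
  second <- select_second_frame(aif, cfg)

  seg <- tbase:second
  ref <- switch(cfg$aif_reference,
                enhancement = curve_enhancement(aif),
                absolute = aif$values)
  integral <- pracma::trapz(aif$times[seg], ref[seg])
  if (integral <= 0) stop("AIF integral over the scan interval must be > 0")

  dhu <- series$voxels[second, , , drop = FALSE] -
    series$voxels[tbase, , , drop = FALSE]
  dim(dhu) <- d[2:3]
  dhu_avg <- mean(dhu[compartment$mask])
  p_avg <- HU_FLOW_SCALE * dhu_avg / integral
  bf_raw <- HU_FLOW_SCALE * dhu / integral

  # Eq-level conservation: compartment mean of the raw map must equal p_avg
  stopifnot(isTRUE(all.equal(mean(bf_raw[compartment$mask]), p_avg,
                             tolerance = 1e-9)))
  cl <- clamp_bf(bf_raw)
  perfusion_map(cl$bf, toupper(cfg$variant),
                timing = c(tbase = tbase, second = second),
                provenance = list(config = unclass(cfg), p_avg = p_avg,
                                  dhu_avg = dhu_avg, aif_integral = integral),
                n_negative = cl$n_negative)
}
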