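#' Effective dose from dose-length product
#'
#' `E = DLP * k` with the abdominal conversion factor
#' `k = 0.0153 mSv/(mGy cm)` by default.
#'
#' @param dlp dose-length product, mGy cm (>= 0).
#' @param k conversion factor, mSv/(mGy cm) (>= 0).
#' @return effective dose, mSv.
#' @examples
#' effective_dose(100) # 1.53
#' @export
effective_dose <- function(dlp, k = 0.0153) {
  if (any(dlp < 0)) stop("dlp must be >= 0")
  if (any(k < 0)) stop("k must be >= 0")
  dlp * k
}

#' Percent reduction of a quantity relative to a reference
#'
#' `100 * (1 - new/reference)`; e.g. dose or scan-time savings of a two-scan
#' protocol versus a full dynamic acquisition.
#'
#' @param new new (reduced) value.
#' @param reference reference value (> 0).
#' @return reduction in percent.
#' @examples
#' percent_reduction(0.27, 4.64) # 94.18...
#' @export
percent_reduction <- function(new, reference) {
  if (any(reference <= 0)) stop("reference must be > 0")
  100 * (1 - new / reference)
}

#' Radiation dose record for a protocol
#'
#' @param dlp dose-length product, mGy cm (>= 0).
#' @param n_volumes number of volume acquisitions.
#' @param label protocol name.
#' @param conversion_k mSv/(mGy cm); default 0.0153 (abdomen).
#' @return a `dose_record` list with the derived `effective_dose` (mSv).
#' @export
dose_record <- function(dlp, n_volumes, label, conversion_k = 0.0153) {
  if (dlp < 0) stop("dlp must be >= 0")
  if (n_volumes < 0) stop("n_volumes must be >= 0")
  structure(list(dlp = dlp, conversion_k = conversion_k,
                 effective_dose = effective_dose(dlp, conversion_k),
                 n_volumes = as.integer(n_volumes), label = label),
            class = "dose_record")
}

#' @export
print.dose_record <- function(x, ...) {
  cat(sprintf("<dose_record> %s: DLP %g mGy.cm x %g -> %.3g mSv (%d volumes)\n",
              x$label, x$dlp, x$conversion_k, x$effective_dose, x$n_volumes))
  invisible(x)
}

#' Total acquisition time of a protocol variant
#'
#' * `dynamic`: the full dynamic series — `(n_frames - 1) * frame_spacing +
#'   acq_time`, i.e. the span from the start of the first to the end of the
#'   last volume acquisition.
#' * `fpa`: the two-scan protocol — `monitor_lead + fpa_last_delay +
#'   acq_time`, i.e. from the start of bolus monitoring, through the trigger
#'   (`monitor_lead` seconds later), to the end of a second scan acquired
#'   `fpa_last_delay` seconds after the trigger.
#'
#' These are the package's own bookkeeping formulas for protocol comparison;
#' scanner overheads (tube ramp-up, table movement) are not modeled.
#'
#' @param protocol an [acquisition_protocol()].
#' @param variant `"dynamic"` or `"fpa"`.
#' @param fpa_last_delay second-scan delay after the trigger, seconds (fpa
#'   variant; typically the upper end of [optimum_delay_window()]).
#' @param acq_time single-volume acquisition time, seconds (default 0.5).
#' @param monitor_lead bolus-monitoring start to trigger, seconds (fpa
#'   variant; default 0 counts from monitoring start at the trigger search).
#' @return total acquisition time, seconds.
#' @export
protocol_scan_time <- function(protocol, variant = c("dynamic", "fpa"),
                               fpa_last_delay = 0, acq_time = 0.5,
                               monitor_lead = 0) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  variant <- match.arg(variant)
  if (fpa_last_delay < 0 || acq_time < 0 || monitor_lead < 0) {
    stop("time arguments must be >= 0")
  }
  switch(variant,
         dynamic = (protocol$n_frames - 1) * protocol$frame_spacing + acq_time,
         fpa = monitor_lead + fpa_last_delay + acq_time)
}

#' Dose and scan-time comparison between dynamic and two-scan protocols
#'
#' The two-scan FPA dose defaults to `2/n_frames` of the dynamic DLP
#' (dose scales with the number of acquisitions; bolus-monitoring dose is
#' not included).
#'
#' @param dlp_dynamic DLP of the full dynamic acquisition, mGy cm.
#' @param protocol an [acquisition_protocol()].
#' @param fpa_last_delay second-scan delay after the trigger, seconds.
#' @param monitor_lead bolus-monitoring lead time, seconds.
#' @param acq_time single-volume acquisition time, seconds.
#' @param conversion_k effective-dose conversion factor, mSv/(mGy cm).
#' @param dlp_fpa optional explicit FPA DLP; default `dlp_dynamic * 2/n_frames`.
#' @return data.frame with one row per protocol: label, n_volumes, dlp,
#'   effective_dose, scan_time, and percent reduction versus dynamic.
#' @export
dose_comparison <- function(dlp_dynamic, protocol = acquisition_protocol(),
                            fpa_last_delay = 20, monitor_lead = 6.5,
                            acq_time = 0.5, conversion_k = 0.0153,
                            dlp_fpa = NULL) {
  if (is.null(dlp_fpa)) dlp_fpa <- dlp_dynamic * 2 / protocol$n_frames
  dyn <- dose_record(dlp_dynamic, protocol$n_frames, "dynamic", conversion_k)
  fpa <- dose_record(dlp_fpa, 2L, "fpa", conversion_k)
  st_dyn <- protocol_scan_time(protocol, "dynamic", acq_time = acq_time)
  st_fpa <- protocol_scan_time(protocol, "fpa", fpa_last_delay = fpa_last_delay,
                               acq_time = acq_time, monitor_lead = monitor_lead)
  data.frame(
    label = c("dynamic", "fpa"),
    n_volumes = c(dyn$n_volumes, fpa$n_volumes),
    dlp = c(dyn$dlp, fpa$dlp),
    effective_dose = c(dyn$effective_dose, fpa$effective_dose),
    scan_time = c(st_dyn, st_fpa),
    dose_reduction_pct = c(0, percent_reduction(fpa$effective_dose, dyn$effective_dose)),
    time_reduction_pct = c(0, percent_reduction(st_fpa, st_dyn)),
    stringsAsFactors = FALSE
  )
}
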