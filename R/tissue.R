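#' Tissue compartment specification
#'
#' Ground-truth description of a perfused tissue region: true blood flow
#' `bf_true` (ml/100 ml/min), mean transit time `mtt` (s) of the boxcar
#' residue, and the unenhanced attenuation `baseline_hu`.
#'
#' The boxcar residue means contrast that entered less than `mtt` seconds ago
#' is still in the compartment and older contrast has left; with `mtt` longer
#' than the measurement window the "no contrast exits" assumption underlying
#' the two-scan first-pass estimate holds exactly.
#'
#' @param label region name (`"parenchyma"`, `"carcinoma"`, ...).
#' @param bf_true true blood flow, ml/100 ml/min (>= 0).
#' @param mtt mean transit time, seconds (> 0); default 12.
#' @param baseline_hu unenhanced tissue attenuation, HU.
#' @return a `tissue_spec` object.
#' @export
tissue_spec <- function(label, bf_true, mtt = 12, baseline_hu = 40) {
  if (bf_true < 0) stop("bf_true must be >= 0")
  if (mtt <= 0) stop("mtt must be > 0")
  structure(list(label = label, bf_true = bf_true, mtt = mtt,
                 baseline_hu = baseline_hu),
            class = "tissue_spec")
}

#' @export
print.tissue_spec <- function(x, ...) {
  cat(sprintf("<tissue_spec> '%s': BF %g ml/100 ml/min, MTT %g s, baseline %g HU\n",
              x$label, x$bf_true, x$mtt, x$baseline_hu))
  invisible(x)
}

#' Simulate a noise-free tissue TAC from an AIF
#'
#' Indicator-dilution forward model with a boxcar residue:
#' \deqn{TAC(t) = b_t + \frac{BF}{6000} \int_0^t AIF_{enh}(\tau) R(t - \tau)\, d\tau}
#' where `AIF_enh` is the AIF enhancement above its baseline, and
#' `R(lag) = 1` for `lag < mtt`, else 0. The integral is evaluated by the
#' trapezoidal rule on the AIF's own sample grid, with the boxcar applied to
#' the sampled integrand. While `t < onset + mtt` no contrast has left the
#' compartment and the TAC equals the plain cumulative integral, which is the
#' regime in which the two-scan estimate recovers `bf_true` exactly.
#'
#' @param aif a [ct_curve()] sampled on the protocol time grid.
#' @param spec a [tissue_spec()].
#' @param times optional protocol time grid; when given it must match the
#'   AIF's sample grid exactly (guards against mixing grids).
#' @return a [ct_curve()] on the same time grid, baseline `spec$baseline_hu`.
#' @export
simulate_tac <- function(aif, spec, times = NULL) {
  stopifnot(inherits(aif, "ct_curve"), inherits(spec, "tissue_spec"))
  if (!is.null(times) && !isTRUE(all.equal(as.numeric(times), aif$times))) {
    stop("mismatched time grids: AIF is not sampled on the requested times")
  }
  times <- aif$times
  enh <- curve_enhancement(aif)
  n <- length(times)
  vals <- numeric(n)
  for (j in seq_len(n)) {
    if (j == 1) {
      vals[j] <- 0
      next
    }
    lag <- times[j] - times[seq_len(j)]
    integrand <- enh[seq_len(j)] * as.numeric(lag < spec$mtt)
    vals[j] <- pracma::trapz(times[seq_len(j)], integrand)
  }
  ct_curve(times, spec$baseline_hu + (spec$bf_true / HU_FLOW_SCALE) * vals,
           spec$baseline_hu)
}
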