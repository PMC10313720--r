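#' Pearson product-moment correlation
#'
#' Thin, contract-checked front end over [stats::cor()]: requires equal
#' lengths of at least 3 and non-degenerate variance in both vectors.
#'
#' @param x,y numeric vectors.
#' @return the correlation coefficient `r` in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate variance: sd is 0")
  stats::cor(x, y, method = "pearson")
}

#' Coefficient of variation, percent
#'
#' `100 * sample SD / mean`; used to quantify the sensitivity of blood-flow
#' values to acquisition timing.
#'
#' @param values numeric vector with non-zero mean, length >= 2.
#' @return COV in percent (>= 0 for positive-mean data).
#' @examples
#' cov_percent(c(90, 110)) # 14.142...
#' @export
cov_percent <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("zero mean: COV undefined")
  100 * stats::sd(values) / m
}

#' Tissue contrast: Student's t-test between carcinoma and parenchyma BF
#'
#' Two-sided Student's t-test (equal-variance by default, matching the
#' classical two-sample test; `paired = TRUE` for within-subject designs) on
#' blood-flow values of the two tissues.
#'
#' @param bf_carcinoma,bf_parenchyma numeric vectors (each length >= 2;
#'   equal lengths when `paired`).
#' @param paired logical; default FALSE.
#' @return named numeric `c(t, p)`.
#' @export
tissue_contrast <- function(bf_carcinoma, bf_parenchyma, paired = FALSE) {
  if (length(bf_carcinoma) < 2 || length(bf_parenchyma) < 2) {
    stop("need at least 2 observations per group")
  }
  ht <- stats::t.test(bf_carcinoma, bf_parenchyma,
                      paired = paired, var.equal = TRUE,
                      alternative = "two.sided")
  c(t = unname(ht$statistic), p = ht$p.value)
}
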