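#' @title Perceived Correctness Score (PCS)
#' @description PCS = wneuro x upattern x ln(1 + Efocus) combines three
#'   aspects of a candidate electrode configuration: field focusing
#'   (Efocus = Emax / (Eavg + eps)), neural activation sufficiency (a
#'   logistic weight on the membrane-potential peak) and the balance of the
#'   three exported field descriptors (upattern = 1 / (1 + C), C the
#'   coefficient of variation of |Emax|, |Eavg|, |Eint|). The multiplicative
#'   form makes a low value in any component lower the composite score.
#' @name pcs_scoring
NULL

PCS_EPSILON <- 1e-9

#' Field-focusing ratio
#'
#' Efocus = Emax / (Eavg + eps), with eps = 1e-9 guarding division by zero.
#'
#' @param e_max maximum field magnitude, V/m
#' @param e_avg volume-average field magnitude, V/m
#' @param epsilon small guard constant
#' @return dimensionless focusing ratio
#' @export
efocus <- function(e_max, e_avg, epsilon = PCS_EPSILON) {
  stopifnot(e_max >= 0, e_avg >= 0)
  e_max / (e_avg + epsilon)
}

#' Neural-activation weight
#'
#' Logistic weight wneuro = 1 / (1 + exp(-(v_peak - v_th) * k)), equal to
#' 0.5 exactly at threshold and strictly increasing in v_peak.
#'
#' @param v_peak membrane-potential peak in mV
#' @param v_th activation threshold in mV (default -55)
#' @param k sigmoid slope in 1/mV (default 0.05)
#' @return weight in (0, 1)
#' @export
neuro_weight <- function(v_peak, v_th = -55, k = 0.05) {
  stopifnot(is.finite(v_peak))
  1 / (1 + exp(-(v_peak - v_th) * k))
}

#' Descriptor spread term
#'
#' C = population standard deviation of (|Emax|, |Eavg|, |Eint|) divided by
#' their mean (an n = 3 coefficient of variation over the raw SI
#' magnitudes). All-zero descriptors return C = 0 by convention (the
#' composite score is zero in that case regardless).
#'
#' @param e_max,e_avg,e_int the three exported field descriptors
#' @return dimensionless spread, >= 0
#' @export
spread_term <- function(e_max, e_avg, e_int) {
  x <- abs(c(e_max, e_avg, e_int))
  mu <- mean(x)
  if (mu == 0) return(0)
  sqrt(mean((x - mu)^2)) / mu
}

#' Descriptor-balance weight
#'
#' upattern = 1 / (1 + C), in (0, 1]; equals 1 when the three descriptors
#' are perfectly balanced.
#'
#' @param spread spread term C >= 0
#' @return weight in (0, 1]
#' @export
upattern <- function(spread) {
  stopifnot(spread >= 0)
  1 / (1 + spread)
}

#' Composite Perceived Correctness Score
#'
#' Composes the three components with the natural logarithm ("log" read as
#' ln; the base only rescales scores monotonically, so rankings are
#' invariant). All intermediates are returned for audit.
#'
#' @param field a `field_features` (or list with `e_max`, `e_avg`, `e_int`)
#' @param neural a `neural_features` (or list with `v_peak_mv`)
#' @param v_th activation threshold in mV
#' @param k sigmoid slope in 1/mV
#' @param epsilon guard constant for Efocus
#' @return a `pcs_components` list: `e_focus`, `w_neuro`, `u_pattern`,
#'   `spread`, `pcs`, `epsilon`
#' @export
pcs_score <- function(field, neural, v_th = -55, k = 0.05,
                      epsilon = PCS_EPSILON) {
  ef <- efocus(field$e_max, field$e_avg, epsilon)
  wn <- neuro_weight(neural$v_peak_mv, v_th, k)
  C <- spread_term(field$e_max, field$e_avg, field$e_int)
  up <- upattern(C)
  structure(list(e_focus = ef, w_neuro = wn, u_pattern = up, spread = C,
                 pcs = wn * up * log1p(ef), epsilon = epsilon),
            class = "pcs_components")
}

#' @export
print.pcs_components <- function(x, ...) {
  cat(sprintf(
    "<pcs: %.4f  (Efocus %.3f, wneuro %.3f, upattern %.3f, C %.3f)>\n",
    x$pcs, x$e_focus, x$w_neuro, x$u_pattern, x$spread))
  invisible(x)
}
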