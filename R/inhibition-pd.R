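## Inhibition, target modulation, and the downstream PD response.
## PROTACs built on inhibitor warheads both degrade the target and inhibit
## whatever target remains; the PD model composes the two into a single
## downstream readout.

#' Fractional target inhibition from binding occupancy
#'
#' Fraction of the remaining (non-degraded) target protein whose activity
#' is shut down by PROTAC binding. By default engagement is assumed
#' negligible (`TE << 1`, the catalytic regime), giving simple binary-site
#' occupancy `I = C / (kd_poi + C)`. Supplying `te` uses the full form
#' `I = 1 - kd_poi * (1 - TE) / (kd_poi + C)`.
#'
#' @param c PROTAC concentration, nM (vectorized, >= 0).
#' @param kd_poi Binary PROTAC--target dissociation constant, nM.
#' @param te Optional ternary-complex engagement fraction(s).
#' @return Inhibition fraction(s) in [0, 1].
#' @export
inhibition_fraction <- function(c, kd_poi, te = NULL) {
  check_scalar(kd_poi, "kd_poi", lower = 0, strict_lower = TRUE)
  if (any(c < 0)) stop_protac("'c' must be non-negative")
  if (is.null(te)) {
    return(c / (kd_poi + c))
  }
  check_fraction_vec(te, "te")
  1 - kd_poi * (1 - te) / (kd_poi + c)
}

#' Fractional target inhibition from an IC50 of a non-degrading control
#'
#' Target inhibition by the PROTAC itself cannot easily be measured, but
#' the PD effect of the matched non-degrading control compound can.
#' Re-expressing occupancy in terms of the concentration `ic50` at which
#' inhibition alone halves the baseline PD response gives
#' \deqn{I = \frac{C (1 - P_{50})}{C (1 - P_{50}) + IC_{50} P_{50}}}
#' which equals binary-site occupancy with an apparent
#' `kd_poi = ic50 * p50 / (1 - p50)`.
#'
#' @param c PROTAC concentration, nM (vectorized, >= 0).
#' @param ic50 Concentration halving the baseline PD response by inhibition
#'   alone, nM.
#' @param p50 Relative protein level of half-maximal PD response, in (0, 1).
#' @return Inhibition fraction(s) in [0, 1].
#' @examples
#' inhibition_from_ic50(100, ic50 = 120, p50 = 0.5)  # ~0.4545
#' @export
inhibition_from_ic50 <- function(c, ic50, p50) {
  check_scalar(ic50, "ic50", lower = 0, strict_lower = TRUE)
  check_scalar(p50, "p50", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (any(c < 0)) stop_protac("'c' must be non-negative")
  c * (1 - p50) / (c * (1 - p50) + ic50 * p50)
}

#' Target modulation from degradation and inhibition
#'
#' Active protein remaining is the fraction neither degraded nor inhibited,
#' so `TM = 1 - (1 - D)(1 - I) = D + I - D * I`.
#'
#' @param d Degradation fraction(s) in [0, 1].
#' @param i Inhibition fraction(s) in [0, 1].
#' @return Target modulation fraction(s) in [0, 1].
#' @export
target_modulation <- function(d, i) {
  check_fraction_vec(d, "d")
  check_fraction_vec(i, "i")
  d + i - d * i
}

#' Downstream pharmacodynamic response from target modulation
#'
#' Direct-response model mapping target modulation `TM` to the relative
#' downstream PD readout (baseline-normalized):
#' \deqn{PD = PD_{min} + (1 - PD_{min})\frac{(1-TM)^n (1 - P_{50}^n)}
#'   {P_{50}^n + (1-TM)^n (1 - 2 P_{50}^n)}}
#' with `PD(0) = 1`, `PD(1) = pd_min`, strictly decreasing in `TM`. The
#' saturation parameter `p50` is the remaining-protein level that halves
#' the target-dependent response; `hill` is an empirical steepness for
#' far-downstream readouts.
#'
#' @param tm Target modulation fraction(s) in [0, 1].
#' @param params A [pd_params()] object.
#' @return Relative PD response(s) in `[pd_min, 1]`.
#' @examples
#' pd_response(0.13, pd_params(p50 = 0.87, hill = 7))  # 0.5
#' @export
pd_response <- function(tm, params) {
  stopifnot(inherits(params, "pd_params"))
  check_fraction_vec(tm, "tm")
  s <- params$p50^params$hill
  u <- (1 - tm)^params$hill
  params$pd_min + (1 - params$pd_min) * u * (1 - s) / (s + u * (1 - 2 * s))
}

#' Attribute the overall effect to degradation vs inhibition
#'
#' Splits target modulation `TM = D + I - D*I` into relative contributions
#' of the two mechanisms. Because TM is symmetric in D and I, the default
#' is the symmetric (Shapley) attribution -- each mechanism carries half of
#' the shared interaction term: `share_D` proportional to `D * (1 - I/2)`
#' and `share_I` to `I * (1 - D/2)`, whose weighted contributions sum to TM
#' exactly. A sequential degradation-first split (degradation claims `D`,
#' inhibition the remainder `I * (1 - D)`) is available as an alternative.
#'
#' @param d Degradation fraction in [0, 1].
#' @param i Inhibition fraction in [0, 1].
#' @param method `"shapley"` (default) or `"sequential"`.
#' @return Named numeric of shares `c(degradation = , inhibition = )`
#'   summing to 1.
#' @export
deconvolve_contributions <- function(d, i, method = c("shapley", "sequential")) {
  method <- match.arg(method)
  check_scalar(d, "d", lower = 0, upper = 1)
  check_scalar(i, "i", lower = 0, upper = 1)
  if (d == 0 && i == 0) {
    stop_protac("contribution split undefined when both d = 0 and i = 0")
  }
  contrib <- switch(method,
    shapley = c(degradation = d * (1 - i / 2), inhibition = i * (1 - d / 2)),
    sequential = c(degradation = d, inhibition = i * (1 - d))
  )
  contrib / sum(contrib)
}
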