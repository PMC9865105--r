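## Degradation models. Two complementary views of the same biology:
## the mechanistic "kcat model" predicts degradation from biochemical
## parameters (a priori), while the descriptive "hook model" is fitted to
## experimental concentration-degradation profiles (a posteriori). The two
## are algebraically equivalent under the parameter mapping implemented in
## hook_from_mechanistic().

## Steady-state degradation of the kcat model. With
## beta = alpha*E0*kcat*t1/2 / ln(2):
##   Dss(C) = beta / (beta + alpha*E0 + KD,P + KD,E + KD,P*KD,E/C + C)
mechanistic_dss <- function(c, params) {
  b <- params$binding
  mech_dss_raw(c, b$kd_poi, b$kd_e3, b$alpha, params$cell$e3_total,
               params$cell$half_life, params$kcat)
}

mech_dss_raw <- function(c, kd_poi, kd_e3, alpha, e0, half_life, kcat) {
  beta <- alpha * e0 * kcat * half_life / log(2)
  out <- numeric(length(c))
  pos <- c > 0
  cp <- c[pos]
  out[pos] <- beta / (beta + alpha * e0 + kd_poi + kd_e3 +
                        kd_poi * kd_e3 / cp + cp)
  out
}

## Shared exponential-approach kinetics: starting from baseline, relative
## degradation approaches its steady-state value with effective rate
## (kdeg + kcat*TE) = kdeg / (1 - Dss), i.e.
##   D(t) = Dss * (1 - exp(-ln(2) * t / (t1/2 * (1 - Dss))))
approach_steady_state <- function(dss, t, half_life) {
  dss * (1 - exp(-log(2) * t / (half_life * (1 - dss))))
}

#' Degradation time course from mechanistic parameters (kcat model)
#'
#' Closed-form solution of the indirect-response turnover model in which
#' baseline synthesis/turnover (rate `ln(2)/half_life`) competes with
#' PROTAC-catalyzed destruction (rate `kcat * TE(C)`), with target
#' engagement constant over time in vitro:
#' \deqn{D(C, t) = D_{ss}(C)\,\bigl(1 - e^{-\ln 2\, t /(t_{1/2}(1 - D_{ss}(C)))}\bigr)}
#'
#' @param c Unbound PROTAC concentration, nM (vectorized, >= 0).
#' @param t Incubation time, h (vectorized, >= 0; recycled against `c`).
#' @param params A [mechanistic_params()] object.
#' @return Fraction(s) of target protein degraded.
#' @export
degradation_time_course <- function(c, t, params) {
  stopifnot(inherits(params, "mechanistic_params"))
  if (any(c < 0)) stop_protac("'c' must be non-negative")
  if (any(t < 0)) stop_protac("'t' must be non-negative")
  dss <- mechanistic_dss(c, params)
  approach_steady_state(dss, t, params$cell$half_life)
}

#' Catalytic efficiency: engagement needed for 50\% steady-state degradation
#'
#' `TE50 = kdeg_p / kcat = ln(2) / (kcat * half_life)` is the target
#' engagement at which PROTAC-catalyzed destruction matches baseline
#' turnover, so that steady-state degradation is 50\%. Small TE50 means an
#' efficient catalyst: little engagement suffices for deep degradation.
#'
#' @param params A [mechanistic_params()] object with `kcat > 0`.
#' @return TE50 as a dimensionless fraction.
#' @examples
#' p <- mechanistic_params(ternary_binding(100, 100, 10),
#'                         cell_system(50, half_life = log(2) / 0.043),
#'                         kcat = 4.6)
#' te50(p)  # ~0.0093, i.e. ~1% engagement halves the protein
#' @export
te50 <- function(params) {
  stopifnot(inherits(params, "mechanistic_params"))
  if (params$kcat <= 0) {
    stop_protac("TE50 is undefined for kcat = 0 (no catalyzed degradation)")
  }
  params$cell$kdeg_p / params$kcat
}

#' Steady-state degradation from target engagement
#'
#' The hyperbolic relationship `Dss = TE / (TE50 + TE)`.
#'
#' @param te Target engagement fraction(s) in [0, 1].
#' @param te50 Catalytic efficiency, see [te50()].
#' @return Steady-state degradation fraction(s).
#' @export
dss_from_te <- function(te, te50) {
  check_fraction_vec(te, "te")
  check_scalar(te50, "te50", lower = 0, strict_lower = TRUE)
  te / (te50 + te)
}

#' Hook model: bell-shaped concentration-degradation profile
#'
#' Descriptive three-parameter model of PROTAC-mediated degradation
#' including the hook effect:
#' \deqn{D(C) = \frac{D_{max}\,(DC_{50}^2 + DC_{max}^2 - 2\,DC_{50} DC_{max})}
#'   {DC_{50}^2 + DC_{max}^2 - 4\,DC_{50} DC_{max} + DC_{50} C +
#'    DC_{50} DC_{max}^2 / C}}
#' The curve is symmetric about `dcmax` on the log-concentration axis
#' (`D(C) = D(dcmax^2 / C)`), attains `dmax` exactly at `C = dcmax`, and
#' `dmax / 2` exactly at `C = dc50` (and at the mirrored concentration
#' `dcmax^2 / dc50`).
#'
#' @param c PROTAC concentration, nM (vectorized; `c = 0` returns the
#'   continuity limit 0).
#' @param params A [hook_params()] object.
#' @return Degradation fraction(s).
#' @examples
#' hp <- hook_params(dmax = 0.949, dc50 = 0.29, dcmax = 68.9)
#' hook_degradation(c(0.29, 68.9), hp)  # Dmax/2, Dmax
#' @export
hook_degradation <- function(c, params) {
  stopifnot(inherits(params, "hook_params"))
  if (any(c < 0)) stop_protac("'c' must be non-negative")
  hook_d_raw(c, params$dmax, params$dc50, params$dcmax)
}

## unvalidated evaluator shared with the fitting engine
hook_d_raw <- function(c, dmax, d50, dmx) {
  out <- numeric(length(c))
  pos <- c > 0
  cp <- c[pos]
  num <- dmax * (d50^2 + dmx^2 - 2 * d50 * dmx)
  den <- d50^2 + dmx^2 - 4 * d50 * dmx + d50 * cp + d50 * dmx^2 / cp
  out[pos] <- num / den
  out
}

#' Hyperbolic Emax model
#'
#' `E(C) = emax * C / (C + ec50)`; the low-concentration limit of the hook
#' model (`C << dcmax`) with `emax = dmax` and `ec50 = dc50`.
#'
#' @param c Concentration, nM (vectorized, >= 0).
#' @param params An [emax_params()] object.
#' @return Effect fraction(s).
#' @export
emax_effect <- function(c, params) {
  stopifnot(inherits(params, "emax_params"))
  if (any(c < 0)) stop_protac("'c' must be non-negative")
  params$emax * c / (c + params$ec50)
}

#' Extended hook model: time-resolved degradation profiles
#'
#' Combines the steady-state hook profile with exponential approach
#' kinetics governed by the target-protein half-life. Because the
#' effective rate `kdeg / (1 - Dss(C))` depends on concentration, the
#' apparent `Dmax` grows and the apparent `DC50` shrinks with incubation
#' time, while `DCmax` stays put -- pre-steady-state profiles look like
#' hook curves with time-dependent descriptive parameters.
#'
#' @param c PROTAC concentration, nM (vectorized).
#' @param t Incubation time, h (vectorized, recycled).
#' @param params An [extended_hook_params()] object (steady-state values).
#' @return Degradation fraction(s).
#' @examples
#' eh <- extended_hook_params(hook_params(0.949, 0.29, 68.9), half_life = 45)
#' extended_hook(68.9, 6, eh)  # ~0.794: well short of the 94.9% steady state
#' @export
extended_hook <- function(c, t, params) {
  stopifnot(inherits(params, "extended_hook_params"))
  if (any(t < 0)) stop_protac("'t' must be non-negative")
  dss <- hook_degradation(c, params$hook)
  approach_steady_state(dss, t, params$half_life)
}

#' Map mechanistic (kcat model) parameters to hook parameters
#'
#' The steady-state profile of the kcat model is exactly a hook curve; this
#' returns its descriptive parameters in closed form:
#' `dcmax = sqrt(kd_poi * kd_e3)` (the concentration minimizing
#' `kd_poi*kd_e3/C + C`, i.e. maximizing engagement), `dmax = Dss(dcmax)`,
#' and `dc50` as the smaller root of `Dss(C) = dmax / 2`, which reduces to
#' the quadratic `C^2 - (Q + 4 dcmax) C + dcmax^2 = 0` with
#' `Q = beta + alpha*E0 + kd_poi + kd_e3`,
#' `beta = alpha*E0*kcat*half_life/ln(2)`.
#'
#' @param params A [mechanistic_params()] object with `kcat > 0`.
#' @return A [hook_params()] object reproducing the mechanistic
#'   steady-state profile at every concentration.
#' @export
hook_from_mechanistic <- function(params) {
  stopifnot(inherits(params, "mechanistic_params"))
  if (params$kcat <= 0) {
    stop_protac("degenerate mapping: kcat = 0 gives no degradation ",
                "and no hook parameters")
  }
  b <- params$binding
  e0 <- params$cell$e3_total
  beta <- b$alpha * e0 * params$kcat * params$cell$half_life / log(2)
  q <- beta + b$alpha * e0 + b$kd_poi + b$kd_e3
  dcmax <- sqrt(b$kd_poi * b$kd_e3)
  dmax <- beta / (q + 2 * dcmax)
  dc50 <- smaller_quad_root(q + 4 * dcmax, dcmax^2)
  hook_params(dmax = dmax, dc50 = dc50, dcmax = dcmax)
}
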