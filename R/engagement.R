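## Target engagement: the fraction of total target protein bound in a
## POI-PROTAC-E3 ternary complex at a given unbound PROTAC concentration,
## under a rapid-equilibrium model of the two binary binding events and
## the cooperative ternary complex.

#' Ternary-complex target engagement (ligase-unsaturated form)
#'
#' Closed-form target engagement under the assumption that the degradation
#' machinery -- in particular the targeted E3 ligase -- is not saturated by
#' the target protein, so engagement is independent of target expression:
#'
#' \deqn{TE(C) = \frac{\alpha E_0}{\alpha E_0 + K_{D,P} + K_{D,E} +
#'   K_{D,P} K_{D,E}/C + C}}
#'
#' The curve is bell-shaped on the log-concentration axis: `TE(0) = 0`,
#' `TE -> 0` as `C -> Inf`, with its maximum at the geometric mean
#' `C = sqrt(kd_poi * kd_e3)` -- the molecular origin of the hook effect.
#'
#' @param c Unbound PROTAC concentration, nM (vectorized, >= 0).
#' @param binding A [ternary_binding()] object.
#' @param e3_total Total targeted E3 ligase concentration, nM.
#' @return Target engagement fraction(s) in [0, 1].
#' @examples
#' b <- ternary_binding(100, 100, alpha = 1)
#' ternary_te(100, b, e3_total = 100)  # 0.2, the peak engagement
#' @seealso [ternary_te_exact()] for the protein-level dependent solution.
#' @export
ternary_te <- function(c, binding, e3_total) {
  stopifnot(inherits(binding, "ternary_binding"))
  check_scalar(e3_total, "e3_total", lower = 0, strict_lower = TRUE)
  if (any(c < 0)) stop_protac("'c' must be non-negative")
  out <- numeric(length(c))
  pos <- c > 0
  cp <- c[pos]
  ae0 <- binding$alpha * e3_total
  out[pos] <- ae0 / (ae0 + binding$kd_poi + binding$kd_e3 +
                       binding$kd_poi * binding$kd_e3 / cp + cp)
  out
}

#' Ternary-complex target engagement (exact equilibrium solution)
#'
#' Exact rapid-equilibrium engagement accounting for finite target-protein
#' levels: the physically meaningful (smaller) root of the ternary-complex
#' mass-balance quadratic, evaluated in a cancellation-safe form. In the
#' limit of vanishing target expression (`poi_total -> 0`) this converges
#' to [ternary_te()].
#'
#' @param c Unbound PROTAC concentration, nM (vectorized, >= 0).
#' @param binding A [ternary_binding()] object.
#' @param e3_total Total targeted E3 ligase concentration, nM.
#' @param poi_total Total target protein concentration, nM.
#' @return Target engagement fraction(s), bounded by
#'   `min(1, e3_total / poi_total)`.
#' @export
ternary_te_exact <- function(c, binding, e3_total, poi_total) {
  stopifnot(inherits(binding, "ternary_binding"))
  check_scalar(e3_total, "e3_total", lower = 0, strict_lower = TRUE)
  check_scalar(poi_total, "poi_total", lower = 0, strict_lower = TRUE)
  if (any(c < 0)) stop_protac("'c' must be non-negative")
  out <- numeric(length(c))
  pos <- c > 0
  cp <- c[pos]
  ratio <- e3_total / poi_total
  ## TE solves TE^2 - A*TE + ratio = 0 with
  ## A = 1 + E0/P0 + (KD,P + C)(KD,E + C) / (P0 * alpha * C)
  a <- 1 + ratio + (binding$kd_poi + cp) * (binding$kd_e3 + cp) /
    (poi_total * binding$alpha * cp)
  out[pos] <- smaller_quad_root(a, ratio)
  out
}
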