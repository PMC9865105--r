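## Experimental-design utilities: how long to incubate before descriptive
## degradation parameters can be trusted as steady-state values, and which
## concentrations to put on the plate.

## Closed form for the DC50 criterion. At c = f * DC50 the hyperbolic
## steady-state profile sits at Dss = Dmax * f / (1 + f); requiring the
## pre-steady-state profile to reach Dmax / 2 there by time t gives
##   t >= t_half * (1 - Dmax * f / (1 + f)) * log(2 f / (f - 1)) / log(2).
dc50_criterion_time <- function(half_life, dmax, factor_tol) {
  half_life * (1 - dmax * factor_tol / (1 + factor_tol)) *
    log(2 * factor_tol / (factor_tol - 1)) / log(2)
}

## Dmax criterion: apparent plateau Dmax * (1 - exp(-ln2 t / (t_half (1-Dmax))))
## within `point_tol` of Dmax.
dmax_criterion_time <- function(half_life, dmax, point_tol) {
  if (dmax <= point_tol) return(0)
  half_life * (1 - dmax) * log(dmax / point_tol) / log(2)
}

## Generic route: root-find the apparent DC50 (concentration where the
## time-t profile reaches half the steady-state Dmax) and the apparent
## plateau on a candidate time, then scan integer hours.
design_profile_ok <- function(t, half_life, dmax, factor_tol, point_tol) {
  dss <- function(c) dmax * c / (c + 1)  # hyperbolic, DC50 = 1 (scale-free)
  d_ct <- function(c) approach_steady_state(dss(c), t, half_life)
  plateau <- approach_steady_state(dmax, t, half_life)
  if (abs(dmax - plateau) > point_tol) return(FALSE)
  if (d_ct(1e12) < dmax / 2) return(FALSE)  # half-depth not yet reachable
  app_dc50 <- stats::uniroot(function(c) d_ct(c) - dmax / 2,
                             lower = 1e-9, upper = 1e12,
                             tol = 1e-12)$root
  app_dc50 <= factor_tol
}

#' Minimum incubation time for trustworthy steady-state estimates
#'
#' Smallest whole-hour incubation time after which descriptive parameters
#' fitted to a concentration-degradation profile are acceptably close to
#' their steady-state values: the apparent DC50 within a fold-factor
#' (default 1.5) of the steady-state DC50, and the apparent Dmax within a
#' tolerance (default 5 percentage points) of the steady-state Dmax.
#' Profiles are assumed to evolve with exponential-approach kinetics on a
#' hyperbolic steady-state shape; the apparent DC50 is the concentration
#' where the time-t profile reaches half the steady-state Dmax.
#'
#' Under the default tolerances the DC50 criterion is the binding one and
#' admits a closed form, `t* = half_life * (1 - 0.6 * dmax) * ln(6)/ln(2)`,
#' rounded up to whole hours; `method = "simulate"` instead solves for the
#' apparent parameters numerically on each candidate hour, which also
#' honors non-default tolerances where the closed form's premise (DC50
#' criterion binding) may fail.
#'
#' @param half_life Target-protein half-life, h (use a generous estimate:
#'   too high is safer than too low).
#' @param dmax_assumed Anticipated steady-state maximal degradation,
#'   fraction in (0, 1).
#' @param dc50_factor_tolerance Acceptable fold-error of the apparent DC50
#'   (> 1; default 1.5).
#' @param dmax_point_tolerance Acceptable absolute Dmax error, as a
#'   fraction (default 0.05, i.e. 5 percentage points).
#' @param method `"closed_form"` (default) or `"simulate"`.
#' @return Minimum incubation time, integer hours (>= 1).
#' @examples
#' min_incubation_time(24, 0.80)  # 33 h
#' @export
min_incubation_time <- function(half_life, dmax_assumed,
                                dc50_factor_tolerance = 1.5,
                                dmax_point_tolerance = 0.05,
                                method = c("closed_form", "simulate")) {
  method <- match.arg(method)
  check_scalar(half_life, "half_life", lower = 0, strict_lower = TRUE)
  check_scalar(dmax_assumed, "dmax_assumed", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(dmax_point_tolerance, "dmax_point_tolerance", lower = 0,
               strict_lower = TRUE)
  if (!is.numeric(dc50_factor_tolerance) || dc50_factor_tolerance <= 1) {
    stop_protac("'dc50_factor_tolerance' must be a fold-factor > 1")
  }
  if (method == "closed_form") {
    t_star <- max(
      dc50_criterion_time(half_life, dmax_assumed, dc50_factor_tolerance),
      dmax_criterion_time(half_life, dmax_assumed, dmax_point_tolerance)
    )
    return(max(1L, as.integer(ceiling(t_star - 1e-9))))
  }
  t <- 1L
  while (!design_profile_ok(t, half_life, dmax_assumed,
                            dc50_factor_tolerance, dmax_point_tolerance)) {
    t <- t + 1L
    if (t > 100000L) stop_protac("no feasible incubation time found")
  }
  t
}

#' Minimum-incubation-time grid over half-lives and degradation depths
#'
#' Element-wise [min_incubation_time()] over a grid of half-lives (rows)
#' and assumed steady-state Dmax values (columns). The defaults span the
#' practically relevant range (2-192 h half-lives, 30-99\% degradation).
#' Required incubation decreases with increasing Dmax and with decreasing
#' half-life.
#'
#' @param half_lives Numeric vector of half-lives, h.
#' @param dmaxes Numeric vector of assumed Dmax values, fractions.
#' @inheritParams min_incubation_time
#' @return Integer matrix of hours, `half_lives` x `dmaxes`, dimnames set
#'   to the input values.
#' @export
incubation_table <- function(half_lives = c(2, 4, 6, 12, 24, 36, 48, 72,
                                            96, 192),
                             dmaxes = c(0.30, 0.50, 0.60, 0.70, 0.75,
                                        0.80, 0.85, 0.90, 0.95, 0.99),
                             dc50_factor_tolerance = 1.5,
                             dmax_point_tolerance = 0.05,
                             method = "closed_form") {
  if (!length(half_lives) || !length(dmaxes)) {
    stop_protac("'half_lives' and 'dmaxes' must be non-empty")
  }
  out <- outer(half_lives, dmaxes, Vectorize(function(hl, dm) {
    min_incubation_time(hl, dm, dc50_factor_tolerance,
                        dmax_point_tolerance, method)
  }))
  dimnames(out) <- list(half_life_h = as.character(half_lives),
                        dmax = as.character(dmaxes))
  storage.mode(out) <- "integer"
  out
}

#' Recommend a concentration grid covering the full hook profile
#'
#' Reliable hook-parameter estimates need concentrations spanning from no
#' effect, through the rising phase and the peak at DCmax, into the hook
#' region beyond. The grid is log-spaced and symmetric about the DCmax
#' anchor -- estimated as `sqrt(kd_poi * kd_e3)` from binary affinities
#' when no degradation data exist yet, or taken from fitted hook
#' parameters -- and widened below the anchor until the predicted
#' degradation falls under 5\% of Dmax.
#'
#' @param source A [ternary_binding()] or [hook_params()] object.
#' @param n_points Number of concentrations (>= 6).
#' @param span_decades Minimum total width of the grid in log10 units
#'   (default 4).
#' @return A list of class `concentration_plan` with the `anchor` (nM),
#'   the `grid` of concentrations (nM), and a `rationale` tag per point
#'   (`"no_effect"`, `"rising"`, `"peak"`, `"hook"`).
#' @export
recommend_concentrations <- function(source, n_points = 8L,
                                     span_decades = 4) {
  if (n_points < 6L) {
    stop_protac("'n_points' must be at least 6 to cover all profile regions")
  }
  if (inherits(source, "ternary_binding")) {
    anchor <- sqrt(source$kd_poi * source$kd_e3)
    hook <- NULL
  } else if (inherits(source, "hook_params")) {
    anchor <- source$dcmax
    hook <- source
  } else {
    stop_protac("'source' must be a ternary_binding or hook_params object")
  }
  half_width <- span_decades / 2
  if (!is.null(hook)) {
    ## widen downward until predicted degradation < 5% of Dmax
    c_low <- stats::uniroot(
      function(lc) hook_degradation(10^lc, hook) - 0.05 * hook$dmax,
      lower = log10(anchor) - 18, upper = log10(anchor), tol = 1e-10)$root
    half_width <- max(half_width, log10(anchor) - c_low + 0.1)
  }
  grid <- 10^seq(log10(anchor) - half_width, log10(anchor) + half_width,
                 length.out = n_points)
  rationale <- if (!is.null(hook)) {
    d <- hook_degradation(grid, hook)
    ifelse(grid > anchor * 1.0001, "hook",
           ifelse(d < 0.05 * hook$dmax, "no_effect",
                  ifelse(d > 0.95 * hook$dmax, "peak", "rising")))
  } else {
    ifelse(grid > anchor * 1.0001, "hook",
           ifelse(grid < anchor / 10^(half_width / 2), "no_effect",
                  ifelse(grid > anchor / 2, "peak", "rising")))
  }
  structure(list(anchor = anchor, grid = grid, rationale = rationale),
            class = "concentration_plan")
}

#' @export
print.concentration_plan <- function(x, ...) {
  cat(sprintf("Concentration plan (anchor DCmax = %.3g nM):\n", x$anchor))
  print(data.frame(conc_nM = signif(x$grid, 4), region = x$rationale))
  invisible(x)
}
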