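## Forward-prediction workflows: translating degradation across cellular
## systems, relating engagement to degradation depth, planning affinity
## improvements, and projecting full time courses of degradation and the
## downstream PD response.

#' Predict maximal degradation across cellular systems
#'
#' `Dmax` in a new cell type follows from that system's E3 ligase
#' expression and target half-life, with the catalytic rate constant
#' `kcat` shared across systems (it is a property of the target/E3 pair,
#' not of the PROTAC or the cell). Lower E3 expression or faster target
#' turnover both lower the achievable degradation depth.
#'
#' @param params A [mechanistic_params()] object calibrated in a reference
#'   system.
#' @param systems A list of [cell_system()] objects (optionally named).
#' @return Named numeric vector of predicted `Dmax` fractions.
#' @export
predict_dmax_across_systems <- function(params, systems) {
  stopifnot(inherits(params, "mechanistic_params"))
  if (inherits(systems, "cell_system")) systems <- list(systems)
  out <- vapply(systems, function(sys) {
    stopifnot(inherits(sys, "cell_system"))
    p <- mechanistic_params(params$binding, sys, params$kcat)
    if (p$kcat == 0) return(0)
    dcmax <- sqrt(p$binding$kd_poi * p$binding$kd_e3)
    mechanistic_dss(dcmax, p)
  }, numeric(1))
  if (!is.null(names(systems))) names(out) <- names(systems)
  out
}

#' Steady-state degradation as a function of target engagement
#'
#' The hyperbolic engagement-degradation relationship
#' `Dss = TE / (TE50 + TE)`: because PROTACs act catalytically, TE50 is
#' typically around 1\%, so even a few percent engagement translates into
#' deep degradation.
#'
#' @param params A [mechanistic_params()] object with `kcat > 0`.
#' @param te_grid Engagement fractions in [0, 1].
#' @return `Dss` fractions, one per grid point.
#' @export
te_dmax_curve <- function(params, te_grid) {
  dss_from_te(te_grid, te50(params))
}

#' How much must binding improve to hit a target degradation depth?
#'
#' One-dimensional search for a common fold-change applied to the chosen
#' binding parameters (`kd_poi` and/or `kd_e3` divided by the fold,
#' `alpha` multiplied by it) such that the predicted steady-state `Dmax`
#' reaches the target. With engagement already far above TE50, affinity
#' gains saturate: the theoretical ceiling as affinities improve without
#' bound is `Dmax = 1 / (1 + TE50)`, and targets above it are flagged
#' infeasible with the advice to increase `kcat` (different warheads or a
#' different E3 ligase) instead.
#'
#' @param params A [mechanistic_params()] object (current compound).
#' @param target A [hook_params()] object; only `target$dmax` must be met.
#' @param adjustable Character subset of `c("kd_poi", "kd_e3", "alpha")`.
#' @return A list of class `affinity_target_result`: `fold_changes` (named,
#'   1 for untouched parameters), `achieved` hook parameters, `feasible`
#'   flag, `ceiling` (the asymptotic Dmax), and a `recommendation` string
#'   when infeasible.
#' @export
required_affinity_change <- function(params, target,
                                     adjustable = c("kd_poi", "kd_e3",
                                                    "alpha")) {
  stopifnot(inherits(params, "mechanistic_params"),
            inherits(target, "hook_params"))
  adjustable <- match.arg(adjustable, several.ok = TRUE)
  if (params$kcat <= 0) stop_protac("kcat must be positive")
  ceiling_dmax <- 1 / (1 + te50(params))
  apply_fold <- function(fold) {
    b <- params$binding
    mechanistic_params(
      ternary_binding(
        kd_poi = b$kd_poi / if ("kd_poi" %in% adjustable) fold else 1,
        kd_e3 = b$kd_e3 / if ("kd_e3" %in% adjustable) fold else 1,
        alpha = b$alpha * if ("alpha" %in% adjustable) fold else 1
      ),
      params$cell, params$kcat)
  }
  dmax_at <- function(fold) hook_from_mechanistic(apply_fold(fold))$dmax
  folds <- stats::setNames(rep(1, 3), c("kd_poi", "kd_e3", "alpha"))
  if (target$dmax >= ceiling_dmax) {
    return(structure(list(
      fold_changes = folds, achieved = hook_from_mechanistic(params),
      feasible = FALSE, ceiling = ceiling_dmax,
      recommendation = sprintf(
        paste0("target Dmax %.1f%% exceeds the affinity ceiling %.1f%%; ",
               "binding improvements cannot reach it -- increase kcat ",
               "(new warheads or a different E3 ligase) instead"),
        100 * target$dmax, 100 * ceiling_dmax)),
      class = "affinity_target_result"))
  }
  current <- dmax_at(1)
  if (abs(current - target$dmax) < 1e-12) {
    fold <- 1
  } else {
    lo <- -12; hi <- 12
    f <- function(lf) dmax_at(exp(lf)) - target$dmax
    fold <- exp(stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root)
  }
  folds[adjustable] <- fold
  structure(list(fold_changes = folds,
                 achieved = hook_from_mechanistic(apply_fold(fold)),
                 feasible = TRUE, ceiling = ceiling_dmax,
                 recommendation = NULL),
            class = "affinity_target_result")
}

#' @export
print.affinity_target_result <- function(x, ...) {
  cat("Affinity optimization target:\n")
  cat(sprintf("  fold changes: KD,P 1/%.3g, KD,E 1/%.3g, alpha x%.3g\n",
              x$fold_changes[["kd_poi"]], x$fold_changes[["kd_e3"]],
              x$fold_changes[["alpha"]]))
  cat("  achieved profile: ")
  print(x$achieved)
  cat(sprintf("  feasible: %s (Dmax ceiling %.1f%%)\n", x$feasible,
              100 * x$ceiling))
  if (!is.null(x$recommendation)) cat("  ", x$recommendation, "\n")
  invisible(x)
}

#' Predict time courses of degradation and the downstream PD response
#'
#' For a constant in vitro PROTAC concentration, evaluates degradation
#' over time (mechanistic or extended hook model), constant inhibition
#' (from the PD parameters' IC50, or 0 for non-inhibiting PROTACs), the
#' combined target modulation, and the downstream PD response. At `t = 0`
#' target modulation equals inhibition alone: the early response is
#' occupancy-driven, degradation takes over as it accumulates.
#'
#' @param c Constant PROTAC concentration, nM.
#' @param times Incubation times, h.
#' @param params A [mechanistic_params()] or [extended_hook_params()]
#'   object governing degradation kinetics.
#' @param pd A [pd_params()] object (its `ic50`, when present, sets the
#'   inhibition level).
#' @return A data.frame with columns `time_h`, `degradation`,
#'   `inhibition`, `target_modulation`, `pd_response`.
#' @examples
#' eh <- extended_hook_params(hook_params(0.9, 1, 100), half_life = 24)
#' pd <- pd_params(p50 = 0.5, hill = 1, pd_min = 0, ic50 = 120)
#' predict_time_courses(100, c(0, 6, 24, 72), eh, pd)
#' @export
predict_time_courses <- function(c, times, params, pd) {
  stopifnot(inherits(pd, "pd_params"))
  check_scalar(c, "c", lower = 0)
  if (any(times < 0)) stop_protac("'times' must be non-negative")
  d <- if (inherits(params, "mechanistic_params")) {
    degradation_time_course(c, times, params)
  } else if (inherits(params, "extended_hook_params")) {
    extended_hook(c, times, params)
  } else {
    stop_protac("'params' must be mechanistic_params or extended_hook_params")
  }
  i <- if (is.null(pd$ic50)) 0 else inhibition_from_ic50(c, pd$ic50, pd$p50)
  tm <- target_modulation(d, rep(i, length(d)))
  data.frame(time_h = times, degradation = d, inhibition = i,
             target_modulation = tm, pd_response = pd_response(tm, pd))
}
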