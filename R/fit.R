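## Nonlinear least-squares fitting of the degradation and PD models.
## All fits share one engine: Levenberg-Marquardt (minpack.lm::nls.lm) on
## unconstrained transformed parameters (log for concentrations and rates,
## logit for fractions), with seeded multi-start to escape local minima in
## the hook surface. Objective is unweighted least squares on the
## fraction-of-baseline scale, matching normalized plate-reader/Western
## readouts; an optional weight vector is accepted but off by default.

logit <- stats::qlogis
expit <- stats::plogis

fit_control <- function() {
  minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15, ptol = 1e-15)
}

## Run nls.lm from several jittered starts, keep the best RSS.
## Returns list(theta, rss, converged) or NULL if every start failed.
lm_multistart <- function(resid_fun, theta0, n_starts, seed, jitter_sd = 0.5,
                          weights = NULL) {
  starts <- list(theta0)
  if (n_starts > 1) {
    jit <- with_preserved_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        theta0 + stats::rnorm(length(theta0), sd = jitter_sd)
      })
    })
    starts <- c(starts, jit)
  }
  wfun <- if (is.null(weights)) resid_fun else {
    sw <- sqrt(weights)
    function(th) sw * resid_fun(th)
  }
  best <- NULL
  for (th0 in starts) {
    ans <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = wfun, control = fit_control()),
      error = function(e) NULL
    )
    if (is.null(ans)) next
    rss <- sum(ans$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-14) {
      best <- list(theta = ans$par, rss = rss,
                   converged = ans$info %in% 1:4)
    }
  }
  best
}

new_protac_fit <- function(model, estimates, theta, rss, n_obs, converged,
                           data, fitted, residuals, refit, predict_fun,
                           excluded = integer(0), note = NULL, extra = list()) {
  structure(
    c(list(model = model, estimates = estimates, theta = theta, rss = rss,
           n_obs = n_obs, converged = converged, data = data,
           fitted = fitted, residuals = residuals, refit = refit,
           predict_fun = predict_fun, excluded = excluded, note = note,
           ci = NULL, draws = NULL, n_boot = 0L, boot_seed = NULL),
      extra),
    class = "protac_fit"
  )
}

#' @export
print.protac_fit <- function(x, ...) {
  cat(sprintf("<protac_fit: %s model, %d observations, RSS = %.4g%s>\n",
              x$model, x$n_obs, x$rss,
              if (x$converged) "" else ", NOT CONVERGED"))
  est <- data.frame(estimate = x$estimates)
  if (!is.null(x$ci)) {
    est$ci_lower <- x$ci[, 1L][rownames(est)]
    est$ci_upper <- x$ci[, 2L][rownames(est)]
  }
  print(est)
  if (length(x$excluded)) {
    cat("Excluded rows:", paste(x$excluded, collapse = ", "), "\n")
  }
  if (!is.null(x$note)) cat("Note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.protac_fit <- function(object, ...) object$estimates

## ---- dataset checks ------------------------------------------------------

fit_data_checks <- function(data, readout, min_conc = 4L,
                            single_time = FALSE, single_compound = TRUE) {
  data <- as_dose_response(data)
  data <- data[data$readout == readout, , drop = FALSE]
  if (nrow(data) == 0L) {
    stop_protac(sprintf("no rows with readout '%s'", readout))
  }
  if (single_compound && length(unique(data$compound)) > 1L) {
    stop_protac("data must contain a single compound for this fit; ",
                "found: ", paste(unique(data$compound), collapse = ", "))
  }
  if (single_time && length(unique(data$time_h)) > 1L) {
    stop_protac("this model assumes a single incubation time; ",
                "use fit_extended_hook() for multi-time data")
  }
  n_conc <- length(unique(data$conc_nM[data$conc_nM > 0]))
  if (n_conc < min_conc) {
    stop_protac(sprintf(
      "at least %d distinct positive concentrations are required ",
      min_conc), sprintf("for identifiability (found %d)", n_conc))
  }
  data
}

## Mean response per concentration, ordered by concentration.
conc_profile <- function(conc, resp) {
  agg <- tapply(resp, conc, mean)
  data.frame(conc = as.numeric(names(agg)), resp = as.numeric(agg))
}

## Shared initialization heuristics for hook-shaped profiles.
hook_start <- function(conc, resp) {
  prof <- conc_profile(conc[conc > 0], resp[conc > 0])
  dmax0 <- min(max(1 - min(prof$resp), 0.05), 0.98)
  dcmax0 <- prof$conc[which.min(prof$resp)]
  below <- prof$conc[prof$resp <= 1 - dmax0 / 2]
  dc500 <- if (length(below)) min(below) else dcmax0 / 4
  if (dc500 >= dcmax0) dc500 <- dcmax0 / 4
  c(dmax = dmax0, dc50 = dc500, dcmax = dcmax0)
}

## ---- hook fit ------------------------------------------------------------

## clamps keep the optimizer inside the numerically safe region without
## altering any realistic optimum
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

hook_theta_to_est <- function(th) {
  dc50 <- clamp(exp(th[2L]), 1e-12, 1e12)
  c(dmax = unname(clamp(expit(th[1L]), 1e-10, 1 - 1e-10)),
    dc50 = unname(dc50),
    dcmax = unname(dc50 * (1 + clamp(exp(th[3L]), 1e-10, 1e12))))
}

hook_est_to_theta <- function(est) {
  c(logit(est[["dmax"]]), log(est[["dc50"]]),
    log(est[["dcmax"]] / est[["dc50"]] - 1))
}

hook_pred <- function(th, conc) {
  e <- hook_theta_to_est(th)
  1 - hook_d_raw(conc, e[["dmax"]], e[["dc50"]], e[["dcmax"]])
}

#' Fit the hook model to a concentration-degradation profile
#'
#' Least-squares estimation of `(dmax, dc50, dcmax)` on relative protein
#' levels `response = 1 - D(C)` at a single incubation time. Starting
#' values come from data heuristics (`dcmax` at the response minimum,
#' `dmax` from the response depth, `dc50` at the first half-depth
#' crossing) followed by seeded multi-start Levenberg-Marquardt.
#'
#' When the fitted `dcmax` lies beyond the largest observed concentration
#' (no detectable hook), an extra-sum-of-squares F-test against the nested
#' Emax model is run and, if the third parameter is not justified at the
#' 5\% level, the result carries a note recommending the Emax fallback.
#'
#' @param data A dose-response dataset (see [dose_response_dataset()]) with
#'   `protein_level` readout, one compound, one incubation time, and at
#'   least 4 distinct positive concentrations.
#' @param n_starts Number of multi-start optimizations (first start is the
#'   heuristic; the rest are jittered).
#' @param seed Integer seed for the start jitter (fits are deterministic
#'   given data and seed).
#' @param weights Optional per-observation weights (default: unweighted).
#' @return A `protac_fit` object; `coef()` returns the estimates.
#' @export
fit_hook <- function(data, n_starts = 5L, seed = 1L, weights = NULL) {
  data <- fit_data_checks(data, "protein_level", single_time = TRUE)
  conc <- data$conc_nM
  resp <- data$response
  start <- hook_start(conc, resp)
  theta0 <- hook_est_to_theta(start)
  resid_fun <- function(th) resp - hook_pred(th, conc)
  best <- lm_multistart(resid_fun, theta0, n_starts, seed, weights = weights)
  if (is.null(best)) stop_protac("hook fit failed from every start")
  est <- hook_theta_to_est(best$theta)
  note <- NULL
  if (est[["dcmax"]] > max(conc)) {
    ftest <- tryCatch(
      hook_vs_emax_ftest(data, best$rss, n_starts, seed, weights),
      error = function(e) NULL
    )
    if (!is.null(ftest) && ftest$p > 0.05) {
      note <- sprintf(
        paste0("no hook detectable within the observed concentration range ",
               "(fitted DCmax = %.3g nM > max C = %.3g nM); the third ",
               "parameter is not justified (F-test p = %.3f) -- consider ",
               "the Emax model"),
        est[["dcmax"]], max(conc), ftest$p)
    }
  }
  if (!best$converged) {
    warning("hook fit did not report convergence; inspect the result",
            call. = FALSE)
  }
  make_curve_fit("hook", est, best, data, conc, resp,
                 pred = hook_pred, to_theta = hook_est_to_theta,
                 theta_to_est = hook_theta_to_est,
                 predict_fun = function(est, c, t = NULL) {
                   1 - hook_degradation(
                     c, hook_params(est[["dmax"]], est[["dc50"]],
                                    est[["dcmax"]]))
                 },
                 note = note)
}

hook_vs_emax_ftest <- function(data, rss_hook, n_starts, seed, weights) {
  fe <- fit_emax(data, exclude_above_hook = FALSE, n_starts = n_starts,
                 seed = seed, weights = weights)
  n <- nrow(data)
  df_extra <- 1L
  df_full <- n - 3L
  fstat <- ((fe$rss - rss_hook) / df_extra) / (rss_hook / df_full)
  list(f = fstat, p = stats::pf(max(fstat, 0), df_extra, df_full,
                                lower.tail = FALSE))
}

## Assemble a protac_fit for single-curve models sharing the same plumbing.
make_curve_fit <- function(model, est, best, data, conc, resp, pred,
                           to_theta, theta_to_est, predict_fun,
                           excluded = integer(0), note = NULL,
                           time = NULL, extra = list()) {
  fitted <- if (is.null(time)) pred(best$theta, conc) else
    pred(best$theta, conc, time)
  refit <- function(new_resp, theta_start = best$theta) {
    rf <- if (is.null(time)) {
      function(th) new_resp - pred(th, conc)
    } else {
      function(th) new_resp - pred(th, conc, time)
    }
    ans <- lm_multistart(rf, theta_start, n_starts = 1L, seed = 0L)
    if (is.null(ans)) return(NULL)
    theta_to_est(ans$theta)
  }
  new_protac_fit(model, est, best$theta, best$rss, length(resp),
                 best$converged, data, fitted, resp - fitted, refit,
                 predict_fun, excluded = excluded, note = note, extra = extra)
}

## ---- Emax fit ------------------------------------------------------------

emax_theta_to_est <- function(th) {
  c(emax = unname(clamp(expit(th[1L]), 1e-10, 1 - 1e-10)),
    ec50 = unname(clamp(exp(th[2L]), 1e-12, 1e12)))
}

emax_pred <- function(th, conc) {
  e <- emax_theta_to_est(th)
  1 - e[["emax"]] * conc / (conc + e[["ec50"]])
}

#' Fit the hyperbolic Emax model to a concentration-degradation profile
#'
#' Estimates `(emax, ec50)` on `response = 1 - E(C)`. With
#' `exclude_above_hook = TRUE`, concentrations above the empirical
#' degradation maximum (the concentration of minimal mean response) are
#' dropped before fitting -- the conventional workaround for hook-shaped
#' data -- and the dropped row indices are recorded in the result's
#' `excluded` field.
#'
#' @inheritParams fit_hook
#' @param exclude_above_hook Drop concentrations above the empirical
#'   response minimum before fitting.
#' @return A `protac_fit` object.
#' @export
fit_emax <- function(data, exclude_above_hook = FALSE, n_starts = 5L,
                     seed = 1L, weights = NULL) {
  data <- fit_data_checks(data, "protein_level", single_time = TRUE)
  excluded <- integer(0)
  if (exclude_above_hook) {
    ## keep only concentrations strictly below the empirical degradation
    ## maximum (the concentration of minimal mean response)
    prof <- conc_profile(data$conc_nM, data$response)
    c_hook <- prof$conc[which.min(prof$resp)]
    excluded <- which(data$conc_nM >= c_hook)
    if (length(excluded)) {
      kept <- data[-excluded, , drop = FALSE]
      if (length(unique(kept$conc_nM[kept$conc_nM > 0])) >= 4L) {
        data_fit <- kept
      } else {
        warning("exclusion above the empirical hook would leave fewer ",
                "than 4 concentrations; fitting all data", call. = FALSE)
        excluded <- integer(0)
        data_fit <- data
      }
    } else {
      data_fit <- data
    }
  } else {
    data_fit <- data
  }
  conc <- data_fit$conc_nM
  resp <- data_fit$response
  start <- hook_start(conc, resp)
  theta0 <- c(logit(start[["dmax"]]), log(start[["dc50"]]))
  wts <- if (is.null(weights)) NULL else
    weights[setdiff(seq_len(nrow(data)), excluded)]
  best <- lm_multistart(function(th) resp - emax_pred(th, conc),
                        theta0, n_starts, seed, weights = wts)
  if (is.null(best)) stop_protac("Emax fit failed from every start")
  est <- emax_theta_to_est(best$theta)
  make_curve_fit("emax", est, best, data_fit, conc, resp,
                 pred = emax_pred,
                 to_theta = function(e) c(logit(e[["emax"]]),
                                          log(e[["ec50"]])),
                 theta_to_est = emax_theta_to_est,
                 predict_fun = function(est, c, t = NULL) {
                   1 - emax_effect(c, emax_params(est[["emax"]],
                                                  est[["ec50"]]))
                 },
                 excluded = excluded)
}

## ---- extended hook fit ---------------------------------------------------

ext_theta_to_est <- function(th, half_life) {
  est <- hook_theta_to_est(th[1:3])
  if (length(th) >= 4L) {
    est[["half_life"]] <- clamp(exp(th[4L]), 1e-6, 1e9)
  } else {
    est[["half_life"]] <- half_life
  }
  est
}

## returns degradation; caller converts to relative protein level
ext_pred <- function(th, conc, time, half_life = NULL) {
  e <- ext_theta_to_est(th, half_life)
  dss <- hook_d_raw(conc, e[["dmax"]], e[["dc50"]], e[["dcmax"]])
  approach_steady_state(dss, time, e[["half_life"]])
}

#' Fit the extended hook model across incubation times
#'
#' Simultaneous fit of the steady-state parameters `(dmax, dc50, dcmax)`
#' -- and optionally the target half-life -- to profiles at one or more
#' incubation times, using the time-resolved hook model. This is the
#' estimation route for steady-state degradation parameters when the
#' required incubation times are impractically long (slow-turnover
#' targets): pre-steady-state data plus the half-life pin down where the
#' profile is headed.
#'
#' @inheritParams fit_hook
#' @param half_life Known target-protein half-life in h, or `NULL` to
#'   co-estimate it (requires at least 2 distinct incubation times).
#' @param estimate_half_life Set `TRUE` to co-estimate the half-life even
#'   when a starting value is supplied via `half_life`.
#' @return A `protac_fit` with steady-state estimates (and `half_life` if
#'   co-estimated); `predict(fit, c, t)` evaluates the fitted model at any
#'   incubation time, observed or not.
#' @export
fit_extended_hook <- function(data, half_life = NULL,
                              estimate_half_life = is.null(half_life),
                              n_starts = 5L, seed = 1L, weights = NULL) {
  data <- fit_data_checks(data, "protein_level")
  times <- unique(data$time_h)
  if (length(times) < 2L && estimate_half_life) {
    stop_protac("half-life is not identifiable from a single incubation ",
                "time; supply 'half_life' or provide >= 2 time points")
  }
  if (is.null(half_life) && !estimate_half_life) {
    stop_protac("either supply 'half_life' or set estimate_half_life = TRUE")
  }
  conc <- data$conc_nM
  time <- data$time_h
  resp <- data$response
  late <- time == max(time)
  start <- hook_start(conc[late], resp[late])
  theta0 <- c(logit(min(start[["dmax"]] * 1.1, 0.98)), log(start[["dc50"]]),
              log(start[["dcmax"]] / start[["dc50"]] - 1))
  hl0 <- half_life %||% (2 * max(time))
  if (estimate_half_life) theta0 <- c(theta0, log(hl0))
  fixed_hl <- if (estimate_half_life) NULL else half_life
  pred <- function(th, conc, time) 1 - ext_pred(th, conc, time, fixed_hl)
  best <- lm_multistart(function(th) resp - pred(th, conc, time),
                        theta0, n_starts, seed, weights = weights)
  if (is.null(best)) stop_protac("extended hook fit failed from every start")
  est <- ext_theta_to_est(best$theta, fixed_hl)
  make_curve_fit("extended_hook", est, best, data, conc, resp,
                 pred = pred,
                 to_theta = function(e) {
                   th <- c(logit(e[["dmax"]]), log(e[["dc50"]]),
                           log(e[["dcmax"]] / e[["dc50"]] - 1))
                   if (estimate_half_life) th <- c(th, log(e[["half_life"]]))
                   th
                 },
                 theta_to_est = function(th) ext_theta_to_est(th, fixed_hl),
                 predict_fun = function(est, c, t) {
                   1 - extended_hook(c, t, extended_hook_params(
                     hook_params(est[["dmax"]], est[["dc50"]],
                                 est[["dcmax"]]), est[["half_life"]]))
                 },
                 time = time)
}

## ---- kcat fit ------------------------------------------------------------

#' Fit the catalyzed degradation rate constant (kcat model)
#'
#' One-dimensional least-squares estimate of `kcat` with all binding and
#' cellular parameters fixed from orthogonal assays -- the mechanistic
#' calibration step. Profiles may span several incubation times.
#'
#' @inheritParams fit_hook
#' @param binding A [ternary_binding()] object (from biochemical assays).
#' @param cell A [cell_system()] object (E3 expression, protein half-life).
#' @return A `protac_fit` with single estimate `kcat` (h^-1). Data showing
#'   no degradation at all return `kcat = 0` with a warning.
#' @export
fit_kcat <- function(data, binding, cell, n_starts = 3L, seed = 1L,
                     weights = NULL) {
  stopifnot(inherits(binding, "ternary_binding"),
            inherits(cell, "cell_system"))
  data <- fit_data_checks(data, "protein_level")
  conc <- data$conc_nM
  time <- data$time_h
  resp <- data$response
  if (mean(1 - resp) <= 1e-8) {
    warning("no degradation signal in the data; returning kcat = 0",
            call. = FALSE)
    best <- list(theta = -Inf, rss = sum((resp - 1)^2), converged = TRUE)
    return(make_curve_fit(
      "kcat", c(kcat = 0), best, data, conc, resp,
      pred = function(th, conc, time) rep(1, length(conc)),
      to_theta = function(e) log(max(e[["kcat"]], 1e-12)),
      theta_to_est = function(th) c(kcat = unname(exp(th))),
      predict_fun = function(est, c, t) rep(1, length(c)),
      time = time))
  }
  pred <- function(th, conc, time) {
    kcat <- clamp(exp(th[1L]), 0, 1e9)
    dss <- mech_dss_raw(conc, binding$kd_poi, binding$kd_e3,
                        binding$alpha, cell$e3_total, cell$half_life, kcat)
    1 - approach_steady_state(dss, time, cell$half_life)
  }
  ## crude bracket for the start: match mean observed degradation at the
  ## most degrading concentration
  theta0 <- log(cell$kdeg_p / max(ternary_te(conc[conc > 0], binding,
                                             cell$e3_total)))
  best <- lm_multistart(function(th) resp - pred(th, conc, time),
                        theta0, n_starts, seed, jitter_sd = 1,
                        weights = weights)
  if (is.null(best)) stop_protac("kcat fit failed from every start")
  est <- c(kcat = unname(exp(best$theta[1L])))
  make_curve_fit("kcat", est, best, data, conc, resp,
                 pred = pred,
                 to_theta = function(e) log(e[["kcat"]]),
                 theta_to_est = function(th) c(kcat = unname(exp(th))),
                 predict_fun = function(est, c, t) {
                   1 - degradation_time_course(
                     c, t, mechanistic_params(binding, cell, est[["kcat"]]))
                 },
                 time = time)
}

## ---- PD fit --------------------------------------------------------------

## Constrained reparameterization: s = p50^hill in (0, 1/2], hill > 0.
## theta = (qlogis(2 s), log hill[, qlogis(pd_min)])
pd_theta_to_est <- function(th, fix_pd_min) {
  s <- 0.5 * clamp(expit(th[1L]), 1e-10, 1)
  hill <- clamp(exp(th[2L]), 1e-2, 1e3)
  pd_min <- if (is.null(fix_pd_min)) {
    clamp(expit(th[3L]), 0, 1 - 1e-10)
  } else {
    fix_pd_min
  }
  c(p50 = unname(clamp(s^(1 / hill), 1e-12, 1 - 1e-12)),
    hill = unname(hill), pd_min = unname(pd_min))
}

pd_est_to_theta <- function(est, fix_pd_min) {
  th <- c(logit(min(2 * est[["p50"]]^est[["hill"]], 1 - 1e-9)),
          log(est[["hill"]]))
  if (is.null(fix_pd_min)) {
    th <- c(th, logit(max(min(est[["pd_min"]], 1 - 1e-9), 1e-9)))
  }
  th
}

#' Fit the PD model linking target modulation to a downstream response
#'
#' Estimates `(p50, hill, pd_min)` of the direct-response PD model from
#' downstream-readout dose-response data, with target modulation composed
#' from supplied degradation parameters and (optionally) inhibition via the
#' IC50 of a non-degrading control. The constraint `p50^hill <= 1/2` is
#' enforced by reparameterization, never by rejection during optimization.
#'
#' Several compounds can be fitted simultaneously with shared PD
#' parameters by passing named lists of degradation parameters (and IC50s)
#' keyed by compound -- the route for testing on-target consistency.
#'
#' @param data Dose-response data with `pd_response` readout.
#' @param degradation A [hook_params()] or [extended_hook_params()] object,
#'   or a named list of such objects keyed by compound.
#' @param ic50 Inhibitory potency (nM) of the matched non-degrading
#'   control; scalar, named vector keyed by compound, or `NULL` to model
#'   degradation only (`I = 0`).
#' @param fix_pd_min Fix the target-independent floor at this value
#'   (commonly 0) instead of estimating it; `NULL` estimates it.
#' @inheritParams fit_hook
#' @return A `protac_fit` object with estimates `p50`, `hill`, `pd_min`.
#' @export
fit_pd <- function(data, degradation, ic50 = NULL, fix_pd_min = NULL,
                   n_starts = 5L, seed = 1L, weights = NULL) {
  data <- fit_data_checks(data, "pd_response", single_compound = FALSE)
  if (!is.null(fix_pd_min)) {
    check_scalar(fix_pd_min, "fix_pd_min", lower = 0, upper = 1,
                 strict_upper = TRUE)
  }
  compounds <- unique(data$compound)
  deg_list <- if (inherits(degradation, "hook_params") ||
                  inherits(degradation, "extended_hook_params")) {
    stats::setNames(rep(list(degradation), length(compounds)), compounds)
  } else {
    degradation
  }
  missing_deg <- setdiff(compounds, names(deg_list))
  if (length(missing_deg)) {
    stop_protac("no degradation parameters supplied for compound(s): ",
                paste(missing_deg, collapse = ", "))
  }
  ic50_vec <- if (is.null(ic50)) NULL else if (length(ic50) == 1L &&
                                               is.null(names(ic50))) {
    stats::setNames(rep(ic50, length(compounds)), compounds)
  } else {
    ic50
  }
  conc <- data$conc_nM
  time <- data$time_h
  resp <- data$response
  d_frac <- numeric(nrow(data))
  for (cmp in compounds) {
    idx <- data$compound == cmp
    dp <- deg_list[[cmp]]
    d_frac[idx] <- if (inherits(dp, "extended_hook_params")) {
      extended_hook(conc[idx], time[idx], dp)
    } else {
      hook_degradation(conc[idx], dp)
    }
  }
  pred <- function(th, conc, time) {
    est <- pd_theta_to_est(th, fix_pd_min)
    p50 <- est[["p50"]]
    i_frac <- numeric(length(conc))
    if (!is.null(ic50_vec)) {
      for (cmp in compounds) {
        idx <- data$compound == cmp
        if (!is.na(ic50_vec[cmp])) {
          ci <- conc[idx] * (1 - p50)
          i_frac[idx] <- ci / (ci + ic50_vec[[cmp]] * p50)
        }
      }
    }
    tm <- pmin(pmin(d_frac, 1) + i_frac - pmin(d_frac, 1) * i_frac, 1)
    s <- p50^est[["hill"]]
    u <- (1 - tm)^est[["hill"]]
    est[["pd_min"]] + (1 - est[["pd_min"]]) * u * (1 - s) /
      (s + u * (1 - 2 * s))
  }
  theta0 <- pd_est_to_theta(c(p50 = 0.7, hill = 2,
                              pd_min = max(min(min(resp), 0.5), 0.01)),
                            fix_pd_min)
  best <- lm_multistart(function(th) resp - pred(th, conc, time),
                        theta0, n_starts, seed, weights = weights)
  if (is.null(best)) stop_protac("PD fit failed from every start")
  est <- pd_theta_to_est(best$theta, fix_pd_min)
  make_curve_fit("pd", est, best, data, conc, resp,
                 pred = pred,
                 to_theta = function(e) pd_est_to_theta(e, fix_pd_min),
                 theta_to_est = function(th) pd_theta_to_est(th, fix_pd_min),
                 predict_fun = function(est, c, t = NULL) {
                   stop("use predict on the training design for PD fits")
                 },
                 time = time)
}

#' Predict from a fitted model
#'
#' @param object A `protac_fit`.
#' @param c Concentrations, nM.
#' @param t Incubation time(s), h (used by time-resolved models).
#' @param ... Unused.
#' @return Predicted relative response at the requested design points.
#' @export
predict.protac_fit <- function(object, c, t = NULL, ...) {
  object$predict_fun(object$estimates, c, t)
}
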