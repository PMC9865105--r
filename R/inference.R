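## Bootstrap confidence intervals, Welch comparisons of fitted parameters,
## and rank-agreement diagnostics.

#' Residual-bootstrap confidence intervals for a fitted model
#'
#' Nonparametric residual bootstrap: centered residuals are resampled with
#' replacement onto the fitted curve and the model is refitted (starting
#' from the original estimates), yielding percentile 95\% intervals. The
#' residual flavor is chosen over case resampling because replicate counts
#' in typical degradation assays are small. Fully seeded: the same seed
#' reproduces identical intervals.
#'
#' @param fit A converged `protac_fit`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the resampling stream.
#' @param level Confidence level (default 0.95).
#' @return The fit with `ci` (per-parameter bounds), `draws` (successful
#'   bootstrap estimates, one row per resample) and bookkeeping fields
#'   filled in. Fewer than 200 successful refits triggers an instability
#'   warning when at least that many were requested.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000L, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "protac_fit"))
  if (!fit$converged) {
    stop_protac("bootstrap requires a converged fit")
  }
  n <- fit$n_obs
  res <- fit$residuals - mean(fit$residuals)
  draws <- with_preserved_seed(seed, {
    out <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      new_resp <- fit$fitted + sample(res, n, replace = TRUE)
      out[[b]] <- fit$refit(new_resp)
    }
    out
  })
  ok <- !vapply(draws, is.null, logical(1))
  mat <- do.call(rbind, draws[ok])
  if (sum(ok) < min(200L, n_boot)) {
    warning(sprintf(
      "only %d of %d bootstrap refits succeeded; intervals are unstable",
      sum(ok), n_boot), call. = FALSE)
  }
  a <- (1 - level) / 2
  ci <- t(apply(mat, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  dimnames(ci) <- list(colnames(mat), c("lower", "upper"))
  fit$ci <- ci
  fit$draws <- mat
  fit$n_boot <- as.integer(n_boot)
  fit$boot_seed <- as.integer(seed)
  fit
}

#' Welch comparison of a fitted parameter between two fits
#'
#' Two-sided Welch t-test on a named parameter using bootstrap standard
#' errors, with Welch-Satterthwaite degrees of freedom computed from the
#' bootstrap sample sizes. Both fits must carry bootstrap draws (see
#' [bootstrap_ci()]).
#'
#' @param fit_a,fit_b `protac_fit` objects with bootstrap draws.
#' @param parameter Name of the parameter to compare (e.g. `"dmax"`).
#' @param alpha Significance level (default 0.05, i.e. 95\% confidence).
#' @return A list with the point estimates, `statistic`, `df`, `p_value`,
#'   and logical `significant`.
#' @export
welch_compare <- function(fit_a, fit_b, parameter, alpha = 0.05) {
  stopifnot(inherits(fit_a, "protac_fit"), inherits(fit_b, "protac_fit"))
  for (f in list(fit_a, fit_b)) {
    if (is.null(f$draws) || !parameter %in% colnames(f$draws)) {
      stop_protac(sprintf(
        "both fits need bootstrap draws for parameter '%s'; ", parameter),
        "run bootstrap_ci() first")
    }
  }
  ea <- fit_a$estimates[[parameter]]
  eb <- fit_b$estimates[[parameter]]
  se_a <- stats::sd(fit_a$draws[, parameter])
  se_b <- stats::sd(fit_b$draws[, parameter])
  na <- nrow(fit_a$draws)
  nb <- nrow(fit_b$draws)
  v <- se_a^2 + se_b^2
  stat <- (ea - eb) / sqrt(v)
  df <- v^2 / (se_a^4 / (na - 1) + se_b^4 / (nb - 1))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  list(parameter = parameter, estimate_a = ea, estimate_b = eb,
       statistic = stat, df = df, p_value = p, alpha = alpha,
       significant = p < alpha)
}

#' Kendall rank agreement between predicted and observed values
#'
#' Kendall's tau (tau-b: concordant/discordant pair counting with tie
#' correction), the rank-agreement metric used to compare compound
#' rankings produced by competing models.
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2).
#' @return Kendall's tau in [-1, 1].
#' @export
kendall_rank_agreement <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop_protac("'predicted' and 'observed' must have equal length")
  }
  if (length(predicted) < 2L) {
    stop_protac("at least 2 pairs are required")
  }
  stats::cor(predicted, observed, method = "kendall")
}
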