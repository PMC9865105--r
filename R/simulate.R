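## Seeded synthetic-data generator. Produces replicate-structured
## dose-response datasets from any model in the framework, emulating the
## shape of normalized degradation and biomarker assays: log-spaced
## concentration series, a few replicates, additive Gaussian noise on the
## fraction scale (sd 0.05 by default), readings truncated to [0, 1.2].

#' Define a synthetic data-generating truth
#'
#' @param model One of `"mechanistic"`, `"hook"`, `"extended_hook"`,
#'   `"pd"`.
#' @param params The generating parameter object: [mechanistic_params()],
#'   [hook_params()], [extended_hook_params()], or for `"pd"` a list with
#'   elements `pd` ([pd_params()]) and `degradation` (hook or extended
#'   hook parameters).
#' @param concentrations Concentration grid, nM.
#' @param times Incubation time(s), h.
#' @param replicates Replicates per design point.
#' @param noise_sd Additive Gaussian noise sd on the fraction scale
#'   (default 0.05; 0 gives exact model output).
#' @param noise_cv Alternative multiplicative noise: coefficient of
#'   variation applied to the model value (used when `noise_sd` is NULL).
#' @param seed Integer seed; fully determines the simulated dataset.
#' @param compound Compound label for the records.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(model = c("mechanistic", "hook",
                                      "extended_hook", "pd"),
                            params, concentrations, times = 24,
                            replicates = 3L, noise_sd = 0.05,
                            noise_cv = NULL, seed = 1L,
                            compound = "cpd") {
  model <- match.arg(model)
  expected <- switch(model,
    mechanistic = "mechanistic_params",
    hook = "hook_params",
    extended_hook = "extended_hook_params",
    pd = NULL)
  if (!is.null(expected) && !inherits(params, expected)) {
    stop_protac(sprintf("'params' must be a %s object for model '%s'",
                        expected, model))
  }
  if (model == "pd" && !(is.list(params) && inherits(params$pd, "pd_params"))) {
    stop_protac("for model 'pd', 'params' must be list(pd = , degradation = )")
  }
  if (!is.null(noise_sd)) check_scalar(noise_sd, "noise_sd", lower = 0)
  if (!is.null(noise_cv)) check_scalar(noise_cv, "noise_cv", lower = 0)
  if (any(concentrations < 0)) stop_protac("concentrations must be >= 0")
  if (any(times <= 0)) stop_protac("times must be positive")
  structure(list(model = model, params = params,
                 concentrations = concentrations, times = times,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 noise_cv = noise_cv, seed = as.integer(seed),
                 compound = compound),
            class = "synthetic_truth")
}

## Noise-free model surface over the (concentration, time) design.
truth_response <- function(truth, conc, time) {
  switch(truth$model,
    mechanistic = 1 - degradation_time_course(conc, time, truth$params),
    hook = 1 - hook_degradation(conc, truth$params),
    extended_hook = 1 - extended_hook(conc, time, truth$params),
    pd = {
      dp <- truth$params$degradation
      d <- if (inherits(dp, "extended_hook_params")) {
        extended_hook(conc, time, dp)
      } else {
        hook_degradation(conc, dp)
      }
      pd <- truth$params$pd
      i <- if (is.null(pd$ic50)) 0 else
        inhibition_from_ic50(conc, pd$ic50, pd$p50)
      pd_response(target_modulation(d, i), pd)
    })
}

#' Simulate a dose-response dataset from a synthetic truth
#'
#' Responses are the model prediction plus seeded noise, truncated to
#' `[0, 1.2]`. Zero noise returns the model surface exactly; an identical
#' seed reproduces the dataset bit-for-bit.
#'
#' @param truth A [synthetic_truth()] object.
#' @return A `dose_response` data.frame with one row per
#'   concentration x time x replicate.
#' @examples
#' tr <- synthetic_truth("hook", hook_params(0.949, 0.29, 68.9),
#'                       concentrations = 10^seq(-2, 3, length.out = 10),
#'                       times = 6, noise_sd = 0, seed = 7)
#' head(simulate_dataset(tr))
#' @export
simulate_dataset <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  design <- expand.grid(replicate = seq_len(truth$replicates),
                        conc_nM = truth$concentrations,
                        time_h = truth$times,
                        KEEP.OUT.ATTRS = FALSE)
  mu <- truth_response(truth, design$conc_nM, design$time_h)
  noise <- with_preserved_seed(truth$seed, {
    n <- nrow(design)
    if (!is.null(truth$noise_sd)) {
      stats::rnorm(n, sd = truth$noise_sd)
    } else if (!is.null(truth$noise_cv)) {
      mu * stats::rnorm(n, sd = truth$noise_cv)
    } else {
      numeric(n)
    }
  })
  resp <- pmin(pmax(mu + noise, 0), 1.2)
  dose_response_dataset(
    compound = truth$compound, conc_nM = design$conc_nM,
    time_h = design$time_h, replicate = design$replicate,
    response = resp,
    readout = if (truth$model == "pd") "pd_response" else "protein_level")
}
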