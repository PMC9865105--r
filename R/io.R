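## Data exchange. The interchange format is a plain CSV matching how
## normalized degradation/biomarker readouts are typically tabulated:
## columns compound, conc_nM, time_h, replicate, response_pct, readout.
## Internally responses are fractions of baseline; percent appears only at
## the file boundary.

DR_READOUTS <- c("protein_level", "pd_response")

#' Construct a dose-response dataset
#'
#' Replicate-structured concentration-response records. Responses are
#' fractions of the untreated baseline (1 = no effect); readings slightly
#' above 1 (up to 1.2) are tolerated as assay noise.
#'
#' @param compound Compound identifier(s).
#' @param conc_nM PROTAC concentration(s), nM (>= 0).
#' @param time_h Incubation time(s), h (> 0).
#' @param replicate Replicate index(es).
#' @param response Relative response(s), fraction of baseline.
#' @param readout `"protein_level"` or `"pd_response"`.
#' @return A `data.frame` of class `dose_response`.
#' @export
dose_response_dataset <- function(compound, conc_nM, time_h, replicate,
                                  response, readout = "protein_level") {
  df <- data.frame(compound = as.character(compound), conc_nM = conc_nM,
                   time_h = time_h, replicate = as.integer(replicate),
                   response = response, readout = as.character(readout),
                   stringsAsFactors = FALSE)
  as_dose_response(df)
}

#' Validate and classify a data.frame as a dose-response dataset
#'
#' @param data A data.frame with columns `compound`, `conc_nM`, `time_h`,
#'   `replicate`, `response`, `readout`.
#' @return The validated `dose_response` data.frame.
#' @export
as_dose_response <- function(data) {
  required <- c("compound", "conc_nM", "time_h", "replicate", "response",
                "readout")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop_protac("missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(data$conc_nM) | data$conc_nM < 0)
  if (length(bad)) {
    stop_protac("negative or non-finite concentration in row(s): ",
                paste(bad, collapse = ", "))
  }
  bad <- which(!is.finite(data$time_h) | data$time_h <= 0)
  if (length(bad)) {
    stop_protac("non-positive incubation time in row(s): ",
                paste(bad, collapse = ", "))
  }
  bad <- which(!is.finite(data$response) | data$response < 0)
  if (length(bad)) {
    stop_protac("negative or non-finite response in row(s): ",
                paste(bad, collapse = ", "))
  }
  bad <- which(!data$readout %in% DR_READOUTS)
  if (length(bad)) {
    stop_protac("unknown readout kind in row(s) ",
                paste(bad, collapse = ", "), " (expected one of: ",
                paste(DR_READOUTS, collapse = ", "), ")")
  }
  class(data) <- c("dose_response", "data.frame")
  data
}

#' Read a dose-response CSV
#'
#' Expects header columns `compound, conc_nM, time_h, replicate,
#' response_pct, readout`; the percent-scale response column is converted
#' to fractions on read. Malformed rows are reported with their row
#' numbers.
#'
#' @param path Path to a CSV file.
#' @return A `dose_response` data.frame.
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop_protac("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"response_pct" %in% names(raw)) {
    stop_protac("missing required column(s): response_pct")
  }
  raw$response <- raw$response_pct / 100
  raw$response_pct <- NULL
  as_dose_response(raw)
}

#' Write a dose-response dataset to CSV
#'
#' Inverse of [read_dose_response()]: fractions are written on the percent
#' scale, and a write-then-read round trip reproduces the dataset.
#'
#' @param data A `dose_response` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(data, path) {
  data <- as_dose_response(data)
  out <- data.frame(compound = data$compound, conc_nM = data$conc_nM,
                    time_h = data$time_h, replicate = data$replicate,
                    response_pct = 100 * data$response,
                    readout = data$readout)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten a fit result to a key-value report
#'
#' Serializes a `protac_fit` (estimates, confidence bounds, RSS,
#' exclusions, seeds) to a flat named list suitable for JSON output.
#'
#' @param fit A `protac_fit`.
#' @return A named list of scalars/vectors.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "protac_fit"))
  rep <- list(model = fit$model, converged = fit$converged,
              n_obs = fit$n_obs, rss = fit$rss)
  for (p in names(fit$estimates)) rep[[p]] <- fit$estimates[[p]]
  if (!is.null(fit$ci)) {
    for (p in rownames(fit$ci)) {
      rep[[paste0(p, "_ci_lower")]] <- fit$ci[p, "lower"]
      rep[[paste0(p, "_ci_upper")]] <- fit$ci[p, "upper"]
    }
    rep$n_boot <- fit$n_boot
    rep$boot_seed <- fit$boot_seed
  }
  if (length(fit$excluded)) rep$excluded_rows <- fit$excluded
  if (!is.null(fit$note)) rep$note <- fit$note
  rep
}
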