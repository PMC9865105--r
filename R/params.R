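## Parameter containers for the degradation framework. All constructors
## validate their inputs once so downstream numerical code can assume sane
## values. Units are fixed package-wide: concentrations in nM, times in h,
## extents of degradation / engagement / inhibition as fractions in [0, 1].

#' Ternary-complex binding parameters
#'
#' Describes the PROTAC's two binary binding events and their cooperativity.
#' The dissociation constants refer to the PROTAC--target (POI) and
#' PROTAC--E3-ligase binary complexes; the cooperativity factor `alpha`
#' relates binary to ternary complex affinity (`alpha > 1`: the ternary
#' complex is stabilized relative to the binary complexes).
#'
#' @param kd_poi Dissociation constant of the PROTAC--POI binary complex (nM).
#' @param kd_e3 Dissociation constant of the PROTAC--E3 binary complex (nM).
#' @param alpha Cooperativity factor (dimensionless, > 0).
#' @return An object of class `ternary_binding`.
#' @examples
#' ternary_binding(kd_poi = 100, kd_e3 = 100, alpha = 10)
#' @export
ternary_binding <- function(kd_poi, kd_e3, alpha = 1) {
  check_scalar(kd_poi, "kd_poi", lower = 0, strict_lower = TRUE)
  check_scalar(kd_e3, "kd_e3", lower = 0, strict_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, strict_lower = TRUE)
  structure(list(kd_poi = kd_poi, kd_e3 = kd_e3, alpha = alpha),
            class = "ternary_binding")
}

#' Cellular system parameters
#'
#' The cellular context that determines how a given PROTAC performs:
#' expression level of the targeted E3 ligase and the baseline turnover
#' half-life of the target protein. The turnover rate constant
#' `kdeg_p = ln(2) / half_life` is derived on construction. The optional
#' baseline target-protein concentration `poi_total` is used only by the
#' exact (protein-level dependent) target-engagement solution.
#'
#' @param e3_total Total targeted E3 ligase concentration, nM.
#' @param half_life Baseline target-protein half-life, h.
#' @param poi_total Optional baseline total target protein concentration, nM.
#' @return An object of class `cell_system` with derived field `kdeg_p` (1/h).
#' @examples
#' cell_system(e3_total = 50, half_life = 45)
#' @export
cell_system <- function(e3_total, half_life, poi_total = NULL) {
  check_scalar(e3_total, "e3_total", lower = 0, strict_lower = TRUE)
  check_scalar(half_life, "half_life", lower = 0, strict_lower = TRUE)
  check_scalar(poi_total, "poi_total", lower = 0, strict_lower = TRUE,
               allow_null = TRUE)
  structure(list(e3_total = e3_total, half_life = half_life,
                 poi_total = poi_total, kdeg_p = log(2) / half_life),
            class = "cell_system")
}

#' Mechanistic degradation parameters (kcat model inputs)
#'
#' Bundles binding, cellular context, and the PROTAC-catalyzed degradation
#' rate constant `kcat` (h^-1, the rate of ubiquitination-limited target
#' destruction per unit of ternary-complex engagement).
#'
#' @param binding A [ternary_binding()] object.
#' @param cell A [cell_system()] object.
#' @param kcat Catalyzed degradation rate constant, h^-1 (>= 0).
#' @return An object of class `mechanistic_params`.
#' @export
mechanistic_params <- function(binding, cell, kcat) {
  stopifnot(inherits(binding, "ternary_binding"), inherits(cell, "cell_system"))
  check_scalar(kcat, "kcat", lower = 0)
  structure(list(binding = binding, cell = cell, kcat = kcat),
            class = "mechanistic_params")
}

#' Descriptive hook-model parameters
#'
#' The three parameters of the bell-shaped concentration-degradation curve:
#' maximal extent of degradation `dmax`, concentration of half-maximal
#' degradation `dc50`, and concentration of maximal degradation `dcmax`
#' (beyond which the hook effect sets in). Requires `dc50 < dcmax`.
#'
#' @param dmax Maximal extent of degradation, fraction in [0, 1).
#' @param dc50 Concentration of half-maximal degradation, nM.
#' @param dcmax Concentration of maximal degradation, nM (> dc50).
#' @return An object of class `hook_params`.
#' @examples
#' hook_params(dmax = 0.949, dc50 = 0.29, dcmax = 68.9)
#' @export
hook_params <- function(dmax, dc50, dcmax) {
  check_scalar(dmax, "dmax", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(dc50, "dc50", lower = 0, strict_lower = TRUE)
  check_scalar(dcmax, "dcmax", lower = 0, strict_lower = TRUE)
  if (dc50 >= dcmax) {
    stop_protac("'dc50' must be smaller than 'dcmax'")
  }
  structure(list(dmax = dmax, dc50 = dc50, dcmax = dcmax),
            class = "hook_params")
}

#' Time-resolved (extended) hook-model parameters
#'
#' Steady-state hook parameters plus the target-protein half-life that
#' governs how quickly the profile approaches steady state.
#'
#' @param hook A [hook_params()] object holding the steady-state values.
#' @param half_life Target-protein half-life, h.
#' @return An object of class `extended_hook_params`.
#' @export
extended_hook_params <- function(hook, half_life) {
  stopifnot(inherits(hook, "hook_params"))
  check_scalar(half_life, "half_life", lower = 0, strict_lower = TRUE)
  structure(list(hook = hook, half_life = half_life),
            class = "extended_hook_params")
}

#' Hyperbolic Emax-model parameters
#'
#' @param emax Maximal effect, fraction in [0, 1).
#' @param ec50 Concentration of half-maximal effect, nM.
#' @return An object of class `emax_params`.
#' @export
emax_params <- function(emax, ec50) {
  check_scalar(emax, "emax", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(ec50, "ec50", lower = 0, strict_lower = TRUE)
  structure(list(emax = emax, ec50 = ec50), class = "emax_params")
}

#' Downstream pharmacodynamic response parameters
#'
#' Parameters of the direct-response model linking target modulation to a
#' relative downstream PD readout: the target-independent response floor
#' `pd_min`, the remaining-protein level of half-maximal target-dependent
#' response `p50`, an empirical Hill coefficient `hill`, and (optionally)
#' the PROTAC concentration `ic50` that halves the baseline response by
#' inhibition alone, measured with a non-degrading control compound.
#'
#' The model requires `p50^hill <= 1/2` so its denominator stays positive
#' for all target-modulation values; the boundary case (e.g. `p50 = 0.5`,
#' `hill = 1`, where the response reduces to `1 - TM`) is allowed.
#'
#' @param p50 Relative protein level of half-maximal target-dependent
#'   response, fraction in (0, 1).
#' @param hill Empirical Hill coefficient (> 0).
#' @param pd_min Target-independent response floor, fraction in [0, 1).
#' @param ic50 Optional inhibitory potency, nM; `NULL` for PROTACs without
#'   inhibitory activity (e.g. scaffolding targets).
#' @return An object of class `pd_params`.
#' @examples
#' pd_params(p50 = 0.87, hill = 7)
#' @export
pd_params <- function(p50, hill = 1, pd_min = 0, ic50 = NULL) {
  check_scalar(p50, "p50", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(hill, "hill", lower = 0, strict_lower = TRUE)
  check_scalar(pd_min, "pd_min", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(ic50, "ic50", lower = 0, strict_lower = TRUE, allow_null = TRUE)
  if (p50^hill > 0.5 + 1e-12) {
    stop_protac(sprintf(
      "'p50^hill' must be <= 1/2 (got %.4g); lower p50 or raise hill",
      p50^hill
    ))
  }
  structure(list(p50 = p50, hill = hill, pd_min = pd_min, ic50 = ic50),
            class = "pd_params")
}

#' @export
print.ternary_binding <- function(x, ...) {
  cat(sprintf(
    "Ternary binding: KD,P = %g nM, KD,E = %g nM, alpha = %g\n",
    x$kd_poi, x$kd_e3, x$alpha
  ))
  invisible(x)
}

#' @export
print.cell_system <- function(x, ...) {
  cat(sprintf(
    "Cell system: E0 = %g nM, t1/2,P = %g h (kdeg,P = %.4g 1/h)%s\n",
    x$e3_total, x$half_life, x$kdeg_p,
    if (is.null(x$poi_total)) "" else sprintf(", P0 = %g nM", x$poi_total)
  ))
  invisible(x)
}

#' @export
print.mechanistic_params <- function(x, ...) {
  print(x$binding)
  print(x$cell)
  cat(sprintf("kcat = %g 1/h (TE50 = %.4g)\n", x$kcat,
              if (x$kcat > 0) x$cell$kdeg_p / x$kcat else NA_real_))
  invisible(x)
}

#' @export
print.hook_params <- function(x, ...) {
  cat(sprintf(
    "Hook parameters: Dmax = %.1f%%, DC50 = %g nM, DCmax = %g nM\n",
    100 * x$dmax, x$dc50, x$dcmax
  ))
  invisible(x)
}

#' @export
print.extended_hook_params <- function(x, ...) {
  cat("Extended hook (steady-state values):\n  ")
  print(x$hook)
  cat(sprintf("  t1/2,P = %g h\n", x$half_life))
  invisible(x)
}

#' @export
print.emax_params <- function(x, ...) {
  cat(sprintf("Emax parameters: Emax = %.1f%%, EC50 = %g nM\n",
              100 * x$emax, x$ec50))
  invisible(x)
}

#' @export
print.pd_params <- function(x, ...) {
  cat(sprintf(
    "PD parameters: P50 = %g, hill = %g, PDmin = %g%s\n",
    x$p50, x$hill, x$pd_min,
    if (is.null(x$ic50)) ", no inhibition" else sprintf(", IC50 = %g nM", x$ic50)
  ))
  invisible(x)
}
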