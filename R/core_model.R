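# Forward model: Langmuir adsorption coupled to the adsorption-limited
# peak-current conversion, and its inverses.

#' Equilibrium adsorbed moles (Langmuir isotherm)
#'
#' Amount of analyte bound at equilibrium to a finite pool of electrode sites:
#' `bound = C * eld / (K_D + C)`. Strictly increasing and concave in `C`,
#' saturating below `eld`.
#'
#' @param C Free analyte concentration \[M\] (vectorised).
#' @param params A [kinetic_params()] object (uses `K_D`).
#' @param eld Available binding sites \[mol\]; defaults to `params$ELD_tot`.
#' @return Adsorbed analyte \[mol\], same length as `C`.
#' @examples
#' p <- serotonin_cnt_params()
#' equilibrium_bound(7e-7, p)  # half saturation at C = K_D
#' @export
equilibrium_bound <- function(C, params, eld = params$ELD_tot) {
  .check_params(params)
  if (any(!is.finite(C)) || any(C < 0)) {
    stop("'C' must be a nonnegative concentration [M]", call. = FALSE)
  }
  if (any(!is.finite(eld)) || any(eld < 0)) {
    stop("'eld' must be a nonnegative number of moles", call. = FALSE)
  }
  C * eld / (params$K_D + C)
}

#' Time-dependent adsorbed moles under constant applied concentration
#'
#' Exponential approach to the Langmuir equilibrium during an accumulation
#' period at constant analyte concentration:
#' `bound(t) = bound_eq * (1 - exp(-(C*k_on + k_off) * t_acc))`.
#' This is the adsorption regime; see [desorption_at_time()] for the
#' zero-concentration regime.
#'
#' @inheritParams equilibrium_bound
#' @param t_acc Accumulation time \[s\] (vectorised with `C`).
#' @return Adsorbed analyte \[mol\].
#' @examples
#' p <- serotonin_cnt_params()
#' cfg <- electrochem_config(scan_rate = 0.4)
#' adsorption_at_time(1e-6, 1800, p)
#' @export
adsorption_at_time <- function(C, t_acc, params, eld = params$ELD_tot) {
  .check_params(params, need_rates = TRUE)
  if (any(!is.finite(t_acc)) || any(t_acc < 0)) {
    stop("'t_acc' must be a nonnegative time [s]", call. = FALSE)
  }
  eq <- equilibrium_bound(C, params, eld)
  lambda <- C * params$k_on + params$k_off
  eq * (1 - exp(-lambda * t_acc))
}

#' Desorption of bound analyte into analyte-free solution
#'
#' When the applied concentration is zero the bound pool decays
#' exponentially: `bound(t) = bound0 * exp(-k_off * t)`.
#'
#' @param bound0 Initially bound analyte \[mol\].
#' @param t Elapsed time \[s\].
#' @param params A [kinetic_params()] object (uses `k_off`).
#' @return Remaining bound analyte \[mol\].
#' @export
desorption_at_time <- function(bound0, t, params) {
  .check_params(params, need_rates = TRUE, need_KD = FALSE)
  if (any(!is.finite(bound0)) || any(bound0 < 0)) {
    stop("'bound0' must be nonnegative [mol]", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be a nonnegative time [s]", call. = FALSE)
  }
  bound0 * exp(-t * params$k_off)
}

#' Convert adsorbed moles to anodic peak current
#'
#' Adsorption-limited peak current: `Ipa = gain * n^2 F^2 / (4 R T) * nu *
#' bound`. Linear and homogeneous in both the bound amount and the scan rate.
#'
#' @param bound Adsorbed analyte \[mol\] (vectorised).
#' @param config An [electrochem_config()] object.
#' @return Anodic peak current \[A\].
#' @examples
#' cfg <- electrochem_config(scan_rate = 0.4)
#' bound_to_current(1e-11, cfg)  # ~1.5e-5 A
#' @export
bound_to_current <- function(bound, config) {
  .check_config(config)
  if (any(!is.finite(bound)) || any(bound < 0)) {
    stop("'bound' must be nonnegative [mol]", call. = FALSE)
  }
  config$gain * current_conversion_factor(config) * bound
}

#' Moles-to-amperes conversion factor
#'
#' `n^2 F^2 nu / (4 R T)` in A per mol, excluding the gain.
#'
#' @param config An [electrochem_config()] object.
#' @return Conversion factor \[A mol^-1\].
#' @export
current_conversion_factor <- function(config) {
  .check_config(config)
  config$n^2 * config$F^2 / (4 * config$R * config$temperature) *
    config$scan_rate
}

#' Convert anodic peak current to adsorbed moles
#'
#' Algebraic inverse of [bound_to_current()].
#'
#' @param Ipa Anodic peak current \[A\] (vectorised).
#' @param config An [electrochem_config()] object.
#' @return Adsorbed analyte \[mol\].
#' @export
current_to_bound <- function(Ipa, config) {
  .check_config(config)
  if (any(!is.finite(Ipa)) || any(Ipa < 0)) {
    stop("'Ipa' must be nonnegative [A]", call. = FALSE)
  }
  Ipa / (config$gain * current_conversion_factor(config))
}

#' Infer applied concentration from a measured peak current
#'
#' Inverts the full forward chain `C -> bound(t_acc) -> Ipa` by bracketed
#' root-finding on the strictly increasing map from concentration to current.
#' The map's supremum (all sites occupied) bounds the feasible signal; a
#' current at or above that ceiling raises an infeasible-signal error.
#'
#' @param Ipa Measured anodic peak current \[A\], scalar.
#' @param t_acc Accumulation time used for the measurement \[s\].
#' @param params A [kinetic_params()] object.
#' @param config An [electrochem_config()] object.
#' @param eld Available binding sites \[mol\]; defaults to `ELD_tot`.
#' @param bracket_upper Initial upper bracket for the search \[M\]; expanded
#'   on demand up to 1e3 M before failing.
#' @return Concentration \[M\].
#' @examples
#' p <- serotonin_cnt_params()
#' cfg <- electrochem_config(scan_rate = 0.4)
#' ipa <- bound_to_current(adsorption_at_time(1e-7, 1800, p), cfg)
#' concentration_from_current(ipa, 1800, p, cfg)  # 1e-7
#' @export
concentration_from_current <- function(Ipa, t_acc, params, config,
                                       eld = params$ELD_tot,
                                       bracket_upper = 1e-1) {
  .check_params(params, need_rates = TRUE)
  .check_config(config)
  if (length(Ipa) != 1 || !is.finite(Ipa) || Ipa < 0) {
    stop("'Ipa' must be a single nonnegative current [A]", call. = FALSE)
  }
  if (Ipa == 0) return(0)
  ceiling_A <- bound_to_current(eld, config)
  if (Ipa >= ceiling_A) {
    stop(sprintf(
      "infeasible signal: Ipa = %g A is at or above the attainable ceiling %g A (all %g mol sites occupied)",
      Ipa, ceiling_A, eld), call. = FALSE)
  }
  f <- function(C) bound_to_current(adsorption_at_time(C, t_acc, params, eld),
                                    config) - Ipa
  lo <- 1e-15
  hi <- bracket_upper
  while (f(hi) < 0 && hi < 1e3) hi <- hi * 10
  if (f(hi) < 0) {
    stop(sprintf(
      "infeasible signal: Ipa = %g A not attainable at t_acc = %g s within the search bracket",
      Ipa, t_acc), call. = FALSE)
  }
  while (f(lo) > 0 && lo > 1e-30) lo <- lo / 10
  # Root-find in log10(C) so the tolerance is relative across magnitudes.
  g <- function(u) f(10^u)
  u <- stats::uniroot(g, c(log10(lo), log10(hi)), tol = 1e-11)$root
  10^u
}
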