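# Simulators for the binding assays: ITC thermograms, fluorescence
# quench titrations (Hill form), and in-line probing saturation curves.

# Exact single-site ITC forward model with displaced-volume correction
# for a perfusion cell. Each injection of volume v into a cell of
# volume V0 dilutes existing contents by d = 1 - v/V0, so after i
# injections the macromolecule is M0 d^i and the titrant Xs (1 - d^i).
# Bound complex comes from the quadratic in total ligand / total sites /
# Kd; the observed heat of injection i is the change in cell heat
# content plus the average heat carried out in the displaced volume.
# All concentrations in molar, volumes in liters, dh in kcal/mol,
# heats in ucal.
#' @noRd
itc_injection_heats <- function(kd, dh, n_sites, cell_conc, syringe_conc,
                                n_injections, injection_volume, cell_volume,
                                dilution_heat = 0) {
  i <- seq_len(n_injections)
  d <- 1 - injection_volume / cell_volume
  Mt <- cell_conc * d^i
  Xt <- syringe_conc * (1 - d^i)
  sites <- n_sites * Mt
  b <- sites + Xt + kd
  ml <- (b - sqrt(b^2 - 4 * sites * Xt)) / 2
  Q <- dh * 1e9 * cell_volume * ml          # ucal of heat content
  Qprev <- c(0, Q[-n_injections])
  dQ <- Q - Qprev +
    (injection_volume / cell_volume) * (Q + Qprev) / 2 + dilution_heat
  list(heat = dQ, molar_ratio = Xt / Mt)
}

#' An ITC thermogram
#'
#' @param injection_index Integer injection numbers.
#' @param injection_volume Per-injection volume, microliters.
#' @param molar_ratio Cumulative titrant/macromolecule ratio,
#'   non-decreasing.
#' @param heat Heat per injection, microcalories (finite).
#' @param cell_conc,syringe_conc Concentrations in micromolar.
#' @param temperature Kelvin.
#' @param cell_volume Cell volume in milliliters.
#' @return An object of class `thermogram` (a data frame with metadata
#'   attributes).
#' @export
thermogram <- function(injection_index, injection_volume, molar_ratio, heat,
                       cell_conc, syringe_conc, temperature,
                       cell_volume = 1.4195) {
  if (any(diff(molar_ratio) < 0)) {
    abort_invalid("`molar_ratio` must be non-decreasing")
  }
  if (any(!is.finite(heat))) abort_invalid("heats must be finite")
  check_number(cell_conc, "cell_conc", positive = TRUE)
  check_number(syringe_conc, "syringe_conc", positive = TRUE)
  check_number(temperature, "temperature", positive = TRUE)
  out <- data.frame(
    injection_index = as.integer(injection_index),
    injection_volume = injection_volume,
    molar_ratio = molar_ratio, heat = heat
  )
  attr(out, "cell_conc") <- cell_conc
  attr(out, "syringe_conc") <- syringe_conc
  attr(out, "temperature") <- temperature
  attr(out, "cell_volume") <- cell_volume
  class(out) <- c("thermogram", "data.frame")
  out
}

#' Simulate a one-site ITC thermogram
#'
#' Defaults follow the published protocol: 26 injections at 30 C
#' (303.15 K) on a perfusion-cell instrument. The model is the exact
#' single-site quadratic with displaced-volume correction and a
#' constant per-injection heat of dilution.
#'
#' @param kd Dissociation constant, molar (> 0). Alternatively supply
#'   `ka` (association constant, 1/M).
#' @param ka Association constant, 1/M; overrides `kd` when given.
#' @param dh Binding enthalpy, kcal/mol (negative = exothermic).
#' @param n_sites Stoichiometry (sites per macromolecule).
#' @param cell_conc Macromolecule concentration in the cell, micromolar.
#' @param syringe_conc Titrant concentration in the syringe, micromolar.
#' @param n_injections Number of injections.
#' @param injection_volume Per-injection volume, microliters.
#' @param cell_volume Cell volume, milliliters (VP-ITC default 1.4195).
#' @param temperature Kelvin (default 303.15, i.e. 30 C).
#' @param dilution_heat Constant heat of dilution per injection, ucal.
#' @param noise_sd Gaussian noise s.d. on per-injection heats, ucal.
#' @param seed Seed for the noise generator, or `NULL`.
#' @return A [thermogram()].
#' @examples
#' tg <- simulate_itc(ka = 4.12e6, dh = -8, cell_conc = 10,
#'                    syringe_conc = 130)
#' @export
simulate_itc <- function(kd = NULL, ka = NULL, dh, n_sites = 1,
                         cell_conc, syringe_conc, n_injections = 26,
                         injection_volume = 10, cell_volume = 1.4195,
                         temperature = 303.15, dilution_heat = 0,
                         noise_sd = 0, seed = NULL) {
  if (!is.null(ka)) {
    check_number(ka, "ka", positive = TRUE)
    kd <- 1 / ka
  }
  check_number(kd, "kd", positive = TRUE)
  check_number(dh, "dh")
  check_number(n_sites, "n_sites", positive = TRUE)
  check_number(cell_conc, "cell_conc", positive = TRUE)
  check_number(syringe_conc, "syringe_conc", positive = TRUE)
  check_number(injection_volume, "injection_volume", positive = TRUE)
  check_number(cell_volume, "cell_volume", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  sim <- itc_injection_heats(
    kd = kd, dh = dh, n_sites = n_sites,
    cell_conc = cell_conc * 1e-6, syringe_conc = syringe_conc * 1e-6,
    n_injections = n_injections,
    injection_volume = injection_volume * 1e-6,
    cell_volume = cell_volume * 1e-3,
    dilution_heat = dilution_heat
  )
  heat <- sim$heat
  if (noise_sd > 0) {
    heat <- heat + with_local_seed(seed, stats::rnorm(n_injections, 0, noise_sd))
  }
  thermogram(seq_len(n_injections), injection_volume, sim$molar_ratio, heat,
             cell_conc, syringe_conc, temperature, cell_volume)
}

#' A dose-response titration curve
#'
#' @param ligand_conc Ligand concentrations, molar (> 0).
#' @param response Fluorescence fraction bound or cleavage fraction.
#' @param replicate_id Replicate label.
#' @return An object of class `titration_curve` (a data frame).
#' @export
titration_curve <- function(ligand_conc, response, replicate_id = 1L) {
  if (any(ligand_conc <= 0)) abort_invalid("`ligand_conc` must be > 0")
  out <- data.frame(ligand_conc = ligand_conc, response = response,
                    replicate_id = replicate_id)
  class(out) <- c("titration_curve", "data.frame")
  out
}

#' Simulate a fluorescence-quench titration (Hill form)
#'
#' Fraction bound follows `Y = X^h / (kd^h + X^h)` with the maximum
#' fixed at 1, as used for quench titrations normalized by
#' [fraction_bound()].
#'
#' @param kd Midpoint concentration, molar (> 0).
#' @param hill_h Hill slope (> 0).
#' @param conc Concentration grid, molar; default 24 log-spaced points
#'   spanning `kd / 100` to `kd * 100`.
#' @param noise_sd Gaussian noise s.d. on the response.
#' @param seed Seed or `NULL`.
#' @return A [titration_curve()].
#' @export
simulate_quench <- function(kd, hill_h = 1, conc = NULL, noise_sd = 0,
                            seed = NULL) {
  check_number(kd, "kd", positive = TRUE)
  check_number(hill_h, "hill_h", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (is.null(conc)) {
    conc <- exp(seq(log(kd / 100), log(kd * 100), length.out = 24))
  }
  y <- conc^hill_h / (kd^hill_h + conc^hill_h)
  if (noise_sd > 0) {
    y <- y + with_local_seed(seed, stats::rnorm(length(conc), 0, noise_sd))
  }
  titration_curve(conc, y)
}

#' Simulate paired in-line probing titrations (oxidized vs reduced)
#'
#' One-site saturation curves for the oxidized (FAD) and reduced
#' (FADH2) ligand sharing a single maximal response, as used when band
#' intensities rather than a normalized fraction are fit.
#'
#' @param kd_ox Kd for the oxidized ligand, molar.
#' @param kd_red Kd for the reduced ligand, molar; `Inf` gives a flat
#'   (non-binder) curve.
#' @param shared_bmax Shared maximal response.
#' @param conc Concentration grid, molar; default log-spaced around
#'   `kd_ox`.
#' @param noise_sd Gaussian noise s.d.
#' @param seed Seed or `NULL`.
#' @return List with elements `ox` and `red`, each a [titration_curve()].
#' @export
simulate_inline_probing <- function(kd_ox, kd_red, shared_bmax = 1,
                                    conc = NULL, noise_sd = 0, seed = NULL) {
  check_number(kd_ox, "kd_ox", positive = TRUE)
  if (!identical(kd_red, Inf)) check_number(kd_red, "kd_red", positive = TRUE)
  check_number(shared_bmax, "shared_bmax", positive = TRUE)
  if (is.null(conc)) {
    conc <- exp(seq(log(kd_ox / 50), log(kd_ox * 200), length.out = 16))
  }
  y_ox <- shared_bmax * conc / (kd_ox + conc)
  y_red <- if (identical(kd_red, Inf)) rep(0, length(conc)) else
    shared_bmax * conc / (kd_red + conc)
  if (noise_sd > 0) {
    noise <- with_local_seed(seed, stats::rnorm(2 * length(conc), 0, noise_sd))
    y_ox <- y_ox + noise[seq_along(conc)]
    y_red <- y_red + noise[length(conc) + seq_along(conc)]
  }
  list(ox = titration_curve(conc, y_ox, "ox"),
       red = titration_curve(conc, y_red, "red"))
}
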