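# Nernst and thermodynamic-cycle relations shared by the assay
# simulator and the Em-inference pipeline.
#
# Sign conventions used throughout the package:
#   * potentials are millivolts vs the standard hydrogen electrode (SHE);
#   * the Nernst equation for the couple Ox + n e- -> Red is
#       E = Em + (RT/nF) ln([Ox]/[Red]),
#     so (RT/nF) ln(ox/red) = E - Em is the "Nernst term" of a species;
#   * preferential binding of the oxidized form (Kd_red > Kd_ox) makes
#     the bound couple harder to reduce and shifts Em negative:
#       dEm = -(RT/nF) ln(Kd_red / Kd_ox).

#' Assay thermodynamic conditions
#'
#' Bundles the temperature and electron count entering the Nernst
#' prefactor RT/nF. Flavin oxidation/reduction in these assays is the
#' two-electron conversion between the oxidized quinone and the fully
#' reduced hydroquinone (no semiquinone accumulates), so `n_electrons`
#' defaults to 2. The default temperature of 295 K corresponds to the
#' room-temperature equilibration assay; note that a prefactor of
#' 12.5 mV (the constant conventionally printed on Nernst-plot axes)
#' corresponds to roughly 290 K at n = 2.
#'
#' @param temperature Temperature in kelvin (> 0).
#' @param n_electrons Electrons transferred per redox event (1 or 2).
#' @return An object of class `thermo_conditions`.
#' @examples
#' cond <- thermo_conditions()          # 295 K, 2-electron couple
#' nernst_prefactor(cond)               # ~12.7 mV
#' nernst_prefactor(thermo_conditions(290))  # ~12.5 mV
#' @export
thermo_conditions <- function(temperature = 295, n_electrons = 2) {
  check_number(temperature, "temperature", positive = TRUE)
  if (!is.numeric(n_electrons) || length(n_electrons) != 1L ||
      !(n_electrons %in% c(1, 2))) {
    abort_invalid("`n_electrons` must be 1 or 2")
  }
  structure(
    list(temperature = temperature, n_electrons = as.integer(n_electrons)),
    class = "thermo_conditions"
  )
}

#' A redox couple with a known midpoint potential
#'
#' @param name Label for the couple (e.g. `"FAD"`, `"AQS"`).
#' @param e_m Midpoint reduction potential in mV vs SHE.
#' @param n_electrons Electrons transferred (>= 1).
#' @return An object of class `redox_couple`.
#' @seealso [reference_dye()] for the bundled indicator dyes.
#' @export
redox_couple <- function(name, e_m, n_electrons = 2) {
  stopifnot(is.character(name), length(name) == 1L)
  check_number(e_m, "e_m")
  check_number(n_electrons, "n_electrons", positive = TRUE)
  structure(
    list(name = name, e_m = e_m, n_electrons = as.integer(n_electrons)),
    class = "redox_couple"
  )
}

#' Bundled reference indicator dyes
#'
#' The equilibration assay co-reduces the flavin with an indicator dye of
#' known potential: anthraquinone-2-sulfonate (AQS, Em = -225 mV) or
#' phenosafranin (PSF, Em = -252 mV), both two-electron couples.
#'
#' @param name `"AQS"` or `"PSF"`.
#' @return A [redox_couple()].
#' @export
reference_dye <- function(name = c("AQS", "PSF")) {
  name <- match.arg(name)
  switch(name,
    AQS = redox_couple("AQS", -225, 2),
    PSF = redox_couple("PSF", -252, 2)
  )
}

#' Oxidized/reduced dissociation-constant pair
#'
#' Affinity of an aptamer for the oxidized and the reduced form of its
#' ligand, the quantity that bridges binding and redox worlds: the free
#' energy of the cycle free-ox -> bound-ox -> bound-red -> free-red
#' must close, so any imbalance between `kd_ox` and `kd_red` shifts the
#' midpoint potential of the bound ligand (see [delta_em_from_kd()]).
#'
#' @param kd_ox,kd_red Dissociation constants (molar, > 0) for the
#'   oxidized and reduced ligand.
#' @return An object of class `binding_pair`.
#' @export
binding_pair <- function(kd_ox, kd_red) {
  check_number(kd_ox, "kd_ox", positive = TRUE)
  check_number(kd_red, "kd_red", positive = TRUE)
  structure(list(kd_ox = kd_ox, kd_red = kd_red), class = "binding_pair")
}

#' Nernst prefactor RT/nF in millivolts
#'
#' @param cond A [thermo_conditions()].
#' @return RT/nF in mV. At 290 K and n = 2 this is the 12.5 mV constant
#'   conventionally used on Nernst-plot axes.
#' @export
nernst_prefactor <- function(cond = thermo_conditions()) {
  stopifnot(inherits(cond, "thermo_conditions"))
  1000 * .R_GAS * cond$temperature / (cond$n_electrons * .FARADAY)
}

#' Kd ratio implied by a midpoint-potential shift
#'
#' Thermodynamic cycle: a shift `delta_em` of the bound ligand's
#' midpoint potential relative to free implies
#' `Kd_red / Kd_ox = exp(-delta_em / (RT/nF))`. A negative shift
#' (harder to reduce when bound) means the oxidized form is bound more
#' tightly (ratio > 1).
#'
#' @param delta_em Em(bound) - Em(free) in mV.
#' @param cond A [thermo_conditions()].
#' @return Dimensionless ratio Kd_red / Kd_ox.
#' @examples
#' kd_ratio_from_delta_em(-40)  # ~23-fold preference for the oxidized form
#' @export
kd_ratio_from_delta_em <- function(delta_em, cond = thermo_conditions()) {
  check_number(delta_em, "delta_em")
  exp(-delta_em / nernst_prefactor(cond))
}

#' Midpoint-potential shift implied by differential binding
#'
#' Inverse of [kd_ratio_from_delta_em()]:
#' `delta_em = -(RT/nF) ln(Kd_red / Kd_ox)`.
#'
#' @param pair A [binding_pair()].
#' @param cond A [thermo_conditions()].
#' @return Em shift in mV (negative when the oxidized form binds tighter).
#' @export
delta_em_from_kd <- function(pair, cond = thermo_conditions()) {
  stopifnot(inherits(pair, "binding_pair"))
  -nernst_prefactor(cond) * log(pair$kd_red / pair$kd_ox)
}

#' Midpoint potential of the bound couple
#'
#' @param em_free Em of the free ligand, mV vs SHE.
#' @param pair A [binding_pair()].
#' @param cond A [thermo_conditions()].
#' @return `em_free + delta_em_from_kd(pair, cond)` in mV.
#' @export
em_bound <- function(em_free, pair, cond = thermo_conditions()) {
  check_number(em_free, "em_free")
  em_free + delta_em_from_kd(pair, cond)
}

#' Gibbs free energy of reduction from a midpoint potential
#'
#' @param couple A [redox_couple()].
#' @return `-n F Em` in J mol^-1 (Em converted to volts internally).
#'   More negative potentials give more positive reduction free energies.
#' @export
gibbs_from_em <- function(couple) {
  stopifnot(inherits(couple, "redox_couple"))
  -couple$n_electrons * .FARADAY * couple$e_m / 1000
}

#' Equilibrium reduced fraction of a couple at a solution potential
#'
#' @param E Solution potential, mV vs SHE. Vectorised.
#' @param couple A [redox_couple()] (supplies Em and n).
#' @param cond A [thermo_conditions()] (supplies the temperature).
#' @return `1 / (1 + exp((E - Em) / (RT/nF)))`, in (0, 1), strictly
#'   decreasing in `E` and exactly 0.5 at `E = Em`.
#' @export
fraction_reduced_at_potential <- function(E, couple,
                                          cond = thermo_conditions()) {
  stopifnot(inherits(couple, "redox_couple"), is.numeric(E))
  pref <- nernst_prefactor(
    thermo_conditions(cond$temperature, couple$n_electrons)
  )
  1 / (1 + exp((E - couple$e_m) / pref))
}

#' @export
print.redox_couple <- function(x, ...) {
  cat(sprintf("<redox_couple> %s: Em = %.1f mV vs SHE (n = %d)\n",
              x$name, x$e_m, x$n_electrons))
  invisible(x)
}

#' @export
print.binding_pair <- function(x, ...) {
  cat(sprintf("<binding_pair> Kd_ox = %.3g M, Kd_red = %.3g M (ratio %.3g)\n",
              x$kd_ox, x$kd_red, x$kd_red / x$kd_ox))
  invisible(x)
}
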