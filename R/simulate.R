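# Forward simulator of the xanthine-oxidase dual-indicator
# equilibration assay.
#
# Electrons generated by xanthine oxidation are delivered slowly enough
# that the flavin and the reference dye stay mutually equilibrated: at
# every timepoint there is a single solution potential E at which the
# summed reduced equivalents of all couples equal the equivalents
# delivered so far. The mediator (methyl viologen, Em ~ -446 mV) is far
# below both indicators and is treated as kinetically instantaneous and
# spectrally silent; the glucose/glucose-oxidase/catalase oxygen scrub
# is assumed perfect.

#' A redox-active species in the equilibration assay
#'
#' @param couple A [redox_couple()].
#' @param concentration Concentration in micromolar (> 0); the assay
#'   convention is 20 uM each for flavin and dye.
#' @param basis A [basis_spectrum()] giving its oxidized/reduced
#'   absorptivities.
#' @param role `"flavin"` or `"reference_dye"`.
#' @return An object of class `assay_species`.
#' @export
assay_species <- function(couple, concentration, basis,
                          role = c("flavin", "reference_dye")) {
  stopifnot(inherits(couple, "redox_couple"), inherits(basis, "basis_spectrum"))
  role <- match.arg(role)
  check_number(concentration, "concentration", positive = TRUE)
  structure(
    list(couple = couple, concentration = concentration, basis = basis,
         role = role),
    class = "assay_species"
  )
}

#' Configuration of a simulated equilibration assay
#'
#' Defaults encode the published assay conditions: 20 uM flavin and
#' 20 uM reference dye reduced by the xanthine/xanthine-oxidase system
#' (700 uM xanthine x 2 electrons = 1400 uM-equivalents of capacity, far
#' above the 80 uM-equivalents the two indicators can accept), spectra
#' collected every minute for up to 180 min. Electron delivery is
#' modeled as pseudo-zero-order; the default rate (0.8 uM-equivalents
#' per minute) fully reduces both couples within the 120-180 min window.
#'
#' @param species List of [assay_species()]; exactly one `"flavin"` and
#'   one `"reference_dye"`.
#' @param electron_capacity Total deliverable reducing equivalents
#'   (uM-equivalents); default 1400 from 700 uM xanthine.
#' @param delivery_rate uM-equivalents per minute (> 0).
#' @param timepoints Minutes, strictly increasing; default 0-180 every 1.
#' @param noise_sd Gaussian absorbance noise s.d. (AU, >= 0).
#' @param seed Integer seed for the noise generator, or `NULL`.
#' @param conditions A [thermo_conditions()].
#' @param isosbestic_map Optional named list/vector mapping a role to the
#'   wavelength (nm, on the grid) at which that species is isosbestic.
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(species, electron_capacity = 1400,
                         delivery_rate = 0.8, timepoints = 0:180,
                         noise_sd = 0, seed = NULL,
                         conditions = thermo_conditions(),
                         isosbestic_map = NULL) {
  if (!is.list(species) || !all(vapply(species, inherits, TRUE, "assay_species"))) {
    abort_invalid("`species` must be a list of assay_species objects")
  }
  roles <- vapply(species, `[[`, "", "role")
  if (sum(roles == "flavin") != 1L || sum(roles == "reference_dye") != 1L) {
    abort_invalid("need exactly one flavin and one reference_dye species")
  }
  check_number(electron_capacity, "electron_capacity", positive = TRUE)
  check_number(delivery_rate, "delivery_rate", nonneg = TRUE)
  if (length(timepoints) < 1L || any(diff(timepoints) <= 0)) {
    abort_invalid("`timepoints` must be strictly increasing")
  }
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  grid <- species[[1]]$basis$wavelengths
  for (sp in species) {
    if (!identical(sp$basis$wavelengths, grid)) {
      abort_invalid("all species must share one wavelength grid")
    }
  }
  if (!is.null(isosbestic_map)) {
    bad <- setdiff(unlist(isosbestic_map), grid)
    if (length(bad)) {
      abort_invalid(sprintf("isosbestic_map wavelength(s) off-grid: %s",
                            paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(species = species, electron_capacity = electron_capacity,
         delivery_rate = delivery_rate, timepoints = as.numeric(timepoints),
         noise_sd = noise_sd, seed = seed, conditions = conditions,
         isosbestic_map = isosbestic_map),
    class = "assay_config"
  )
}

#' Cumulative reducing equivalents delivered by each timepoint
#'
#' Pseudo-zero-order delivery capped at the donor capacity:
#' `delivered(t) = min(rate * t, capacity)`.
#'
#' @param config An [assay_config()].
#' @return Numeric vector of uM-equivalents, one per timepoint.
#' @export
electron_schedule <- function(config) {
  stopifnot(inherits(config, "assay_config"))
  pmin(config$delivery_rate * config$timepoints, config$electron_capacity)
}

#' Partition delivered electrons among couples at a shared potential
#'
#' Solves, by bisection, for the unique solution potential E at which
#' `sum_i c_i n_i f_red_i(E)` equals the delivered equivalents, then
#' returns each couple's reduced fraction at that potential. The
#' residual tolerance is 1e-9 uM-equivalents.
#'
#' @param delivered Delivered uM-equivalents (scalar, >= 0). Values
#'   above the total acceptor capacity are clamped with a warning.
#' @param species List of [assay_species()].
#' @param cond A [thermo_conditions()] (temperature source).
#' @return List with `potential` (mV; `Inf`/`-Inf` at the fully oxidized
#'   / fully reduced endpoints) and `f_red` (named by species role).
#' @export
partition_electrons <- function(delivered, species,
                                cond = thermo_conditions()) {
  check_number(delivered, "delivered", nonneg = TRUE)
  caps <- vapply(species, function(sp) sp$concentration * sp$couple$n_electrons,
                 0)
  roles <- vapply(species, `[[`, "", "role")
  total <- sum(caps)
  if (delivered > total + 1e-9) {
    warning(sprintf(
      "delivered equivalents (%g) exceed acceptor capacity (%g); clamping",
      delivered, total
    ))
    delivered <- total
  }
  f_at <- function(E) {
    vapply(species, function(sp) {
      fraction_reduced_at_potential(E, sp$couple, cond)
    }, 0)
  }
  if (delivered <= 0) {
    return(list(potential = Inf, f_red = stats::setNames(rep(0, length(species)), roles)))
  }
  if (delivered >= total) {
    return(list(potential = -Inf, f_red = stats::setNames(rep(1, length(species)), roles)))
  }
  ems <- vapply(species, function(sp) sp$couple$e_m, 0)
  prefs <- vapply(species, function(sp) {
    nernst_prefactor(thermo_conditions(cond$temperature, sp$couple$n_electrons))
  }, 0)
  lo <- min(ems) - 45 * max(prefs)  # essentially fully reduced
  hi <- max(ems) + 45 * max(prefs)  # essentially fully oxidized
  resid <- function(E) sum(caps * f_at(E)) - delivered
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    r <- resid(mid)
    if (abs(r) < 1e-9 || (hi - lo) < 1e-12) break
    if (r > 0) lo <- mid else hi <- mid  # resid decreasing in E
  }
  list(potential = mid, f_red = stats::setNames(f_at(mid), roles))
}

#' Simulate a dual-indicator equilibration assay
#'
#' For each timepoint, partitions the delivered electrons among the
#' couples at a shared solution potential and composes the absorbance
#' spectrum `A(lambda) = sum_i c_i (f_ox_i eps_ox_i + f_red_i eps_red_i)`
#' (1 cm path), plus optional seeded Gaussian noise. The first frame is
#' fully oxidized; once delivery reaches the acceptor capacity the
#' frames are fully reduced.
#'
#' @param config An [assay_config()].
#' @return An object of class `time_series_spectra` with fields `times`
#'   (minutes), `wavelengths` (nm), `absorbance` (time x wavelength
#'   matrix), `f_red` (time x species matrix of true reduced fractions,
#'   for oracle use), `potential` (mV per timepoint) and `provenance`.
#' @export
simulate_assay <- function(config) {
  stopifnot(inherits(config, "assay_config"))
  delivered <- electron_schedule(config)
  # The xanthine donor capacity (1400 uM-eq) far exceeds what the two
  # indicators can accept (~80 uM-eq); saturation is the designed
  # endpoint, so clamp silently here rather than through the
  # partition_electrons misuse warning.
  acceptor_cap <- sum(vapply(config$species, function(sp) {
    sp$concentration * sp$couple$n_electrons
  }, 0))
  delivered <- pmin(delivered, acceptor_cap)
  nw <- length(config$species[[1]]$basis$wavelengths)
  nt <- length(config$timepoints)
  A <- matrix(0, nt, nw)
  f_red <- matrix(0, nt, length(config$species))
  colnames(f_red) <- vapply(config$species, `[[`, "", "role")
  potential <- numeric(nt)
  for (i in seq_len(nt)) {
    part <- partition_electrons(delivered[i], config$species, config$conditions)
    potential[i] <- part$potential
    f_red[i, ] <- part$f_red
    for (k in seq_along(config$species)) {
      sp <- config$species[[k]]
      A[i, ] <- A[i, ] + sp$concentration *
        ((1 - part$f_red[k]) * sp$basis$eps_ox + part$f_red[k] * sp$basis$eps_red)
    }
  }
  if (config$noise_sd > 0) {
    A <- A + with_local_seed(
      config$seed,
      matrix(stats::rnorm(nt * nw, 0, config$noise_sd), nt, nw)
    )
  }
  time_series_spectra(
    times = config$timepoints,
    wavelengths = config$species[[1]]$basis$wavelengths,
    absorbance = A,
    provenance = list(config = config, seed = config$seed,
                      config_hash = config_hash(serialize_config(config))),
    f_red = f_red, potential = potential
  )
}

#' Time-resolved absorbance spectra
#'
#' The raw object of the equilibration assay: an absorbance matrix with
#' a time axis in minutes and a wavelength axis in nm.
#'
#' @param times Minutes, strictly increasing.
#' @param wavelengths nm, strictly increasing.
#' @param absorbance `length(times)` x `length(wavelengths)` matrix.
#' @param provenance Optional list describing how the data were made.
#' @param f_red,potential Optional simulator ground truth (reduced
#'   fractions and solution potential per timepoint).
#' @return An object of class `time_series_spectra`.
#' @export
time_series_spectra <- function(times, wavelengths, absorbance,
                                provenance = NULL, f_red = NULL,
                                potential = NULL) {
  if (any(diff(times) <= 0)) abort_invalid("`times` must be strictly increasing")
  if (any(diff(wavelengths) <= 0)) {
    abort_invalid("`wavelengths` must be strictly increasing")
  }
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) != length(times) ||
      ncol(absorbance) != length(wavelengths)) {
    abort_invalid(sprintf(
      "absorbance matrix is %d x %d but axes are %d times x %d wavelengths",
      nrow(absorbance), ncol(absorbance), length(times), length(wavelengths)
    ))
  }
  if (any(!is.finite(absorbance))) {
    abort_invalid("absorbance values must all be finite")
  }
  structure(
    list(times = as.numeric(times), wavelengths = as.numeric(wavelengths),
         absorbance = absorbance, provenance = provenance, f_red = f_red,
         potential = potential),
    class = "time_series_spectra"
  )
}

# Flatten an assay_config into plain lists for hashing / JSON sidecars.
#' @noRd
serialize_config <- function(config) {
  list(
    species = lapply(config$species, function(sp) {
      list(name = sp$couple$name, e_m = sp$couple$e_m,
           n_electrons = sp$couple$n_electrons,
           concentration = sp$concentration, role = sp$role,
           isosbestic = sp$basis$isosbestic)
    }),
    electron_capacity = config$electron_capacity,
    delivery_rate = config$delivery_rate,
    timepoints = range(config$timepoints),
    n_timepoints = length(config$timepoints),
    noise_sd = config$noise_sd,
    seed = config$seed,
    temperature = config$conditions$temperature,
    n_electrons = config$conditions$n_electrons,
    isosbestic_map = config$isosbestic_map
  )
}

#' @export
print.time_series_spectra <- function(x, ...) {
  cat(sprintf(
    "<time_series_spectra> %d frames (%g-%g min) x %d wavelengths (%g-%g nm)\n",
    length(x$times), min(x$times), max(x$times),
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)
  ))
  invisible(x)
}
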