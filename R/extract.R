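# Em inference from dual-indicator spectra:
# spectra -> oxidized-fraction traces (anchored at the fully-oxidized
# first frame and the fully-reduced plateau) -> Nernst terms
# (RT/nF) ln(ox/red) -> linear regression of the dye's terms on the
# flavin's -> Em of the flavin from the intercept and the dye's known
# potential.
#
# Axis convention: at a shared solution potential E each species'
# Nernst term equals E - Em of that species, so plotting the
# *reference dye* on y against the *flavin* on x gives an intercept
# b = Em(flavin) - Em(dye) (the y value where the flavin term crosses
# zero, i.e. at E = Em(flavin)), and Em(flavin) = Em(dye) + b.

#' Detect the fully-reduced plateau of a spectral time series
#'
#' Earliest frame from which the maximum absolute frame-to-frame change
#' stays below `tol` for `window` consecutive steps. If the series
#' never settles, the last frame is returned with a warning.
#'
#' @param ts A [time_series_spectra()].
#' @param tol Absorbance tolerance (AU) on frame-to-frame change. For
#'   noisy data use a few multiples of the noise s.d.
#' @param window Number of consecutive quiet steps required.
#' @return Frame index (1-based).
#' @export
detect_plateau <- function(ts, tol = 1e-3, window = 5) {
  stopifnot(inherits(ts, "time_series_spectra"))
  nt <- length(ts$times)
  if (nt < 2L) abort_invalid("need at least 2 timepoints")
  steps <- apply(abs(diff(ts$absorbance)), 1, max)  # change frame i -> i+1
  window <- min(window, length(steps))
  quiet <- steps < tol
  for (i in seq_len(length(steps) - window + 1L)) {
    if (all(quiet[i:(i + window - 1L)])) return(i)
  }
  warning("no plateau detected; falling back to the last frame")
  nt
}

#' Oxidized-fraction trace from an absorbance time series
#'
#' Anchors the absorbance at one wavelength between a fully-oxidized
#' frame (`t_ox`, by assay design the first measurement) and a
#' fully-reduced frame (`t_red`, the plateau):
#' `f_ox(t) = (A(t) - A(t_red)) / (A(t_ox) - A(t_red))`. Values are not
#' clipped; under noise they may fall slightly outside `[0, 1]`.
#'
#' @param ts A [time_series_spectra()], or a numeric absorbance vector
#'   over `ts$times` (e.g. a dye-subtracted trace) together with `ts`.
#' @param wavelength Measurement wavelength in nm (must be on the grid);
#'   by the isosbestic-point convention this is the *other* species'
#'   isosbestic wavelength, so the trace reports on one species only.
#' @param t_ox,t_red Anchor frame indices (default first frame and
#'   [detect_plateau()]).
#' @param role Species the trace reports on (annotation only).
#' @param band_halfwidth Optional half-width in nm for band-averaging
#'   around `wavelength` (0 = single wavelength, the assay convention).
#' @param trace Optional pre-extracted absorbance vector overriding the
#'   wavelength lookup (used after dye subtraction).
#' @return An object of class `fraction_trace` with fields `times`,
#'   `fraction_oxidized`, `species_role`, `wavelength_used`.
#' @export
fraction_oxidized_trace <- function(ts, wavelength, t_ox = 1L, t_red = NULL,
                                    role = "flavin", band_halfwidth = 0,
                                    trace = NULL) {
  stopifnot(inherits(ts, "time_series_spectra"))
  if (is.null(trace)) {
    trace <- absorbance_at(ts, wavelength, band_halfwidth)
  } else if (length(trace) != length(ts$times)) {
    abort_invalid("`trace` must have one value per timepoint")
  }
  if (is.null(t_red)) t_red <- detect_plateau(ts)
  a_ox <- trace[t_ox]
  a_red <- trace[t_red]
  if (abs(a_ox - a_red) < 1e-8) {
    abort_invalid(sprintf(
      "degenerate anchors at %g nm: |A(t_ox) - A(t_red)| = %.3g",
      wavelength, abs(a_ox - a_red)
    ))
  }
  structure(
    list(times = ts$times,
         fraction_oxidized = (trace - a_red) / (a_ox - a_red),
         species_role = role, wavelength_used = wavelength,
         t_ox = t_ox, t_red = t_red),
    class = "fraction_trace"
  )
}

# Absorbance trace at one wavelength, optionally band-averaged.
#' @noRd
absorbance_at <- function(ts, wavelength, band_halfwidth = 0) {
  if (band_halfwidth > 0) {
    sel <- which(abs(ts$wavelengths - wavelength) <= band_halfwidth)
  } else {
    sel <- match(wavelength, ts$wavelengths)
  }
  if (!length(sel) || anyNA(sel)) {
    abort_invalid(sprintf("wavelength %g nm is not on the grid", wavelength))
  }
  if (length(sel) > 1L) rowMeans(ts$absorbance[, sel, drop = FALSE])
  else ts$absorbance[, sel]
}

#' Remove a reference dye's contribution from a measurement wavelength
#'
#' Phenosafranin absorbs appreciably at the flavin measurement
#' wavelength (456 nm), so its fraction-weighted basis contribution is
#' subtracted before the flavin's oxidized fraction is formed:
#' `A_corr(t) = A(t) - c_dye * (f_ox_dye(t) eps_ox(l) + f_red_dye(t) eps_red(l))`.
#'
#' @param ts A [time_series_spectra()].
#' @param measure_wavelength Wavelength (nm) being corrected.
#' @param dye_trace The dye's [fraction_oxidized_trace()].
#' @param dye_species The dye's [assay_species()] (concentration and
#'   basis spectrum; a dye-only calibration run can supply the basis).
#' @param band_halfwidth Optional band-averaging half-width in nm.
#' @return Numeric corrected absorbance trace over `ts$times`.
#' @export
subtract_reference_contribution <- function(ts, measure_wavelength, dye_trace,
                                            dye_species, band_halfwidth = 0) {
  stopifnot(inherits(ts, "time_series_spectra"),
            inherits(dye_trace, "fraction_trace"))
  if (!inherits(dye_species, "assay_species")) {
    abort_invalid(paste(
      "missing or invalid dye species: supply the dye's assay_species",
      "(its basis can be calibrated from a dye-only run)"
    ))
  }
  a <- absorbance_at(ts, measure_wavelength, band_halfwidth)
  i <- which.min(abs(dye_species$basis$wavelengths - measure_wavelength))
  f_ox <- dye_trace$fraction_oxidized
  a - dye_species$concentration *
    (f_ox * dye_species$basis$eps_ox[i] + (1 - f_ox) * dye_species$basis$eps_red[i])
}

#' Nernst concentration terms of a fraction trace
#'
#' `term(t) = (RT/nF) ln(f_ox / (1 - f_ox))` in mV. Points with
#' fractions outside (0, 1) give non-finite terms; they are flagged by
#' value (NaN/Inf), not dropped.
#'
#' @param trace A `fraction_trace` (or bare numeric fractions).
#' @param cond A [thermo_conditions()] supplying the prefactor; the
#'   convention (as on published Nernst-plot axes) applies one shared
#'   prefactor to both species.
#' @return Numeric vector of mV terms.
#' @export
nernst_terms <- function(trace, cond = thermo_conditions()) {
  f <- if (inherits(trace, "fraction_trace")) trace$fraction_oxidized else trace
  suppressWarnings(nernst_prefactor(cond) * log(f / (1 - f)))
}

#' Fit the Nernst regression relating flavin and dye terms
#'
#' Ordinary least squares of the reference dye's Nernst terms (y) on
#' the flavin's (x). At a shared solution potential the intercept is
#' `b = Em(flavin) - Em(dye)` and, with one shared prefactor, the slope
#' is `n_dye / n_flavin` (1 for two matched two-electron couples).
#' Points where either species' oxidized fraction falls outside
#' `mask_bounds` are excluded: the log terms diverge at the anchors.
#'
#' @param flavin_terms,dye_terms Paired mV terms ([nernst_terms()]), or
#'   `fraction_trace` objects (terms then computed internally, and the
#'   mask applied to the fractions directly).
#' @param mask_bounds Fraction bounds `(lo, hi)` for inclusion.
#' @param cond A [thermo_conditions()].
#' @param method `"ols"` (default) or `"orthogonal"` (total least
#'   squares; both axes carry error under noise).
#' @return An object of class `nernst_fit` with fields `x_terms`
#'   (flavin), `y_terms` (dye), `slope`, `intercept_b` (mV),
#'   `r_squared`, `mask`.
#' @export
fit_nernst <- function(flavin_terms, dye_terms, mask_bounds = c(0.05, 0.95),
                       cond = thermo_conditions(),
                       method = c("ols", "orthogonal")) {
  method <- match.arg(method)
  get_f <- function(z) if (inherits(z, "fraction_trace")) z$fraction_oxidized else NULL
  f_flavin <- get_f(flavin_terms)
  f_dye <- get_f(dye_terms)
  x <- if (is.null(f_flavin)) flavin_terms else nernst_terms(flavin_terms, cond)
  y <- if (is.null(f_dye)) dye_terms else nernst_terms(dye_terms, cond)
  if (length(x) != length(y)) abort_invalid("term vectors must be paired")
  pref <- nernst_prefactor(cond)
  in_bounds <- function(f, terms) {
    if (!is.null(f)) {
      f > mask_bounds[1] & f < mask_bounds[2]
    } else {
      # invert the logit at the shared prefactor
      lo <- pref * log(mask_bounds[1] / (1 - mask_bounds[1]))
      hi <- pref * log(mask_bounds[2] / (1 - mask_bounds[2]))
      terms > lo & terms < hi
    }
  }
  mask <- is.finite(x) & is.finite(y) & in_bounds(f_flavin, x) & in_bounds(f_dye, y)
  if (sum(mask) < 3L) {
    abort_invalid(sprintf(
      "only %d point(s) survive masking; need at least 3", sum(mask)
    ))
  }
  xm <- x[mask]; ym <- y[mask]
  if (method == "ols") {
    fit <- stats::lm(ym ~ xm)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- summary(fit)$r.squared
  } else {
    # total least squares via the first principal axis
    cx <- xm - mean(xm); cy <- ym - mean(ym)
    e <- eigen(stats::cov(cbind(cx, cy)))
    slope <- e$vectors[2, 1] / e$vectors[1, 1]
    intercept <- mean(ym) - slope * mean(xm)
    r2 <- stats::cor(xm, ym)^2
  }
  structure(
    list(x_terms = x, y_terms = y, slope = slope, intercept_b = intercept,
         r_squared = r2, mask = mask, method = method,
         mask_bounds = mask_bounds),
    class = "nernst_fit"
  )
}

#' Flavin midpoint potential from a Nernst fit
#'
#' @param fit A `nernst_fit`.
#' @param dye The reference dye's [redox_couple()].
#' @return `Em(dye) + intercept_b` in mV vs SHE.
#' @export
em_from_fit <- function(fit, dye) {
  stopifnot(inherits(fit, "nernst_fit"), inherits(dye, "redox_couple"))
  dye$e_m + fit$intercept_b
}

#' Check a run for semiquinone formation
#'
#' The one-electron flavin radical absorbs near 600 nm; its absence
#' justifies treating the titration as a single two-electron process.
#' The check fails if any frame's band-average absorbance exceeds both
#' anchor frames' band averages by more than `threshold`.
#'
#' @param ts A [time_series_spectra()].
#' @param band Wavelength window in nm, default `c(590, 610)`.
#' @param threshold Excess absorbance (AU) that triggers failure.
#' @param t_ox,t_red Anchor frame indices (defaults: first and last).
#' @return List with `pass` (logical) and `max_transient` (AU), the
#'   largest excess over the anchors.
#' @export
semiquinone_check <- function(ts, band = c(590, 610), threshold = 0.01,
                              t_ox = 1L, t_red = length(ts$times)) {
  stopifnot(inherits(ts, "time_series_spectra"))
  sel <- which(ts$wavelengths >= band[1] & ts$wavelengths <= band[2])
  if (!length(sel)) abort_invalid("`band` lies outside the wavelength grid")
  bm <- rowMeans(ts$absorbance[, sel, drop = FALSE])
  excess <- bm - pmax(bm[t_ox], bm[t_red])
  max_tr <- max(excess)
  list(pass = max_tr <= threshold, max_transient = max_tr)
}

#' Run the full Em-inference pipeline over replicate assays
#'
#' For each run: locate the fully-reduced plateau, form the dye's and
#' the flavin's oxidized-fraction traces at their measurement
#' wavelengths (subtracting the dye's contribution at the flavin
#' wavelength when `dye_species` is supplied, as required for
#' phenosafranin), regress the Nernst terms and convert the intercept
#' to the flavin Em. Replicates are averaged; the reported uncertainty
#' is the sample standard deviation.
#'
#' @param runs A [time_series_spectra()] or list of them (replicates).
#'   All replicates must share the reference dye identity (checked
#'   against simulator provenance when present).
#' @param dye The reference dye's [redox_couple()].
#' @param flavin_wavelength,dye_wavelength Measurement wavelengths (nm):
#'   each species is read at the *other* species' isosbestic point
#'   (AQS assays: dye at 335, flavin at 355) or, for PSF assays, the dye
#'   at 540 and the flavin at its peak (456) with dye subtraction.
#' @param dye_species Optional dye [assay_species()] enabling
#'   subtraction of the dye's contribution at `flavin_wavelength`.
#' @param cond A [thermo_conditions()].
#' @param mask_bounds,plateau_tol,plateau_window,band_halfwidth,method
#'   Analysis settings passed to the component steps.
#' @param em_free Optional Em of the free flavin (mV) for reporting the
#'   shift `delta_em_vs_free`.
#' @param check_semiquinone Run [semiquinone_check()] per replicate.
#' @return An object of class `em_result`: `e_m` (mV, mean across
#'   replicates), `sd` (mV; `NA` for a single run), `n_replicates`,
#'   `reference_dye`, `delta_em_vs_free`, plus per-run fits in `runs`.
#' @export
run_em_pipeline <- function(runs, dye, flavin_wavelength, dye_wavelength,
                            dye_species = NULL, cond = thermo_conditions(),
                            mask_bounds = c(0.05, 0.95), plateau_tol = 1e-3,
                            plateau_window = 5, band_halfwidth = 0,
                            method = "ols", em_free = NULL,
                            check_semiquinone = TRUE) {
  if (inherits(runs, "time_series_spectra")) runs <- list(runs)
  if (!length(runs)) abort_invalid("need at least one run")
  stopifnot(inherits(dye, "redox_couple"))
  dye_names <- unlist(lapply(runs, function(r) {
    sp <- r$provenance$config$species
    if (is.null(sp)) return(NULL)
    # provenance may hold live assay_species or the flattened sidecar form
    vapply(Filter(function(s) identical(s$role, "reference_dye"), sp),
           function(s) s$name %||% s$couple$name, "")
  }))
  if (length(unique(dye_names)) > 1L) {
    abort_invalid(sprintf("runs mix reference dyes: %s",
                          paste(unique(dye_names), collapse = ", ")))
  }
  per_run <- lapply(runs, function(ts) {
    t_red <- detect_plateau(ts, tol = plateau_tol, window = plateau_window)
    dye_trace <- fraction_oxidized_trace(
      ts, dye_wavelength, t_ox = 1L, t_red = t_red, role = "reference_dye",
      band_halfwidth = band_halfwidth
    )
    flavin_abs <- if (!is.null(dye_species)) {
      subtract_reference_contribution(ts, flavin_wavelength, dye_trace,
                                      dye_species, band_halfwidth)
    } else NULL
    flavin_trace <- fraction_oxidized_trace(
      ts, flavin_wavelength, t_ox = 1L, t_red = t_red, role = "flavin",
      band_halfwidth = band_halfwidth, trace = flavin_abs
    )
    fit <- fit_nernst(flavin_trace, dye_trace, mask_bounds = mask_bounds,
                      cond = cond, method = method)
    list(
      e_m = em_from_fit(fit, dye), fit = fit, t_red = t_red,
      semiquinone = if (check_semiquinone) {
        semiquinone_check(ts, t_red = t_red)
      }
    )
  })
  ems <- vapply(per_run, `[[`, 0, "e_m")
  structure(
    list(
      e_m = mean(ems),
      sd = if (length(ems) > 1L) stats::sd(ems) else NA_real_,
      n_replicates = length(ems),
      reference_dye = dye,
      delta_em_vs_free = if (!is.null(em_free)) mean(ems) - em_free,
      per_run_em = ems,
      runs = per_run
    ),
    class = "em_result"
  )
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf(
    "<em_result> Em = %.1f %s mV vs SHE (n = %d, dye %s at %.0f mV)\n",
    x$e_m, if (is.na(x$sd)) "+/- NA" else sprintf("+/- %.1f", x$sd),
    x$n_replicates, x$reference_dye$name, x$reference_dye$e_m
  ))
  if (!is.null(x$delta_em_vs_free)) {
    cat(sprintf("  delta Em vs free = %.1f mV\n", x$delta_em_vs_free))
  }
  invisible(x)
}

#' @export
print.nernst_fit <- function(x, ...) {
  cat(sprintf(
    "<nernst_fit> intercept b = %.2f mV, slope = %.3f, r^2 = %.4f (%d/%d points)\n",
    x$intercept_b, x$slope, x$r_squared, sum(x$mask), length(x$mask)
  ))
  invisible(x)
}
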