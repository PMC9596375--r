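# Binding-isotherm estimators: one-site ITC, Hill fluorescence quench,
# shared-amplitude in-line probing, and spectral-shift metrics.

#' Fraction bound from fluorescence readings
#'
#' `(F - F0) / (Fc - F0)` where `F0` is the ligand-only fluorescence and
#' `Fc` the fully-complexed fluorescence. Not clipped: noisy values may
#' fall outside `[0, 1]` and are preserved.
#'
#' @param f Measured fluorescence (vectorised).
#' @param f0 Ligand-only fluorescence.
#' @param fc Fully-complexed fluorescence.
#' @return Fraction bound.
#' @export
fraction_bound <- function(f, f0, fc) {
  if (abs(fc - f0) < .Machine$double.eps * 100) {
    abort_invalid("degenerate normalization: Fc equals F0")
  }
  (f - f0) / (fc - f0)
}

#' Fit a Hill binding curve with the maximum fixed at 1
#'
#' Nonlinear least squares of `Y = X^h / (kd^h + X^h)` with multistart
#' initialization: `kd` starts at the geometric median of the
#' concentration grid and the Hill slope at each of 0.5, 1 and 2; the
#' best converged start (lowest residual sum of squares) is kept.
#'
#' @param curve A [titration_curve()] with >= 4 distinct concentrations.
#' @param weights Optional per-point weights for weighted least squares.
#' @return An object of class `hill_fit` with `k_d`, `h`, standard
#'   errors, `b_max = 1` and the residual norm.
#' @export
fit_hill <- function(curve, weights = NULL) {
  stopifnot(inherits(curve, "titration_curve") || is.data.frame(curve))
  x <- curve$ligand_conc
  y <- curve$response
  if (length(unique(x)) < 4L) {
    abort_invalid("need at least 4 distinct concentrations")
  }
  if (max(abs(y)) < 1e-6) {
    abort_invalid("response is identically zero: no binding signal to fit")
  }
  if (is.null(weights)) weights <- rep(1, length(y))
  kd0 <- exp(stats::median(log(x)))
  best <- NULL
  diagnostics <- character()
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      stats::nls(
        y ~ x^h / (kd^h + x^h),
        start = list(kd = kd0, h = h0), weights = weights,
        algorithm = "port",
        lower = c(kd = min(x) / 1e3, h = 0.05),
        upper = c(kd = max(x) * 1e3, h = 20),
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, sprintf("h0 = %g: %s", h0, conditionMessage(fit)))
    } else if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    abort_invalid(paste0("Hill fit failed to converge from all starts:\n  ",
                         paste(diagnostics, collapse = "\n  ")))
  }
  co <- summary(best)$coefficients
  structure(
    list(k_d = co["kd", "Estimate"], h = co["h", "Estimate"],
         k_d_se = co["kd", "Std. Error"], h_se = co["h", "Std. Error"],
         b_max = 1, rss = stats::deviance(best), fit = best),
    class = "hill_fit"
  )
}

#' Fit a one-site ITC thermogram
#'
#' Nonlinear least squares of per-injection heats against the exact
#' single-site quadratic solution with displaced-volume correction
#' (the same forward model as [simulate_itc()]). Parameters are the
#' stoichiometry `n`, `log10(Kd)`, the binding enthalpy `dH`
#' (kcal/mol) and, unless `subtract_dilution` indicates the baseline
#' was already removed, a constant per-injection dilution offset. The
#' binding entropy is derived from `dG = RT ln Kd = dH - T dS`.
#'
#' @param tg A [thermogram()] with >= 6 injections.
#' @param subtract_dilution If `TRUE`, the heats are assumed already
#'   baseline-corrected and no offset is fitted; if `FALSE` (default) a
#'   constant dilution offset is estimated alongside.
#' @return An object of class `one_site_itc_fit` with `n_sites`, `k_d`
#'   (molar), `dh` (kcal/mol), `ds` (cal/mol/K), `dg` (kcal/mol),
#'   `dilution_heat` (ucal), standard errors and the residual norm.
#'   Warns when the c-value (cell concentration / Kd) is far outside
#'   `[1, 1000]`, where Kd is poorly determined.
#' @examples
#' tg <- simulate_itc(ka = 4.12e6, dh = -8, cell_conc = 10,
#'                    syringe_conc = 130)
#' fit <- fit_one_site_itc(tg, subtract_dilution = TRUE)
#' 1e9 * fit$k_d  # ~243 nM
#' @export
fit_one_site_itc <- function(tg, subtract_dilution = FALSE) {
  stopifnot(inherits(tg, "thermogram"))
  if (nrow(tg) < 6L) abort_invalid("need at least 6 injections")
  cell_conc <- attr(tg, "cell_conc") * 1e-6
  syringe_conc <- attr(tg, "syringe_conc") * 1e-6
  temperature <- attr(tg, "temperature")
  cell_volume <- attr(tg, "cell_volume") * 1e-3
  v_inj <- tg$injection_volume[1] * 1e-6
  n_inj <- nrow(tg)
  heat <- tg$heat
  model <- function(log10_kd, dh, n, offset) {
    itc_injection_heats(
      kd = 10^log10_kd, dh = dh, n_sites = n,
      cell_conc = cell_conc, syringe_conc = syringe_conc,
      n_injections = n_inj, injection_volume = v_inj,
      cell_volume = cell_volume, dilution_heat = offset
    )$heat
  }
  # dH scale from the initial (near-saturating-binding) injections
  moles_per_inj <- v_inj * syringe_conc
  dh0 <- mean(heat[1:3]) / (moles_per_inj * 1e9)
  best <- NULL
  diagnostics <- character()
  for (log10_kd0 in seq(-9, -4, by = 1)) {
    fit <- tryCatch({
      if (subtract_dilution) {
        stats::nls(
          heat ~ model(log10_kd, dh, n, 0),
          start = list(log10_kd = log10_kd0, dh = dh0, n = 1),
          algorithm = "port",
          lower = c(log10_kd = -12, dh = -1e3, n = 0.05),
          upper = c(log10_kd = -1, dh = 1e3, n = 20),
          control = stats::nls.control(maxiter = 200)
        )
      } else {
        stats::nls(
          heat ~ model(log10_kd, dh, n, offset),
          start = list(log10_kd = log10_kd0, dh = dh0, n = 1, offset = 0),
          algorithm = "port",
          lower = c(log10_kd = -12, dh = -1e3, n = 0.05, offset = -1e4),
          upper = c(log10_kd = -1, dh = 1e3, n = 20, offset = 1e4),
          control = stats::nls.control(maxiter = 200)
        )
      }
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics,
                       sprintf("log10(Kd) = %g: %s", log10_kd0,
                               conditionMessage(fit)))
    } else if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    abort_invalid(paste0("ITC fit failed to converge from all starts:\n  ",
                         paste(diagnostics, collapse = "\n  ")))
  }
  est <- stats::coef(best)
  # standard errors are unavailable when a parameter is unidentifiable
  # (e.g. a dilution-only thermogram); report NA rather than failing
  ses <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                  error = function(e) {
                    stats::setNames(rep(NA_real_, length(est)), names(est))
                  })
  kd <- 10^est[["log10_kd"]]
  dh <- est[["dh"]]
  n <- est[["n"]]
  cval <- n * cell_conc / kd
  if (cval < 1 || cval > 1000) {
    warning(sprintf(
      "c-value %.3g outside `[1, 1000]`; Kd is poorly determined", cval
    ))
  }
  dg <- .R_KCAL * temperature * log(kd)        # kcal/mol
  ds <- (dh - dg) / temperature * 1000         # cal/mol/K
  structure(
    list(
      n_sites = n, k_d = kd, dh = dh, ds = ds, dg = dg,
      dilution_heat = if (subtract_dilution) 0 else est[["offset"]],
      k_d_se = log(10) * kd * ses[["log10_kd"]],
      dh_se = ses[["dh"]],
      n_se = ses[["n"]],
      c_value = cval, rss = stats::deviance(best),
      temperature = temperature, fit = best
    ),
    class = "one_site_itc_fit"
  )
}

#' Joint one-site fit of oxidized/reduced titrations with shared maximum
#'
#' Fits `Y = Bmax X / (Kd + X)` jointly to two curves (oxidized and
#' reduced ligand) with a single shared `Bmax` and separate `Kd`
#' values. When the reduced curve is flat (non-binder), its Kd is
#' reported as censored with a lower bound at the largest concentration
#' probed rather than as a point estimate.
#'
#' @param curve_ox,curve_red [titration_curve()] objects.
#' @return An object of class `shared_bmax_fit` with `k_d_ox`,
#'   `k_d_red`, `b_max`, `censored_red` and (when censored)
#'   `k_d_red_lower`.
#' @export
fit_inline_probing <- function(curve_ox, curve_red) {
  if (!nrow(curve_ox) || !nrow(curve_red)) {
    abort_invalid("both curves must be non-empty")
  }
  flat_red <- max(abs(curve_red$response)) <
    0.02 * max(abs(curve_ox$response))
  if (flat_red) {
    ox <- stats::nls(
      response ~ bmax * ligand_conc / (kd + ligand_conc),
      data = curve_ox,
      start = list(bmax = max(curve_ox$response),
                   kd = exp(stats::median(log(curve_ox$ligand_conc)))),
      algorithm = "port",
      lower = c(bmax = 1e-12, kd = min(curve_ox$ligand_conc) / 1e3)
    )
    co <- stats::coef(ox)
    return(structure(
      list(k_d_ox = unname(co["kd"]), k_d_red = Inf,
           b_max = unname(co["bmax"]), censored_red = TRUE,
           k_d_red_lower = max(curve_red$ligand_conc)),
      class = "shared_bmax_fit"
    ))
  }
  x <- c(curve_ox$ligand_conc, curve_red$ligand_conc)
  y <- c(curve_ox$response, curve_red$response)
  is_red <- rep(c(0, 1), c(nrow(curve_ox), nrow(curve_red)))
  kd0 <- exp(stats::median(log(x)))
  fit <- stats::nls(
    y ~ bmax * x / (ifelse(is_red == 1, kd_red, kd_ox) + x),
    start = list(bmax = max(y), kd_ox = kd0, kd_red = kd0),
    algorithm = "port",
    lower = c(bmax = 1e-12, kd_ox = min(x) / 1e3, kd_red = min(x) / 1e3),
    upper = c(bmax = 10 * max(abs(y)), kd_ox = max(x) * 1e6,
              kd_red = max(x) * 1e6),
    control = stats::nls.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  structure(
    list(k_d_ox = unname(co["kd_ox"]), k_d_red = unname(co["kd_red"]),
         b_max = unname(co["bmax"]), censored_red = FALSE,
         rss = stats::deviance(fit), fit = fit),
    class = "shared_bmax_fit"
  )
}

#' Normalize a spectrum to unit maximum absorbance
#'
#' @param spectrum Data frame with columns `wavelength_nm` and
#'   `absorbance` (or a bare numeric vector).
#' @return Same shape, absorbance divided by its maximum (argmax is
#'   preserved).
#' @export
normalize_spectrum <- function(spectrum) {
  a <- if (is.data.frame(spectrum)) spectrum$absorbance else spectrum
  m <- max(a)
  if (!is.finite(m) || m <= 0) {
    abort_invalid("cannot normalize: maximum absorbance is not positive")
  }
  if (is.data.frame(spectrum)) {
    spectrum$absorbance <- a / m
    spectrum
  } else {
    a / m
  }
}

#' Peak shift between free and bound spectra
#'
#' Difference of argmax wavelengths within a search window (restricted
#' by default to the visible flavin band, 400-520 nm, to avoid the
#' near-UV peak), plus the bound-minus-free difference spectrum and its
#' local maxima within the window as shoulder candidates.
#'
#' @param free_spectrum,bound_spectrum Data frames with columns
#'   `wavelength_nm` and `absorbance` on a common grid.
#' @param search_window Wavelength window in nm, default `c(400, 520)`.
#' @return List with `delta_lambda_max` (nm, positive = red shift),
#'   `lambda_max_free`, `lambda_max_bound`, `difference` (data frame)
#'   and `shoulder_candidates` (nm).
#' @export
delta_lambda_max <- function(free_spectrum, bound_spectrum,
                             search_window = c(400, 520)) {
  if (!identical(free_spectrum$wavelength_nm, bound_spectrum$wavelength_nm)) {
    abort_invalid("spectra must share a common wavelength grid")
  }
  wl <- free_spectrum$wavelength_nm
  sel <- which(wl >= search_window[1] & wl <= search_window[2])
  if (!length(sel)) abort_invalid("search window lies outside the grid")
  argmax_in <- function(a, label) {
    aw <- a[sel]
    if (diff(range(aw)) < 1e-12) {
      abort_invalid(sprintf("%s spectrum is flat in the search window", label))
    }
    wl[sel][which.max(aw)]
  }
  lmax_free <- argmax_in(free_spectrum$absorbance, "free")
  lmax_bound <- argmax_in(bound_spectrum$absorbance, "bound")
  d <- bound_spectrum$absorbance - free_spectrum$absorbance
  dw <- d[sel]
  interior <- 2:(length(dw) - 1L)
  shoulders <- wl[sel][interior][dw[interior] > dw[interior - 1L] &
                                 dw[interior] > dw[interior + 1L]]
  list(
    delta_lambda_max = lmax_bound - lmax_free,
    lambda_max_free = lmax_free, lambda_max_bound = lmax_bound,
    difference = data.frame(wavelength_nm = wl, absorbance = d),
    shoulder_candidates = shoulders
  )
}

#' @export
print.one_site_itc_fit <- function(x, ...) {
  cat(sprintf(
    "<one_site_itc_fit> n = %.2f, Kd = %.3g M (c = %.3g), dH = %.2f kcal/mol, dS = %.2f cal/mol/K\n",
    x$n_sites, x$k_d, x$c_value, x$dh, x$ds
  ))
  invisible(x)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> Kd = %.3g M, h = %.3f (Bmax fixed at 1)\n",
              x$k_d, x$h))
  invisible(x)
}

#' @export
print.shared_bmax_fit <- function(x, ...) {
  if (x$censored_red) {
    cat(sprintf(
      "<shared_bmax_fit> Kd_ox = %.3g M, Kd_red censored (> %.3g M), Bmax = %.3g\n",
      x$k_d_ox, x$k_d_red_lower, x$b_max
    ))
  } else {
    cat(sprintf("<shared_bmax_fit> Kd_ox = %.3g M, Kd_red = %.3g M, Bmax = %.3g\n",
                x$k_d_ox, x$k_d_red, x$b_max))
  }
  invisible(x)
}
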