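# Em inference pipeline: plateau detection, fraction traces, dye
# subtraction, Nernst regression, and end-to-end recovery.

test_that("detect_plateau finds the earliest settled frame", {
  # constant series settles immediately
  flat <- time_series_spectra(0:10, 1:5, matrix(1, 11, 5))
  expect_equal(detect_plateau(flat), 1L)
  # noiseless simulated run settles at/after delivery saturation
  cfg <- make_assay_config(-251, "PSF", timepoints = 0:150)
  ts <- simulate_assay(cfg)
  t_sat <- min(which(electron_schedule(cfg) >= 80))
  expect_gte(detect_plateau(ts), t_sat)
  # monotone never-settling series falls back to the last index
  ramp <- time_series_spectra(0:10, 1:5, matrix(0.1 * (0:10), 11, 5))
  expect_warning(idx <- detect_plateau(ramp), "no plateau")
  expect_equal(idx, 11L)
  expect_error(detect_plateau(time_series_spectra(0, 1:5, matrix(1, 1, 5))),
               "2 timepoints")
})

test_that("fraction_oxidized_trace anchors exactly and matches the simulator", {
  cfg <- make_assay_config(-209, "AQS", "free-FAD", timepoints = 0:150)
  ts <- simulate_assay(cfg)
  t_red <- detect_plateau(ts)
  # flavin read at 355 nm (AQS isosbestic)
  tr <- fraction_oxidized_trace(ts, 355, t_red = t_red)
  expect_equal(tr$fraction_oxidized[1], 1)
  expect_equal(tr$fraction_oxidized[t_red], 0)
  expect_lt(max(abs(tr$fraction_oxidized - (1 - ts$f_red[, "flavin"]))), 1e-6)
  # dye read at 335 nm (flavin isosbestic)
  trd <- fraction_oxidized_trace(ts, 335, t_red = t_red, role = "reference_dye")
  expect_lt(max(abs(trd$fraction_oxidized - (1 - ts$f_red[, "reference_dye"]))),
            1e-6)
  # degenerate anchors are refused, naming the wavelength
  expect_error(fraction_oxidized_trace(ts, 750, t_red = t_red), "750")
  expect_error(fraction_oxidized_trace(ts, 351.5, t_red = t_red), "grid")
})

test_that("dye subtraction recovers the pure flavin trace", {
  cfg <- make_assay_config(-234, "PSF", timepoints = 0:150)
  ts <- simulate_assay(cfg)
  t_red <- detect_plateau(ts)
  dye_sp <- cfg$species[[2]]
  flavin_sp <- cfg$species[[1]]
  # oracle dye trace from the simulator's ground truth: anchoring the
  # true oxidized fraction is the identity, so this isolates the
  # subtraction step from the 540-nm readout
  dye_tr <- fraction_oxidized_trace(ts, 540, t_red = t_red,
                                    role = "reference_dye",
                                    trace = 1 - ts$f_red[, "reference_dye"])
  corr <- subtract_reference_contribution(ts, 456, dye_tr, dye_sp)
  i <- match(456, flavin_sp$basis$wavelengths)
  flavin_only <- flavin_sp$concentration *
    ((1 - ts$f_red[, "flavin"]) * flavin_sp$basis$eps_ox[i] +
       ts$f_red[, "flavin"] * flavin_sp$basis$eps_red[i])
  expect_lt(max(abs(corr - flavin_only)), 1e-6)
  # zero dye concentration leaves the trace untouched
  dye0 <- dye_sp; dye0$concentration <- 1e-12
  raw <- ts$absorbance[, match(456, ts$wavelengths)]
  expect_equal(subtract_reference_contribution(ts, 456, dye_tr, dye0), raw,
               tolerance = 1e-9)
  expect_error(subtract_reference_contribution(ts, 456, dye_tr, NULL),
               "dye species")
  # the 540-nm readout itself is only lightly contaminated by the
  # flavin tail, so the practical path stays well under a milli-AU
  dye_tr_540 <- fraction_oxidized_trace(ts, 540, t_red = t_red,
                                        role = "reference_dye")
  corr2 <- subtract_reference_contribution(ts, 456, dye_tr_540, dye_sp)
  expect_lt(max(abs(corr2 - flavin_only)), 1e-3)
})

test_that("nernst_terms computes and flags the log-ratio terms", {
  cond <- thermo_conditions(290.13, 2)  # prefactor almost exactly 12.5
  pref <- nernst_prefactor(cond)
  expect_equal(nernst_terms(0.5, cond), 0)
  expect_equal(nernst_terms(0.9, cond), pref * log(9), tolerance = 1e-12)
  expect_equal(round(nernst_terms(0.9, cond), 1), 27.5)
  flagged <- nernst_terms(c(1, 0, 1.2, -0.1), cond)
  expect_true(all(!is.finite(flagged)))
})

test_that("fit_nernst recovers intercept, slope and honors the mask", {
  # identical couples: intercept 0, slope 1
  res0 <- recover_em(-252, "PSF")
  fit0 <- res0$runs[[1]]$fit
  expect_equal(fit0$intercept_b, 0, tolerance = 0.05)
  expect_equal(fit0$slope, 1, tolerance = 0.01)
  expect_gt(fit0$r_squared, 0.9999)

  # flavin -234 vs PSF -252: intercept +18; free FAD -209 vs AQS: +16
  fit18 <- recover_em(-234, "PSF")$runs[[1]]$fit
  expect_equal(fit18$intercept_b, 18, tolerance = 0.1)
  expect_equal(fit18$slope, 1, tolerance = 0.01)
  fit16 <- recover_em(-209, "AQS", "free-FAD")$runs[[1]]$fit
  expect_equal(fit16$intercept_b, 16, tolerance = 0.1)

  # fewer than 3 surviving points is an error that reports the count
  expect_error(fit_nernst(c(0, 1, NA), c(0, 1, 2), cond = room_temp),
               "2 point")
})

test_that("em_from_fit applies the intercept rule", {
  fit <- structure(list(intercept_b = 16), class = "nernst_fit")
  expect_equal(em_from_fit(fit, reference_dye("AQS")), -209)
  fit$intercept_b <- 1
  expect_equal(em_from_fit(fit, reference_dye("PSF")), -251)
  fit$intercept_b <- 0
  expect_equal(em_from_fit(fit, reference_dye("PSF")), -252)
})

test_that("noiseless end-to-end recovery is exact across the Em grid", {
  # |Em(flavin) - Em(dye)| <= 30 mV on both dye routes
  cases <- rbind(
    data.frame(em = c(-211, -223, -234, -245, -199), dye = "AQS",
               preset = "free-FAD"),
    data.frame(em = c(-226, -234, -251, -263, -274), dye = "PSF",
               preset = "C14U-bound-flavin")
  )
  for (k in seq_len(nrow(cases))) {
    res <- recover_em(cases$em[k], cases$dye[k], cases$preset[k],
                      timepoints = 0:150)
    expect_lt(abs(res$e_m - cases$em[k]), 0.2)
    expect_true(res$runs[[1]]$fit$slope >= 0.99 &&
                  res$runs[[1]]$fit$slope <= 1.01)
  }
})

test_that("slope reflects the electron-count ratio with a shared prefactor", {
  # hypothetical 1-electron dye against the 2-electron flavin
  cfg <- make_assay_config(-251, "PSF", dye_n = 1, timepoints = 0:150)
  ts <- simulate_assay(cfg)
  args <- pipeline_args(cfg)
  res <- run_em_pipeline(ts, args$dye, args$flavin_wavelength,
                         args$dye_wavelength, dye_species = args$dye_species,
                         cond = room_temp)
  expect_equal(res$runs[[1]]$fit$slope, 0.5, tolerance = 0.01)
})

test_that("masking choice barely moves the noiseless answer", {
  a <- recover_em(-251, "PSF", mask_bounds = c(0.05, 0.95))
  b <- recover_em(-251, "PSF", mask_bounds = c(0.10, 0.90))
  expect_lt(abs(a$e_m - b$e_m), 0.1)
})

test_that("semiquinone_check passes clean runs and catches a 600-nm spike", {
  cfg <- make_assay_config(-251, "PSF", timepoints = 0:120)
  ts <- simulate_assay(cfg)
  chk <- semiquinone_check(ts)
  expect_true(chk$pass)
  # positive control on an AQS run (no assay species absorbs near
  # 600 nm there, unlike phenosafranin whose oxidized tail covers it)
  spiked <- simulate_assay(make_assay_config(-209, "AQS", "free-FAD",
                                             timepoints = 0:120))
  mid <- floor(nrow(spiked$absorbance) / 2)
  band <- which(spiked$wavelengths >= 590 & spiked$wavelengths <= 610)
  spiked$absorbance[mid, band] <- spiked$absorbance[mid, band] + 0.05
  chk2 <- semiquinone_check(spiked)
  expect_false(chk2$pass)
  expect_gt(chk2$max_transient, 0.04)
  expect_true(semiquinone_check(spiked, threshold = Inf)$pass)
})

test_that("run_em_pipeline averages replicates and reports the shift", {
  # three identical noiseless runs: zero spread
  cfg <- make_assay_config(-251, "PSF", timepoints = 0:150)
  ts <- simulate_assay(cfg)
  args <- pipeline_args(cfg)
  res3 <- run_em_pipeline(list(ts, ts, ts), args$dye, args$flavin_wavelength,
                          args$dye_wavelength, dye_species = args$dye_species,
                          cond = room_temp, em_free = -211)
  expect_equal(res3$sd, 0)
  expect_equal(res3$n_replicates, 3)
  expect_equal(round(res3$delta_em_vs_free), -40)

  # noisy triplicate lands within the reported +/- 2 mV
  true_em <- em_bound(-211, binding_pair(1, 23), room_temp)
  runs <- lapply(1:3, function(s) {
    simulate_assay(make_assay_config(true_em, "PSF", noise_sd = 0.003,
                                     seed = s, timepoints = 0:150))
  })
  noisy <- suppressWarnings(run_em_pipeline(
    runs, args$dye, args$flavin_wavelength, args$dye_wavelength,
    dye_species = args$dye_species, cond = room_temp
  ))
  expect_lt(abs(noisy$e_m - true_em), 2)

  # mixed reference dyes across replicates are refused
  other <- simulate_assay(make_assay_config(-223, "AQS", "free-FAD",
                                            timepoints = 0:150))
  expect_error(
    run_em_pipeline(list(ts, other), args$dye, args$flavin_wavelength,
                    args$dye_wavelength, dye_species = args$dye_species),
    "mix"
  )
})
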