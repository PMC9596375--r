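# Equilibration-assay simulator: electron bookkeeping, shared-potential
# partition, spectra composition, and the binding-data simulators.

test_that("electron_schedule is capped, non-decreasing and zero at t = 0", {
  cfg <- make_assay_config(-210, "AQS", "free-FAD", timepoints = 0:200)
  cfg$delivery_rate <- 1
  cfg$electron_capacity <- 80
  d <- electron_schedule(cfg)
  expect_equal(d[1], 0)
  expect_equal(d[length(d)], 80)
  expect_true(all(diff(d) >= 0))
})

test_that("partition_electrons solves the shared-potential condition", {
  cond <- thermo_conditions(298.15, 2)
  pref <- nernst_prefactor(cond)
  cfg <- make_assay_config(-211, "AQS", "free-FAD", cond = cond)
  species <- cfg$species  # flavin Em -211, AQS Em -225, both 20 uM, n = 2

  # nothing delivered -> fully oxidized
  p0 <- partition_electrons(0, species, cond)
  expect_equal(unname(p0$f_red), c(0, 0))

  # oracle: at E = -211 the flavin is half reduced and the dye fraction
  # follows in closed form; feed the implied equivalents back in
  f_dye <- 1 / (1 + exp((-211 + 225) / pref))
  delivered <- 40 * 0.5 + 40 * f_dye
  p <- partition_electrons(delivered, species, cond)
  expect_equal(p$potential, -211, tolerance = 1e-6)
  expect_equal(unname(p$f_red["flavin"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(p$f_red["reference_dye"]), f_dye, tolerance = 1e-8)

  # symmetry: identical couples at equal concentration split evenly
  twin <- cfg
  twin$species[[2]]$couple$e_m <- -211
  ps <- partition_electrons(40, twin$species, cond)
  expect_equal(unname(ps$f_red), c(0.5, 0.5), tolerance = 1e-8)

  # over-capacity input clamps with a warning
  expect_warning(pc <- partition_electrons(200, species, cond), "clamp")
  expect_equal(unname(pc$f_red), c(1, 1))
})

test_that("solution potential decreases monotonically with delivery", {
  cond <- room_temp
  species <- make_assay_config(-234, "PSF")$species
  delivered <- seq(1, 79, by = 2)
  E <- vapply(delivered, function(d) {
    partition_electrons(d, species, cond)$potential
  }, 0)
  expect_true(all(diff(E) < 0))
})

test_that("simulated spectra conserve electrons and honor the anchors", {
  cfg <- make_assay_config(-251, "PSF", timepoints = 0:150)
  ts <- simulate_assay(cfg)
  caps <- vapply(cfg$species, function(s) s$concentration * s$couple$n_electrons, 0)
  delivered <- pmin(electron_schedule(cfg), sum(caps))
  consumed <- as.vector(ts$f_red %*% caps)
  expect_lt(max(abs(consumed - delivered)), 1e-6)
  # first frame fully oxidized, tail fully reduced
  expect_equal(unname(ts$f_red[1, ]), c(0, 0))
  expect_equal(unname(ts$f_red[nrow(ts$f_red), ]), c(1, 1), tolerance = 1e-12)
})

test_that("flavin absorbance at its isosbestic point is time-invariant", {
  cfg <- make_assay_config(-209, "AQS", "free-FAD")
  ts <- simulate_assay(cfg)
  flavin <- cfg$species[[1]]
  i <- match(335, flavin$basis$wavelengths)
  a_flavin <- flavin$concentration *
    ((1 - ts$f_red[, "flavin"]) * flavin$basis$eps_ox[i] +
       ts$f_red[, "flavin"] * flavin$basis$eps_red[i])
  expect_lt(diff(range(a_flavin)), 1e-9)
})

test_that("zero delivery and zero noise give frozen identical frames", {
  cfg <- make_assay_config(-251, "PSF", timepoints = 0:20)
  cfg$delivery_rate <- 0
  ts <- simulate_assay(cfg)
  expect_equal(max(abs(sweep(ts$absorbance, 2, ts$absorbance[1, ]))), 0)
})

test_that("seeded noise is reproducible and separable", {
  a <- simulate_assay(make_assay_config(-251, "PSF", noise_sd = 0.003,
                                        seed = 7, timepoints = 0:30))
  b <- simulate_assay(make_assay_config(-251, "PSF", noise_sd = 0.003,
                                        seed = 7, timepoints = 0:30))
  c <- simulate_assay(make_assay_config(-251, "PSF", noise_sd = 0.003,
                                        seed = 8, timepoints = 0:30))
  clean <- simulate_assay(make_assay_config(-251, "PSF", timepoints = 0:30))
  expect_identical(a$absorbance, b$absorbance)
  expect_false(identical(a$absorbance, c$absorbance))
  # noiseless component identical across seeds
  expect_equal(mean(a$absorbance - clean$absorbance), 0, tolerance = 1e-3)
  expect_equal(sd(as.vector(a$absorbance - clean$absorbance)), 0.003,
               tolerance = 0.05)
})

test_that("simulate_itc reproduces the saturation limits", {
  # dH = 0 -> all heats equal the dilution heat
  tg0 <- simulate_itc(kd = 1e-7, dh = 0, cell_conc = 10, syringe_conc = 130,
                      dilution_heat = -0.4)
  expect_equal(tg0$heat, rep(-0.4, 26), tolerance = 1e-12)
  # very tight binding: step at molar ratio = n_sites
  tg <- simulate_itc(kd = 1e-12, dh = -10, cell_conc = 10, syringe_conc = 130)
  before <- tg$heat[tg$molar_ratio < 0.9]
  after <- tg$heat[tg$molar_ratio > 1.1]
  moles_per_inj <- 10e-6 * 130e-6  # 10 uL (in L) x 130 uM (in M) = mol
  expect_equal(before / (-10 * 1e9 * moles_per_inj), rep(1, length(before)),
               tolerance = 0.01)
  expect_lt(max(abs(after)), abs(before[1]) * 0.01)
  expect_error(simulate_itc(kd = -1, dh = 1, cell_conc = 1, syringe_conc = 1),
               "kd")
})

test_that("simulate_quench follows the Hill form exactly when noiseless", {
  grid <- 1e-6 * c(0.01, 0.1, 1, 10, 100)
  for (h in c(0.5, 1, 2)) {
    cur <- simulate_quench(kd = 1e-6, hill_h = h, conc = grid)
    expect_equal(cur$response[3], 0.5, tolerance = 1e-12)  # X = kd
    if (h == 1) {
      expect_equal(cur$response, grid / (1e-6 + grid), tolerance = 1e-12)
    }
  }
})

test_that("simulate_inline_probing shares Bmax and handles non-binders", {
  pair <- simulate_inline_probing(1e-6, 1e-6, shared_bmax = 0.8)
  expect_equal(pair$ox$response, pair$red$response)
  flat <- simulate_inline_probing(1e-6, Inf, shared_bmax = 0.8)
  expect_equal(flat$red$response, rep(0, nrow(flat$red)))
})

test_that("assay_config validates its invariants", {
  cfg <- make_assay_config(-210, "AQS", "free-FAD")
  expect_error(
    assay_config(cfg$species, timepoints = c(0, 1, 1, 2)),
    "strictly increasing"
  )
  expect_error(
    assay_config(cfg$species[1]),
    "exactly one flavin and one reference_dye"
  )
  expect_error(
    assay_config(cfg$species, noise_sd = -1),
    "noise_sd"
  )
  expect_error(
    assay_config(cfg$species, isosbestic_map = list(flavin = 335.5)),
    "off-grid"
  )
})
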