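# Synergy coefficient, dose-response fitting, dose conversions, sensitivity.

test_that("synergy coefficient reproduces the worked gel example", {
  s <- synergy_coefficient(9.04, 5.38, 2.6)
  expect_equal(s$s, 9.04 / 7.98)
  expect_true(s$synergistic)
  expect_gt(s$s, 1)
})

test_that("synergy edge cases: additive boundary, zero numerator, bad denominator", {
  s1 <- synergy_coefficient(3.5, 2, 1.5)
  expect_equal(s1$s, 1)
  expect_false(s1$synergistic)
  expect_equal(synergy_coefficient(0, 1, 1)$s, 0)
  expect_error(synergy_coefficient(1, 0, 0), "positive")
  expect_error(synergy_coefficient(1, -2, 1), "positive")
})

test_that("synergy coefficient is invariant under common rescaling", {
  set.seed(71)
  for (i in 1:20) {
    x <- runif(3, 0.1, 10)
    c_ <- runif(1, 0.01, 100)
    expect_equal(synergy_coefficient(c_ * x[1], c_ * x[2], c_ * x[3])$s,
                 synergy_coefficient(x[1], x[2], x[3])$s)
  }
})

test_that("power density reproduces the printed dose series", {
  expect_equal(round(power_density(100, 2.5), 1), 20.4)
  expect_equal(power_density(0, 2.5), 0)
  # exact area gives 101.9; the printed 102.0 implies an area rounded to 4.9
  expect_equal(round(power_density(500, 2.5), 1), 101.9)
  expect_equal(round(power_density(500, 2.5, rounded_area = TRUE), 1), 102.0)
  printed <- c(0, 20.4, 61.2, 102.0, 142.9, 183.7)
  expect_equal(round(power_density(c(0, 100, 300, 500, 700, 900), 2.5,
                                   rounded_area = TRUE), 1), printed)
  expect_error(power_density(100, 0), "positive")
})

test_that("LD50 fold reduction matches the printed factors and is antisymmetric", {
  expect_equal(round(ld50_fold_reduction(143, 34), 1), 4.2)
  expect_equal(round(ld50_fold_reduction(350, 34), 1), 10.3)
  expect_equal(ld50_fold_reduction(50, 50), 1)
  expect_equal(ld50_fold_reduction(143, 34) * ld50_fold_reduction(34, 143), 1)
  expect_error(ld50_fold_reduction(143, 0), "positive")
})

test_that("noiseless logistic data are recovered essentially exactly", {
  d <- gen_dose_response(100, 3, upper = 1, lower = 0,
                         doses = c(0, 20, 60, 100, 140, 180),
                         replicates = 1, noise_sd = 0)
  fit <- fit_dose_response(d)
  expect_equal(fit$ld50, 100, tolerance = 0.01)
  expect_equal(fit$slope, 3, tolerance = 0.01)
  expect_equal(fit$upper, 1, tolerance = 0.01)
  expect_equal(fit$lower, 0, tolerance = 0.01)
})

test_that("a sharp viability step brackets the LD50 between its doses", {
  d <- data.frame(dose = c(0, 20, 40, 80, 160),
                  viability = c(1, 1, 1, 0, 0))
  fit <- fit_dose_response(d)
  expect_gt(fit$ld50, 40)
  expect_lt(fit$ld50, 80)
})

test_that("degenerate dose-response inputs are rejected or flagged", {
  expect_error(fit_dose_response(data.frame(dose = c(0, 1, 2),
                                            viability = c(1, 0.5, 0))),
               "4 distinct doses")
  expect_error(fit_dose_response(data.frame(dose = c(0, 1, 2, 3, 4),
                                            viability = c(1, 0.5, 0, 0, 1.2))),
               "viability")
  up <- gen_dose_response(100, 3, doses = c(0, 40, 80, 120, 160),
                          replicates = 1, noise_sd = 0)
  up$viability <- 1 - up$viability  # viability rising with dose
  w <- capture_warnings(fit <- fit_dose_response(up))
  expect_match(w, "increases with dose", all = FALSE)
  expect_true(fit$increasing)
})

test_that("LD50 recovery from noisy replicates: median error <= 5%, 90th percentile <= 10%", {
  set.seed(99)
  errs <- vapply(1:100, function(i) {
    d <- gen_dose_response(100, 3, upper = 1, lower = 0, replicates = 3,
                           noise_sd = 0.05)
    abs(fit_dose_response(d)$ld50 / 100 - 1)
  }, numeric(1))
  expect_lte(median(errs), 0.05)
  expect_lte(unname(quantile(errs, 0.9)), 0.10)
})

test_that("an empty perturbation grid yields an empty sensitivity report", {
  sc <- scenario_preset("combined", n_photons = 1e3 + 1, seed = 1)
  sc$transport <- transport_settings(1e3, seed = 1)
  rep <- sensitivity_scan(sc, rel = numeric(0))
  expect_identical(nrow(rep$cells), 0L)
  expect_identical(nrow(rep$index), 0L)
})

test_that("doubling mu_a of a clear absorber follows the Beer-Lambert absorbed fraction", {
  sp <- test_absorber()
  sc <- scenario(
    "slab", background = background_optics(0, 0, 0, 1),
    loadings = list(loading(sp, number_density = 1e6)),   # mu_a = 0.05
    geometry = geometry(10, 10, 10, 10), beam = beam_spec(radius = 5),
    transport = transport_settings(5e4, seed = 72, n_outside = 1))
  rep <- sensitivity_scan(sc, parameters = "mu_a_absorber", rel = 1.0)
  L <- 10
  a2 <- rep$cells$absorbed_fraction
  a0 <- a2 - rep$cells$absorbed_fraction_delta
  expect_equal(a0, 1 - exp(-0.05 * L), tolerance = 0.02)
  expect_equal(a2, 1 - exp(-0.10 * L), tolerance = 0.02)
})

test_that("sensitivity ordering separates absorber, scatterer and background roles", {
  sc <- scenario_preset("combined", n_photons = 2e4, seed = 73)
  rep <- sensitivity_scan(sc, rel = c(-0.1, 0.1))
  ix <- setNames(rep$index$index_absorbed, rep$index$parameter)
  sp <- setNames(rep$index$index_spatial, rep$index$parameter)
  # the absorber dominates the global absorbed fraction
  expect_gt(abs(ix["mu_a_absorber"]), abs(ix["mu_s_scatterer"]))
  expect_gt(abs(ix["mu_a_absorber"]), abs(ix["mu_a_bkg"]))
  expect_gt(abs(ix["mu_a_absorber"]), abs(ix["mu_s_bkg"]))
  # the scatterer reshapes the field without moving global absorption
  expect_gt(sp["mu_s_scatterer"], abs(ix["mu_s_scatterer"]))
  # the refractive index matters more for absorption than background optics
  expect_gt(abs(ix["n"]), abs(ix["mu_s_bkg"]))
})
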