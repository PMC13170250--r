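# Phase-function sampling, Fresnel boundaries and the Monte Carlo kernel.

test_that("Henyey-Greenstein sampling reproduces its first moment", {
  set.seed(7)
  n <- 1e6
  for (g in c(0, 0.5, 0.9)) {
    cosu <- sample_phase_function(g, runif(n))
    expect_true(all(cosu >= -1 & cosu <= 1))
    se <- sd(cosu) / sqrt(n)
    expect_lt(abs(mean(cosu) - g), 3 * se)
  }
  expect_error(sample_phase_function(1, 0.5), "< 1")
  expect_error(sample_phase_function(-1.2, 0.5), "< 1")
})

test_that("Henyey-Greenstein second moment matches numerical integration", {
  g <- 0.5
  # independent oracle: E[cos^2] by quadrature over the HG density
  hg_pdf <- function(ct) 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * ct)^1.5
  m2 <- stats::integrate(function(ct) ct^2 * hg_pdf(ct), -1, 1,
                         rel.tol = 1e-10)$value
  set.seed(8)
  n <- 1e6
  cosu <- sample_phase_function(g, runif(n))
  se <- sd(cosu^2) / sqrt(n)
  expect_lt(abs(mean(cosu^2) - m2), 3 * se)
})

test_that("Fresnel reflectance covers matched, normal and total internal reflection", {
  expect_equal(fresnel_reflectance(1.34, 1.34, 0.3), 0)
  expect_equal(fresnel_reflectance(1.0, 1.34, 1.0), ((1 - 1.34) / (1 + 1.34))^2)
  # beyond the critical angle sin_c = 1/1.34
  cos_beyond <- sqrt(1 - (1 / 1.34)^2) * 0.5
  expect_equal(fresnel_reflectance(1.34, 1.0, cos_beyond), 1)
  r <- fresnel_reflectance(1.0, 1.5, seq(0.05, 1, by = 0.05))
  expect_true(all(r >= 0 & r <= 1))
  expect_error(fresnel_reflectance(1.0, 1.34, 0), "cos_incident")
})

test_that("non-scattering absorber follows Beer-Lambert within 2%", {
  g <- geometry(radius = 10, height = 6, n_r = 20, n_z = 24)
  med <- uniform_medium(g, mu_a = 0.5, mu_s = 0, g = 0, n = 1)
  run <- run_transport(med, beam = beam_spec(radius = 5),
                       settings = transport_settings(1e6, seed = 11,
                                                     n_outside = 1))
  prof <- depth_profile(run$fluence)
  expected <- exp(-0.5 * prof$z) / (pi * 5^2)
  sel <- 0.5 * prof$z <= 3
  expect_lt(max(abs(prof$value[sel] / expected[sel] - 1)), 0.02)
})

test_that("energy budget closes within 1e-3 across media", {
  g <- small_geom()
  configs <- list(
    uniform_medium(g, 0.06, 0.1, 0.9, 1.34),
    uniform_medium(g, 0.005, 3.05, 0.015, 1.34),
    uniform_medium(g, 0.2, 1.0, 0.5, 1.5),
    uniform_medium(g, 0, 0.5, 0, 1.0))   # no absorber
  for (i in seq_along(configs)) {
    run <- run_transport(configs[[i]], beam = beam_spec(radius = 4),
                         settings = transport_settings(1e5, seed = 20 + i))
    b <- run$fluence$budget
    expect_true(all(b >= 0 & b <= 1))
    expect_lt(abs(sum(b) - 1), 1e-3)
  }
})

test_that("with no absorber everything escapes and nothing is absorbed", {
  g <- small_geom()
  med <- uniform_medium(g, mu_a = 0, mu_s = 0.5, g = 0, n = 1)
  run <- run_transport(med, beam = beam_spec(radius = 4),
                       settings = transport_settings(1e5, seed = 31,
                                                     n_outside = 1))
  b <- run$fluence$budget
  expect_identical(b[["absorbed"]], 0)
  expect_lt(abs(b[["reflected"]] + b[["transmitted"]] + b[["side_escaped"]] - 1),
            1e-3)
  expect_identical(run$absorption$absorbed_fraction, 0)
})

test_that("a vacuum phantom carries the collimated beam profile unchanged", {
  g <- geometry(radius = 10, height = 5, n_r = 20, n_z = 5)
  med <- uniform_medium(g, 0, 0, 0, n = 1)
  run <- run_transport(med, beam = beam_spec(radius = 5),
                       settings = transport_settings(2e5, seed = 32,
                                                     n_outside = 1))
  # fluence inside the beam column equals the incident irradiance 1/(pi R^2)
  phi_beam <- run$fluence$phi[1:10, ]
  expect_equal(mean(phi_beam), 1 / (pi * 25), tolerance = 0.01)
  # and each depth layer is flat
  prof <- depth_profile(run$fluence)
  expect_lt(diff(range(prof$value)) / mean(prof$value), 0.01)
  # outside the beam: nothing
  expect_identical(sum(run$fluence$phi[15:20, ]), 0)
})

test_that("identical configuration and seed give bit-identical tallies", {
  g <- small_geom()
  med <- uniform_medium(g, 0.02, 1, 0.7, 1.34)
  r1 <- run_transport(med, beam = beam_spec(radius = 3),
                      settings = transport_settings(2e4, seed = 33))
  r2 <- run_transport(med, beam = beam_spec(radius = 3),
                      settings = transport_settings(2e4, seed = 33))
  expect_identical(r1$fluence$phi, r2$fluence$phi)
  expect_identical(r1$absorption$a_total, r2$absorption$a_total)
  expect_identical(r1$fluence$budget, r2$fluence$budget)
  r3 <- run_transport(med, beam = beam_spec(radius = 3),
                      settings = transport_settings(2e4, seed = 34))
  expect_false(identical(r1$fluence$phi, r3$fluence$phi))
})

test_that("adding a pure absorber never increases fluence beyond noise", {
  g <- small_geom()
  blank <- uniform_medium(g, 0.01, 0.5, 0.5, 1.34)
  doped <- uniform_medium(g, 0.06, 0.5, 0.5, 1.34)
  rb <- run_transport(blank, beam = beam_spec(radius = 4),
                      settings = transport_settings(1e5, seed = 41))
  rd <- run_transport(doped, beam = beam_spec(radius = 4),
                      settings = transport_settings(1e5, seed = 42))
  pooled <- sqrt(rb$fluence$stderr^2 + rd$fluence$stderr^2)
  expect_true(all(rd$fluence$phi <= rb$fluence$phi + 3 * pooled))
})

test_that("scattering prolongs the mean photon pathlength", {
  g <- small_geom()
  clear <- uniform_medium(g, 0.05, 0, 0, 1.34)
  turbid <- uniform_medium(g, 0.05, 1.0, 0, 1.34)
  rc <- run_transport(clear, beam = beam_spec(radius = 4),
                      settings = transport_settings(5e4, seed = 43))
  rt <- run_transport(turbid, beam = beam_spec(radius = 4),
                      settings = transport_settings(5e4, seed = 44))
  expect_gt(rt$fluence$mean_pathlength, rc$fluence$mean_pathlength)
  expect_gt(rt$fluence$mean_scatter_events, rc$fluence$mean_scatter_events)
})

test_that("degenerate beams, grids and settings are rejected", {
  expect_error(beam_spec(radius = 0), "positive")
  expect_error(geometry(n_r = 1), ">= 2")
  expect_error(transport_settings(n_photons = 10), ">= 1000")
  expect_error(transport_settings(w_min = 0), "w_min")
  expect_error(run_transport(list()), "medium")
})
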