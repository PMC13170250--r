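# Enhancement maps, masking discipline and depth profiles.

test_that("identical runs give an identity enhancement map", {
  g <- small_geom()
  med <- uniform_medium(g, 0.02, 0.5, 0.5, 1.34)
  r1 <- run_transport(med, beam = beam_spec(radius = 4),
                      settings = quick_settings(seed = 51))
  r2 <- run_transport(med, beam = beam_spec(radius = 4),
                      settings = quick_settings(seed = 51))
  em <- enhancement_map(r1$fluence, r2$fluence)
  expect_true(all(em$e[em$valid_mask] == 1))
  expect_equal(em$summary$median_volume, 1)
  am <- absorption_enhancement_map(r1$absorption, r2$absorption)
  expect_true(all(am$e[am$valid_mask] == 1))
})

test_that("grid mismatch is rejected before any ratio is formed", {
  med1 <- uniform_medium(small_geom(), 0.02, 0.5, 0.5, 1.34)
  med2 <- uniform_medium(small_geom(n_z = 10), 0.02, 0.5, 0.5, 1.34)
  r1 <- run_transport(med1, beam = beam_spec(radius = 4),
                      settings = quick_settings(n = 5e3, seed = 52))
  r2 <- run_transport(med2, beam = beam_spec(radius = 4),
                      settings = quick_settings(n = 5e3, seed = 53))
  expect_error(enhancement_map(r1$fluence, r2$fluence), "identical grids")
})

test_that("a reference with no absorbed power yields an all-invalid mask", {
  g <- small_geom()
  case <- run_transport(uniform_medium(g, 0.05, 0.5, 0, 1.34),
                        beam = beam_spec(radius = 4),
                        settings = quick_settings(n = 5e3, seed = 54))
  ref <- run_transport(uniform_medium(g, 0, 0.5, 0, 1.34),
                       beam = beam_spec(radius = 4),
                       settings = quick_settings(n = 5e3, seed = 55))
  am <- absorption_enhancement_map(case$absorption, ref$absorption)
  expect_identical(am$summary$n_valid, 0L)
  expect_true(is.na(am$summary$median_volume))
  expect_true(all(is.na(am$e)))
})

test_that("no ratio is reported where the reference is indistinguishable from zero", {
  g <- geometry(radius = 10, height = 20, n_r = 20, n_z = 40)
  # a strong absorber starves the deep voxels of the reference
  ref <- run_transport(uniform_medium(g, 0.8, 0.1, 0.9, 1.34),
                       beam = beam_spec(radius = 4),
                       settings = quick_settings(n = 2e4, seed = 56))
  case <- run_transport(uniform_medium(g, 0.8, 0.5, 0.0, 1.34),
                        beam = beam_spec(radius = 4),
                        settings = quick_settings(n = 2e4, seed = 57))
  em <- enhancement_map(case$fluence, ref$fluence, floor_sigma = 10)
  expect_lt(em$summary$n_valid, length(em$e))
  expect_true(all(is.na(em$e[!em$valid_mask])))
  expect_true(all(ref$fluence$phi[em$valid_mask] >
                  10 * ref$fluence$stderr[em$valid_mask]))
})

test_that("enhancement ratios chain consistently: (A/B)(B/C) = (A/C)", {
  g <- small_geom()
  media <- phantom_media(g)
  bm <- beam_spec(radius = 4)
  ra <- run_transport(media$scatterer, beam = bm, settings = quick_settings(5e4, 61))
  rb <- run_transport(media$blank, beam = bm, settings = quick_settings(5e4, 62))
  rc <- run_transport(media$absorber, beam = bm, settings = quick_settings(5e4, 63))
  ab <- enhancement_map(ra$fluence, rb$fluence)
  bc <- enhancement_map(rb$fluence, rc$fluence)
  ac <- enhancement_map(ra$fluence, rc$fluence)
  joint <- ab$valid_mask & bc$valid_mask & ac$valid_mask
  lhs <- ab$e[joint] * bc$e[joint]
  rhs <- ac$e[joint]
  pooled <- rhs * sqrt((ab$stderr[joint] / ab$e[joint])^2 +
                       (bc$stderr[joint] / bc$e[joint])^2 +
                       (ac$stderr[joint] / ac$e[joint])^2)
  expect_true(mean(abs(lhs - rhs) <= 4 * pooled) > 0.99)
})

test_that("depth profile of a clear absorber matches Beer-Lambert within 2%", {
  g <- geometry(radius = 10, height = 6, n_r = 20, n_z = 12)
  run <- run_transport(uniform_medium(g, 0.5, 0, 0, 1),
                       beam = beam_spec(radius = 5),
                       settings = transport_settings(5e5, seed = 64,
                                                     n_outside = 1))
  prof <- depth_profile(run$fluence)
  expect_true(all(diff(prof$z) > 0))
  expected <- exp(-0.5 * prof$z) / (pi * 25)
  expect_lt(max(abs(prof$value / expected - 1)), 0.02)
})

test_that("profile ratios agree with the laterally averaged enhancement profile", {
  g <- small_geom()
  media <- phantom_media(g)
  bm <- beam_spec(radius = 4)
  rs <- run_transport(media$scatterer, beam = bm, settings = quick_settings(5e4, 65))
  rb <- run_transport(media$blank, beam = bm, settings = quick_settings(5e4, 66))
  ep <- enhancement_profile(rs$fluence, rb$fluence)
  ps <- depth_profile(rs$fluence)
  pb <- depth_profile(rb$fluence)
  ok <- is.finite(ep$e)
  expect_equal(ep$e[ok], (ps$value / pb$value)[ok], tolerance = 1e-12)
  # scatterer beats blank near the entry side
  expect_true(all(ep$e[ep$z <= 2] > 1))
})

test_that("near the entry the fluence ordering is scatterer >= combined >= absorber", {
  g <- geometry(radius = 15, height = 20, n_r = 30, n_z = 20)
  media <- phantom_media(g)
  bm <- beam_spec(radius = 5)
  runs <- lapply(list(media$scatterer, media$combined, media$absorber),
                 function(m) run_transport(m, beam = bm,
                                           settings = quick_settings(1e5, 67)))
  profs <- lapply(runs, function(r) depth_profile(r$fluence))
  entry <- profs[[1]]$z <= 2
  for (pair in list(c(1, 2), c(2, 3))) {
    d <- profs[[pair[1]]]$value[entry] - profs[[pair[2]]]$value[entry]
    pooled <- sqrt(profs[[pair[1]]]$stderr[entry]^2 +
                   profs[[pair[2]]]$stderr[entry]^2)
    expect_true(all(d >= 3 * pooled))
  }
})
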