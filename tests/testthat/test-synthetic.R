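# Synthetic study generator: AIF shapes, tissue curves, study layout,
# T1-to-concentration conversion.

test_that("Weibull AIF peaks at the analytic mode and obeys amplitude/delay", {
  grid <- time_grid(interval = 0.001, n_points = 6001, unit = "min")
  k <- 3; c <- 1.8498
  cp <- generate_aif_curve(aif_weibull(k, c), grid)
  mode_analytic <- c * ((k - 1) / k)^(1 / k)   # 1.616 min
  expect_equal(grid$times[which.max(cp$values)], mode_analytic,
               tolerance = 1e-3)
  expect_true(all(cp$values >= 0))

  zero <- generate_aif_curve(aif_weibull(k, c, amplitude = 0), grid)
  expect_true(all(zero$values == 0))

  delayed <- generate_aif_curve(aif_weibull(k, c, delay = 0.5), grid)
  expect_equal(grid$times[which.max(delayed$values)],
               grid$times[which.max(cp$values)] + 0.5, tolerance = 2e-3)
  expect_true(all(delayed$values[grid$times < 0.5] == 0))
})

test_that("invalid AIF parameters are rejected by name", {
  expect_error(aif_weibull(k = -1), "k")
  expect_error(aif_weibull(c = 0), "c")
  expect_error(aif_biexp(a1 = 0, a2 = 1, m1 = 1, m2 = 1), "a1")
  expect_error(aif_weibull(delay = -1), "delay")
})

test_that("tissue curves follow the two-compartment convolution", {
  fx <- biexp_fixture()
  ct <- tissue_response(fx$cp, fx$k1, fx$k2)
  expect_lt(max(abs(ct$values - fx$ct_closed)), 1e-6)

  # K1 = 0 gives the zero curve; K2 = 0 gives K1 x cumulative integral
  expect_true(all(tissue_response(fx$cp, 0, 0.3)$values == 0))
  ct0 <- tissue_response(fx$cp, 0.25, 0)
  cum <- c(0, pracma::cumtrapz(fx$cp$times, fx$cp$values)[-1])
  expect_equal(ct0$values, 0.25 * cum, tolerance = 1e-8)
})

test_that("convolution error falls ~4x when the grid spacing halves", {
  e1 <- {
    fx <- biexp_fixture(dt = 0.04)
    max(abs(tissue_response(fx$cp, fx$k1, fx$k2)$values - fx$ct_closed))
  }
  e2 <- {
    fx <- biexp_fixture(dt = 0.02)
    max(abs(tissue_response(fx$cp, fx$k1, fx$k2)$values - fx$ct_closed))
  }
  expect_gt(e1 / e2, 3.3)
  expect_lt(e1 / e2, 4.7)
})

test_that("noisy tissue curves are reproducible and validated", {
  grid <- study_grid()
  cp <- generate_aif_curve(aif_weibull(amplitude = 5), grid)
  a <- generate_tissue_curve(cp, 0.3, 0.1, noise_sd = 0.05, seed = 9)
  b <- generate_tissue_curve(cp, 0.3, 0.1, noise_sd = 0.05, seed = 9)
  expect_identical(a$values, b$values)
  clean <- generate_tissue_curve(cp, 0.3, 0.1, noise_sd = 0)
  expect_false(identical(a$values, clean$values))
  expect_error(generate_tissue_curve(cp, 0.3, 0.1, noise_sd = -1),
               "noise_sd")
  expect_error(tissue_response(cp, -0.1, 0.2), "k1")
})

test_that("simulated studies match the acquisition layout and are seeded", {
  st <- simulate_study(study_config(seed = 5))
  expect_length(st$patients, 12L)
  ids <- vapply(st$patients, `[[`, "", "patient_id")
  expect_length(unique(ids), 12L)
  p <- st$patients[[1]]
  expect_length(p$cp$times, 46L)
  expect_equal(max(p$cp$times) * 60, 535.5)   # 45 intervals of 11.9 s
  expect_true(all(p$k1 >= 0.1 & p$k1 <= 1.1))

  st2 <- simulate_study(study_config(seed = 5))
  expect_identical(st, st2)
  st3 <- simulate_study(study_config(seed = 6))
  expect_false(identical(st$patients[[1]]$ctis$values,
                         st3$patients[[1]]$ctis$values))
})

test_that("baseline frames delay the AIF onset", {
  st <- simulate_study(study_config(n_patients = 1, baseline_frames = 4,
                                    seed = 2))
  cp <- st$patients[[1]]$cp
  expect_true(all(cp$values[1:4] == 0))
  expect_gt(cp$values[10], 0)
})

test_that("T1 conversion matches the relaxivity formula", {
  expect_equal(conc_from_t1(1.0, 1.0), 0)
  expect_equal(conc_from_t1(0.5, 1.0, r1 = 4.24), (1 / 4.24) * (2 - 1),
               tolerance = 1e-12)
  expect_equal(round(conc_from_t1(0.5, 1.0, 4.24), 4), 0.2358)
  # monotone decreasing in t1_t
  expect_gt(conc_from_t1(0.25, 1.0), conc_from_t1(0.5, 1.0))
  expect_error(conc_from_t1(-0.5, 1.0), "t1_t")
  expect_error(conc_from_t1(0.5, 0), "t10")
})

test_that("time grids and series validate their invariants", {
  expect_error(time_grid(interval = 0, n_points = 5), "interval")
  expect_error(time_grid(interval = 1, n_points = 1), "n_points")
  expect_error(conc_ts(c(0, 1, 1), c(1, 2, 3)), "increasing")
  expect_error(conc_ts(c(0, 1), c(1, NA)), "finite")
  g <- time_grid(interval = 11.9, n_points = 46)
  expect_equal(diff(g$times)[1] * 60, 11.9)
})
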