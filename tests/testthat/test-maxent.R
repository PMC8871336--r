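# Maximum-entropy density fitting: moments, multiplier solving, evaluation,
# blind AIF estimation.

test_that("empirical moments are plain averages with forced normalization", {
  mc <- empirical_moments(c(1, 2, 3), list(known_fun("identity")))
  expect_equal(mc$values, c(1, 2))
  expect_equal(empirical_moments(c(1, 1, 1), list(known_fun("log")))$values[2],
               0)
  expect_equal(empirical_moments(c(1, 2), list(known_fun("power", 3)))$values[2],
               4.5)
  expect_error(empirical_moments(c(1, -2, 3), list(known_fun("log"))),
               "index: 2")
})

test_that("mean constraint on [0, 60] recovers the exponential closed form", {
  mc <- make_constraints(c("const", "identity"), c(1, 2))
  for (slv in c("dual_descent", "tlbo")) {
    fit <- maxent_solve(mc, c(0, 60), solver = slv,
                        control = list(seed = 4))
    expect_true(fit$converged)
    expect_lte(max(abs(fit$residuals)), 1e-5)
    expect_equal(unname(coef(fit)), c(log(2), 0.5), tolerance = 1e-4)
    xs <- seq(0, 60, length.out = 1000)
    expect_lt(max(abs(predict(fit, xs) - dexp(xs, rate = 0.5))), 1e-3)
    expect_equal(predict(fit, 0), 0.5, tolerance = 1e-3)
  }
})

test_that("mean and second-moment constraints recover the standard normal", {
  mc <- make_constraints(c("const", "identity", "power"), c(1, 0, 1),
                         p = list(NULL, NULL, 2))
  for (slv in c("dual_descent", "tlbo")) {
    fit <- maxent_solve(mc, c(-8, 8), solver = slv, control = list(seed = 4))
    expect_lte(max(abs(fit$residuals)), 1e-5)
    expect_equal(unname(coef(fit)), c(0.5 * log(2 * pi), 0, 0.5),
                 tolerance = 1e-4)
    xs <- seq(-8, 8, length.out = 1000)
    expect_lt(max(abs(predict(fit, xs) - dnorm(xs))), 1e-3)
  }
})

test_that("no constraints beyond normalization gives the uniform density", {
  mc <- make_constraints("const", 1)
  fit <- maxent_solve(mc, c(0, 1))
  expect_equal(predict(fit, 0.5), 1, tolerance = 1e-10)
  expect_equal(predict(fit, c(-0.1, 1.1)), c(0, 0))
})

test_that("returned densities are normalized and satisfy their constraints", {
  set.seed(7)
  for (x in list(rweibull(400, 2, 1), rgamma(400, 3, 2), runif(400, 1, 4))) {
    fit <- maxent(x)
    g <- aifmem:::simpson_grid(fit$support)
    expect_equal(sum(g$w * predict(fit, g$x)), 1, tolerance = 1e-6)
    # re-evaluate G_k(lambda) - mu_k independently of the solver path
    for (k in seq_along(fit$functions)) {
      Gk <- sum(g$w * kf_eval(fit$functions[[k]], g$x) * predict(fit, g$x))
      expect_lt(abs(Gk - fit$constraints$values[k]), 1e-5)
    }
  }
})

test_that("adding a constraint never increases the fitted entropy", {
  set.seed(21)
  x <- rweibull(1000, 2.6, 1.738)
  supp <- c(max(1e-6, 0.5 * min(x)), 1.5 * max(x))
  nested <- list(
    list(known_fun("log")),
    list(known_fun("log"), known_fun("power", 3)),
    list(known_fun("log"), known_fun("power", 3), known_fun("identity")))
  ents <- vapply(nested, function(fns) {
    fit <- maxent(x, functions = fns, support = supp)
    density_entropy(fit, supp)
  }, numeric(1))
  expect_true(all(diff(ents) <= 1e-8))
})

test_that("infeasible constraints fail loudly with residuals attached", {
  # mean far above anything attainable on [0, 1]
  mc <- make_constraints(c("const", "identity"), c(1, 5))
  expect_warning(fit <- maxent_solve(mc, c(0, 1), control = list(max_iter = 50)),
                 "residual")
  expect_false(fit$converged)
  expect_true(max(abs(fit$residuals)) > 1e-5)
})

test_that("support validation protects log-type functions", {
  mc <- make_constraints(c("const", "log"), c(1, 0))
  expect_error(maxent_solve(mc, c(0, 1)), "support")
  expect_error(maxent_solve(mc, c(2, 1)), "support")
})

test_that("blind AIF density fit stays close to the generating Weibull", {
  set.seed(42)
  x <- rweibull(2000, 2.6, 1.738)
  fit <- fit_aif_density(x)
  expect_true(fit$density$converged)
  kl <- kl_divergence(fit$density, weibull_dist(2.6, 1.738),
                      fit$density$support)
  expect_lt(kl, 0.05)
  expect_length(fit$aif, length(x))   # value mode: one estimate per input
})

test_that("AIF fitting modes honour their contracts", {
  grid <- study_grid()
  cp <- generate_aif_curve(aif_weibull(amplitude = 5), grid)
  suppressMessages(fit <- fit_aif_density(cp))   # zero-level samples dropped
  expect_s3_class(fit$aif, "conc_ts")
  expect_length(fit$aif$values, length(cp$values))
  expect_equal(fit$n_excluded,
               sum(cp$values <= 1e-3 * max(cp$values)))
  expect_true(fit$density$converged)
  # rescaling matches the measured curve's time integral
  expect_equal(pracma::trapz(fit$aif$times, fit$aif$values),
               pracma::trapz(cp$times, cp$values), tolerance = 1e-8)

  # constant curve under time mode: uniform weights, flat estimated AIF
  flat <- conc_ts(grid$times, rep(2, 46))
  tfit <- fit_aif_density(flat, functions = list(known_fun("identity")),
                          mode = "time_density",
                          control = list(seed = 1))
  inner <- tfit$aif$values[3:44]
  expect_lt(diff(range(inner)) / mean(inner), 0.25)
})

test_that("maxent JSON serialization round-trips the multipliers", {
  set.seed(3)
  fit <- maxent(rweibull(300, 3, 2))
  path <- tempfile(fileext = ".json")
  maxent_to_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$lambdas, unname(fit$lambdas), tolerance = 1e-12)
  expect_equal(back$support, fit$support)
  expect_identical(back$converged, fit$converged)
})
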