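test_that("z-scores match direct arithmetic on printed-style summaries", {
  # Fulton's K at 22 degC vs the 19 degC control
  expect_equal(z_score(1.43, 0.03, 1.32, 0.04), 2.2)
  # CS at 28 degC (a declining biomarker)
  expect_equal(z_score(0.0028, 0.0004, 0.0054, 0.0011), -2.22133,
               tolerance = 1e-5)
  expect_equal(z_score(5, 0.1, 5, 0.2), 0)
  expect_equal(z_score(5, 0, 5, 0), 0) # equal means, both SEs zero
  expect_error(z_score(5, 0, 6, 0), "undefined")
})

test_that("the psi transform honours clipping, direction and one-sided credit", {
  eps <- 1e-6
  expect_equal(psi_transform(0), 1 - eps)
  expect_equal(psi_transform(2.2), exp(-2.2))
  expect_equal(psi_transform(-2.2213, "harmful_increase"), exp(-2.2213))
  # one-sided mode credits beneficial deviations (declining harmful trait,
  # rising performance trait) and penalises harmful-direction deviations
  expect_equal(psi_transform(-2.2213, "harmful_increase", one_sided = TRUE),
               1 - eps)
  expect_equal(psi_transform(2.2213, "harmful_increase", one_sided = TRUE),
               exp(-2.2213))
  expect_equal(psi_transform(2.2, one_sided = TRUE), 1 - eps)
  expect_equal(psi_transform(-2.2, one_sided = TRUE), exp(-2.2))
  # huge deviations clip at epsilon
  expect_equal(psi_transform(100), eps)
  # sign symmetry of the default transform
  z <- seq(-10, 10, by = 0.25)
  expect_equal(psi_transform(z), psi_transform(-z))
  expect_error(psi_transform(1, epsilon = 0.7), "epsilon")
  expect_error(psi_transform(1, direction = "up"), "direction")
})

test_that("beta shapes reproduce the mean/precision parameterisation", {
  expect_equal(beta_shapes(0.5, 10), tibble::tibble(p = 5, q = 5))
  expect_equal(beta_shapes(0.2, 50), tibble::tibble(p = 10, q = 40))
  expect_error(beta_shapes(0, 10), "inside")
  expect_error(beta_shapes(0.5, 0), "positive")

  # Monte-Carlo check of induced mean and variance
  set.seed(2)
  sh <- beta_shapes(0.2, 50)
  x <- rbeta(2e5, sh$p, sh$q)
  expect_lt(abs(mean(x) - 0.2), 3 * sqrt(0.2 * 0.8 / 51 / 2e5))
  expect_lt(abs(var(x) - 0.2 * 0.8 / 51), 2e-4)
})

test_that("thriving observations anchor the control and invert harmful traits", {
  s <- make_summaries(means = c(10, 10, 10, 10), ses = c(1, 1, 1, 1))
  obs <- thriving_observations(s, directions = c(tr = "benign_deviation"))
  # a trait identical to its control thrives everywhere
  expect_equal(obs$psi, rep(1 - 1e-6, 4))
  expect_equal(obs$temperature, c(19, 22, 24, 28))

  s2 <- make_summaries(means = c(10, 12, 14, 16), ses = rep(1, 4))
  benign <- thriving_observations(s2, directions = c(tr = "benign_deviation"))
  harmful <- thriving_observations(s2, directions = c(tr = "harmful_increase"))
  # symmetric transform: direction inversion is numerically inert
  expect_equal(benign$psi, harmful$psi)
  expect_true(all(harmful$direction_applied[harmful$trait_id == "tr"]))
  # one-sided: increases of a harmful trait are penalised, not credited
  harm1 <- thriving_observations(s2, directions = c(tr = "harmful_increase"),
                                 one_sided = TRUE)
  expect_true(all(harm1$psi[harm1$temperature > 19] < 0.5))

  expect_equal(nrow(thriving_observations(s2, include_control = FALSE)), 3)
})

test_that("psi observations always respect the epsilon bounds", {
  cal <- default_calibration()
  ds <- simulate_traits(design_spec(), cal, seed = 31)
  sm <- summarize_traits(
    dplyr::filter(ds$trait_table, trait_id %in% thriving_traits()),
    control_temp = 19
  )
  obs <- thriving_observations(sm)
  expect_true(all(obs$psi >= 1e-6 & obs$psi <= 1 - 1e-6))
  # 14 traits x (control anchor + 3 treatments x 2 tanks)
  expect_equal(nrow(obs), 14 * 7)
})

test_that("the sub-model recovers parameters simulated from itself", {
  d <- simulate_submodel_data(n = 60, a0 = 6, a1 = -0.25, phi = 25, seed = 17)
  fit <- fit_submodel(d, seed = 17, quiet = TRUE)
  td <- tidy(fit)
  expect_true(all(td$rhat < 1.1))
  truth <- c(a0 = 6, a1 = -0.25, phi = 25)
  for (p in names(truth)) {
    row <- td[td$term == p, ]
    expect_gt(truth[[p]], row$conf.low)
    expect_lt(truth[[p]], row$conf.high)
  }
  # predicted curve tracks the true inverse-logit curve
  cv <- predict_curve(fit)
  truth_curve <- plogis(6 - 0.25 * cv$temperature)
  expect_lt(max(abs(cv$psi_mean - truth_curve)), 0.05)
})

test_that("flat psi data concentrate the slope near zero", {
  d <- tibble::tibble(
    trait_id = "flat",
    temperature = rep(c(19, 22, 24, 28), each = 5),
    psi = rep(0.5, 20)
  )
  fit <- fit_submodel_fast(d, seed = 3)
  a1 <- fit$draws$a1
  expect_lt(abs(mean(a1)), 2 * sd(a1))
})

test_that("the split-chain diagnostic sits near 1 for well-mixed chains", {
  set.seed(5)
  iid <- matrix(rnorm(8000), ncol = 4)
  expect_lt(split_rhat(iid), 1.01)
  # four identical chains: between-chain variance only from the split halves
  one <- rnorm(2000)
  expect_lt(split_rhat(cbind(one, one, one, one)), 1.01)
  # stuck chain at a different level is flagged
  bad <- cbind(rnorm(1000), rnorm(1000) + 5)
  expect_gt(split_rhat(bad), 1.5)
  # degenerate constant chains
  expect_equal(split_rhat(matrix(1, 100, 3)), 1)
})

test_that("MCMC fits are reproducible under a fixed seed", {
  d <- simulate_submodel_data(n = 20, seed = 9)
  f1 <- fit_submodel_fast(d, seed = 77)
  f2 <- fit_submodel_fast(d, seed = 77)
  expect_equal(f1$draws, f2$draws)
})

test_that("curve prediction honours logit identities and guards", {
  d <- simulate_submodel_data(n = 40, a0 = 6, a1 = -0.25, seed = 12)
  fit <- fit_submodel_fast(d, seed = 12)
  # if every draw has a negative slope, the mean curve is decreasing
  if (all(fit$draws$a1 < 0)) {
    cv <- predict_curve(fit)
    expect_true(all(diff(cv$psi_mean) < 0))
  }
  # a point where a0 + a1 T = 0 for all draws maps to psi = 0.5
  fixed <- fit
  fixed$draws$a0 <- 6
  fixed$draws$a1 <- -0.25
  expect_equal(predict_curve(fixed, grid = 24)$psi_mean, 0.5)
  expect_error(predict_curve(fit, grid = numeric()), "empty")
  expect_error(predict_curve(fit, grid = c(10, 20)), "beyond")
})

test_that("sub-model input contracts are enforced", {
  expect_error(
    fit_submodel(tibble::tibble(temperature = c(19, 22), psi = c(0.5, 0.4))),
    "3 observations"
  )
  expect_error(
    fit_submodel(tibble::tibble(temperature = rep(19, 5), psi = runif(5))),
    "2 temperatures"
  )
  expect_error(
    fit_submodel(tibble::tibble(temperature = c(19, 22, 24), psi = c(0.5, 1, 0.4))),
    "inside"
  )
})
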