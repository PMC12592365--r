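test_that("pooling emits one datum per trait per grid point", {
  curves <- dplyr::bind_rows(lapply(paste0("t", 1:14), make_curve))
  pooled <- pool_curves(curves)
  expect_equal(nrow(pooled), 14 * 91)
  expect_setequal(names(pooled), c("trait_id", "temperature", "psi"))

  flat <- dplyr::bind_rows(
    make_curve("a", a0 = qlogis(0.8), a1 = 0),
    make_curve("b", a0 = qlogis(0.8), a1 = 0)
  )
  expect_true(all(pool_curves(flat)$psi == 0.8))

  expect_error(pool_curves(make_curve("solo")), "2 trait curves")
  bad <- dplyr::bind_rows(
    make_curve("a"), make_curve("b", grid = seq(19, 28, by = 0.5))
  )
  expect_error(pool_curves(bad), "mismatched")
})

test_that("the beta GAM recovers a known inverse-logit curve within 0.05", {
  set.seed(101)
  n <- 500
  temp <- runif(n, 19, 28)
  mu <- plogis(10 - 0.45 * temp)
  d <- tibble::tibble(temperature = temp,
                      psi = rbeta(n, mu * 100, (1 - mu) * 100))
  ic <- fit_integrated_gam(d)
  truth <- plogis(10 - 0.45 * ic$curve$temperature)
  expect_lt(max(abs(ic$curve$psi_fit - truth)), 0.05)
  expect_true(all(ic$curve$psi_fit > 0 & ic$curve$psi_fit < 1))
})

test_that("constant data give a constant fit (intercept-only limit)", {
  set.seed(7)
  d <- tibble::tibble(
    temperature = runif(200, 19, 28),
    psi = pmin(pmax(rbeta(200, 0.7 * 200, 0.3 * 200), 1e-6), 1 - 1e-6)
  )
  ic <- fit_integrated_gam(d)
  expect_true(all(abs(ic$curve$psi_fit - 0.7) < 0.02))
})

test_that("two traits symmetric about 0.5 pool to a flat 0.5 curve", {
  up <- make_curve("up", a0 = -11.75, a1 = 0.5) # increasing
  down <- make_curve("down", a0 = 11.75, a1 = -0.5) # its mirror image
  pooled <- pool_curves(dplyr::bind_rows(up, down))
  ic <- fit_integrated_gam(pooled)
  expect_true(all(abs(ic$curve$psi_fit - 0.5) < 0.05))
})

test_that("an infinite smoothing penalty collapses to the logit-linear fit", {
  set.seed(33)
  temp <- runif(300, 19, 28)
  mu <- plogis(8 - 0.35 * temp)
  d <- tibble::tibble(temperature = temp,
                      psi = rbeta(300, mu * 60, (1 - mu) * 60))
  heavy <- mgcv::gam(
    psi ~ s(temperature, k = 5, bs = "cr"), sp = 1e9,
    family = mgcv::betar(link = "logit"), data = d
  )
  linear <- mgcv::gam(
    psi ~ temperature,
    family = mgcv::betar(link = "logit"), data = d
  )
  grid <- data.frame(temperature = seq(19, 28, by = 0.1))
  ph <- plogis(as.numeric(mgcv::predict.gam(heavy, grid, type = "link")))
  pl <- plogis(as.numeric(mgcv::predict.gam(linear, grid, type = "link")))
  expect_lt(max(abs(ph - pl)), 0.01)
})

test_that("habitat classification partitions the grid at the threshold", {
  grid <- seq(19, 28, by = 0.1)
  curve <- tibble::tibble(
    temperature = grid, psi_fit = plogis(0.5 * (23.7 - grid))
  )
  cl <- classify_habitat(curve)
  expect_equal(cl$intervals$habitat, c("hotspot", "occasional"))
  expect_equal(cl$intervals$from, c(19, 23.8))
  expect_equal(cl$intervals$to, c(23.7, 28))
  expect_equal(cl$crossings, 23.7)
  expect_equal(hotspot_upper_bound(cl), 23.7)

  # partition covers the grid exactly once
  n_pts <- sum(vapply(seq_len(nrow(cl$intervals)), function(i) {
    sum(grid >= cl$intervals$from[i] & grid <= cl$intervals$to[i])
  }, numeric(1)))
  expect_equal(n_pts, length(grid))

  # curve entirely above the threshold -> no occasional class
  all_hot <- classify_habitat(tibble::tibble(temperature = grid, psi_fit = 0.9))
  expect_identical(all_hot$intervals$habitat, "hotspot")
  expect_length(all_hot$crossings, 0)
  expect_true(is.na(hotspot_upper_bound(
    classify_habitat(tibble::tibble(temperature = grid, psi_fit = 0.1))
  )))
})

test_that("raising the threshold never enlarges the hotspot set", {
  grid <- seq(19, 28, by = 0.1)
  curve <- tibble::tibble(
    temperature = grid,
    psi_fit = 0.5 + 0.4 * sin((grid - 19) / 2) # non-monotone
  )
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    cl <- classify_habitat(curve, threshold = th)
    hs <- cl$intervals[cl$intervals$habitat == "hotspot", ]
    if (nrow(hs) == 0) 0 else sum(hs$to - hs$from)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("non-monotone curves produce interval unions with matching crossings", {
  grid <- seq(19, 28, by = 0.1)
  curve <- tibble::tibble(
    temperature = grid,
    psi_fit = 0.5 + 0.3 * sin(2 * pi * (grid - 19) / 4.5)
  )
  cl <- classify_habitat(curve)
  expect_gt(nrow(cl$intervals), 2)
  expect_equal(length(cl$crossings), nrow(cl$intervals) - 1)
})

test_that("GAM input contracts are enforced", {
  expect_error(
    fit_integrated_gam(tibble::tibble(temperature = 19, psi = 0.5)),
    "10 data points"
  )
  expect_error(
    fit_integrated_gam(tibble::tibble(temperature = rep(20, 20),
                                      psi = runif(20, 0.2, 0.8))),
    "single temperature"
  )
  expect_error(
    fit_integrated_gam(tibble::tibble(temperature = runif(20, 19, 28),
                                      psi = c(1, runif(19, 0.2, 0.8)))),
    "inside"
  )
})
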