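test_that("identical design, calibration and seed give identical tables", {
  cal <- default_calibration()
  d <- design_spec()
  a <- simulate_traits(d, cal, seed = 11)
  b <- simulate_traits(d, cal, seed = 11)
  expect_identical(a$trait_table, b$trait_table)
  c <- simulate_traits(d, cal, seed = 12)
  expect_false(identical(a$trait_table$value, c$trait_table$value))
})

test_that("zero calibrated se collapses a cell to its mean", {
  cal <- tibble::tibble(
    trait_id = "flat", treatment = c(19, 22), mean = c(5, 7), se = 0,
    n_ref = 10L, family = "normal", direction = "benign_deviation",
    source = "chosen"
  )
  d <- design_spec(treatments = c(19, 22), control_temp = 19, tank_cv = 0)
  ds <- simulate_traits(d, cal, seed = 3)
  vals <- split(ds$trait_table$value, ds$trait_table$treatment)
  expect_true(all(vals[["19"]] == 5))
  expect_true(all(vals[["22"]] == 7))
})

test_that("simulated treatment means track the calibration (moment fidelity)", {
  cal <- default_calibration()
  n_big <- stats::setNames(
    rep(2000L, length(unique(cal$trait_id))), unique(cal$trait_id)
  )
  ds <- simulate_traits(design_spec(tank_cv = 0), cal, seed = 42,
                        n_per_trait = n_big)
  chk <- dplyr::summarise(
    dplyr::group_by(ds$trait_table, trait_id, treatment),
    m = mean(value), se_sim = stats::sd(value) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  chk <- dplyr::left_join(
    chk, dplyr::select(cal, trait_id, treatment, cmean = mean),
    by = c("trait_id", "treatment")
  )
  # 3 standard errors, with a small absolute floor for near-degenerate
  # cells (e.g. the 0.01-s shelter mean, where most draws are exactly 0)
  tol <- pmax(3 * chk$se_sim, 0.02)
  expect_true(
    all(abs(chk$m - chk$cmean) <= tol),
    info = paste(
      chk$trait_id[abs(chk$m - chk$cmean) > tol],
      chk$treatment[abs(chk$m - chk$cmean) > tol],
      collapse = ", "
    )
  )
})

test_that("draws respect each family's support", {
  cal <- default_calibration()
  ds <- simulate_traits(design_spec(), cal, seed = 5)
  tt <- ds$trait_table
  counts <- tt[tt$trait_id %in% c("chase", "bite"), "value", drop = TRUE]
  expect_true(all(counts >= 0 & counts == round(counts)))
  dur <- tt[tt$trait_id %in% c("swim_time", "shelter_time"), "value", drop = TRUE]
  expect_true(all(dur >= 0 & dur <= 120 & dur == round(dur)))
  pos_traits <- unique(cal$trait_id[cal$family %in% c("gamma", "lognormal")])
  expect_true(all(tt$value[tt$trait_id %in% pos_traits] > 0))
  # every (treatment, tank) pair of the design appears
  expect_equal(nrow(unique(tt[, c("treatment", "tank")])), 8)
})

test_that("body-condition traits satisfy the per-fish condition identity", {
  ds <- simulate_traits(design_spec(), default_calibration(), seed = 8)
  wide <- tidyr::pivot_wider(
    dplyr::filter(ds$trait_table, trait_id %in%
                    c("weight", "total_length", "standard_length", "fulton_k")),
    id_cols = "fish_id", names_from = "trait_id", values_from = "value"
  )
  expect_equal(wide$fulton_k, 100 * wide$weight / wide$total_length^3,
               tolerance = 1e-12)
  expect_equal(wide$standard_length, wide$total_length / 1.22, tolerance = 1e-12)
})

test_that("compound Poisson-gamma draws match their mean and variance", {
  set.seed(21)
  x <- rtweedie(2e5, mean = 2, var = 2 * 2^1.5, index = 1.5)
  expect_gt(mean(x == 0), 0.05) # exact zeros occur
  expect_equal(mean(x), 2, tolerance = 3 * sqrt(2 * 2^1.5 / 2e5) / 2)
  expect_equal(stats::var(x), 2 * 2^1.5, tolerance = 0.1)
  expect_error(rtweedie(5, 2, 1, index = 2.5), "index")
})

test_that("noiseless O2 traces carry the exact analytic slope", {
  tr <- simulate_o2_trace(
    true_mo2 = 13.5, fish_mass = 0.008, chamber_volume = 0.300,
    tubing_volume = 0, fish_volume = 0, noise_sd = 0, seed = 1
  )
  # three 120-sample closed segments
  closed_n <- table(tr$cycle[tr$phase == "closed"])
  expect_equal(unname(as.integer(closed_n)), rep(120L, 3))
  for (k in 1:3) {
    s <- closed_phase_slope(tr, k)
    expect_equal(s$slope, -0.36, tolerance = 1e-10)
    expect_equal(s$r2, 1, tolerance = 1e-12)
  }
  # 9.5-min cycles at 1 Hz
  expect_equal(nrow(tr), 3 * 570)
  expect_true(all(diff(tr$time_s) == 1))
})

test_that("zero consumption gives a flat closed phase", {
  tr <- simulate_o2_trace(0, fish_mass = 0.008, noise_sd = 0, seed = 1)
  closed <- tr[tr$phase == "closed", ]
  expect_true(all(closed$o2_mg_per_l == closed$o2_mg_per_l[1]))
})

test_that("the generator refuses depleting or invalid parameter sets", {
  # >20% depletion while sealed
  expect_error(
    simulate_o2_trace(true_mo2 = 2000, fish_mass = 0.05, noise_sd = 0),
    "20%"
  )
  expect_error(simulate_o2_trace(10, 0.008, o2_start = 8), "6.5")
  expect_error(
    simulate_o2_trace(10, 0.5, chamber_volume = 0.3, fish_volume = 0.4),
    "effective volume"
  )
})

test_that("growth-pair generator is reproducible and respects its moments", {
  a <- simulate_growth_pairs(500, beta0 = 0.012, beta1 = 3.2, seed = 4)
  b <- simulate_growth_pairs(500, beta0 = 0.012, beta1 = 3.2, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$weight > 0 & a$standard_length > 0))
  expect_equal(mean(a$standard_length), 6, tolerance = 0.1)
})
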