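# shared fixtures and reduced MCMC schedule for module-level tests
# (acceptance tests use the full default schedule)

fast_schedule <- list(n_chains = 3, n_adapt = 500, n_burn = 1000, n_keep = 1000)

fit_submodel_fast <- function(obs, seed = 1L) {
  fit_submodel(
    obs,
    n_chains = fast_schedule$n_chains, n_adapt = fast_schedule$n_adapt,
    n_burn = fast_schedule$n_burn, n_keep = fast_schedule$n_keep,
    seed = seed, quiet = TRUE
  )
}

# beta-regression data simulated from the sub-model itself
simulate_submodel_data <- function(n = 60, a0 = 6, a1 = -0.25, phi = 25,
                                   tmin = 19, tmax = 28, seed = 1L) {
  set.seed(seed)
  temp <- runif(n, tmin, tmax)
  mu <- stats::plogis(a0 + a1 * temp)
  tibble::tibble(
    trait_id = "sim", temperature = temp,
    psi = stats::rbeta(n, mu * phi, (1 - mu) * phi)
  )
}

# minimal one-trait summary table with a control row
make_summaries <- function(means, ses, treatments = c(19, 22, 24, 28),
                           control = 19, trait = "tr", n = 10L) {
  tibble::tibble(
    trait_id = trait, treatment = treatments, tank = NA_character_,
    mean = means, se = ses, n = n, is_control = treatments == control
  )
}

# one respirometry run (fish + blank) with the chamber sized so the sealed
# 150-s phase depletes ~8% of the starting O2 — how chambers are matched to
# fish in practice, and what keeps closed-phase regressions above the R2 gate
respiro_run <- function(true_mo2, noise_sd, seed, fish_mass = 0.008,
                        background_slope = -0.03, depletion = 0.56) {
  slope_target <- depletion / 150 * 3600 # mg/L/h
  mass <- fish_mass
  v_eff <- true_mo2 * mass / slope_target
  tubing <- 0.005
  chamber <- v_eff + mass - tubing
  geometry <- tibble::tibble(
    chamber_id = c("fish", "blank"), is_blank = c(FALSE, TRUE),
    chamber_volume = chamber, tubing_volume = tubing,
    fish_mass = c(mass, 0), fish_volume = c(mass, 0)
  )
  traces <- dplyr::bind_rows(
    simulate_o2_trace(
      true_mo2, mass, chamber_volume = chamber, tubing_volume = tubing,
      noise_sd = noise_sd, background_slope = background_slope,
      chamber_id = "fish", seed = seed
    ),
    simulate_o2_trace(
      0, 0, chamber_volume = chamber, tubing_volume = tubing,
      noise_sd = noise_sd, background_slope = background_slope,
      chamber_id = "blank", seed = seed + 50000
    )
  )
  rmr(mo2_records(traces, geometry))$rmr
}

# fabricated monotone trait curve on the standard grid
make_curve <- function(trait, a0 = 12, a1 = -0.5, grid = seq(19, 28, by = 0.1)) {
  psi <- stats::plogis(a0 + a1 * grid)
  tibble::tibble(
    trait_id = trait, temperature = grid,
    psi_mean = psi, psi_lo = pmax(psi - 0.05, 1e-6), psi_hi = pmin(psi + 0.05, 1 - 1e-6)
  )
}
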