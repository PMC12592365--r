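#' Describe the rearing design to simulate
#'
#' @param treatments Treatment temperatures, degC, strictly increasing.
#' @param control_temp The control temperature; must be one of `treatments`.
#' @param tanks_per_treatment Number of replicate tanks per treatment.
#' @param weeks Length of the exposure, weeks (metadata only).
#' @param tank_cv Coefficient of variation of the multiplicative tank-level
#'   random effect on trait means (mirrors "aquarium as a random factor");
#'   set to 0 to disable.
#'
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(treatments = c(19, 22, 24, 28), control_temp = 19,
                        tanks_per_treatment = 2, weeks = 11, tank_cv = 0.05) {
  stopifnot(
    length(treatments) >= 1, !is.unsorted(treatments, strictly = TRUE),
    length(control_temp) == 1, control_temp %in% treatments,
    tanks_per_treatment >= 1, weeks >= 1, tank_cv >= 0
  )
  structure(
    list(
      treatments = treatments, control_temp = control_temp,
      tanks_per_treatment = as.integer(tanks_per_treatment),
      weeks = as.integer(weeks), tank_cv = tank_cv
    ),
    class = "design_spec"
  )
}

#' Simulate an individual-level trait table from a calibration
#'
#' Draws one value per fish (or per focal observation, for behavioural
#' traits) per trait, from the trait's sampling family, with the treatment
#' mean and a dispersion chosen so that the standard error of the treatment
#' mean at the calibration's reference sample size `n_ref` equals the
#' calibrated s.e.m. The per-fish standard deviation is therefore
#' `se * sqrt(n_ref)`, a property of the population that does not change
#' when a different number of fish is simulated.
#'
#' Families:
#' * `normal`, `lognormal`, `gamma`: moment-matched to (mean, sd).
#' * `duration`: integer seconds within the 120-s observation window, drawn
#'   as a beta-binomial count of seconds so the mean is exact and values
#'   respect the window; when the calibrated s.e.m. implies more dispersion
#'   than the window can hold, the intra-class correlation is capped at
#'   0.98 and the cell is flagged in the `dispersion_note` attribute.
#' * `compound_poisson_gamma`: Tweedie-type count process (index 1.5 by
#'   default) supporting exact zeros; draws are rounded to integer counts.
#'
#' Weight, total and standard length and Fulton's K are drawn jointly from
#' an allometric construction (length lognormal, weight a power law of
#' standard length with residual noise) so the per-fish identity
#' K = 100 W / TL^3 holds exactly; see [body_condition_params()].
#'
#' A multiplicative lognormal tank effect (CV `design$tank_cv`) perturbs
#' each tank's trait mean; control and test tanks are affected alike.
#'
#' @param design A [design_spec()].
#' @param calibration A calibration table from [default_calibration()].
#' @param seed Integer seed; identical inputs give identical tables.
#' @param n_per_trait Optional named integer vector overriding the
#'   per-treatment sample size for selected traits (defaults to each
#'   trait's `n_ref`).
#'
#' @return A list of class `synthetic_dataset` with elements `trait_table`
#'   (tibble: fish_id, tank, treatment, week, trait_id, value), `truth`
#'   (the calibration used) and `design`.
#' @export
#' @examples
#' ds <- simulate_traits(design_spec(tank_cv = 0), default_calibration(), seed = 1)
#' dplyr::count(ds$trait_table, trait_id)
simulate_traits <- function(design, calibration, seed = 1L, n_per_trait = NULL) {
  stopifnot(inherits(design, "design_spec"))
  check_calibration(calibration, design)
  set.seed(as.integer(seed))

  tw_index <- attr(calibration, "tweedie_index") %||% 1.5
  tw_phi <- attr(calibration, "tweedie_phi") %||% 2
  window <- attr(calibration, "duration_window_s") %||% 120

  trio <- c("weight", "total_length", "standard_length", "fulton_k")
  has_trio <- all(trio %in% calibration$trait_id)
  traits <- setdiff(unique(calibration$trait_id), if (has_trio) trio else character())

  tanks <- tidyr::expand_grid(
    treatment = design$treatments,
    tank_index = seq_len(design$tanks_per_treatment)
  )
  tanks$tank <- sprintf("T%g_%d", tanks$treatment, tanks$tank_index)
  # multiplicative tank effect, E[factor] = 1
  if (design$tank_cv > 0) {
    s2 <- log1p(design$tank_cv^2)
    tanks$tank_factor <- exp(stats::rnorm(nrow(tanks), -s2 / 2, sqrt(s2)))
  } else {
    tanks$tank_factor <- 1
  }

  notes <- character()
  n_for <- function(trait, n_ref) {
    n <- if (!is.null(n_per_trait) && trait %in% names(n_per_trait)) {
      n_per_trait[[trait]]
    } else {
      n_ref
    }
    as.integer(n)
  }
  split_n <- function(n, k) { # allocate n fish over k tanks as evenly as possible
    base <- n %/% k
    extra <- n %% k
    base + as.integer(seq_len(k) <= extra)
  }

  rows <- list()
  weeks_of <- function(trait) if (trait %in% c("swim_time", "shelter_time", "chase", "bite")) design$weeks else design$weeks

  # --- body condition trio ------------------------------------------------
  if (has_trio) {
    w_cal <- calibration[calibration$trait_id == "weight", ]
    k_cal <- calibration[calibration$trait_id == "fulton_k", ]
    b1 <- allometry_exponents()
    for (i in seq_along(design$treatments)) {
      tt <- design$treatments[i]
      wrow <- w_cal[w_cal$treatment == tt, ]
      krow <- k_cal[k_cal$treatment == tt, ]
      n_t <- n_for("weight", wrow$n_ref)
      tk <- tanks[tanks$treatment == tt, ]
      ns <- split_n(n_t, nrow(tk))
      for (j in seq_len(nrow(tk))) {
        bc <- simulate_body_condition(
          ns[j], wrow$mean * tk$tank_factor[j], krow$mean * tk$tank_factor[j],
          wrow$se * sqrt(wrow$n_ref), b1[i]
        )
        ids <- sprintf("%s_f%02d", tk$tank[j], seq_len(ns[j]))
        rows[[length(rows) + 1]] <- tibble::tibble(
          fish_id = rep(ids, 4),
          tank = tk$tank[j], treatment = tt, week = design$weeks,
          trait_id = rep(trio, each = ns[j]),
          value = c(bc$weight, bc$total_length, bc$standard_length, bc$fulton_k)
        )
      }
    }
  }

  # --- remaining traits, one family draw per tank -------------------------
  for (trait in traits) {
    cal_t <- calibration[calibration$trait_id == trait, ]
    for (i in seq_len(nrow(cal_t))) {
      tt <- cal_t$treatment[i]
      n_t <- n_for(trait, cal_t$n_ref[i])
      sd_t <- cal_t$se[i] * sqrt(cal_t$n_ref[i])
      tk <- tanks[tanks$treatment == tt, ]
      ns <- split_n(n_t, nrow(tk))
      for (j in seq_len(nrow(tk))) {
        mu <- cal_t$mean[i] * tk$tank_factor[j]
        dr <- draw_family(
          ns[j], mu, sd_t, cal_t$family[i],
          tweedie_index = tw_index, window = window
        )
        if (!is.null(dr$note)) {
          notes <- c(notes, sprintf("%s @ %g degC: %s", trait, tt, dr$note))
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          fish_id = sprintf("%s_%s_%02d", tk$tank[j], trait, seq_len(ns[j])),
          tank = tk$tank[j], treatment = tt, week = weeks_of(trait),
          trait_id = trait, value = dr$values
        )
      }
    }
  }

  trait_table <- dplyr::bind_rows(rows)
  out <- list(trait_table = trait_table, truth = calibration, design = design)
  attr(out, "dispersion_note") <- unique(notes)
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  cat("  traits:", length(unique(x$trait_table$trait_id)),
      " observations:", nrow(x$trait_table), "\n")
  cat("  treatments:", paste(x$design$treatments, collapse = "/"),
      "degC, control", x$design$control_temp, "degC\n")
  invisible(x)
}

#' @keywords internal
check_calibration <- function(calibration, design) {
  need <- c("trait_id", "treatment", "mean", "se", "n_ref", "family", "direction")
  if (!all(need %in% names(calibration))) {
    stop("calibration must have columns ", paste(need, collapse = ", "))
  }
  if (any(calibration$se < 0)) stop("calibration se must be non-negative")
  pos <- calibration$family %in% c("gamma", "lognormal")
  if (any(calibration$mean[pos] <= 0)) {
    stop("gamma/lognormal calibration means must be strictly positive")
  }
  miss <- dplyr::anti_join(
    tidyr::expand_grid(
      trait_id = unique(calibration$trait_id),
      treatment = design$treatments
    ),
    calibration,
    by = c("trait_id", "treatment")
  )
  if (nrow(miss) > 0) {
    stop(
      "calibration lacks entries for: ",
      paste(sprintf("%s@%g", miss$trait_id, miss$treatment), collapse = ", ")
    )
  }
  invisible(TRUE)
}

#' Draw one tank's values for a single (trait, treatment) cell
#' @keywords internal
draw_family <- function(n, mean, sd, family, tweedie_index = 1.5, window = 120) {
  if (n == 0) return(list(values = numeric()))
  if (sd == 0 && family != "duration") {
    return(list(values = rep(mean, n)))
  }
  note <- NULL
  values <- switch(family,
    normal = stats::rnorm(n, mean, sd),
    lognormal = {
      s2 <- log1p((sd / mean)^2)
      stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
    },
    gamma = {
      shape <- mean^2 / sd^2
      stats::rgamma(n, shape = shape, rate = shape / mean)
    },
    duration = {
      if (mean < 0 || mean > window) {
        stop("duration mean must lie within the observation window [0, ", window, "]")
      }
      p <- mean / window
      base_var <- window * p * (1 - p)
      if (sd^2 <= base_var || p %in% c(0, 1)) {
        # at or below binomial dispersion; cannot be made underdispersed
        if (sd^2 < 0.75 * base_var && p > 0 && p < 1) {
          note <- sprintf(
            "duration dispersion floor: requested sd %.3g below binomial sd %.3g",
            sd, sqrt(base_var)
          )
        }
        stats::rbinom(n, window, p)
      } else {
        rho <- (sd^2 / base_var - 1) / (window - 1)
        if (rho > 0.98) {
          note <- sprintf(
            "duration dispersion cap: requested sd %.3g exceeds the %g-s window capacity",
            sd, window
          )
          rho <- 0.98
        }
        ab <- (1 / rho) - 1
        stats::rbinom(n, window, stats::rbeta(n, p * ab, (1 - p) * ab))
      }
    },
    compound_poisson_gamma = {
      # stochastic rounding keeps the mean exactly unbiased
      x <- rtweedie(n, mean, sd^2, index = tweedie_index)
      floor(x) + stats::rbinom(n, 1, x - floor(x))
    },
    stop("unknown sampling family: ", family)
  )
  list(values = values, note = note)
}

#' Compound Poisson-gamma (Tweedie) random draws
#'
#' Mean/variance-parameterized Tweedie draws with power index in (1, 2):
#' a Poisson number of gamma jumps, giving exact zeros with positive
#' probability. Used for agonistic behaviour counts.
#'
#' @param n Number of draws.
#' @param mean,var Target mean and variance (`var = phi * mean^index`).
#' @param index Tweedie power index, strictly between 1 and 2.
#' @return Numeric vector of non-negative draws.
#' @export
rtweedie <- function(n, mean, var, index = 1.5) {
  stopifnot(index > 1, index < 2, mean > 0, var > 0)
  phi <- var / mean^index
  lambda <- mean^(2 - index) / (phi * (2 - index))
  alpha <- (2 - index) / (index - 1)
  gam_scale <- phi * (index - 1) * mean^(index - 1)
  nj <- stats::rpois(n, lambda)
  out <- numeric(n)
  pos <- nj > 0
  out[pos] <- stats::rgamma(sum(pos), shape = alpha * nj[pos], scale = gam_scale)
  out
}

#' Jointly draw weight, lengths and Fulton's K for one tank
#'
#' @param n Number of fish.
#' @param w_mean,k_mean Target means of weight (g) and Fulton's K.
#' @param sd_w Per-fish weight standard deviation.
#' @param beta1 Allometric exponent.
#' @return Tibble with weight, total_length, standard_length, fulton_k.
#' @keywords internal
simulate_body_condition <- function(n, w_mean, k_mean, sd_w, beta1) {
  p <- body_condition_params(w_mean, k_mean, sd_w, beta1)
  tl <- stats::rlnorm(n, p$m, sqrt(p$s2))
  sl <- tl / tl_sl_ratio()
  w <- p$cc * sl^beta1 * exp(stats::rnorm(n, 0, p$sigma_eps))
  tibble::tibble(
    weight = w, total_length = tl, standard_length = sl,
    fulton_k = fulton_k(w, tl)
  )
}

#' Simulate paired length-weight growth data
#'
#' Standalone generator for allometric-model tests: lengths lognormal,
#' weights following `W = beta0 * SL^beta1 * exp(noise)`.
#'
#' @param n Number of fish.
#' @param beta0,beta1 Power-law intercept and growth exponent.
#' @param length_mean,length_cv Mean and CV of standard length (cm).
#' @param noise_sd Lognormal residual sd on weight; 0 gives exact power data.
#' @param seed Integer seed.
#' @return Tibble with `standard_length` and `weight`.
#' @export
simulate_growth_pairs <- function(n, beta0 = 0.01, beta1 = 3,
                                  length_mean = 6, length_cv = 0.25,
                                  noise_sd = 0.05, seed = 1L) {
  stopifnot(n >= 1, beta0 > 0, length_mean > 0, length_cv > 0, noise_sd >= 0)
  set.seed(as.integer(seed))
  s2 <- log1p(length_cv^2)
  sl <- stats::rlnorm(n, log(length_mean) - s2 / 2, sqrt(s2))
  w <- beta0 * sl^beta1 * exp(stats::rnorm(n, 0, noise_sd))
  tibble::tibble(standard_length = sl, weight = w)
}

#' Simulate an intermittent-flow respirometry O2 trace
#'
#' Emits cycles sampled at 1 Hz. Each 9.5-min cycle has a 2-min closed
#' (measurement) phase, a 30-s wait and a flushing phase filling the rest of
#' the cycle, during which the chamber is renewed and restored to the start
#' concentration. While the chamber is sealed (closed + wait), O2 declines
#' linearly at `true_mo2 * fish_mass / effective_volume` mg/L/h; Gaussian
#' measurement noise is added to every sample. The generator refuses
#' parameter sets that would deplete the chamber by more than 20% of the
#' starting concentration while sealed.
#'
#' @param true_mo2 True mass-specific oxygen consumption, mgO2/kg/h.
#' @param fish_mass Fish mass, kg (0 for a blank chamber).
#' @param chamber_volume,tubing_volume Chamber and tubing volumes, L.
#' @param fish_volume Fish volume, L; defaults to neutral buoyancy
#'   (`fish_mass` / 1 kg/L).
#' @param o2_start Starting O2 concentration, mg/L (must lie in 6.5-7.5).
#' @param noise_sd Measurement noise sd, mg/L.
#' @param background_slope Additional sealed-phase O2 decline from microbial
#'   background respiration, mg/L/h (non-positive). This is what blank
#'   chambers (fish_mass 0) record.
#' @param n_cycles Number of measurement cycles.
#' @param chamber_id Chamber label.
#' @param seed Integer seed.
#'
#' @return Tibble of class `respirometry_trace` with columns `chamber_id`,
#'   `cycle`, `time_s`, `o2_mg_per_l`, `phase` and the geometry stored in
#'   attribute `"geometry"`.
#' @export
#' @examples
#' tr <- simulate_o2_trace(13.5, fish_mass = 0.008, noise_sd = 0, seed = 1)
#' closed_phase_slope(tr, cycle = 1)
simulate_o2_trace <- function(true_mo2, fish_mass,
                              chamber_volume = 0.300, tubing_volume = 0.015,
                              fish_volume = fish_mass / 1.0,
                              o2_start = 7.0, noise_sd = 0.005,
                              background_slope = 0,
                              n_cycles = 3, chamber_id = "ch1", seed = 1L) {
  stopifnot(
    true_mo2 >= 0, fish_mass >= 0, noise_sd >= 0, n_cycles >= 1,
    background_slope <= 0
  )
  if (o2_start < 6.5 || o2_start > 7.5) {
    stop("o2_start must lie between 6.5 and 7.5 mg/L")
  }
  v_eff <- chamber_volume + tubing_volume - fish_volume
  if (v_eff <= 0) stop("effective volume (chamber + tubing - fish) must be positive")

  slope_h <- -true_mo2 * fish_mass / v_eff + background_slope # mg/L/h, <= 0
  closed_s <- 120L; wait_s <- 30L; cycle_s <- 570L
  sealed_drop <- -slope_h / 3600 * (closed_s + wait_s)
  if (sealed_drop > 0.2 * o2_start) {
    stop(sprintf(
      paste0(
        "parameters deplete the chamber by %.1f%% of the starting O2 while ",
        "sealed (limit 20%%); reduce true_mo2 or fish_mass, or enlarge the chamber"
      ),
      100 * sealed_drop / o2_start
    ))
  }

  set.seed(as.integer(seed))
  one_cycle <- function(k) {
    t_local <- seq_len(cycle_s) - 1L
    phase <- rep("flush", cycle_s)
    phase[t_local < closed_s] <- "closed"
    phase[t_local >= closed_s & t_local < closed_s + wait_s] <- "wait"
    o2 <- rep(o2_start, cycle_s)
    sealed <- t_local < closed_s + wait_s
    o2[sealed] <- o2_start + slope_h / 3600 * t_local[sealed]
    tibble::tibble(
      chamber_id = chamber_id, cycle = k,
      time_s = t_local + (k - 1L) * cycle_s,
      o2_mg_per_l = o2 + stats::rnorm(cycle_s, 0, noise_sd),
      phase = phase
    )
  }
  out <- dplyr::bind_rows(lapply(seq_len(n_cycles), one_cycle))
  attr(out, "geometry") <- list(
    chamber_volume = chamber_volume, tubing_volume = tubing_volume,
    fish_volume = fish_volume, fish_mass = fish_mass,
    effective_volume = v_eff, is_blank = fish_mass == 0
  )
  class(out) <- c("respirometry_trace", class(out))
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
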