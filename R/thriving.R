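#' Standardised deviation of a treatment summary from the control
#'
#' `Z = (x_mean - control_mean) / sqrt(x_se^2 + control_se^2)`: the trait's
#' deviation from the control treatment in combined standard-error units.
#'
#' @param x_mean,x_se Treatment mean and s.e.m.
#' @param control_mean,control_se Control mean and s.e.m.
#' @return Numeric z-score(s).
#' @export
#' @examples
#' z_score(1.43, 0.03, 1.32, 0.04)
z_score <- function(x_mean, x_se, control_mean, control_se) {
  denom <- sqrt(x_se^2 + control_se^2)
  zero <- denom == 0
  if (any(zero & x_mean != control_mean)) {
    stop("both standard errors are zero with unequal means: Z undefined")
  }
  out <- numeric(length(denom))
  out[!zero] <- (x_mean[!zero] - control_mean[!zero]) / denom[!zero]
  out
}

#' Probability of thriving from a z-score
#'
#' Maps a standardised trait deviation to a probability of thriving,
#' `psi = exp(-|z'|)`, clipped into `[epsilon, 1 - epsilon]`. A trait that
#' matches the control exactly (z = 0) gives `psi = 1 - epsilon`. For
#' `harmful_increase` traits the z-score is sign-inverted first; under the
#' default symmetric transform the inversion is numerically inert (the
#' absolute value removes the sign) but it becomes decisive in the
#' one-sided mode, which only penalises deviations in the trait's harmful
#' direction — increases of a `harmful_increase` trait (elevated stress
#' biomarkers), decreases of any other trait — and credits beneficial
#' deviations with full thriving probability: `psi = exp(-max(0, z*))`
#' with `z* = z` for harmful traits and `z* = -z` otherwise.
#'
#' @param z Numeric z-score(s).
#' @param direction `"benign_deviation"` (default) or `"harmful_increase"`.
#' @param epsilon Boundary clip keeping psi inside (0, 1); default 1e-6.
#' @param one_sided Credit beneficial deviations with psi near 1.
#' @return Probabilities in `[epsilon, 1 - epsilon]`.
#' @export
#' @examples
#' psi_transform(2.2)
#' psi_transform(-2.2213, direction = "harmful_increase", one_sided = TRUE)
psi_transform <- function(z, direction = "benign_deviation",
                          epsilon = 1e-6, one_sided = FALSE) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  direction <- rep_len(direction, length(z))
  if (!all(direction %in% c("benign_deviation", "harmful_increase"))) {
    stop("direction must be 'benign_deviation' or 'harmful_increase'")
  }
  if (one_sided) {
    # penalise only the harmful direction: up for stress biomarkers,
    # down for performance traits
    zp <- ifelse(direction == "harmful_increase", z, -z)
    psi <- exp(-pmax(0, zp))
  } else {
    psi <- exp(-abs(z))
  }
  pmin(pmax(psi, epsilon), 1 - epsilon)
}

#' Beta distribution shapes from mean and precision
#'
#' Mean/precision parameterisation of the beta regression likelihood:
#' `p = mu * phi`, `q = (1 - mu) * phi`, inducing mean `mu` and variance
#' `mu (1 - mu) / (1 + phi)`.
#'
#' @param mu Mean(s), strictly inside (0, 1).
#' @param phi Precision(s), strictly positive.
#' @return Tibble with columns `p` and `q`.
#' @export
#' @examples
#' beta_shapes(0.2, 50)
beta_shapes <- function(mu, phi) {
  if (any(mu <= 0) || any(mu >= 1)) stop("mu must lie strictly inside (0, 1)")
  if (any(phi <= 0)) stop("phi must be strictly positive")
  tibble::tibble(p = mu * phi, q = (1 - mu) * phi)
}

#' Convert trait summaries into thriving observations
#'
#' For every non-control summary row, computes the z-score against the
#' trait's control row and the probability of thriving psi. The control
#' row's own psi (exactly `1 - epsilon`, since it matches itself) is
#' included as a datum by default, anchoring each sub-model's regression at
#' the control temperature.
#'
#' @param summaries Output of [summarize_traits()].
#' @param directions Named vector mapping trait ids to directionality (see
#'   [default_directions()]); unlisted traits default to
#'   `"benign_deviation"`.
#' @param epsilon,one_sided Passed to [psi_transform()].
#' @param include_control Keep the control anchor datum.
#' @return Tibble: `trait_id`, `temperature`, `tank`, `z`, `psi`,
#'   `direction_applied`.
#' @export
thriving_observations <- function(summaries, directions = default_directions(),
                                  epsilon = 1e-6, one_sided = FALSE,
                                  include_control = TRUE) {
  stopifnot(all(c("trait_id", "treatment", "mean", "se", "is_control") %in% names(summaries)))
  ctrl <- summaries[summaries$is_control, ]
  if (any(duplicated(ctrl$trait_id))) {
    stop("more than one control row per trait: pool control tanks first")
  }
  if (!all(unique(summaries$trait_id) %in% ctrl$trait_id)) {
    stop("some traits lack a control row")
  }

  dir_of <- function(trait) {
    ifelse(trait %in% names(directions), unname(directions[trait]), "benign_deviation")
  }
  test <- summaries[!summaries$is_control, ]
  test <- dplyr::left_join(
    test,
    dplyr::select(ctrl, "trait_id", control_mean = "mean", control_se = "se"),
    by = "trait_id"
  )
  test$z <- z_score(test$mean, test$se, test$control_mean, test$control_se)
  out <- tibble::tibble(
    trait_id = test$trait_id, temperature = test$treatment, tank = test$tank,
    z = test$z,
    psi = psi_transform(test$z, dir_of(test$trait_id), epsilon, one_sided),
    direction_applied = dir_of(test$trait_id) == "harmful_increase"
  )
  if (include_control) {
    anchor <- tibble::tibble(
      trait_id = ctrl$trait_id, temperature = ctrl$treatment,
      tank = NA_character_, z = 0, psi = 1 - epsilon,
      direction_applied = dir_of(ctrl$trait_id) == "harmful_increase"
    )
    out <- dplyr::bind_rows(anchor, out)
  }
  dplyr::arrange(out, .data$trait_id, .data$temperature, .data$tank)
}

# JAGS model: beta likelihood, logit-linear mean in temperature,
# weakly informative independent Normal(0, precision 0.001) priors on the
# intercept a0 and slope a1, phi = U^2 with U ~ Uniform(0, 50).
#
# Sampled in the centred basis b = (a0 + a1 tbar, a1): the posterior over
# (a0, a1) has a strong ridge when temperature is far from 0, which stalls
# componentwise samplers. The multivariate normal prior on b is exactly the
# one induced by the stated independent priors (covariance V [[1 + tbar^2,
# tbar], [tbar, 1]], V = 1000), so the posterior is identical and a0, a1
# are recovered by deterministic transform.
submodel_jags_code <- function() {
  "model {
    for (i in 1:N) {
      psi[i] ~ dbeta(p[i], q[i])
      p[i] <- mu[i] * phi
      q[i] <- (1 - mu[i]) * phi
      logit(mu[i]) <- b[1] + b[2] * (temp[i] - tbar)
    }
    b[1:2] ~ dmnorm(zero[1:2], Omega[1:2, 1:2])
    a0 <- b[1] - b[2] * tbar
    a1 <- b[2]
    phi <- pow(U, 2)
    U ~ dunif(0, 50)
  }"
}

#' Fit the Bayesian beta-regression thriving sub-model for one trait
#'
#' Samples the posterior of `(a0, a1, phi)` under
#' `psi_i ~ Beta(mu_i phi, (1 - mu_i) phi)` with
#' `logit(mu_i) = a0 + a1 * TEMP_i`, weakly informative `Normal(0, 0.001)`
#' (precision) priors on the coefficients and `phi = U^2`,
#' `U ~ Uniform(0, 50)`. Default schedule: 3 chains, 1000 adaptation, 4000
#' burn-in and 2000 retained iterations per chain. Convergence is assessed
#' with the split-chain Gelman-Rubin statistic; a fit with any rhat >= 1.1
#' is returned with `converged = FALSE` and a warning, never silently.
#'
#' @param observations Tibble with columns `temperature` and `psi` (one
#'   trait's thriving observations), psi strictly inside (0, 1).
#' @param n_chains,n_adapt,n_burn,n_keep MCMC schedule.
#' @param seed Integer seed (chain RNGs are derived from it).
#' @param quiet Suppress the non-convergence warning.
#' @return Object of class `beta_submodel`: posterior `draws` (tibble with
#'   columns a0, a1, phi, chain), `rhat`, `converged`, `trait_id`, `n_obs`,
#'   the schedule, and the temperature range of the data.
#' @export
fit_submodel <- function(observations, n_chains = 3, n_adapt = 1000,
                         n_burn = 4000, n_keep = 2000, seed = 1L,
                         quiet = FALSE) {
  stopifnot(all(c("temperature", "psi") %in% names(observations)))
  psi <- observations$psi
  temp <- observations$temperature
  if (length(psi) < 3) stop("at least 3 observations are required")
  if (length(unique(temp)) < 2) stop("observations must span at least 2 temperatures")
  if (any(psi <= 0 | psi >= 1)) stop("psi must lie strictly inside (0, 1)")

  inits <- lapply(seq_len(n_chains), function(k) {
    list(
      .RNG.name = "base::Wichmann-Hill",
      .RNG.seed = (as.integer(seed) * 1009L + k) %% 2147483562L + 1L
    )
  })
  tbar <- mean(temp)
  prior_var <- 1000 # Normal(0, 0.001) precision on each coefficient
  omega <- (1 / prior_var) * matrix(c(1, -tbar, -tbar, 1 + tbar^2), 2, 2)
  jm <- rjags::jags.model(
    textConnection(submodel_jags_code()),
    data = list(
      N = length(psi), psi = psi, temp = temp, tbar = tbar,
      zero = c(0, 0), Omega = omega
    ),
    inits = inits, n.chains = n_chains, n.adapt = n_adapt, quiet = TRUE
  )
  stats::update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(
    jm, c("a0", "a1", "phi"), n.iter = n_keep, progress.bar = "none"
  )

  rhat <- vapply(
    c("a0", "a1", "phi"),
    function(p) split_rhat(sapply(samp, function(ch) as.numeric(ch[, p]))),
    numeric(1)
  )
  converged <- all(rhat < 1.1)
  trait <- if ("trait_id" %in% names(observations)) observations$trait_id[1] else NA_character_
  if (!converged && !quiet) {
    warning(
      "thriving sub-model", if (!is.na(trait)) paste0(" for '", trait, "'"),
      " did not converge (max rhat = ", signif(max(rhat), 4),
      "); inspect the chains or lengthen the schedule",
      call. = FALSE
    )
  }

  draws <- dplyr::bind_rows(lapply(seq_along(samp), function(k) {
    m <- as.matrix(samp[[k]])
    tibble::tibble(a0 = m[, "a0"], a1 = m[, "a1"], phi = m[, "phi"], chain = k)
  }))
  structure(
    list(
      trait_id = trait, draws = draws, rhat = rhat, converged = converged,
      n_obs = length(psi), temp_range = range(temp),
      schedule = list(
        n_chains = n_chains, n_adapt = n_adapt, n_burn = n_burn, n_keep = n_keep
      )
    ),
    class = "beta_submodel"
  )
}

#' Split-chain Gelman-Rubin statistic
#'
#' Splits each chain in half and computes the potential scale reduction
#' factor over the resulting 2m half-chains; values near 1 indicate that
#' the chains have mixed.
#'
#' @param chains Numeric matrix, one column per chain.
#' @return rhat (scalar).
#' @export
split_rhat <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains)
  half <- n %/% 2
  splits <- do.call(cbind, lapply(seq_len(ncol(chains)), function(j) {
    cbind(chains[seq_len(half), j], chains[(n - half + 1):n, j])
  }))
  m <- ncol(splits)
  nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  w <- mean(vars)
  b <- nn * stats::var(means)
  if (w == 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' @export
print.beta_submodel <- function(x, ...) {
  cat("<beta_submodel>", if (!is.na(x$trait_id)) x$trait_id, "\n")
  s <- tidy.beta_submodel(x)
  print(as.data.frame(s), row.names = FALSE, digits = 4)
  cat("  converged:", x$converged, " (max rhat", signif(max(x$rhat), 4), ")\n")
  invisible(x)
}

#' @export
tidy.beta_submodel <- function(x, ...) {
  d <- x$draws
  purrr::map_dfr(c("a0", "a1", "phi"), function(p) {
    v <- d[[p]]
    tibble::tibble(
      term = p, estimate = mean(v), std.error = stats::sd(v),
      conf.low = unname(stats::quantile(v, 0.025)),
      conf.high = unname(stats::quantile(v, 0.975)),
      rhat = unname(x$rhat[p])
    )
  })
}

#' @export
glance.beta_submodel <- function(x, ...) {
  tibble::tibble(
    trait_id = x$trait_id, n_obs = x$n_obs, converged = x$converged,
    max_rhat = max(x$rhat),
    n_draws = nrow(x$draws)
  )
}

#' Posterior thriving curve over a temperature grid
#'
#' Evaluates `psi_B(T) = inverse-logit(a0 + a1 T)` over the posterior draws
#' at each grid temperature, reporting the posterior mean and central 95%
#' interval.
#'
#' @param fit A `beta_submodel`.
#' @param grid Temperatures, degC; guarded against extrapolating more than
#'   `guard` degC beyond the fitted data range.
#' @param guard Allowed extrapolation beyond the data range, degC.
#' @return Tibble of class `trait_curve`: `trait_id`, `temperature`,
#'   `psi_mean`, `psi_lo`, `psi_hi`.
#' @export
predict_curve <- function(fit, grid = seq(19, 28, by = 0.1), guard = 2) {
  stopifnot(inherits(fit, "beta_submodel"))
  if (length(grid) == 0) stop("grid is empty")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (min(grid) < fit$temp_range[1] - guard || max(grid) > fit$temp_range[2] + guard) {
    stop(
      "grid extends more than ", guard, " degC beyond the fitted range [",
      fit$temp_range[1], ", ", fit$temp_range[2], "]"
    )
  }
  eta <- outer(fit$draws$a0, rep(1, length(grid))) +
    outer(fit$draws$a1, grid)
  psi <- stats::plogis(eta)
  qs <- apply(psi, 2, stats::quantile, probs = c(0.025, 0.975))
  out <- tibble::tibble(
    trait_id = fit$trait_id, temperature = grid,
    psi_mean = colMeans(psi), psi_lo = qs[1, ], psi_hi = qs[2, ]
  )
  class(out) <- c("trait_curve", class(out))
  out
}

#' Fit thriving sub-models for every trait
#'
#' Maps [fit_submodel()] over the traits present in a thriving-observation
#' table, deriving one reproducible chain seed per trait from `seed`.
#'
#' @param observations Output of [thriving_observations()].
#' @param grid Temperature grid for the predicted curves.
#' @param seed Integer master seed.
#' @inheritParams fit_submodel
#' @return List with `fits` (named list of `beta_submodel`) and `curves`
#'   (row-bound `trait_curve` tibble).
#' @export
fit_thriving_models <- function(observations, grid = seq(19, 28, by = 0.1),
                                n_chains = 3, n_adapt = 1000, n_burn = 4000,
                                n_keep = 2000, seed = 1L, quiet = FALSE) {
  traits <- unique(observations$trait_id)
  fits <- lapply(seq_along(traits), function(i) {
    obs <- observations[observations$trait_id == traits[i], ]
    fit_submodel(
      obs, n_chains = n_chains, n_adapt = n_adapt, n_burn = n_burn,
      n_keep = n_keep, seed = as.integer(seed) + 101L * i, quiet = quiet
    )
  })
  names(fits) <- traits
  curves <- dplyr::bind_rows(lapply(fits, predict_curve, grid = grid))
  class(curves) <- c("trait_curve", class(tibble::tibble()))
  list(fits = fits, curves = curves)
}
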