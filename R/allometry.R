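#' Fit the allometric weight-length growth model
#'
#' Fits `W = beta0 * SL^beta1 + eps` by nonlinear least squares with
#' additive error, initialised from ordinary least squares on
#' `log(W) ~ log(SL)`. `beta1` is the growth coefficient: 3 is isometric,
#' above 3 positively allometric (weight gained faster than length).
#'
#' @param data Data frame with one row per fish.
#' @param length_col,weight_col Column names holding standard length (cm)
#'   and weight (g); both strictly positive.
#' @param treatment Optional treatment label (degC) carried into the result.
#' @param max_iter Maximum optimiser iterations.
#'
#' @return An object of class `growth_fit`: estimates, asymptotic standard
#'   errors, n, residual sd and the underlying `nls` fit. On
#'   non-convergence, an error carrying the log-log fallback estimates in
#'   its `fallback` field.
#' @export
#' @examples
#' d <- simulate_growth_pairs(100, beta0 = 0.01, beta1 = 3.2, seed = 2)
#' fit <- fit_allometry(d)
#' tidy(fit)
fit_allometry <- function(data, length_col = "standard_length",
                          weight_col = "weight", treatment = NA_real_,
                          max_iter = 200) {
  sl <- data[[length_col]]
  w <- data[[weight_col]]
  if (is.null(sl) || is.null(w)) {
    stop("data must contain columns '", length_col, "' and '", weight_col, "'")
  }
  ok <- is.finite(sl) & is.finite(w)
  sl <- sl[ok]; w <- w[ok]
  n <- length(sl)
  if (n < 3) stop("at least 3 observations are required")
  if (any(sl <= 0) || any(w <= 0)) stop("lengths and weights must be positive")
  if (stats::sd(sl) == 0) stop("no length variation: allometric slope is unidentifiable")

  ll <- stats::lm(log(w) ~ log(sl))
  start <- list(b0 = exp(stats::coef(ll)[[1]]), b1 = stats::coef(ll)[[2]])

  fit <- tryCatch(
    minpack.lm::nlsLM(
      w ~ b0 * sl^b1,
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = max_iter)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    err <- simpleError(paste0(
      "allometric fit failed to converge: ", conditionMessage(fit),
      " (log-log fallback: beta0 = ", signif(start$b0, 6),
      ", beta1 = ", signif(start$b1, 6), ")"
    ))
    err$fallback <- c(beta0 = start$b0, beta1 = start$b1)
    stop(err)
  }

  sm <- summary(fit)
  structure(
    list(
      treatment = treatment,
      beta0 = sm$coefficients["b0", "Estimate"],
      beta1 = sm$coefficients["b1", "Estimate"],
      se_beta0 = sm$coefficients["b0", "Std. Error"],
      se_beta1 = sm$coefficients["b1", "Std. Error"],
      n = n,
      residual_sd = sm$sigma,
      fit = fit
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> W = beta0 * SL^beta1\n")
  cat(sprintf(
    "  beta0 = %.5g (se %.3g)   beta1 = %.4f (se %.3g)   n = %d\n",
    x$beta0, x$se_beta0, x$beta1, x$se_beta1, x$n
  ))
  if (!is.na(x$treatment)) cat("  treatment:", x$treatment, "degC\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = c("beta0", "beta1"),
    estimate = c(x$beta0, x$beta1),
    std.error = c(x$se_beta0, x$se_beta1)
  )
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    treatment = x$treatment, nobs = x$n, sigma = x$residual_sd,
    beta1 = x$beta1
  )
}

#' Compare growth coefficients between two treatments
#'
#' Two-sample z-test on the difference of allometric slopes,
#' `z = (beta1_a - beta1_b) / sqrt(se_a^2 + se_b^2)`, with a two-sided
#' standard-normal p-value.
#'
#' @param a,b `growth_fit` objects.
#' @param alpha Significance level for the verdict.
#' @return One-row tibble: the pair, `statistic` (z), `p_value` and
#'   `verdict` (`"different"` / `"no_difference"`).
#' @export
compare_slopes <- function(a, b, alpha = 0.05) {
  stopifnot(inherits(a, "growth_fit"), inherits(b, "growth_fit"))
  se <- sqrt(a$se_beta1^2 + b$se_beta1^2)
  if (se == 0) stop("both slope standard errors are zero: z undefined")
  z <- (a$beta1 - b$beta1) / se
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(
    treatment_a = a$treatment, treatment_b = b$treatment,
    statistic = z, p_value = p,
    verdict = ifelse(p < alpha, "different", "no_difference")
  )
}

#' Test an allometric slope against isometry
#'
#' One-sample t-test of `beta1` against the isometric value 3 on n - 2
#' degrees of freedom (two parameters estimated).
#'
#' @param fit A `growth_fit`.
#' @param alpha Significance level for the verdict.
#' @return One-row tibble: `statistic` (t), `df`, `p_value` and `verdict`
#'   (`"positively_allometric"`, `"negatively_allometric"` or
#'   `"isometric"`).
#' @export
test_isometry <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "growth_fit"), fit$n >= 3)
  df <- fit$n - 2
  # a (near-)zero standard error means the fit is exact to machine
  # precision and the asymptotic t-test is meaningless
  if (fit$se_beta1 <= 1e-8 * max(1, abs(fit$beta1))) {
    if (abs(fit$beta1 - 3) <= 1e-6) {
      return(tibble::tibble(
        treatment = fit$treatment, statistic = 0, df = df, p_value = 1,
        verdict = "isometric", degenerate = FALSE
      ))
    }
    warning("zero slope standard error with beta1 != 3: degenerate test")
    return(tibble::tibble(
      treatment = fit$treatment, statistic = sign(fit$beta1 - 3) * Inf,
      df = df, p_value = 0,
      verdict = ifelse(fit$beta1 > 3, "positively_allometric", "negatively_allometric"),
      degenerate = TRUE
    ))
  }
  t <- (fit$beta1 - 3) / fit$se_beta1
  p <- 2 * stats::pt(-abs(t), df = df)
  verdict <- if (p >= alpha) {
    "isometric"
  } else if (t > 0) {
    "positively_allometric"
  } else {
    "negatively_allometric"
  }
  tibble::tibble(
    treatment = fit$treatment, statistic = t, df = df, p_value = p,
    verdict = verdict, degenerate = FALSE
  )
}

#' Growth-pattern report across treatments
#'
#' Fits the allometric model per treatment from a trait table (trait ids
#' `standard_length` and `weight`, paired by `fish_id`), tests each slope
#' against isometry and compares all treatment pairs. Raw pairwise
#' comparisons by default (`p_adjust = "none"`); Holm correction available.
#'
#' @param trait_table Long trait table (see [simulate_traits()]).
#' @param p_adjust Multiplicity adjustment for the pairwise z-tests.
#' @return List with `fits` (named list of `growth_fit`), `isometry`
#'   (tibble) and `pairwise` (tibble).
#' @export
growth_report <- function(trait_table, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  wide <- tidyr::pivot_wider(
    dplyr::filter(trait_table, .data$trait_id %in% c("standard_length", "weight")),
    id_cols = c("fish_id", "treatment"),
    names_from = "trait_id", values_from = "value"
  )
  wide <- dplyr::filter(wide, !is.na(.data$standard_length), !is.na(.data$weight))
  fits <- lapply(split(wide, wide$treatment), function(d) {
    fit_allometry(d, treatment = d$treatment[1])
  })
  iso <- dplyr::bind_rows(lapply(fits, test_isometry))
  pairs <- utils::combn(names(fits), 2, simplify = FALSE)
  pw <- dplyr::bind_rows(lapply(pairs, function(p) {
    compare_slopes(fits[[p[1]]], fits[[p[2]]])
  }))
  if (p_adjust == "holm" && nrow(pw) > 0) {
    pw$p_value <- stats::p.adjust(pw$p_value, method = "holm")
    pw$verdict <- ifelse(pw$p_value < 0.05, "different", "no_difference")
  }
  list(fits = fits, isometry = iso, pairwise = pw)
}
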