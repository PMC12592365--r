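#' Pool trait-level thriving curves into GAM input data
#'
#' Emits one `(temperature, psi)` datum per trait per grid point — the
#' posterior-mean curve of each sub-model — as the response data of the
#' integrated GAM. Trait identity is retained for diagnostics.
#'
#' @param curves Row-bound `trait_curve` tibble (see
#'   [fit_thriving_models()]); at least 2 traits on a common grid.
#' @return Tibble with columns `trait_id`, `temperature`, `psi`.
#' @export
pool_curves <- function(curves) {
  stopifnot(all(c("trait_id", "temperature", "psi_mean") %in% names(curves)))
  traits <- unique(curves$trait_id)
  if (length(traits) < 2) stop("at least 2 trait curves are required")
  grids <- split(curves$temperature, curves$trait_id)
  ref <- grids[[1]]
  same <- vapply(
    grids,
    function(g) length(g) == length(ref) && all(g == ref),
    logical(1)
  )
  if (!all(same)) {
    stop("trait curves are on mismatched grids: ", paste(traits[!same], collapse = ", "))
  }
  tibble::tibble(
    trait_id = curves$trait_id, temperature = curves$temperature,
    psi = curves$psi_mean
  )
}

#' Fit the integrated beta-likelihood GAM over temperature
#'
#' Fits `logit(E[psi]) = s(TEMP)` with a penalized cubic regression spline
#' (basis dimension `k`) and a Beta likelihood, smoothing selected by REML.
#' This integrates the trait-level probabilities into a single thermal
#' performance curve with a 95% uncertainty band (link-scale normal
#' approximation).
#'
#' @param data Tibble with columns `temperature` and `psi`, psi strictly
#'   inside (0, 1) (e.g. from [pool_curves()]).
#' @param grid Temperatures at which to evaluate the fitted curve.
#' @param k Spline basis dimension; the temperature signal comes from 4
#'   treatment anchors, so a small basis suffices and larger ones are
#'   penalized away.
#' @param bs Spline basis type (mgcv code).
#' @return Object of class `integrated_curve`: `curve` (tibble:
#'   `temperature`, `psi_fit`, `psi_lo`, `psi_hi`), the fitted `gam` model
#'   and the smooth configuration.
#' @export
fit_integrated_gam <- function(data, grid = seq(19, 28, by = 0.1), k = 5,
                               bs = "cr") {
  stopifnot(all(c("temperature", "psi") %in% names(data)))
  if (nrow(data) < 10) stop("at least 10 data points are required")
  if (length(unique(data$temperature)) < 2) {
    stop("degenerate data: a single temperature cannot support a smooth")
  }
  if (any(data$psi <= 0 | data$psi >= 1)) stop("psi must lie strictly inside (0, 1)")

  fit <- mgcv::gam(
    psi ~ s(temperature, k = k, bs = bs),
    family = mgcv::betar(link = "logit"), method = "REML",
    data = data
  )
  pr <- mgcv::predict.gam(
    fit, newdata = data.frame(temperature = grid), type = "link", se.fit = TRUE
  )
  eta <- as.numeric(pr$fit)
  se <- as.numeric(pr$se.fit)
  curve <- tibble::tibble(
    temperature = grid,
    psi_fit = stats::plogis(eta),
    psi_lo = stats::plogis(eta - 1.96 * se),
    psi_hi = stats::plogis(eta + 1.96 * se)
  )
  structure(
    list(curve = curve, model = fit, smooth_config = list(k = k, bs = bs)),
    class = "integrated_curve"
  )
}

#' @export
print.integrated_curve <- function(x, ...) {
  cat("<integrated_curve> beta-likelihood GAM, k =", x$smooth_config$k, "\n")
  rng <- range(x$curve$psi_fit)
  cat(sprintf(
    "  grid %g-%g degC (%d points), fitted psi %.3f-%.3f\n",
    min(x$curve$temperature), max(x$curve$temperature),
    nrow(x$curve), rng[1], rng[2]
  ))
  invisible(x)
}

#' @export
glance.integrated_curve <- function(x, ...) {
  tibble::tibble(
    nobs = stats::nobs(x$model),
    k = x$smooth_config$k,
    edf = sum(x$model$edf),
    phi_hat = x$model$family$getTheta(TRUE)
  )
}

#' Classify the temperature axis into hotspot and occasional habitat
#'
#' Partitions the fitted grid at a thriving-probability threshold: grid
#' points with fitted psi at or above the threshold form the hotspot class
#' (the thermal range securing more than a 50% chance of thriving, at the
#' default threshold; a point exactly at the threshold is the crossing
#' itself and closes the hotspot interval). The rest is occasional habitat.
#' Contiguous runs are reported as intervals, so non-monotone curves yield
#' interval unions. Each crossing is reported at grid resolution as the
#' last hotspot grid point before the curve drops through the threshold
#' (or the last occasional point before it rises through it).
#'
#' @param curve An `integrated_curve` or a tibble with `temperature` and
#'   `psi_fit`.
#' @param threshold Thriving-probability threshold; default 0.5.
#' @return Object of class `habitat_classification`: `intervals` (tibble:
#'   `habitat`, `from`, `to`), `crossings` (numeric), `threshold`,
#'   `grid_step`.
#' @export
classify_habitat <- function(curve, threshold = 0.5) {
  df <- if (inherits(curve, "integrated_curve")) curve$curve else curve
  stopifnot(all(c("temperature", "psi_fit") %in% names(df)), nrow(df) > 0)
  stopifnot(threshold > 0, threshold < 1)
  temp <- df$temperature
  hot <- df$psi_fit >= threshold

  run <- rle(hot)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  intervals <- tibble::tibble(
    habitat = ifelse(run$values, "hotspot", "occasional"),
    from = temp[starts], to = temp[ends]
  )
  crossings <- temp[which(diff(hot) != 0)]
  structure(
    list(
      intervals = intervals, crossings = crossings, threshold = threshold,
      grid_step = if (length(temp) > 1) stats::median(diff(temp)) else NA_real_
    ),
    class = "habitat_classification"
  )
}

#' @export
print.habitat_classification <- function(x, ...) {
  cat("<habitat_classification> threshold", x$threshold, "\n")
  for (i in seq_len(nrow(x$intervals))) {
    cat(sprintf(
      "  %-10s %g - %g degC\n",
      x$intervals$habitat[i], x$intervals$from[i], x$intervals$to[i]
    ))
  }
  if (length(x$crossings)) {
    cat("  crossing(s) at:", paste(x$crossings, collapse = ", "), "degC\n")
  } else {
    cat("  no threshold crossing on the grid\n")
  }
  invisible(x)
}

#' Upper bound of the hotspot habitat range
#'
#' Convenience accessor: the highest temperature of the first hotspot
#' interval (the 50% crossing of a monotone-declining integrated curve, at
#' grid resolution). `NA` if the curve never exceeds the threshold.
#'
#' @param classification A `habitat_classification`.
#' @return Temperature, degC.
#' @export
hotspot_upper_bound <- function(classification) {
  stopifnot(inherits(classification, "habitat_classification"))
  hs <- classification$intervals[classification$intervals$habitat == "hotspot", ]
  if (nrow(hs) == 0) return(NA_real_)
  hs$to[1]
}
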