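#' Closed-phase O2 decline of one measurement cycle
#'
#' Ordinary least-squares regression of O2 concentration on time over the
#' closed (sealed measurement) segment of one cycle, returning the slope in
#' mg/L/h and the coefficient of determination used for quality gating.
#' A perfectly constant trace is degenerate: slope 0, r2 0.
#'
#' @param trace Tibble with columns `time_s`, `o2_mg_per_l`, `phase`,
#'   `cycle` (e.g. from [simulate_o2_trace()]).
#' @param cycle Which cycle to analyse.
#' @return One-row tibble with `cycle`, `slope` (mg/L/h), `r2`, `n`.
#' @export
closed_phase_slope <- function(trace, cycle) {
  seg <- trace[trace$phase == "closed" & trace$cycle == cycle, ]
  if (nrow(seg) == 0) stop("cycle ", cycle, " has no closed-phase samples")
  if (nrow(seg) < 3) stop("need at least 3 closed-phase samples, got ", nrow(seg))
  if (is.unsorted(seg$time_s, strictly = TRUE)) {
    stop("closed-phase times must be strictly increasing")
  }
  if (max(seg$o2_mg_per_l) == min(seg$o2_mg_per_l)) {
    # constant trace: slope 0 by convention, flagged by r2 = 0
    return(tibble::tibble(cycle = cycle, slope = 0, r2 = 0, n = nrow(seg)))
  }
  fit <- stats::lm(o2_mg_per_l ~ time_s, data = seg)
  slope_s <- stats::coef(fit)[["time_s"]]
  # summary.lm warns on noiseless (zero-residual) traces; the fit is valid
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) {
    slope_s <- 0
    r2 <- 0
  }
  tibble::tibble(cycle = cycle, slope = slope_s * 3600, r2 = r2, n = nrow(seg))
}

#' Mass-specific oxygen consumption from a background-corrected slope
#'
#' `MO2 = |fish_slope - background_slope| * effective_volume / fish_mass`,
#' in mgO2/kg/h. Consumption means the fish chamber declines faster (more
#' negative slope) than the background; if the corrected slope indicates net
#' O2 production instead, the value is still returned in magnitude but a
#' warning flags it.
#'
#' @param fish_slope Closed-phase slope of the fish chamber, mg/L/h.
#' @param background_slope Blank-chamber slope for the same cycle, mg/L/h.
#' @param effective_volume Chamber + tubing - fish volume, L.
#' @param fish_mass Fish mass, kg.
#' @return MO2 in mgO2/kg/h.
#' @export
#' @examples
#' compute_mo2(-0.36, 0, effective_volume = 0.300, fish_mass = 0.008)
compute_mo2 <- function(fish_slope, background_slope, effective_volume, fish_mass) {
  if (any(effective_volume <= 0)) stop("effective_volume must be positive")
  if (any(fish_mass <= 0)) stop("fish_mass must be positive")
  corrected <- fish_slope - background_slope
  if (any(corrected > 0)) {
    warning("corrected slope indicates net O2 production in some cycles")
  }
  abs(corrected) * effective_volume / fish_mass
}

#' Per-cycle MO2 records for a set of chambers
#'
#' Computes closed-phase slopes for every chamber and cycle, derives the
#' per-cycle background slope as the mean of the blank chambers' slopes
#' (matched by cycle index), corrects the fish slopes and converts to MO2.
#' The R2 quality gate applies to the fish-chamber regression itself: a
#' nonlinear trace is unusable regardless of the background.
#'
#' @param traces Tibble of samples for all chambers: columns `chamber_id`,
#'   `cycle`, `time_s`, `o2_mg_per_l`, `phase`.
#' @param geometry Tibble with one row per chamber: `chamber_id`,
#'   `is_blank`, `chamber_volume`, `tubing_volume`, `fish_mass` and
#'   optionally `fish_volume` (defaults to neutral buoyancy,
#'   `fish_mass` / 1 kg/L).
#' @param r2_threshold Minimum R2 for a cycle to pass QC (inclusive).
#' @return Tibble with one row per fish chamber and cycle: `chamber_id`,
#'   `cycle`, `slope`, `r2`, `background_slope`, `mo2`, `passed_qc`.
#' @export
mo2_records <- function(traces, geometry, r2_threshold = 0.9) {
  need <- c("chamber_id", "is_blank", "chamber_volume", "tubing_volume", "fish_mass")
  if (!all(need %in% names(geometry))) {
    stop("geometry must have columns ", paste(need, collapse = ", "))
  }
  if (!"fish_volume" %in% names(geometry)) {
    geometry$fish_volume <- geometry$fish_mass / 1.0
  }
  geometry$effective_volume <-
    geometry$chamber_volume + geometry$tubing_volume - geometry$fish_volume
  if (any(geometry$effective_volume <= 0)) stop("non-positive effective volume")
  if (!any(geometry$is_blank)) {
    warning("no blank chambers: background slope taken as 0")
  }

  slopes <- dplyr::bind_rows(lapply(unique(traces$chamber_id), function(ch) {
    tr <- traces[traces$chamber_id == ch, ]
    dplyr::mutate(
      dplyr::bind_rows(lapply(unique(tr$cycle), function(k) closed_phase_slope(tr, k))),
      chamber_id = ch
    )
  }))
  slopes <- dplyr::left_join(slopes, geometry, by = "chamber_id")

  bg <- dplyr::summarise(
    dplyr::group_by(slopes[slopes$is_blank, ], .data$cycle),
    background_slope = mean(.data$slope), .groups = "drop"
  )
  fish <- slopes[!slopes$is_blank, ]
  if (nrow(bg) > 0) {
    fish <- dplyr::left_join(fish, bg, by = "cycle")
    if (any(is.na(fish$background_slope))) {
      stop("no blank measurement for some cycle indices")
    }
  } else {
    fish$background_slope <- 0
  }

  fish$mo2 <- suppressWarnings(compute_mo2(
    fish$slope, fish$background_slope, fish$effective_volume, fish$fish_mass
  ))
  fish$net_production <- fish$slope - fish$background_slope > 0
  fish$passed_qc <- fish$r2 >= r2_threshold
  dplyr::select(
    fish, "chamber_id", "cycle", "slope", "r2", "background_slope",
    "mo2", "net_production", "passed_qc"
  )
}

#' Routine metabolic rate from quality-gated MO2 cycles
#'
#' RMR is the mean MO2 over the cycles whose closed-phase regression
#' attained `r2 >= r2_threshold` (the boundary value is included), per
#' chamber.
#'
#' @param records MO2 records from [mo2_records()] (columns `chamber_id`,
#'   `mo2`, `r2`).
#' @param r2_threshold Minimum R2, inclusive.
#' @return Tibble per chamber: `rmr` (mgO2/kg/h), `n_cycles_used`.
#' @export
rmr <- function(records, r2_threshold = 0.9) {
  if (nrow(records) == 0) stop("no MO2 records supplied")
  kept <- records[records$r2 >= r2_threshold, ]
  failed <- setdiff(unique(records$chamber_id), unique(kept$chamber_id))
  if (length(failed) > 0) {
    stop(
      "all cycles failed the R2 gate for chamber(s): ",
      paste(failed, collapse = ", ")
    )
  }
  dplyr::summarise(
    dplyr::group_by(kept, .data$chamber_id),
    rmr = mean(.data$mo2), n_cycles_used = dplyr::n(), .groups = "drop"
  )
}

#' Q10 thermal sensitivity coefficient
#'
#' Van't Hoff form `Q10 = (rate2 / rate1)^(10 / (temp2 - temp1))`: the
#' factor by which a physiological rate changes over a 10 degC interval.
#'
#' @param rate1,rate2 Positive rates at `temp1` and `temp2`.
#' @param temp1,temp2 Temperatures, degC; must differ.
#' @return Q10 value.
#' @export
#' @examples
#' q10(100, 200, 15, 25) # doubling over 10 degC -> 2
q10 <- function(rate1, rate2, temp1, temp2) {
  if (any(rate1 <= 0) || any(rate2 <= 0)) stop("rates must be strictly positive")
  if (any(temp1 == temp2)) stop("temperatures must differ")
  (rate2 / rate1)^(10 / (temp2 - temp1))
}
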