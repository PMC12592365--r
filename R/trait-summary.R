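#' Fulton's condition factor
#'
#' Body-condition index `K = 100 * weight / length^3`, with weight in grams
#' and total length in centimetres. K is invariant to isometric scaling:
#' doubling length with an eightfold weight leaves it unchanged.
#'
#' @param weight Weight in grams, positive.
#' @param total_length Total length in centimetres, positive.
#' @return Numeric vector of condition factors.
#' @export
#' @examples
#' fulton_k(15, 10.06)
fulton_k <- function(weight, total_length) {
  if (any(!is.finite(weight)) || any(!is.finite(total_length))) {
    stop("weight and total_length must be finite")
  }
  if (any(weight <= 0) || any(total_length <= 0)) {
    stop("weight and total_length must be strictly positive")
  }
  100 * weight / total_length^3
}

#' Summarise trait observations per treatment (or per tank)
#'
#' Reduces an individual-level trait table to the per-trait summaries
#' consumed by the thriving sub-models: arithmetic mean, standard error of
#' the mean (sample sd with the n-1 denominator divided by sqrt(n)) and n.
#' With `grouping = "treatment_by_tank"` each replicate tank yields its own
#' summary row, except at the control temperature, whose tanks are pooled
#' into the single control reference row.
#'
#' @param observations Tibble with columns `trait_id`, `treatment`, `tank`,
#'   `value` (and optionally `week`).
#' @param control_temp Control temperature, degC; must appear in the data.
#' @param grouping `"treatment_by_tank"` (default) or `"treatment"`.
#' @param by_week Keep weeks separate instead of pooling them (diagnostic
#'   mode; the thriving pipeline pools across weeks).
#'
#' @return Tibble with columns `trait_id`, `treatment`, `tank` (`NA` for
#'   pooled rows), `mean`, `se`, `n`, `is_control` (plus `week` when
#'   `by_week`). Exactly one control row per trait (per week).
#' @export
#' @examples
#' obs <- tibble::tibble(
#'   trait_id = "k", treatment = rep(c(19, 22), each = 3),
#'   tank = rep(c("a", "b"), each = 3), value = c(2, 4, 6, 3, 5, 7)
#' )
#' summarize_traits(obs, control_temp = 19)
summarize_traits <- function(observations, control_temp,
                             grouping = c("treatment_by_tank", "treatment"),
                             by_week = FALSE) {
  grouping <- match.arg(grouping)
  need <- c("trait_id", "treatment", "tank", "value")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(observations) == 0) stop("observations is empty")
  if (!control_temp %in% observations$treatment) {
    stop("control_temp ", control_temp, " not present in observations")
  }
  if (any(!is.finite(observations$value))) stop("trait values must be finite")

  keys <- c("trait_id", if (by_week) "week", "treatment")
  df <- dplyr::mutate(observations, is_control = .data$treatment == control_temp)
  if (grouping == "treatment_by_tank") {
    # control tanks pool into one reference row; test tanks stay separate
    df <- dplyr::mutate(df, tank = ifelse(.data$is_control, NA_character_, .data$tank))
    keys <- c(keys, "tank")
  }

  out <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(c(keys, "is_control")))),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
  if (grouping == "treatment") {
    out$tank <- NA_character_
    out <- dplyr::relocate(out, "tank", .after = "treatment")
  }
  bad <- out[out$n < 2, ]
  if (nrow(bad) > 0) {
    stop(
      "standard error undefined (n = 1) for: ",
      paste(sprintf("%s@%g", bad$trait_id, bad$treatment), collapse = ", ")
    )
  }
  dplyr::arrange(out, .data$trait_id, .data$treatment, .data$tank)
}
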