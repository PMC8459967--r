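#' Endpoint titers from serial-dilution ELISA series
#'
#' Computes, per serum x antigen series, the endpoint titer: the highest
#' reciprocal dilution at which the optical density still reaches
#' `target_od` (1.000 at 450 nm by default). In `"discrete"` mode this is the
#' largest measured dilution with OD >= target. In `"interpolated"` mode the
#' series is scanned from the highest dilution downwards for the last
#' crossing pair (OD_i >= target > OD_(i+1)) and the titer is linearly
#' interpolated between the pair in log2(reciprocal dilution) space --
#' reported titers therefore need not be members of the dilution ladder.
#' Series whose OD never drops below target are censored `"above_range"`
#' (titer = highest dilution); series never reaching target get titer `NA`
#' and `"below_range"`.
#'
#' @param data Long-format tibble with columns `serum_id`, `antigen_id`,
#'   `reciprocal_dilution` (positive, unique per series), `od`
#'   (non-negative). Each series needs at least two points.
#' @param target_od Target optical density (default 1.0).
#' @param mode `"interpolated"` (default) or `"discrete"`.
#' @return A tibble with one row per series: `serum_id`, `antigen_id`,
#'   `titer` (reciprocal dilution, `NA` for none), `mode`, `censored`
#'   (`"not_censored"`, `"above_range"`, `"below_range"`) and `noisy`
#'   (`TRUE` when OD rose by more than 10% between successive dilutions,
#'   flagging a non-monotone series).
#' @export
#' @examples
#' series <- tibble::tibble(
#'   serum_id = "r1", antigen_id = "pep1",
#'   reciprocal_dilution = c(2000, 4000, 8000, 16000),
#'   od = c(1.8, 1.4, 1.2, 0.8)
#' )
#' endpoint_titer(series)$titer # ~11314
endpoint_titer <- function(data, target_od = 1.0,
                           mode = c("interpolated", "discrete")) {
  mode <- match.arg(mode)
  check_number(target_od, "target_od", lower = 1e-12)
  need <- c("serum_id", "antigen_id", "reciprocal_dilution", "od")
  if (!all(need %in% names(data))) {
    abort_peptiter(sprintf("Plate data needs columns: %s", toString(need)),
                   "peptiter_validation_error")
  }
  if (any(data$od < 0) || any(data$reciprocal_dilution <= 0)) {
    abort_peptiter("ODs must be non-negative and dilutions positive.",
                   "peptiter_validation_error")
  }
  dup <- dplyr::count(data, .data$serum_id, .data$antigen_id,
                      .data$reciprocal_dilution)
  if (any(dup$n > 1L)) {
    abort_peptiter("Duplicate (serum, antigen, dilution) rows in plate data.",
                   "peptiter_validation_error")
  }
  data |>
    dplyr::group_by(.data$serum_id, .data$antigen_id) |>
    dplyr::arrange(.data$reciprocal_dilution, .by_group = TRUE) |>
    dplyr::summarise(
      titer_one(.data$reciprocal_dilution, .data$od, target_od, mode),
      .groups = "drop"
    )
}

titer_one <- function(dil, od, target, mode) {
  n <- length(od)
  if (n < 2L) {
    abort_peptiter("A dilution series needs at least two points.",
                   "peptiter_validation_error")
  }
  noisy <- any(od[-1] > od[-n] * 1.1)
  if (od[n] >= target) {
    return(tibble::tibble(titer = dil[n], mode = mode,
                          censored = "above_range", noisy = noisy))
  }
  if (all(od < target)) {
    return(tibble::tibble(titer = NA_real_, mode = mode,
                          censored = "below_range", noisy = noisy))
  }
  # last crossing pair, scanning from the highest dilution down
  i <- max(which(od[-n] >= target & od[-1] < target))
  if (mode == "discrete") {
    return(tibble::tibble(titer = max(dil[od >= target]), mode = mode,
                          censored = "not_censored", noisy = noisy))
  }
  frac <- (od[i] - target) / (od[i] - od[i + 1L])
  lt <- log2(dil[i]) + frac * (log2(dil[i + 1L]) - log2(dil[i]))
  tibble::tibble(titer = 2^lt, mode = mode,
                 censored = "not_censored", noisy = noisy)
}

#' Blank-based statistical positivity cutoff (Frey method)
#'
#' Computes the positivity threshold from a set of blank-well ODs as a
#' one-sided prediction bound: `cutoff = mean + sd * t * sqrt(1 + 1/n)`,
#' where `sd` is the sample standard deviation (n - 1 denominator) and `t`
#' the Student quantile at the requested confidence with n - 1 degrees of
#' freedom. At the default 99.9% confidence a fresh blank exceeds the cutoff
#' with probability 0.001.
#'
#' @param blank_od Numeric vector of blank ODs (n >= 2).
#' @param confidence Confidence level in (0.5, 1); default 0.999.
#' @return An object of class `frey_cutoff` with components `n_blanks`,
#'   `mean_blank`, `sd_blank`, `confidence`, `multiplier`, `cutoff`, and
#'   `degenerate` (`TRUE` when the blank sd is zero, in which case the
#'   cutoff collapses to the mean). Supports [tidy()][generics::tidy],
#'   [glance()][generics::glance], `print()` and [ggplot2::autoplot()].
#' @export
#' @examples
#' set.seed(1)
#' frey_cutoff(rnorm(16, 0.05, 0.01))
frey_cutoff <- function(blank_od, confidence = 0.999) {
  if (length(blank_od) < 2L || !is.numeric(blank_od)) {
    abort_peptiter("At least two blank ODs are required.",
                   "peptiter_validation_error")
  }
  if (any(!is.finite(blank_od))) {
    abort_peptiter("Blank ODs must be finite.", "peptiter_validation_error")
  }
  check_number(confidence, "confidence", lower = 0.5 + 1e-12,
               upper = 1 - 1e-12)
  n <- length(blank_od)
  m <- mean(blank_od)
  s <- stats::sd(blank_od)
  multiplier <- stats::qt(confidence, df = n - 1L) * sqrt(1 + 1 / n)
  structure(
    list(
      n_blanks = n, mean_blank = m, sd_blank = s, confidence = confidence,
      multiplier = multiplier, cutoff = m + s * multiplier,
      degenerate = s == 0, blank_od = blank_od
    ),
    class = "frey_cutoff"
  )
}

#' @export
print.frey_cutoff <- function(x, ...) {
  cat(sprintf(
    "Frey blank cutoff: %.4f OD (mean %.4f + sd %.4f x %.3f; n = %d, %.1f%% confidence)%s\n",
    x$cutoff, x$mean_blank, x$sd_blank, x$multiplier, x$n_blanks,
    100 * x$confidence, if (x$degenerate) " [degenerate: zero blank sd]" else ""
  ))
  invisible(x)
}

#' Apply a serum-retention rule to endpoint titers
#'
#' Two rules are used at different pipeline stages: at the titer stage,
#' titers below or equal to the threshold are discarded
#' (`"strict_greater"`); at the prolamin-sensitivity stage, titers equal or
#' higher than the threshold are conserved (`"greater_equal"`). A titer of
#' `NA` ("none") is discarded under both rules.
#'
#' @param titers Titer tibble from [endpoint_titer()].
#' @param threshold Reciprocal-dilution threshold (default 4000).
#' @param rule `"strict_greater"` (default) or `"greater_equal"`.
#' @return The titer tibble with logical `retained` and the `rule` applied.
#' @export
retain_sera <- function(titers, threshold = 4000,
                        rule = c("strict_greater", "greater_equal")) {
  rule <- match.arg(rule)
  check_number(threshold, "threshold", lower = 1e-12)
  kept <- if (rule == "strict_greater") {
    titers$titer > threshold
  } else {
    titers$titer >= threshold
  }
  titers$retained <- !is.na(kept) & kept
  titers$rule <- rule
  titers
}

REACTIVITY_BANDS <- c("-", "+/-", "+", "++", "+++")

#' Band an OD reading into a categorical cross-reactivity call
#'
#' Implements the banding used to report cross-reaction matrices: readings
#' below the blank cutoff are negative (`"-"`); readings above the cutoff but
#' at or below 0.050 OD are `"+/-"`; otherwise the reading is expressed as a
#' fraction of the serum's maximum OD and banded `"+++"` (75-100%), `"++"`
#' (25-75%) or `"+"` (below 25%). The corner case of a reading above 0.050 OD
#' but under 5% of the serum maximum is not covered by the published bands;
#' it is assigned `"+"` and flagged.
#'
#' @param od Numeric vector of OD readings.
#' @param serum_max_od Maximum OD produced by the same serum across antigens
#'   (positive; recycled).
#' @param cutoff Blank-based positivity cutoff (OD, >= 0; a `frey_cutoff`
#'   object is also accepted).
#' @return A tibble with `od`, `pct_of_max`, `band` (factor over
#'   `-, +/-, +, ++, +++`) and `flagged`.
#' @export
#' @examples
#' reactivity_band(c(1.5, 0.045, 0.02), serum_max_od = 1.6, cutoff = 0.03)
reactivity_band <- function(od, serum_max_od, cutoff) {
  if (inherits(cutoff, "frey_cutoff")) cutoff <- cutoff$cutoff
  if (any(serum_max_od <= 0)) {
    abort_peptiter("`serum_max_od` must be positive.",
                   "peptiter_validation_error")
  }
  if (any(od < 0) || any(cutoff < 0)) {
    abort_peptiter("ODs and cutoff must be non-negative.",
                   "peptiter_validation_error")
  }
  p <- od / serum_max_od
  band <- dplyr::case_when(
    od < cutoff ~ "-",
    od <= 0.050 ~ "+/-",
    p >= 0.75 ~ "+++",
    p >= 0.25 ~ "++",
    TRUE ~ "+"
  )
  tibble::tibble(
    od = od,
    pct_of_max = p,
    band = factor(band, levels = REACTIVITY_BANDS),
    flagged = band == "+" & p < 0.05
  )
}

#' Cross-reactivity calls for a serum x antigen OD table
#'
#' Convenience driver: takes one OD per (serum, antigen), derives each
#' serum's maximum OD across antigens, and bands every reading with
#' [reactivity_band()] against the supplied blank cutoff.
#'
#' @param data Tibble with `serum_id`, `antigen_id`, `od` (one row per pair).
#' @param cutoff A `frey_cutoff` object or a numeric cutoff OD.
#' @return A tibble of calls: `serum_id`, `antigen_id`, `od`, `pct_of_max`,
#'   `band`, `flagged`.
#' @export
call_reactivity <- function(data, cutoff) {
  need <- c("serum_id", "antigen_id", "od")
  if (!all(need %in% names(data))) {
    abort_peptiter(sprintf("Reactivity data needs columns: %s",
                           toString(need)),
                   "peptiter_validation_error")
  }
  dup <- dplyr::count(data, .data$serum_id, .data$antigen_id)
  if (any(dup$n > 1L)) {
    abort_peptiter("Duplicate (serum, antigen) cells in reactivity data.",
                   "peptiter_validation_error")
  }
  with_max <- data |>
    dplyr::group_by(.data$serum_id) |>
    dplyr::mutate(serum_max_od = max(.data$od)) |>
    dplyr::ungroup()
  dplyr::bind_cols(
    with_max[c("serum_id", "antigen_id")],
    reactivity_band(with_max$od, with_max$serum_max_od, cutoff)
  )
}

#' Serum x antigen band matrix
#'
#' Pivots reactivity calls into the rectangular layout used for
#' cross-reaction reporting, with `"n/a"` for untested cells. Printing the
#' returned tibble gives an aligned-text table; write it with
#' `write.table(..., sep = "\t")` for TSV.
#'
#' @param calls Call tibble from [call_reactivity()] (needs `serum_id`,
#'   `antigen_id`, `band`; at most one row per pair).
#' @return A wide tibble, one row per serum, one column per antigen.
#' @export
specificity_matrix <- function(calls) {
  if (nrow(calls) == 0L) {
    return(tibble::tibble(serum_id = character(0)))
  }
  dup <- dplyr::count(calls, .data$serum_id, .data$antigen_id)
  if (any(dup$n > 1L)) {
    abort_peptiter("Duplicate (serum, antigen) calls.",
                   "peptiter_validation_error")
  }
  calls |>
    dplyr::mutate(band = as.character(.data$band)) |>
    tidyr::pivot_wider(id_cols = "serum_id", names_from = "antigen_id",
                       values_from = "band", values_fill = "n/a") |>
    dplyr::arrange(.data$serum_id)
}
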