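#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Frey cutoff
#'
#' @param x A [frey_cutoff()] object.
#' @param ... Unused.
#' @return A one-row tibble with the cutoff components.
#' @export
tidy.frey_cutoff <- function(x, ...) {
  tibble::tibble(
    n_blanks = x$n_blanks, mean_blank = x$mean_blank, sd_blank = x$sd_blank,
    confidence = x$confidence, multiplier = x$multiplier, cutoff = x$cutoff,
    degenerate = x$degenerate
  )
}

#' @rdname tidy.frey_cutoff
#' @export
glance.frey_cutoff <- function(x, ...) tidy.frey_cutoff(x, ...)

#' Tidy a hapten selection run
#'
#' `tidy()` returns the full candidate audit table (ranked survivors first,
#' then rejected segments with their reasons); `glance()` summarizes the
#' funnel in one row.
#'
#' @param x A `hapten_selection` object from [run_selection()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hapten_selection <- function(x, ...) x$candidates

#' @rdname tidy.hapten_selection
#' @export
glance.hapten_selection <- function(x, ...) {
  cand <- x$candidates
  tibble::tibble(
    n_families = nrow(x$consensus),
    n_segments = nrow(cand),
    n_selected = sum(cand$status == "candidate"),
    n_rejected_exclusion = sum(cand$reject_reason == "exclusion_shared"),
    n_rejected_hydrophobic = sum(cand$reject_reason == "hydrophobic"),
    n_rejected_repeat = sum(cand$reject_reason == "repeat_run"),
    n_rejected_too_long = sum(cand$reject_reason == "too_long")
  )
}

#' Tidy a serology run
#'
#' `tidy()` returns the titer table with retention flags joined to the
#' reactivity bands; `glance()` gives a one-row summary (cutoff, retained
#' sera, band counts).
#'
#' @param x A `serology_run` object from [run_serology()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.serology_run <- function(x, ...) {
  dplyr::left_join(x$titers, x$calls, by = c("serum_id", "antigen_id"))
}

#' @rdname tidy.serology_run
#' @export
glance.serology_run <- function(x, ...) {
  band_counts <- table(factor(x$calls$band, levels = REACTIVITY_BANDS))
  tibble::tibble(
    cutoff = x$cutoff$cutoff,
    n_series = nrow(x$titers),
    n_retained = sum(x$titers$retained),
    n_negative = unname(band_counts[["-"]]),
    n_trace = unname(band_counts[["+/-"]]),
    n_positive = sum(band_counts[c("+", "++", "+++")])
  )
}
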