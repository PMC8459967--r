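#' Plot ELISA dilution curves
#'
#' OD against reciprocal dilution (log2 x-axis), one panel-free line per
#' serum x antigen series, with the endpoint target OD and, optionally, the
#' blank cutoff as horizontal references.
#'
#' @param plate Long plate tibble (`serum_id`, `antigen_id`,
#'   `reciprocal_dilution`, `od`).
#' @param target_od Endpoint target OD drawn as a dashed line (default 1.0).
#' @param cutoff Optional [frey_cutoff()] object or numeric OD, drawn dotted.
#' @return A ggplot object.
#' @export
plot_dilution_curves <- function(plate, target_od = 1.0, cutoff = NULL) {
  p <- ggplot2::ggplot(
    plate,
    ggplot2::aes(x = .data$reciprocal_dilution, y = .data$od,
                 colour = .data$serum_id, linetype = .data$antigen_id)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(
      trans = "log2",
      labels = function(x) paste0("1:", format(x, big.mark = " ",
                                               scientific = FALSE))
    ) +
    ggplot2::geom_hline(yintercept = target_od, linetype = "dashed") +
    ggplot2::labs(x = "serum dilution", y = "OD (450 nm)",
                  colour = "serum", linetype = "antigen") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    if (inherits(cutoff, "frey_cutoff")) cutoff <- cutoff$cutoff
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dotted")
  }
  p
}

#' Plot the selection funnel
#'
#' Bar chart of candidates kept and rejected at each pipeline stage, in the
#' style of a peptide selection flow chart.
#'
#' @param x A `hapten_selection` object or its `manifest` tibble.
#' @return A ggplot object.
#' @export
plot_selection_funnel <- function(x) {
  manifest <- if (inherits(x, "hapten_selection")) x$manifest else x
  long <- tidyr::pivot_longer(manifest, c("kept", "rejected"),
                              names_to = "outcome", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$stage, levels = manifest$stage),
    y = .data$n, fill = .data$outcome
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "candidates", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot candidate hydropathy against length
#'
#' Scatter of GRAVY versus candidate length, coloured by status/reason, with
#' the hydrophobicity threshold marked. Useful to see why the filters fired.
#'
#' @param candidates Candidate tibble (e.g. `tidy(run_selection(...))`).
#' @param gravy_threshold Threshold line to draw (default 0).
#' @return A ggplot object.
#' @export
plot_candidate_hydropathy <- function(candidates, gravy_threshold = 0) {
  lab <- ifelse(candidates$status == "candidate", "selected",
                candidates$reject_reason)
  ggplot2::ggplot(
    dplyr::mutate(candidates, outcome = lab),
    ggplot2::aes(x = .data$length, y = .data$gravy, colour = .data$outcome)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = gravy_threshold, linetype = "dashed") +
    ggplot2::labs(x = "candidate length (aa)", y = "GRAVY",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` dispatches to [plot_selection_funnel()] for selection runs,
#' [plot_dilution_curves()] for serology runs, and a blank histogram with the
#' cutoff marked for [frey_cutoff()] objects.
#'
#' @param object A `hapten_selection`, `serology_run` or `frey_cutoff`.
#' @param ... Passed through to the underlying plot function.
#' @return A ggplot object.
#' @name autoplot-peptiter
NULL

#' @rdname autoplot-peptiter
#' @export
autoplot.hapten_selection <- function(object, ...) {
  plot_selection_funnel(object)
}

#' @rdname autoplot-peptiter
#' @export
autoplot.serology_run <- function(object, ...) {
  plot_dilution_curves(object$plate,
                       target_od = object$config$titer_target_od,
                       cutoff = object$cutoff, ...)
}

#' @rdname autoplot-peptiter
#' @export
autoplot.frey_cutoff <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(od = object$blank_od),
                  ggplot2::aes(x = .data$od)) +
    ggplot2::geom_histogram(bins = max(10L, object$n_blanks %/% 4L)) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "blank OD (450 nm)", y = "wells",
                  title = sprintf("Frey cutoff %.4f OD (%.1f%% confidence)",
                                  object$cutoff, 100 * object$confidence)) +
    ggplot2::theme_minimal()
}
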