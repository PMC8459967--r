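# Synthetic ELISA plates from four-parameter-logistic (4PL) dose-response
# curves, with analytically known endpoint titers and Gaussian blank wells.

#' Four-parameter logistic OD model
#'
#' `OD(d) = D + (A - D) / (1 + (d / C)^B)` as a function of the reciprocal
#' serum dilution `d`: `A` is the low-dilution (upper) asymptote, `D` the
#' high-dilution (lower) asymptote, `C` the inflection dilution and `B > 0`
#' the slope, so OD decreases monotonically as the serum is diluted out.
#'
#' @param d Reciprocal dilution(s).
#' @param A,D Upper and lower OD asymptotes.
#' @param C Inflection point (reciprocal dilution).
#' @param B Slope parameter (> 0).
#' @return Numeric vector of noise-free ODs.
#' @export
fourpl <- function(d, A, D, C, B) {
  D + (A - D) / (1 + (d / C)^B)
}

#' Analytic endpoint titer of a 4PL curve
#'
#' Closed-form inversion of [fourpl()]: the reciprocal dilution at which the
#' noise-free curve crosses `target_od`. `NA` when the curve never reaches
#' the target (`A <= target_od`) or never drops to it (`D >= target_od`).
#'
#' @inheritParams fourpl
#' @param target_od Target OD (default 1.0).
#' @return The crossing reciprocal dilution, or `NA`.
#' @export
analytic_titer <- function(A, D, C, B, target_od = 1.0) {
  ifelse(A > target_od & target_od > D,
         C * ((A - D) / (target_od - D) - 1)^(1 / B),
         NA_real_)
}

#' Construct ground-truth 4PL parameters for synthetic sera
#'
#' One row per (serum, antigen) curve. Defaults describe a strongly reactive
#' indirect-ELISA serum: upper asymptote 2 OD, background 0.05 OD, slope 2,
#' inflection mid-ladder, read noise 0.02 OD. At slope 2 the curve is close
#' to linear in log2(dilution) around the OD 1.0 crossing, so endpoint
#' interpolation on a 2-fold ladder stays within ~1.3% of the analytic
#' crossing anywhere on the ladder.
#'
#' @param serum_id,antigen_id Labels (recycled to a common length).
#' @param A,D,C,B 4PL parameters (see [fourpl()]).
#' @param noise_sd Gaussian OD noise standard deviation.
#' @param target_od Target OD at which the analytic titer is recorded.
#' @return A tibble with the parameters plus the `analytic_titer` column.
#' @export
elisa_truth <- function(serum_id, antigen_id, A = 2, D = 0.05,
                        C = 12000, B = 2, noise_sd = 0.02,
                        target_od = 1.0) {
  tibble::tibble(
    serum_id = serum_id, antigen_id = antigen_id,
    A = A, D = D, C = C, B = B, noise_sd = noise_sd,
    analytic_titer = analytic_titer(A, D, C, B, target_od)
  )
}

#' Simulate an ELISA plate from 4PL ground truth
#'
#' For every truth row, generates `OD(d) = fourpl(d) + Normal(0, noise_sd)`
#' truncated at zero over the dilution ladder, plus a set of blank wells
#' drawn from `Normal(blank_mean, blank_sd)` truncated at zero.
#'
#' @param truth Truth tibble from [elisa_truth()].
#' @param reciprocal_dilutions Dilution ladder (default the 2-fold series
#'   2000 to 256000 used for endpoint titration).
#' @param n_blanks Number of blank wells (default 16).
#' @param blank_mean,blank_sd Blank OD distribution (defaults 0.05, 0.01).
#' @param seed Optional integer seed (independent of the sequence stream;
#'   RNG state restored afterwards).
#' @return A list with `plate` (long tibble `serum_id`, `antigen_id`,
#'   `reciprocal_dilution`, `od`), `blanks` (numeric vector) and the `truth`
#'   tibble passed in.
#' @export
#' @examples
#' truth <- elisa_truth("r1", "pep1", noise_sd = 0)
#' plate <- generate_elisa_plate(truth, seed = 1)
#' endpoint_titer(plate$plate)
generate_elisa_plate <- function(truth,
                                 reciprocal_dilutions = 2000 * 2^(0:7),
                                 n_blanks = 16L, blank_mean = 0.05,
                                 blank_sd = 0.01, seed = NULL) {
  if (any(diff(reciprocal_dilutions) <= 0) || any(reciprocal_dilutions <= 0)) {
    abort_peptiter("`reciprocal_dilutions` must be positive and increasing.",
                   "peptiter_validation_error")
  }
  check_number(n_blanks, "n_blanks", lower = 2)
  if (!is.null(seed)) withr::local_seed(seed)
  plate <- purrr::pmap_dfr(
    truth,
    function(serum_id, antigen_id, A, D, C, B, noise_sd, ...) {
      tibble::tibble(
        serum_id = serum_id, antigen_id = antigen_id,
        reciprocal_dilution = reciprocal_dilutions,
        od = pmax(0, fourpl(reciprocal_dilutions, A, D, C, B) +
                     stats::rnorm(length(reciprocal_dilutions),
                                  sd = noise_sd))
      )
    }
  )
  blanks <- pmax(0, stats::rnorm(n_blanks, mean = blank_mean, sd = blank_sd))
  list(plate = plate, blanks = blanks, truth = truth)
}
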