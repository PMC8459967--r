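#' Default pipeline configuration
#'
#' All tunable parameters of the selection and serology pipelines with their
#' defaults. Every threshold used by [run_selection()] and [run_serology()]
#' flows through this record; nothing is hardcoded downstream.
#'
#' @details
#' * `min_segment_len` (6): minimum length of an unshared consensus segment
#'   kept as a hapten candidate; six residues is the shortest peptide
#'   generally able to elicit antibodies that re-bind the source protein.
#' * `shared_window` (6): exact-substring window used to call a consensus
#'   position "shared" with another grain.
#' * `gravy_threshold` (0): candidates with GRAVY at or above this are
#'   rejected as hydrophobic (Kyte-Doolittle convention: hydrophilic < 0).
#' * `max_run` (3): longest tolerated run of one repeated residue.
#' * `preferred_min_len` (9): candidates with at least this many residues
#'   (strictly more than 8) are prioritized in ranking, not hard-filtered.
#' * `max_len` (20): candidates longer than this are discarded outright.
#' * `titer_target_od` (1.0): OD the endpoint titer must reach at 450 nm.
#' * `titer_mode` ("interpolated"): "discrete" or "interpolated" (log2 space).
#' * `cutoff_confidence` (0.999): confidence level of the blank-based cutoff.
#' * `retention_titer` (4000): reciprocal-dilution threshold for keeping sera.
#' * `retention_rule` ("strict_greater"): "strict_greater" at the titer stage
#'   ("below or equal" discarded) or "greater_equal" at the prolamin
#'   sensitivity stage ("equal or higher" conserved).
#' * `consensus_gap_rule` ("majority"): whether gaps vote in the consensus
#'   ("majority") or are ignored ("ignore").
#' * `uniqueness_scope` ("cross_grain"): segments must be unique across
#'   grains; "all_vs_all" also disqualifies sharing between a grain's own
#'   protein families.
#' * `gravy_on_ambiguity` ("error"): "error" or "skip" when ambiguity letters
#'   reach the GRAVY computation.
#' * `seed` (NULL): optional integer seed recorded in run manifests.
#'
#' @return A named list of parameters.
#' @seealso [load_config()]
#' @export
default_config <- function() {
  list(
    min_segment_len = 6L,
    shared_window = 6L,
    gravy_threshold = 0,
    max_run = 3L,
    preferred_min_len = 9L,
    max_len = 20L,
    titer_target_od = 1.0,
    titer_mode = "interpolated",
    cutoff_confidence = 0.999,
    retention_titer = 4000,
    retention_rule = "strict_greater",
    consensus_gap_rule = "majority",
    uniqueness_scope = "cross_grain",
    gravy_on_ambiguity = "error",
    seed = NULL
  )
}

#' Load pipeline configuration from a YAML file
#'
#' Reads a flat or one-level-nested YAML file and merges it over
#' [default_config()]. Unknown keys fail closed; out-of-range values raise an
#' error naming the violated bound. An empty file yields all defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated configuration list (see [default_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort_peptiter(sprintf("Config file not found: %s", path),
                   "peptiter_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  # flatten one level of sections (e.g. selection:, serology:)
  flat <- list()
  for (key in names(raw)) {
    val <- raw[[key]]
    if (is.list(val) && !is.null(names(val))) {
      flat <- c(flat, val)
    } else {
      flat[[key]] <- val
    }
  }
  validate_config(utils::modifyList(default_config(), flat, keep.null = TRUE),
                  user_keys = names(flat))
}

validate_config <- function(config, user_keys = names(config)) {
  known <- names(default_config())
  unknown <- setdiff(user_keys, known)
  if (length(unknown) > 0L) {
    abort_peptiter(
      sprintf("Unknown configuration key(s): %s", toString(unknown)),
      "peptiter_config_error"
    )
  }
  check_number(config$min_segment_len, "min_segment_len", lower = 1)
  check_number(config$shared_window, "shared_window", lower = 1)
  check_number(config$gravy_threshold, "gravy_threshold")
  check_number(config$max_run, "max_run", lower = 1)
  check_number(config$preferred_min_len, "preferred_min_len", lower = 1)
  check_number(config$max_len, "max_len", lower = 1)
  if (config$max_len < config$preferred_min_len) {
    abort_peptiter(
      sprintf(
        "max_len (%d) must be >= preferred_min_len (%d).",
        as.integer(config$max_len), as.integer(config$preferred_min_len)
      ),
      "peptiter_config_error"
    )
  }
  check_number(config$titer_target_od, "titer_target_od", lower = 1e-12)
  check_number(config$cutoff_confidence, "cutoff_confidence",
               lower = 0.5 + 1e-12, upper = 1 - 1e-12)
  check_number(config$retention_titer, "retention_titer", lower = 1e-12)
  if (!is.null(config$seed)) check_number(config$seed, "seed")
  choices <- list(
    titer_mode = c("discrete", "interpolated"),
    retention_rule = c("strict_greater", "greater_equal"),
    consensus_gap_rule = c("majority", "ignore"),
    uniqueness_scope = c("cross_grain", "all_vs_all"),
    gravy_on_ambiguity = c("error", "skip")
  )
  for (key in names(choices)) {
    if (!is_scalar_string(config[[key]]) ||
        !config[[key]] %in% choices[[key]]) {
      abort_peptiter(
        sprintf("`%s` must be one of: %s", key, toString(choices[[key]])),
        "peptiter_config_error"
      )
    }
  }
  config
}
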