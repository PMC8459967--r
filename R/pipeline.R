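#' Run the full hapten-selection pipeline
#'
#' Orchestrates consensus building, grain-uniqueness mining, the exclusion
#' screen, the hydropathy/repeat/length filters, ranking and synthesis-string
#' preparation, and records a stage-by-stage funnel manifest in which, at
#' every stage, `found == kept + rejected`.
#'
#' @param alignments Alignment tibble covering all families (`grain`, `gpt`,
#'   `seq_id`, `sequence`), e.g. from [read_alignment()] calls or
#'   [generate_grain_set()].
#' @param exclusion Optional exclusion set: character vector of off-target
#'   consensus sequences or a tibble with a `sequence` column.
#' @param gpt_abundance Optional GPT gluten-proportion mapping for ranking
#'   (see [rank_candidates()]).
#' @param config Configuration list (see [default_config()]).
#' @param scale Hydropathy scale (default [kyte_doolittle()]).
#' @return An object of class `hapten_selection`: a list with `candidates`
#'   (full audit table, ranked survivors first), `consensus`, `manifest`
#'   (funnel counts) and `config`. Supports [tidy()][generics::tidy],
#'   [glance()][generics::glance] and [ggplot2::autoplot()].
#' @export
#' @examples
#' gs <- generate_grain_set(seed = 42)
#' sel <- run_selection(gs$alignments, exclusion = gs$exclusion)
#' glance(sel)
run_selection <- function(alignments, exclusion = NULL,
                          gpt_abundance = NULL, config = default_config(),
                          scale = kyte_doolittle()) {
  config <- validate_config(config)
  validate_alignment_tbl(alignments)

  consensus <- build_consensus(alignments, gap_rule = config$consensus_gap_rule)
  segments <- find_unique_segments(
    consensus, window = config$shared_window,
    min_len = config$min_segment_len, scope = config$uniqueness_scope
  )
  screened <- screen_exclusion(segments, exclusion,
                               window = config$shared_window)
  scored <- score_candidates(screened, consensus, scale = scale,
                             on_ambiguity = config$gravy_on_ambiguity)
  filtered <- filter_candidates(
    scored, gravy_threshold = config$gravy_threshold,
    max_run = config$max_run, max_len = config$max_len
  )
  survivors <- dplyr::filter(filtered, .data$status == "candidate")
  rejected <- dplyr::filter(filtered, .data$status != "candidate")
  ranked <- rank_candidates(survivors, gpt_abundance = gpt_abundance,
                            preferred_min_len = config$preferred_min_len)
  if (nrow(ranked) > 0L) {
    ranked$synthesis_sequence <- prepare_synthesis(ranked$sequence)
  } else {
    ranked$synthesis_sequence <- character(0)
  }
  rejected <- dplyr::arrange(rejected, .data$grain, .data$gpt, .data$start)
  candidates <- dplyr::bind_rows(ranked, rejected)

  n_seg <- nrow(segments)
  n_excl <- sum(screened$status == "rejected")
  n_filt <- nrow(rejected) - n_excl
  manifest <- tibble::tibble(
    stage = c("consensus", "uniqueness_mining", "exclusion_screen",
              "property_filters", "ranking"),
    found = c(dplyr::n_distinct(alignments$grain, alignments$gpt),
              n_seg, n_seg, n_seg - n_excl, nrow(ranked)),
    kept = c(nrow(consensus), n_seg, n_seg - n_excl,
             n_seg - n_excl - n_filt, nrow(ranked)),
    rejected = c(0L, 0L, n_excl, n_filt, 0L)
  )
  structure(
    list(candidates = candidates, consensus = consensus,
         manifest = manifest, config = config),
    class = "hapten_selection"
  )
}

#' @export
print.hapten_selection <- function(x, ...) {
  cat(sprintf(
    "Hapten selection: %d consensus families, %d unique segments, %d selected.\n",
    nrow(x$consensus), x$manifest$found[x$manifest$stage == "exclusion_screen"],
    sum(x$candidates$status == "candidate")
  ))
  print(x$manifest)
  invisible(x)
}

#' Run the serology analytics pipeline
#'
#' Chains the blank-based Frey cutoff, per-series endpoint titers, the serum
#' retention rule and cross-reactivity banding (each serum x antigen pair is
#' banded on its maximum OD across the ladder, relative to the serum's
#' strongest signal) into one reproducible report.
#'
#' @param plate Long plate tibble (`serum_id`, `antigen_id`,
#'   `reciprocal_dilution`, `od`).
#' @param blanks Numeric vector of blank-well ODs (required for banding).
#' @param config Configuration list (see [default_config()]).
#' @return An object of class `serology_run`: `cutoff` (a [frey_cutoff()]
#'   object), `titers` (with retention flags), `calls`, `matrix`
#'   (serum x antigen band table), `manifest` and `config`. Supports
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' truth <- elisa_truth(c("r1", "r2"), "pep1", C = c(12000, 3000))
#' plate <- generate_elisa_plate(truth, seed = 7)
#' run_serology(plate$plate, plate$blanks)
run_serology <- function(plate, blanks, config = default_config()) {
  config <- validate_config(config)
  if (missing(blanks) || is.null(blanks) || length(blanks) == 0L) {
    abort_peptiter("Blank ODs are required to fix the cutoff for banding.",
                   "peptiter_validation_error")
  }
  cutoff <- frey_cutoff(blanks, confidence = config$cutoff_confidence)
  titers <- endpoint_titer(plate, target_od = config$titer_target_od,
                           mode = config$titer_mode)
  titers <- retain_sera(titers, threshold = config$retention_titer,
                        rule = config$retention_rule)
  per_pair <- plate |>
    dplyr::group_by(.data$serum_id, .data$antigen_id) |>
    dplyr::summarise(od = max(.data$od), .groups = "drop")
  calls <- call_reactivity(per_pair, cutoff)
  manifest <- tibble::tibble(
    stage = c("titer", "retention", "banding"),
    found = c(nrow(titers), nrow(titers), nrow(calls)),
    kept = c(nrow(titers), sum(titers$retained), nrow(calls)),
    rejected = c(0L, sum(!titers$retained), 0L)
  )
  structure(
    list(cutoff = cutoff, titers = titers, calls = calls,
         matrix = specificity_matrix(calls), manifest = manifest,
         config = config, plate = plate),
    class = "serology_run"
  )
}

#' @export
print.serology_run <- function(x, ...) {
  print(x$cutoff)
  cat(sprintf("%d series titrated, %d sera retained (%s rule).\n",
              nrow(x$titers), sum(x$titers$retained),
              x$config$retention_rule))
  print(x$matrix)
  invisible(x)
}

#' Write a complete synthetic demo dataset to disk
#'
#' Materializes one seeded scenario as plain-text files: one aligned FASTA
#' per family, the exclusion FASTA, the planted-truth TSV, a 4PL plate TSV
#' with its blank TSV and ELISA truth TSV, and the configuration as YAML --
#' everything needed to exercise both pipelines from files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for both generators.
#' @param config Configuration list to snapshot alongside the data.
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture_set <- function(dir, seed = 1L, config = default_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gs <- generate_grain_set(seed = seed)
  paths <- list()
  fams <- dplyr::group_split(gs$alignments, .data$grain, .data$gpt)
  for (fam in fams) {
    p <- file.path(dir, sprintf("%s_%s.fasta", fam$grain[1], fam$gpt[1]))
    write_alignment_fasta(fam, p)
    paths[[length(paths) + 1L]] <- p
  }
  if (nrow(gs$exclusion) > 0L) {
    p <- file.path(dir, "exclusion_synthetic.fasta")
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(stats::setNames(gs$exclusion$sequence,
                                              gs$exclusion$id)), p)
    paths$exclusion <- p
  }
  paths$truth <- file.path(dir, "planted_truth.tsv")
  utils::write.table(gs$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- elisa_truth(
    serum_id = sprintf("rabbit%02d", 1:6),
    antigen_id = "peptide01",
    C = c(24000, 12000, 6000, 3000, 1500, 500),
    B = 2.2
  )
  sim <- generate_elisa_plate(truth, seed = seed)
  paths$plate <- file.path(dir, "plate.tsv")
  utils::write.table(sim$plate, paths$plate, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$blanks <- file.path(dir, "blanks.tsv")
  utils::write.table(data.frame(od = sim$blanks), paths$blanks, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$elisa_truth <- file.path(dir, "elisa_truth.tsv")
  utils::write.table(sim$truth, paths$elisa_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- config
  cfg$seed <- seed
  paths$config <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
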