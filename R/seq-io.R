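#' Read one aligned protein family
#'
#' Reads a multiple sequence alignment for a single gluten-protein-type (GPT)
#' family from aligned FASTA or Clustal format (via Biostrings) and returns a
#' validated, case-normalized alignment tibble. Lowercase residues are
#' upcased, the `.` gap alias is normalized to `-`, `*` (stop) is rejected,
#' and any letter outside the 20 standard residues plus the ambiguity codes
#' X/B/Z/U/O raises a validation error naming the offending record.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` (aligned FASTA, any line-wrapping width) or
#'   `"clustal"`.
#' @param grain Grain label for the family (e.g. `"wheat"`).
#' @param gpt_name Protein-family label (e.g. `"alpha_gliadin"`).
#' @return A tibble with columns `grain`, `gpt`, `seq_id`, `sequence`, one
#'   row per aligned sequence; all sequences have identical width.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "QPQ", ">s2", "QPQ"), fa)
#' read_alignment(fa, "fasta", grain = "wheat", gpt_name = "alpha_gliadin")
read_alignment <- function(path, format = c("fasta", "clustal"),
                           grain, gpt_name) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_peptiter(sprintf("Alignment file not found: %s", path),
                   "peptiter_io_error")
  }
  seqs <- if (format == "fasta") {
    # readAAStringSet tolerates ragged records, letting us name the offender
    x <- Biostrings::readAAStringSet(path)
    stats::setNames(as.character(x), names(x))
  } else {
    x <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "clustal"),
      error = function(e) {
        abort_peptiter(
          sprintf("Failed to parse %s as Clustal: %s", path,
                  conditionMessage(e)),
          "peptiter_format_error"
        )
      }
    )
    as.character(x)  # named by the Clustal row labels
  }
  if (length(seqs) == 0L) {
    abort_peptiter(sprintf("No sequences in %s", path),
                   "peptiter_format_error")
  }
  protein_family(grain = grain, gpt_name = gpt_name,
                 sequence = unname(seqs), seq_id = names(seqs))
}

#' Construct and validate an aligned protein family
#'
#' The in-memory form of one GPT family: a tibble of aligned residue strings.
#' Enforces the family invariants (equal widths, unique ids, clean alphabet)
#' and performs the same normalization as [read_alignment()].
#'
#' @param grain,gpt_name Labels for the family.
#' @param sequence Character vector of aligned residue strings.
#' @param seq_id Character vector of unique record ids (defaults to `seq1..n`).
#' @return A validated alignment tibble (`grain`, `gpt`, `seq_id`, `sequence`).
#' @export
protein_family <- function(grain, gpt_name, sequence,
                           seq_id = paste0("seq", seq_along(sequence))) {
  if (length(sequence) == 0L) {
    abort_peptiter("A protein family needs at least one sequence.",
                   "peptiter_validation_error")
  }
  if (length(seq_id) != length(sequence)) {
    abort_peptiter("`seq_id` and `sequence` lengths differ.",
                   "peptiter_validation_error")
  }
  if (anyDuplicated(seq_id)) {
    abort_peptiter(
      sprintf("Duplicate sequence ids: %s",
              toString(unique(seq_id[duplicated(seq_id)]))),
      "peptiter_validation_error"
    )
  }
  sequence <- chartr(".", GAP_CHAR, toupper(sequence))
  widths <- nchar(sequence)
  if (widths[1] == 0L) {
    abort_peptiter("Aligned sequences must have positive length.",
                   "peptiter_validation_error")
  }
  if (length(unique(widths)) != 1L) {
    counts <- table(widths)
    majority <- as.integer(names(counts)[counts == max(counts)])
    # on a tie the first record is taken as the reference width
    ref <- if (widths[1] %in% majority) widths[1] else majority[1]
    bad <- seq_id[widths != ref]
    abort_peptiter(
      sprintf("Ragged alignment: record(s) %s differ in length.",
              toString(bad)),
      "peptiter_format_error"
    )
  }
  allowed <- c(AA_STANDARD, AA_AMBIGUITY, GAP_CHAR)
  bad_chars <- vapply(
    seq_chars(sequence),
    function(ch) paste(sort(unique(ch[!ch %in% allowed])), collapse = ""),
    character(1)
  )
  if (any(bad_chars != "")) {
    offender <- which(bad_chars != "")[1]
    abort_peptiter(
      sprintf("Record %s contains invalid residue letter(s): %s",
              seq_id[offender], bad_chars[offender]),
      "peptiter_validation_error"
    )
  }
  tibble::tibble(grain = grain, gpt = gpt_name,
                 seq_id = seq_id, sequence = sequence)
}

validate_alignment_tbl <- function(alignments) {
  need <- c("grain", "gpt", "seq_id", "sequence")
  if (!all(need %in% names(alignments))) {
    abort_peptiter(
      sprintf("Alignment table needs columns: %s", toString(need)),
      "peptiter_validation_error"
    )
  }
  if (nrow(alignments) == 0L) {
    abort_peptiter("No families: the alignment table is empty.",
                   "peptiter_validation_error")
  }
  invisible(alignments)
}

candidate_columns <- c(
  "grain", "gpt", "start", "end", "sequence", "length", "gravy", "max_run",
  "occurrence", "rank_score", "synthesis_sequence", "status", "reject_reason"
)

#' Write a hapten candidate table to TSV
#'
#' Serializes candidates in rank order with the full audit schema (scores,
#' statuses and rejection reasons). Numeric columns are written with enough
#' digits that [read_candidates()] round-trips them bit-exactly.
#'
#' @param candidates A candidate tibble (any subset of pipeline stages);
#'   missing schema columns are filled with `NA`.
#' @param path Output path.
#' @return Invisibly, the normalized table that was written.
#' @export
write_candidates <- function(candidates, path) {
  out <- tibble::as_tibble(candidates)
  for (col in setdiff(candidate_columns, names(out))) out[[col]] <- NA
  out <- out[candidate_columns]
  fmt <- out
  fmt$gravy <- ifelse(is.na(out$gravy), "NA", sprintf("%.17g", out$gravy))
  ok <- tryCatch({
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    abort_peptiter(sprintf("Cannot write candidate table to %s: %s",
                           path, conditionMessage(ok)),
                   "peptiter_io_error")
  }
  invisible(out)
}

#' Read a hapten candidate table written by [write_candidates()]
#'
#' @param path Path to the TSV.
#' @return A tibble with the full candidate schema.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) {
    abort_peptiter(sprintf("Candidate table not found: %s", path),
                   "peptiter_io_error")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = "NA")
  if (!identical(names(tab), candidate_columns)) {
    abort_peptiter("Candidate table header does not match the schema.",
                   "peptiter_format_error")
  }
  tibble::tibble(
    grain = tab$grain, gpt = tab$gpt,
    start = as.integer(tab$start), end = as.integer(tab$end),
    sequence = tab$sequence, length = as.integer(tab$length),
    gravy = as.numeric(tab$gravy), max_run = as.integer(tab$max_run),
    occurrence = as.integer(tab$occurrence),
    rank_score = as.integer(tab$rank_score),
    synthesis_sequence = tab$synthesis_sequence,
    status = tab$status,
    reject_reason = ifelse(is.na(tab$reject_reason), "", tab$reject_reason)
  )
}

#' Write an alignment tibble as aligned FASTA
#'
#' One file per call; all rows must belong to one family (one grain/GPT).
#'
#' @param alignments Alignment tibble (`grain`, `gpt`, `seq_id`, `sequence`).
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_alignment_fasta <- function(alignments, path) {
  validate_alignment_tbl(alignments)
  set <- Biostrings::AAStringSet(
    stats::setNames(alignments$sequence, alignments$seq_id)
  )
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write consensus sequences as ungapped FASTA
#'
#' Headers take the form `>grain|gpt`. Per-position support can be written
#' alongside with [write_consensus_support()].
#'
#' @param consensus A consensus tibble from [build_consensus()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_consensus_fasta <- function(consensus, path) {
  set <- Biostrings::AAStringSet(
    stats::setNames(consensus$sequence, paste(consensus$grain,
                                              consensus$gpt, sep = "|"))
  )
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write per-position consensus support as TSV
#'
#' Long-format table: one row per consensus position with its modal-residue
#' support fraction and the 0-based source alignment column.
#'
#' @inheritParams write_consensus_fasta
#' @return Invisibly, `path`.
#' @export
write_consensus_support <- function(consensus, path) {
  long <- tidyr::unnest(
    dplyr::mutate(
      consensus,
      position = purrr::map(.data$support, ~ seq_along(.x) - 1L),
      residue = purrr::map(.data$sequence,
                           ~ strsplit(.x, "", fixed = TRUE)[[1]])
    ),
    cols = c("position", "residue", "support", "source_columns")
  )
  utils::write.table(
    long[c("grain", "gpt", "position", "residue", "support",
           "source_columns")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
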