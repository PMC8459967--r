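#' Build consensus sequences from aligned protein families
#'
#' Compiles, for every family (grain x GPT) in the alignment table, the
#' modal-residue consensus: at each alignment column the most frequent symbol
#' over the 20 standard residues and the gap is taken. If the mode is a
#' residue it joins the consensus with support = modal count / number of
#' sequences; if the mode is the gap, the column is dropped, so the consensus
#' is ungapped. Ties are broken residue-over-gap, then alphabetically.
#' Ambiguity letters (X/B/Z/U/O) abstain from the vote but still count in the
#' denominator, so they can never win a column.
#'
#' @param alignments Alignment tibble (`grain`, `gpt`, `seq_id`, `sequence`),
#'   e.g. from [read_alignment()] or [generate_grain_set()].
#' @param gap_rule `"majority"` (default; gaps vote and gap-majority columns
#'   are dropped) or `"ignore"` (gaps are excluded from both the vote and the
#'   denominator; columns with no residue votes are dropped).
#' @return A tibble with one row per family: `grain`, `gpt`, `sequence`
#'   (ungapped consensus string), `n_seqs`, and list-columns `support`
#'   (modal-vote fraction per consensus position, each in (0, 1]) and
#'   `source_columns` (0-based alignment column per consensus position,
#'   strictly increasing).
#' @export
#' @examples
#' fam <- protein_family("wheat", "alpha_gliadin", c("QPQ", "QPQ", "QAQ"))
#' build_consensus(fam)$sequence # "QPQ"
build_consensus <- function(alignments, gap_rule = c("majority", "ignore")) {
  gap_rule <- match.arg(gap_rule)
  validate_alignment_tbl(alignments)
  alignments |>
    dplyr::group_by(.data$grain, .data$gpt) |>
    dplyr::summarise(
      consensus_one(.data$sequence, gap_rule,
                    family = paste(.data$grain[1], .data$gpt[1], sep = "/")),
      .groups = "drop"
    )
}

consensus_one <- function(sequences, gap_rule, family = "family") {
  n <- length(sequences)
  mat <- do.call(rbind, seq_chars(sequences))
  levels <- c(AA_STANDARD, GAP_CHAR)
  keep <- logical(ncol(mat))
  winner <- character(ncol(mat))
  supp <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    counts <- tabulate(factor(col, levels = levels), nbins = length(levels))
    names(counts) <- levels
    denom <- if (gap_rule == "majority") n else sum(counts[AA_STANDARD])
    votes <- if (gap_rule == "majority") counts else counts[AA_STANDARD]
    if (all(votes == 0L)) next   # all-gap or all-ambiguity column: drop
    top <- max(votes)
    tied <- names(votes)[votes == top]
    # residue beats gap, then alphabetical residue order
    pick <- if (any(tied != GAP_CHAR)) sort(tied[tied != GAP_CHAR])[1] else GAP_CHAR
    if (pick == GAP_CHAR) next
    keep[j] <- TRUE
    winner[j] <- pick
    supp[j] <- top / denom
  }
  if (!any(keep)) {
    abort_peptiter(
      sprintf("Empty consensus for %s: no column has a residue majority.",
              family),
      "peptiter_validation_error"
    )
  }
  tibble::tibble(
    sequence = paste(winner[keep], collapse = ""),
    n_seqs = n,
    support = list(supp[keep]),
    source_columns = list(which(keep) - 1L)
  )
}
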