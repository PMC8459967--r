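#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of per-residue Kyte-Doolittle hydropathy values over a
#' peptide. Negative GRAVY marks a hydrophilic peptide; the selection
#' pipeline keeps candidates with GRAVY strictly below the configured
#' threshold (default 0).
#'
#' @param sequence Character vector of residue strings (vectorized).
#' @param scale Named hydropathy vector, default [kyte_doolittle()].
#' @param on_ambiguity `"error"` (default) raises on ambiguity letters
#'   (X/B/Z/U/O); `"skip"` drops them from the mean (an all-ambiguity
#'   sequence still errors).
#' @return Numeric vector of GRAVY values, one per input sequence.
#' @export
#' @examples
#' gravy("IIIII") # 4.5
#' gravy("CDEF")  # -0.425
gravy <- function(sequence, scale = kyte_doolittle(),
                  on_ambiguity = c("error", "skip")) {
  on_ambiguity <- match.arg(on_ambiguity)
  validate_scale(scale)
  vapply(sequence, function(s) {
    if (is.na(s) || nchar(s) == 0L) {
      abort_peptiter("GRAVY is undefined for an empty sequence.",
                     "peptiter_validation_error")
    }
    ch <- seq_chars(s)[[1]]
    bad <- !ch %in% AA_STANDARD
    if (any(bad)) {
      if (on_ambiguity == "error" || any(!ch[bad] %in% AA_AMBIGUITY)) {
        abort_peptiter(
          sprintf("Non-standard residue(s) %s in \"%s\"; GRAVY undefined.",
                  toString(unique(ch[bad])), s),
          "peptiter_validation_error"
        )
      }
      ch <- ch[!bad]
      if (length(ch) == 0L) {
        abort_peptiter(
          sprintf("\"%s\" has no standard residues; GRAVY undefined.", s),
          "peptiter_validation_error"
        )
      }
    }
    mean(scale[ch])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Longest single-residue run
#'
#' Length of the longest run of one repeated residue, used to reject
#' candidates with too many consecutive repetitions of the same amino acid
#' (gluten sequences are rich in QQQ.../PPP... motifs that make poor
#' discriminating haptens).
#'
#' @param sequence Character vector of residue strings (vectorized).
#' @return Integer vector of maximal run lengths (each >= 1).
#' @export
#' @examples
#' max_residue_run("QQQPFP") # 3
max_residue_run <- function(sequence) {
  vapply(sequence, function(s) {
    if (is.na(s) || nchar(s) == 0L) {
      abort_peptiter("Run length is undefined for an empty sequence.",
                     "peptiter_validation_error")
    }
    max(rle(seq_chars(s)[[1]])$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

#' Count overlapping occurrences of a segment in a consensus set
#'
#' Total number of (possibly overlapping) exact occurrences of `segment`
#' across a set of consensus strings -- the "occurrence in their respective
#' GPT's consensus sequences" used as the leading ranking key.
#'
#' @param segment A single non-empty residue string.
#' @param sequences Character vector of consensus strings (typically all
#'   consensus sequences of the segment's own grain).
#' @return A single integer count.
#' @export
#' @examples
#' count_occurrences("QQP", "AQQPQQPA") # 2
count_occurrences <- function(segment, sequences) {
  if (!is_scalar_string(segment) || nchar(segment) == 0L) {
    abort_peptiter("`segment` must be a single non-empty string.",
                   "peptiter_validation_error")
  }
  pat <- paste0("(?=", segment, ")")
  sum(vapply(sequences, function(s) {
    hits <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }, integer(1), USE.NAMES = FALSE))
}

#' Score segments with GRAVY, repeat run and occurrence
#'
#' Adds the per-candidate statistics the filters and ranking need: `gravy`,
#' `max_run`, and `occurrence` (overlapping count of the segment across the
#' consensus sequences of its own grain).
#'
#' @param segments Segment tibble from [find_unique_segments()] /
#'   [screen_exclusion()] (columns `grain`, `gpt`, `sequence`, ...).
#' @param consensus Consensus tibble from [build_consensus()].
#' @param scale Hydropathy scale (default [kyte_doolittle()]).
#' @param on_ambiguity Passed to [gravy()].
#' @return The segment tibble with `gravy`, `max_run`, `occurrence` columns.
#' @export
score_candidates <- function(segments, consensus, scale = kyte_doolittle(),
                             on_ambiguity = c("error", "skip")) {
  on_ambiguity <- match.arg(on_ambiguity)
  if (nrow(segments) == 0L) {
    return(dplyr::mutate(segments, gravy = numeric(0), max_run = integer(0),
                         occurrence = integer(0)))
  }
  segments$gravy <- gravy(segments$sequence, scale = scale,
                          on_ambiguity = on_ambiguity)
  segments$max_run <- max_residue_run(segments$sequence)
  segments$occurrence <- vapply(seq_len(nrow(segments)), function(i) {
    own <- consensus$sequence[consensus$grain == segments$grain[i]]
    count_occurrences(segments$sequence[i], own)
  }, integer(1))
  if (any(segments$occurrence < 1L)) {
    abort_peptiter(
      "A segment does not occur in its own grain's consensus set; upstream pipeline bug.",
      "peptiter_validation_error"
    )
  }
  segments
}

#' Filter scored candidates on hydropathy, repeats and length
#'
#' Applies the three rejection rules in fixed order, recording the first
#' applicable reason: (1) `"hydrophobic"` if GRAVY >= `gravy_threshold`
#' (hydrophilic sequences are conserved), (2) `"repeat_run"` if the longest
#' single-residue run exceeds `max_run`, (3) `"too_long"` if the length
#' exceeds `max_len` (long peptides adopt conformations unlike the source
#' protein). All input rows are returned (audit trail); rows already
#' rejected upstream are passed through untouched.
#'
#' @param candidates Scored candidate tibble from [score_candidates()].
#' @param gravy_threshold Reject when `gravy >=` this value (default 0).
#' @param max_run Longest tolerated single-residue run (default 3).
#' @param max_len Maximum candidate length (default 20).
#' @return The candidate tibble with updated `status` / `reject_reason`.
#' @export
filter_candidates <- function(candidates, gravy_threshold = 0,
                              max_run = 3L, max_len = 20L) {
  check_number(gravy_threshold, "gravy_threshold")
  check_number(max_run, "max_run", lower = 1)
  check_number(max_len, "max_len", lower = 1)
  run_limit <- as.integer(max_run)
  len_limit <- as.integer(max_len)
  if (nrow(candidates) == 0L) return(candidates)
  open <- candidates$status == "candidate"
  reason <- dplyr::case_when(
    candidates$gravy >= gravy_threshold ~ "hydrophobic",
    candidates$max_run > run_limit ~ "repeat_run",
    candidates$length > len_limit ~ "too_long",
    TRUE ~ ""
  )
  hit <- open & reason != ""
  candidates$status[hit] <- "rejected"
  candidates$reject_reason[hit] <- reason[hit]
  candidates
}

#' Rank surviving candidates
#'
#' Deterministic total ordering of the filtered candidates by a lexicographic
#' key: peptides of at least `preferred_min_len` residues first (more than 8
#' amino acids are prioritized), then higher occurrence in the grain's
#' consensus set, then higher GPT abundance in gluten, then greater length,
#' with ascending sequence as the final tiebreak. `rank_score` is the 1-based
#' rank.
#'
#' @param candidates Candidate tibble, all rows with `status == "candidate"`.
#' @param gpt_abundance Optional tibble (`grain`, `gpt`, `abundance` in
#'   `[0, 1]`) giving each GPT's proportion of its grain's gluten; `NULL`
#'   (default) uses a uniform abundance. A candidate GPT missing from the
#'   mapping is an error.
#' @param preferred_min_len Length granting ranking priority (default 9).
#' @return The candidates ordered by rank with `gpt_abundance` and
#'   `rank_score` columns.
#' @export
rank_candidates <- function(candidates, gpt_abundance = NULL,
                            preferred_min_len = 9L) {
  check_number(preferred_min_len, "preferred_min_len", lower = 1)
  if (nrow(candidates) == 0L) {
    return(dplyr::mutate(candidates, gpt_abundance = numeric(0),
                         rank_score = integer(0)))
  }
  if (!all(candidates$status == "candidate")) {
    abort_peptiter("rank_candidates() expects only surviving candidates.",
                   "peptiter_validation_error")
  }
  if (is.null(gpt_abundance)) {
    gpt_abundance <- dplyr::distinct(candidates, .data$grain, .data$gpt)
    gpt_abundance$abundance <- 1
  }
  out <- dplyr::left_join(candidates, gpt_abundance,
                          by = c("grain", "gpt"))
  if (anyNA(out$abundance)) {
    missing <- unique(out$gpt[is.na(out$abundance)])
    abort_peptiter(
      sprintf("No gluten abundance configured for GPT(s): %s",
              toString(missing)),
      "peptiter_validation_error"
    )
  }
  out <- dplyr::rename(out, gpt_abundance = "abundance")
  out <- dplyr::arrange(
    out,
    dplyr::desc(.data$length >= preferred_min_len),
    dplyr::desc(.data$occurrence),
    dplyr::desc(.data$gpt_abundance),
    dplyr::desc(.data$length),
    .data$sequence
  )
  out$rank_score <- seq_len(nrow(out))
  out
}

#' Turn a candidate into its synthesis-ready peptide string
#'
#' Prepends an N-terminal cysteine when the sequence contains none (the
#' thiol is needed for maleimide coupling to the carrier protein) and
#' annotates N-terminal acetylation / C-terminal amidation, yielding
#' `"Ac-<seq>-NH2"`.
#'
#' @param sequence Character vector of candidate residue strings.
#' @return Character vector of synthesis strings.
#' @export
#' @examples
#' prepare_synthesis("QPFPQQ") # "Ac-CQPFPQQ-NH2"
prepare_synthesis <- function(sequence) {
  vapply(sequence, function(s) {
    if (is.na(s) || nchar(s) == 0L) {
      abort_peptiter("Cannot prepare synthesis for an empty sequence.",
                     "peptiter_validation_error")
    }
    if (!stringr::str_detect(s, stringr::fixed("C"))) s <- paste0("C", s)
    paste0("Ac-", s, "-NH2")
  }, character(1), USE.NAMES = FALSE)
}
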