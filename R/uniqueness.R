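#' Flag consensus positions shared with other grains
#'
#' A position of a consensus sequence is "shared" when at least one window of
#' `window` residues covering it occurs as an exact substring of any other
#' consensus. Windows containing ambiguity letters (X/B/Z/U/O) never match.
#' With an empty `others` set, or `window` longer than the consensus, every
#' position is unshared.
#'
#' @param cs A consensus residue string (ungapped).
#' @param others Character vector of consensus strings from *other* grains
#'   (uniqueness is across grains, never within one grain's families).
#' @param window Sharedness window length in residues (default 6, the
#'   shortest immunologically relevant peptide length).
#' @return A logical vector, one flag per position of `cs` (`TRUE` = shared).
#' @export
#' @examples
#' mark_shared_positions("QQQPFPWAYSTD", "QQQPFPCDEFGH", window = 6)
mark_shared_positions <- function(cs, others, window = 6L) {
  stopifnot(is_scalar_string(cs))
  check_number(window, "window", lower = 1)
  window <- as.integer(window)
  n <- nchar(cs)
  if (n == 0L) return(logical(0))
  if (length(others) == 0L || window > n) return(rep(FALSE, n))
  starts <- seq_len(n - window + 1L)
  wins <- substring(cs, starts, starts + window - 1L)
  clean <- !stringr::str_detect(wins, "[XBZUO]")
  match_start <- clean & wins %in% kmer_set(others, window)
  cover_mask(match_start, window, n)
}

# all distinct k-mers of a set of strings
kmer_set <- function(strings, k) {
  unique(unlist(lapply(strings, function(s) {
    m <- nchar(s)
    if (m < k) return(character(0))
    substring(s, seq_len(m - k + 1L), seq.int(k, m))
  }), use.names = FALSE))
}

# mask[i] = any(match_start[j]) over window starts j covering position i
cover_mask <- function(match_start, window, n) {
  cm <- cumsum(c(0L, as.integer(match_start)))
  i <- seq_len(n)
  lo <- pmax(1L, i - window + 1L)
  hi <- pmin(i, n - window + 1L)
  (cm[hi + 1L] - cm[lo]) > 0L
}

#' Extract maximal unshared segments from a shared-position mask
#'
#' Scans the mask for maximal runs of unshared positions and keeps those of
#' at least `min_len` residues ("equal or containing more than 6 a.a." under
#' the default). Segments are returned sorted by start and are
#' non-overlapping by construction.
#'
#' @param cs Consensus residue string.
#' @param mask Logical shared-position mask from [mark_shared_positions()];
#'   must have one flag per position of `cs`.
#' @param min_len Minimum segment length kept (default 6).
#' @return A tibble of segments: `start`, `end` (0-based, half-open on the
#'   consensus), `sequence`, `length`, `status` (`"candidate"`),
#'   `reject_reason` (`""`).
#' @export
extract_unshared_segments <- function(cs, mask, min_len = 6L) {
  stopifnot(is_scalar_string(cs))
  if (length(mask) != nchar(cs)) {
    abort_peptiter("`mask` length must equal the consensus length.",
                   "peptiter_validation_error")
  }
  check_number(min_len, "min_len", lower = 1)
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- !runs$values & runs$lengths >= min_len
  if (!any(keep)) {
    return(tibble::tibble(
      start = integer(0), end = integer(0), sequence = character(0),
      length = integer(0), status = character(0), reject_reason = character(0)
    ))
  }
  tibble::tibble(
    start = starts[keep] - 1L,
    end = ends[keep],
    sequence = substring(cs, starts[keep], ends[keep]),
    length = runs$lengths[keep],
    status = rep("candidate", sum(keep)),
    reject_reason = rep("", sum(keep))
  )
}

#' Screen candidate segments against an exclusion set
#'
#' Rejects (with reason `"exclusion_shared"`) every segment of which any
#' `window`-length substring occurs exactly in any exclusion sequence --
#' emulating the discarding of sequences shared with off-target prolamins
#' (maize zein, soy glycinin, rice). Segments shorter than `window` have no
#' window and always pass. Output preserves order and keeps rejected rows as
#' an audit trail.
#'
#' @param segments Segment tibble (from [extract_unshared_segments()] or
#'   [find_unique_segments()]).
#' @param exclusion Character vector of exclusion consensus sequences, or a
#'   tibble with a `sequence` column; `NULL` or empty means no screening.
#' @param window Window length (default 6).
#' @return The segment tibble with updated `status` / `reject_reason`.
#' @export
screen_exclusion <- function(segments, exclusion, window = 6L) {
  check_number(window, "window", lower = 1)
  window <- as.integer(window)
  if (is.data.frame(exclusion)) exclusion <- exclusion$sequence
  if (is.null(exclusion) || length(exclusion) == 0L || nrow(segments) == 0L) {
    return(segments)
  }
  kmers <- kmer_set(exclusion, window)
  hit <- vapply(segments$sequence, function(s) {
    m <- nchar(s)
    if (m < window) return(FALSE)
    wins <- substring(s, seq_len(m - window + 1L), seq.int(window, m))
    clean <- !stringr::str_detect(wins, "[XBZUO]")
    any(clean & wins %in% kmers)
  }, logical(1), USE.NAMES = FALSE)
  reject <- hit & segments$status == "candidate"
  segments$status[reject] <- "rejected"
  segments$reject_reason[reject] <- "exclusion_shared"
  segments
}

#' Mine grain-unique segments across a consensus set
#'
#' Tibble-level driver for the uniqueness mining stage: for each consensus
#' sequence, positions shared with any consensus of a *different* grain (or,
#' under `scope = "all_vs_all"`, any other consensus at all) are masked, and
#' maximal unshared runs of at least `min_len` residues are extracted.
#'
#' @param consensus Consensus tibble from [build_consensus()].
#' @param window Sharedness window (default 6).
#' @param min_len Minimum kept segment length (default 6).
#' @param scope `"cross_grain"` (default) or `"all_vs_all"`.
#' @return A tibble of segments with `grain`, `gpt` plus the
#'   [extract_unshared_segments()] columns.
#' @export
find_unique_segments <- function(consensus, window = 6L, min_len = 6L,
                                 scope = c("cross_grain", "all_vs_all")) {
  scope <- match.arg(scope)
  purrr::map_dfr(seq_len(nrow(consensus)), function(i) {
    row <- consensus[i, ]
    others <- if (scope == "cross_grain") {
      consensus$sequence[consensus$grain != row$grain]
    } else {
      consensus$sequence[-i]
    }
    mask <- mark_shared_positions(row$sequence, others, window = window)
    segs <- extract_unshared_segments(row$sequence, mask, min_len = min_len)
    if (nrow(segs) == 0L) return(NULL)
    dplyr::bind_cols(tibble::tibble(grain = row$grain, gpt = row$gpt), segs)
  })
}
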