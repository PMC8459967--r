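# Independent oracles and small generators shared across tests.

# Kyte-Doolittle 1982 values, typed independently of the package source.
KD_ORACLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

gravy_oracle <- function(s) {
  mean(KD_ORACLE[strsplit(s, "")[[1]]])
}

# naive per-position sharedness oracle: position i is shared iff some window
# cs[j:(j+w-1)] covering i occurs (as a plain substring scan) in any other
# string; windows with ambiguity letters never match
naive_shared_mask <- function(cs, others, w) {
  n <- nchar(cs)
  mask <- rep(FALSE, n)
  if (length(others) == 0L || w > n) return(mask)
  for (j in seq_len(n - w + 1L)) {
    win <- substr(cs, j, j + w - 1L)
    if (grepl("[XBZUO]", win)) next
    if (any(vapply(others, function(o) grepl(win, o, fixed = TRUE),
                   logical(1)))) {
      mask[j:(j + w - 1L)] <- TRUE
    }
  }
  mask
}

# sliding-window overlapping occurrence count
naive_count <- function(segment, strings) {
  k <- nchar(segment)
  sum(vapply(strings, function(s) {
    if (nchar(s) < k) return(0L)
    starts <- seq_len(nchar(s) - k + 1L)
    sum(substring(s, starts, starts + k - 1L) == segment)
  }, integer(1)))
}

random_peptide <- function(len, alphabet = c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# a random sharedness test case with planted common substrings so both
# shared and unshared positions occur
random_shared_case <- function(max_len = 200L) {
  cs <- random_peptide(sample(20:max_len, 1L))
  others <- replicate(sample(1:3, 1L), random_peptide(sample(20:max_len, 1L)))
  # plant a copied block so true sharing exists in ~half the cases
  if (stats::runif(1) < 0.5 && nchar(cs) > 12L) {
    from <- sample(seq_len(nchar(cs) - 10L), 1L)
    block <- substr(cs, from, from + sample(6:10, 1L))
    at <- sample(seq_len(nchar(others[1])), 1L)
    others[1] <- paste0(substr(others[1], 1L, at), block,
                        substr(others[1], at + 1L, nchar(others[1])))
  }
  list(cs = cs, others = others, w = sample(3:8, 1L))
}

make_series <- function(od, dil = 2000 * 2^(seq_along(od) - 1),
                        serum = "r1", antigen = "p1") {
  tibble::tibble(serum_id = serum, antigen_id = antigen,
                 reciprocal_dilution = dil, od = od)
}
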