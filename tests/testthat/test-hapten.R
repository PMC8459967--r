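test_that("GRAVY matches the published scale on hand-computed cases", {
  expect_equal(gravy("IIIII"), 4.5)
  expect_equal(gravy("CDEF"), (2.5 - 3.5 - 3.5 + 2.8) / 4) # -0.425
  expect_equal(gravy("CDEF"), gravy_oracle("CDEF"))
  # vectorized, and every residue agrees with the independent table
  seqs <- names(KD_ORACLE)
  expect_equal(gravy(seqs), unname(KD_ORACLE[seqs]))
})

test_that("GRAVY refuses ambiguity letters by default and can skip them", {
  expect_error(gravy("QX"), class = "peptiter_validation_error")
  expect_error(gravy(""), class = "peptiter_validation_error")
  expect_equal(gravy("QX", on_ambiguity = "skip"), gravy("Q"))
  expect_error(gravy("XX", on_ambiguity = "skip"),
               class = "peptiter_validation_error")
})

test_that("GRAVY obeys the weighted concatenation identity and reversal invariance", {
  withr::local_seed(42)
  for (i in 1:30) {
    a <- random_peptide(sample(1:25, 1))
    b <- random_peptide(sample(1:25, 1))
    lhs <- gravy(paste0(a, b))
    rhs <- (nchar(a) * gravy(a) + nchar(b) * gravy(b)) / (nchar(a) + nchar(b))
    expect_equal(lhs, rhs, tolerance = 1e-12)
    rev_a <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
    expect_identical(gravy(a), gravy(rev_a))
    expect_gte(gravy(a), min(kyte_doolittle()))
    expect_lte(gravy(a), max(kyte_doolittle()))
  }
})

test_that("longest residue runs are measured correctly", {
  expect_equal(max_residue_run(c("QQQPFP", "ABAB", "AAAAA", "Q")),
               c(3L, 1L, 5L, 1L))
  expect_error(max_residue_run(""), class = "peptiter_validation_error")
})

test_that("occurrence counting includes overlaps", {
  expect_equal(count_occurrences("QQP", "AQQPQQPA"), 2L)
  expect_equal(count_occurrences("AQQPQQPA", "AQQPQQPA"), 1L)
  expect_equal(count_occurrences("WWW", "AQQPQQPA"), 0L)
  expect_equal(count_occurrences("AA", "AAAA"), 3L) # overlapping
  withr::local_seed(7)
  for (i in 1:20) {
    seg <- random_peptide(sample(2:5, 1))
    strings <- replicate(3, random_peptide(50))
    expect_equal(count_occurrences(seg, strings), naive_count(seg, strings))
  }
})

test_that("filters reject with the first applicable reason in fixed order", {
  cand <- tibble::tibble(
    grain = "w", gpt = "g", start = 0L, end = 1L,
    sequence = c("DDEEKKNN", "IIIVVVLL", "DQQQQPFD", "DQQQQPFD", "DDEEKKNN"),
    length = c(8L, 8L, 8L, 8L, 25L),
    status = c(rep("candidate", 4), "candidate"),
    reject_reason = "",
    gravy = c(-3, 1.2, -1, 0.4, -3),
    max_run = c(2L, 3L, 4L, 4L, 2L)
  )
  out <- filter_candidates(cand)
  expect_equal(out$reject_reason,
               c("", "hydrophobic", "repeat_run", "hydrophobic", "too_long"))
  expect_equal(out$status == "candidate", out$reject_reason == "")
  # audit: kept + rejected == input; reasons from the fixed vocabulary
  expect_equal(sum(out$status == "candidate") + sum(out$status == "rejected"),
               nrow(cand))
  expect_true(all(out$reject_reason %in%
                    c("", "hydrophobic", "repeat_run", "too_long")))
  # boundary: gravy exactly at the threshold counts as hydrophobic
  at <- filter_candidates(dplyr::mutate(cand[1, ], gravy = 0))
  expect_equal(at$reject_reason, "hydrophobic")
  # rows rejected upstream pass through untouched
  pre <- dplyr::mutate(cand[2, ], status = "rejected",
                       reject_reason = "exclusion_shared")
  expect_identical(filter_candidates(pre), pre)
})

test_that("ranking is the documented lexicographic total order", {
  base <- tibble::tibble(
    grain = "w", gpt = "g", start = 0L, end = 1L, status = "candidate",
    reject_reason = "", gravy = -1, max_run = 2L
  )
  cand <- dplyr::bind_rows(
    dplyr::mutate(base, sequence = "AAAAAAAAAAAA", length = 12L, occurrence = 1L),
    dplyr::mutate(base, sequence = "DDDDDDDD", length = 8L, occurrence = 3L),
    dplyr::mutate(base, sequence = "EEEEEEEEE", length = 9L, occurrence = 1L),
    dplyr::mutate(base, sequence = "QQQQQQQQQQQQ", length = 12L, occurrence = 1L)
  )
  ranked <- rank_candidates(cand, preferred_min_len = 9)
  # preferred-length flag dominates occurrence: the length-8 occurrence-3
  # candidate ranks below every >=9-residue one
  expect_equal(ranked$sequence[4], "DDDDDDDD")
  # within the preferred class: occurrence equal, longer first,
  # alphabetical sequence as final tiebreak
  expect_equal(ranked$sequence[1:3],
               c("AAAAAAAAAAAA", "QQQQQQQQQQQQ", "EEEEEEEEE"))
  expect_equal(ranked$rank_score, 1:4)

  # total order: any input permutation yields the identical output
  withr::local_seed(3)
  for (i in 1:5) {
    perm <- rank_candidates(cand[sample(nrow(cand)), ], preferred_min_len = 9)
    expect_identical(perm$sequence, ranked$sequence)
  }
})

test_that("occurrence outranks abundance, and missing abundance errors", {
  base <- tibble::tibble(
    grain = "w", start = 0L, end = 1L, status = "candidate",
    reject_reason = "", gravy = -1, max_run = 2L, length = 10L
  )
  cand <- dplyr::bind_rows(
    dplyr::mutate(base, gpt = "minor", sequence = "DDDDDDDDDD", occurrence = 3L),
    dplyr::mutate(base, gpt = "major", sequence = "EEEEEEEEEE", occurrence = 1L)
  )
  ab <- tibble::tibble(grain = "w", gpt = c("minor", "major"),
                       abundance = c(0.1, 0.9))
  ranked <- rank_candidates(cand, gpt_abundance = ab)
  expect_equal(ranked$gpt, c("minor", "major"))
  # same occurrence: abundance decides
  cand$occurrence <- 1L
  ranked2 <- rank_candidates(cand, gpt_abundance = ab)
  expect_equal(ranked2$gpt, c("major", "minor"))

  expect_error(rank_candidates(cand, gpt_abundance = ab[1, ]), "major",
               class = "peptiter_validation_error")
  expect_error(rank_candidates(dplyr::mutate(cand, status = "rejected")),
               class = "peptiter_validation_error")
})

test_that("synthesis strings add an N-terminal cysteine only when absent", {
  expect_equal(prepare_synthesis("QPFPQQ"), "Ac-CQPFPQQ-NH2")
  expect_equal(prepare_synthesis("CQQPFP"), "Ac-CQQPFP-NH2")
  expect_equal(prepare_synthesis("QQCPFP"), "Ac-QQCPFP-NH2") # internal Cys
  expect_error(prepare_synthesis(""), class = "peptiter_validation_error")
})
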