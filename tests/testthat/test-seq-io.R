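test_that("aligned FASTA parses, normalizes case and gap aliases", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "qpq", ">s2", "QP."), fa)
  fam <- read_alignment(fa, "fasta", grain = "wheat",
                        gpt_name = "alpha_gliadin")
  expect_equal(nrow(fam), 2L)
  expect_equal(fam$sequence, c("QPQ", "QP-"))
  expect_equal(fam$grain, c("wheat", "wheat"))
  expect_equal(fam$seq_id, c("s1", "s2"))
})

test_that("FASTA parsing is insensitive to line-wrapping width", {
  seq1 <- strrep("QPFPQQ", 10)
  fa_wide <- withr::local_tempfile(fileext = ".fasta")
  fa_narrow <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", seq1, ">b", seq1), fa_wide)
  wrap <- function(s, w) substring(s, seq(1, nchar(s), w),
                                   pmin(seq(1, nchar(s), w) + w - 1, nchar(s)))
  writeLines(c(">a", wrap(seq1, 7), ">b", wrap(seq1, 13)), fa_narrow)
  expect_identical(
    read_alignment(fa_wide, "fasta", "wheat", "x"),
    read_alignment(fa_narrow, "fasta", "wheat", "x")
  )
})

test_that("ragged alignments and invalid letters are rejected with the record named", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "QPQPQPQPQP", ">short", "QPQPQPQPQ"), fa)
  expect_error(read_alignment(fa, "fasta", "wheat", "x"),
               "short", class = "peptiter_format_error")

  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">good", "QPQ", ">badrec", "QJQ"), fa2)
  expect_error(read_alignment(fa2, "fasta", "wheat", "x"),
               "badrec", class = "peptiter_validation_error")

  # '*' (stop) is rejected outright
  expect_error(protein_family("w", "g", c("QP*", "QPQ")),
               class = "peptiter_validation_error")
  # duplicate ids violate the family invariant
  expect_error(protein_family("w", "g", c("QPQ", "QPQ"), c("a", "a")),
               class = "peptiter_validation_error")
})

test_that("Clustal alignments are read and ragged Clustal input errors", {
  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c(
    "CLUSTAL W (1.82) multiple sequence alignment",
    "",
    "",
    "seqA      QPFPQQPFPQ",
    "seqB      QPFPQQPFPQ",
    ""
  ), cl)
  fam <- read_alignment(cl, "clustal", grain = "barley",
                        gpt_name = "c_hordein")
  expect_equal(fam$sequence, c("QPFPQQPFPQ", "QPFPQQPFPQ"))
  expect_equal(fam$seq_id, c("seqA", "seqB"))

  bad <- withr::local_tempfile(fileext = ".aln")
  writeLines(c(
    "CLUSTAL W (1.82) multiple sequence alignment",
    "",
    "",
    "seqA      QPFPQQPFPQ",
    "seqB      QPFPQQPFP",
    ""
  ), bad)
  expect_error(read_alignment(bad, "clustal", "barley", "x"),
               class = "peptiter_error")
})

test_that("candidate tables round-trip bit-exactly through TSV", {
  gs <- generate_grain_set(seed = 5)
  sel <- run_selection(gs$alignments, exclusion = gs$exclusion)
  path <- withr::local_tempfile(fileext = ".tsv")
  written <- write_candidates(tidy(sel), path)
  back <- read_candidates(path)
  expect_identical(back$gravy, written$gravy)
  expect_identical(back$sequence, written$sequence)
  expect_identical(back$rank_score, as.integer(written$rank_score))
  expect_identical(back$reject_reason, written$reject_reason)
  # row order is rank order for survivors
  ranked <- back$rank_score[!is.na(back$rank_score)]
  expect_identical(ranked, seq_along(ranked))
})

test_that("an empty candidate list writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(tibble::tibble(), path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_candidates(path)), 0L)
})

test_that("config loading fills defaults, fails closed and checks bounds", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_identical(load_config(empty), default_config())

  over <- withr::local_tempfile(fileext = ".yaml")
  writeLines("gravy_threshold: -0.5", over)
  cfg <- load_config(over)
  expect_equal(cfg$gravy_threshold, -0.5)
  expect_equal(cfg$max_run, default_config()$max_run)

  unk <- withr::local_tempfile(fileext = ".yaml")
  writeLines("gravvy_threshold: 0.1", unk)
  expect_error(load_config(unk), "gravvy_threshold",
               class = "peptiter_config_error")

  incons <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("max_len: 5", "preferred_min_len: 9"), incons)
  expect_error(load_config(incons), "preferred_min_len",
               class = "peptiter_config_error")

  nested <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("selection:", "  shared_window: 7", "serology:",
               "  cutoff_confidence: 0.99"), nested)
  cfg2 <- load_config(nested)
  expect_equal(cfg2$shared_window, 7)
  expect_equal(cfg2$cutoff_confidence, 0.99)
})

test_that("hydropathy scales read from TSV and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(residue = names(KD_ORACLE), value = unname(KD_ORACLE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(sort(names(read_hydropathy_scale(path))),
               sort(names(kyte_doolittle())))
  expect_equal(read_hydropathy_scale(path)[["I"]], 4.5)

  write.table(tab[-1, ], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_hydropathy_scale(path),
               class = "peptiter_validation_error")
})
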