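# Synthetic grain-family generator with planted ground truth.
#
# The generator emulates the statistical structure the selection pipeline
# assumes: gluten-protein-type (GPT) families that share conserved cores
# across grains while carrying grain-unique inserts of controlled
# hydropathy, repeat and length classes. Because the inserts are sampled
# under global k-mer disjointness, the planted coordinates are exactly
# recoverable by the mining stage.

HYDROPHILIC_POOL <- c("D", "E", "K", "N", "Q", "R", "S", "T", "H", "G", "P")
HYDROPHOBIC_POOL <- c("I", "V", "L", "F", "M", "A", "W")

INSERT_FATES <- c("selected", "rejected_hydrophobic", "rejected_repeat",
                  "rejected_exclusion", "rejected_short")

#' Simulate one aligned protein family from a template
#'
#' Each sequence is the template with independent per-position substitution
#' to a uniformly random *different* residue with probability `sub_rate`,
#' emulating the heterogeneity (nucleotide substitutions) seen within a GPT.
#' Optionally, positions are replaced by gaps at rate `gap_rate`
#' (substitution-only by default so the alignment is exact by construction
#' and template coordinates carry over to the consensus unchanged).
#'
#' @param template Ungapped residue string over the 20 standard amino acids.
#' @param n_seqs Number of sequences to simulate.
#' @param sub_rate Per-position substitution probability in `[0, 0.5)`.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param gap_rate Per-position gap probability (default 0).
#' @param grain,gpt_name Labels for the family.
#' @return An alignment tibble as returned by [protein_family()].
#' @export
generate_msa <- function(template, n_seqs, sub_rate, seed = NULL,
                         gap_rate = 0, grain = "synthetic",
                         gpt_name = "synthetic") {
  stopifnot(is_scalar_string(template), nchar(template) > 0)
  check_number(n_seqs, "n_seqs", lower = 1)
  check_number(sub_rate, "sub_rate", lower = 0, upper = 0.5 - 1e-12)
  check_number(gap_rate, "gap_rate", lower = 0, upper = 1)
  if (!is.null(seed)) withr::local_seed(seed)
  base <- seq_chars(template)[[1]]
  seqs <- vapply(seq_len(n_seqs), function(i) {
    ch <- base
    hit <- stats::runif(length(ch)) < sub_rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(orig) {
        sample(setdiff(AA_STANDARD, orig), 1L)
      }, character(1))
    }
    if (gap_rate > 0) {
      ch[stats::runif(length(ch)) < gap_rate] <- GAP_CHAR
    }
    paste(ch, collapse = "")
  }, character(1))
  protein_family(grain, gpt_name, seqs,
                 seq_id = sprintf("%s_%s_seq%03d", grain, gpt_name,
                                  seq_len(n_seqs)))
}

# --- insert construction under global k-mer disjointness -------------------

new_kmer_registry <- function(k) {
  env <- new.env(parent = emptyenv())
  assign("k", as.integer(k), envir = env)
  assign("seen", character(0), envir = env)
  env
}

registry_fresh <- function(reg, string) {
  k <- get("k", envir = reg)
  if (nchar(string) < k) return(TRUE)
  kmers <- kmer_set(string, k)
  length(kmers) == length(unique(kmers)) &&
    !any(kmers %in% get("seen", envir = reg))
}

registry_add <- function(reg, string) {
  k <- get("k", envir = reg)
  if (nchar(string) < k) return(invisible(NULL))
  assign("seen", union(get("seen", envir = reg), kmer_set(string, k)),
         envir = reg)
  invisible(NULL)
}

sample_residues <- function(pool, len) {
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

# draw an insert matching a planted fate, unique in k-mer space within the
# flanking-core context so the mining stage recovers its exact coordinates
make_insert <- function(fate, reg, left_flank, right_flank,
                        run_limit = 3L, max_tries = 500L) {
  k <- get("k", envir = reg)
  for (try in seq_len(max_tries)) {
    seq <- switch(
      fate,
      selected = sample_residues(HYDROPHILIC_POOL, sample(9:16, 1L)),
      rejected_exclusion = sample_residues(HYDROPHILIC_POOL, sample(9:14, 1L)),
      rejected_hydrophobic = sample_residues(HYDROPHOBIC_POOL, sample(8:12, 1L)),
      rejected_repeat = {
        base <- sample_residues(HYDROPHILIC_POOL, sample(9:14, 1L))
        run_res <- sample(c("Q", "P", "E"), 1L)
        run_len <- sample((run_limit + 1L):(run_limit + 2L), 1L)
        pos <- sample(seq_len(nchar(base) - run_len + 1L), 1L)
        paste0(substr(base, 1L, pos - 1L),
               strrep(run_res, run_len),
               substr(base, pos + run_len, nchar(base)))
      },
      rejected_short = sample_residues(HYDROPHILIC_POOL, sample(4:5, 1L)),
      abort_peptiter(sprintf("Unknown planted fate: %s", fate),
                     "peptiter_validation_error")
    )
    ok <- switch(
      fate,
      selected = ,
      rejected_exclusion = ,
      rejected_short = max_residue_run(seq) <= run_limit && gravy(seq) < -0.2,
      rejected_hydrophobic = max_residue_run(seq) <= run_limit &&
        gravy(seq) >= 0.2,
      rejected_repeat = max_residue_run(seq) > run_limit && gravy(seq) < -0.2
    )
    if (!ok) next
    context <- paste0(
      substr(left_flank, max(1L, nchar(left_flank) - k + 2L),
             nchar(left_flank)),
      seq,
      substr(right_flank, 1L, k - 1L)
    )
    if (!registry_fresh(reg, context)) next
    registry_add(reg, context)
    return(seq)
  }
  abort_peptiter(
    sprintf("Could not construct a '%s' insert under the constraints.", fate),
    "peptiter_generation_error"
  )
}

# wrap an exclusion-fated insert in fresh flanks; every k-mer of the record
# other than the insert's own must be new, so the exclusion screen can only
# fire on the planted decoy
make_exclusion_record <- function(reg, insert, flank_len, max_tries = 500L) {
  k <- get("k", envir = reg)
  seen <- get("seen", envir = reg)
  for (try in seq_len(max_tries)) {
    rec <- paste0(sample_residues(AA_STANDARD, flank_len), insert,
                  sample_residues(AA_STANDARD, flank_len))
    new_kmers <- setdiff(kmer_set(rec, k), kmer_set(insert, k))
    if (any(new_kmers %in% seen)) next
    assign("seen", union(seen, new_kmers), envir = reg)
    return(rec)
  }
  abort_peptiter("Could not construct an exclusion record.",
                 "peptiter_generation_error")
}

make_core <- function(reg, len, max_tries = 500L) {
  for (try in seq_len(max_tries)) {
    seq <- sample_residues(AA_STANDARD, len)
    if (max_residue_run(seq) > 3L) next
    if (!registry_fresh(reg, seq)) next
    registry_add(reg, seq)
    return(seq)
  }
  abort_peptiter("Could not construct a conserved core block.",
                 "peptiter_generation_error")
}

default_gpt_names <- function(grain, j) {
  named <- list(
    wheat = c("alpha_gliadin", "gamma_gliadin", "omega_gliadin", "lmw_gs"),
    barley = c("b_hordein", "c_hordein", "d_hordein", "gamma_hordein"),
    rye = c("gamma_secalin", "omega_secalin", "hmw_secalin"),
    oat = c("avenin_a", "avenin_b")
  )
  pool <- named[[grain]]
  if (!is.null(pool) && j <= length(pool)) pool[j] else paste0(grain, "_gpt", j)
}

#' Generate a synthetic grain set with planted ground truth
#'
#' Builds, for each grain, GPT templates of the form
#' `core1 - insert - core2 - insert - core3 ...`: the core blocks are shared
#' verbatim by every grain (so the mining stage must mask them as shared),
#' while each template carries one grain-unique insert per planted fate slot.
#' Each GPT gets one `selected`-fate insert (hydrophilic, run-clean, 9-16
#' residues) and one decoy whose fate cycles through
#' `rejected_hydrophobic`, `rejected_repeat`, `rejected_exclusion` and
#' `rejected_short` across the GPTs. Exclusion-fated inserts are copied,
#' with fresh flanks, into the returned exclusion set. All inserts are drawn
#' under global `window`-mer disjointness (including core/insert junctions),
#' so on noise-free consensus recovery the pipeline must return exactly the
#' planted segments at their planted coordinates. Families are then
#' simulated from each template with [generate_msa()].
#'
#' @param n_grains Number of grains (default 4; the first four are labelled
#'   wheat/barley/rye/oat).
#' @param gpts_per_grain GPT families per grain (default 2).
#' @param n_seqs Sequences per family (default 20).
#' @param sub_rate Per-position substitution rate (default 0.1).
#' @param seed Optional integer seed.
#' @param core_len Length of each conserved core block (default 12).
#' @param window Sharedness window the set is built against (default 6).
#' @return A list of class `grain_set`:
#'   `alignments` (tibble of all families), `truth` (tibble `grain`, `gpt`,
#'   `fate`, `start`, `end`, `sequence` -- 0-based half-open coordinates on
#'   the template/consensus), `exclusion` (tibble `id`, `sequence`),
#'   `templates` (tibble `grain`, `gpt`, `sequence`) and `params`.
#' @export
#' @examples
#' gs <- generate_grain_set(n_grains = 2, gpts_per_grain = 1, seed = 1)
#' gs$truth
generate_grain_set <- function(n_grains = 4L, gpts_per_grain = 2L,
                               n_seqs = 20L, sub_rate = 0.1, seed = NULL,
                               core_len = 12L, window = 6L) {
  check_number(n_grains, "n_grains", lower = 2)
  check_number(gpts_per_grain, "gpts_per_grain", lower = 1)
  check_number(core_len, "core_len", lower = window)
  if (!is.null(seed)) withr::local_seed(seed)

  grains <- c("wheat", "barley", "rye", "oat")[seq_len(min(n_grains, 4L))]
  if (n_grains > 4L) grains <- c(grains, paste0("grain", 5:n_grains))
  reg <- new_kmer_registry(window)
  cores <- vapply(1:3, function(i) make_core(reg, core_len), character(1))

  decoy_cycle <- setdiff(INSERT_FATES, "selected")
  truth <- list()
  templates <- list()
  alignments <- list()
  exclusion <- list()
  slot <- 0L
  for (g in seq_along(grains)) {
    for (j in seq_len(gpts_per_grain)) {
      slot <- slot + 1L
      gpt <- default_gpt_names(grains[g], j)
      decoy_fate <- decoy_cycle[((slot - 1L) %% length(decoy_cycle)) + 1L]
      ins1 <- make_insert("selected", reg, cores[1], cores[2])
      ins2 <- make_insert(decoy_fate, reg, cores[2], cores[3])
      template <- paste0(cores[1], ins1, cores[2], ins2, cores[3])
      s1 <- nchar(cores[1])
      s2 <- s1 + nchar(ins1) + nchar(cores[2])
      truth[[slot]] <- tibble::tibble(
        grain = grains[g], gpt = gpt,
        fate = c("selected", decoy_fate),
        start = c(s1, s2),
        end = c(s1 + nchar(ins1), s2 + nchar(ins2)),
        sequence = c(ins1, ins2)
      )
      templates[[slot]] <- tibble::tibble(grain = grains[g], gpt = gpt,
                                          sequence = template)
      if (decoy_fate == "rejected_exclusion") {
        exclusion[[length(exclusion) + 1L]] <- tibble::tibble(
          id = sprintf("synthetic_offtarget_%02d", length(exclusion) + 1L),
          sequence = make_exclusion_record(reg, ins2, core_len)
        )
      }
      alignments[[slot]] <- generate_msa(template, n_seqs, sub_rate,
                                         grain = grains[g], gpt_name = gpt)
    }
  }
  structure(
    list(
      alignments = dplyr::bind_rows(alignments),
      truth = dplyr::bind_rows(truth),
      exclusion = if (length(exclusion)) dplyr::bind_rows(exclusion) else
        tibble::tibble(id = character(0), sequence = character(0)),
      templates = dplyr::bind_rows(templates),
      params = list(n_grains = n_grains, gpts_per_grain = gpts_per_grain,
                    n_seqs = n_seqs, sub_rate = sub_rate, seed = seed,
                    core_len = core_len, window = window)
    ),
    class = "grain_set"
  )
}
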