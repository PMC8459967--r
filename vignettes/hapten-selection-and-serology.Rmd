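---
title: "Selecting grain-discriminating peptide haptens and analysing the resulting sera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting grain-discriminating peptide haptens and analysing the resulting sera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptiter)
library(dplyr)
```

## The problem

Immunoassays for gluten need antibodies that can tell the storage proteins
of wheat, barley, rye and oat apart. Raising such antibodies starts from a
bioinformatic step: find short peptide segments that are characteristic of
one grain's gluten protein types (GPTs -- gliadins, hordeins, secalins,
avenins and the glutelins) and absent from the others, synthesize them as
haptens coupled to a carrier protein, immunize, and then measure what the
sera actually recognize. `peptiter` implements both halves of that workflow
as testable, deterministic code:

1. **Selection**: aligned GPT families in, ranked synthesis-ready peptide
   candidates out, with a complete audit trail of why every other segment
   was rejected.
2. **Serology**: ELISA dilution series in, endpoint titers, a statistical
   blank cutoff, serum retention decisions and a categorical
   cross-reactivity matrix out.

Because public sequence databases move and wet-lab readings cannot be
regenerated, the package ships a synthetic-data module that plants known
ground truth with the same statistical structure, so every stage is
verifiable offline.

## The selection model

### Consensus sequences

Each GPT family arrives as a multiple sequence alignment (the package reads
aligned FASTA and Clustal via Biostrings; it does not compute alignments).
`build_consensus()` compiles the modal symbol per alignment column over the
20 standard residues plus the gap:

* If the mode is a residue, it joins the consensus with
  *support* = modal count / number of sequences.
* If the mode is the gap, the column is dropped, so the consensus is
  ungapped -- the form all downstream peptide work needs.
* Ties break residue-over-gap, then alphabetically. Any fixed rule works;
  this one is deterministic and order-independent (shuffling the input
  sequences can never change the output).
* Ambiguity letters (X/B/Z/U/O) abstain from the vote but stay in the
  denominator, so they can never win a column and silently inject a
  non-residue into a peptide.

The alternative `consensus_gap_rule = "ignore"` (gaps vote neither in the
numerator nor the denominator) is available for alignments dominated by
long terminal extensions.

### Grain-unique segments

"Unique to a grain" is operationalized as exact *k*-mer co-occurrence:
position *i* of a consensus is **shared** when at least one window of
`shared_window` residues covering *i* occurs verbatim in some consensus of
a *different* grain (`mark_shared_positions()`). Maximal runs of unshared
positions of at least `min_segment_len` residues become candidate segments
(`extract_unshared_segments()`), and any segment with a window occurring in
an off-target exclusion set (maize zein, soy glycinin, rice in the original
setting) is rejected with reason `exclusion_shared` but kept in the output
as an audit row (`screen_exclusion()`).

Both window parameters default to 6 because six residues is about the
shortest peptide that reliably elicits antibodies able to re-bind the
source protein; the segment-length rule is inclusive ("equal or more than
6"). Exact windows -- rather than a scored pairwise alignment -- are a
deliberate design choice: they are deterministic, independent of alignment
scoring parameters nobody recorded, and checkable against a brute-force
oracle, at the price of being conservative (a single substitution breaks
sharedness). An alignment-tolerant mode is intentionally out of scope.
Uniqueness is assessed **across grains only**: two families of the same
grain may share segments freely, because the assay's goal is to
discriminate grains, not a grain's own GPTs from each other
(`uniqueness_scope = "all_vs_all"` switches this off).

All coordinates in the package are 0-based and half-open on the ungapped
consensus string; `source_columns` maps consensus positions back to
alignment columns.

### Hydropathy, repeats, length

Surviving segments are scored (`score_candidates()`) and filtered
(`filter_candidates()`) in a fixed order, recording the *first* applicable
rejection reason:

| rule | parameter | default | rationale |
|------|-----------|---------|-----------|
| `hydrophobic` | `gravy_threshold` | 0.0 | GRAVY (mean Kyte-Doolittle hydropathy) must be strictly negative: hydrophilic peptides couple well in aqueous buffers and sit on solvent-exposed, antibody-accessible surfaces |
| `repeat_run` | `max_run` | 3 | runs of one residue longer than this (QQQQ...) are typical of low-complexity gluten repeats and make poorly discriminating haptens; 3 keeps the ubiquitous QQQ motifs just inside the gate. The underlying qualitative rule ("too many consecutive repetitions") has no published number, so this is an explicit, configurable choice |
| `too_long` | `max_len` | 20 | peptides beyond ~20 residues fold into conformations unlike the source protein |

GRAVY is the arithmetic mean of the 1982 Kyte-Doolittle per-residue values
(`kyte_doolittle()`, replaceable via a two-column TSV). Ambiguity letters
poison the mean and error by default (`gravy_on_ambiguity = "skip"` drops
them instead); this can only matter for user-supplied segments, since a
consensus never contains them.

### Ranking and synthesis strings

`rank_candidates()` orders survivors by a lexicographic key: peptides of at
least `preferred_min_len = 9` residues first (strictly more than 8 -- a
priority, not a filter), then occurrence in the grain's own consensus set
(overlapping matches counted), then the GPT's proportion of its grain's
gluten, then length, with the sequence string as a final alphabetical
tiebreak making the order total: any permutation of the input yields the
same ranking. The gluten-proportion mapping is user-supplied
(`inst/extdata/gpt_abundance_synthetic.tsv` ships an explicitly synthetic
illustration; no measured table is bundled), and a uniform mapping is used
when none is given.

`prepare_synthesis()` renders each survivor as `Ac-<seq>-NH2` (N-terminal
acetylation, C-terminal amidation, mimicking an internal polypeptide
context) and prepends a cysteine when the sequence contains none, providing
the thiol for maleimide coupling to the carrier.

The original study's final cut from ranked candidates to 14 immunogens
involved expert judgement; the package's ranking is the deterministic part
and makes no attempt to reproduce that choice.

## The serology model

### Endpoint titers

A dilution series is a set of ODs over a ladder of reciprocal dilutions
(2-fold from 2 000 to 256 000 by default). The endpoint titer is the
highest dilution whose OD still reaches `titer_target_od` (1.000 at
450 nm). Two modes:

* `discrete`: the largest *measured* dilution with OD >= target.
* `interpolated` (default): the series is scanned from the highest dilution
  down for the last crossing pair (OD_i >= target > OD_(i+1)) and the titer
  is interpolated linearly in log2(reciprocal dilution). Reported titers
  such as 3 000 or 24 000 on a 2 000/4 000/... ladder imply some
  interpolation was used in practice; linear-in-log2 is the package's own
  stated rule since none was published. The target crossing is exact --
  no tolerance band around OD 1.000 is applied.

Series that never drop below target are censored `above_range` with titer
set to the highest dilution; series that never reach it have titer "none"
(`NA`, `below_range`). Non-monotone series are tolerated (noise happens)
but flagged `noisy` when OD rises by more than 10% between successive
dilutions.

### Blank cutoff (Frey method)

Positivity cutoffs are derived from blank wells as a one-sided prediction
bound:

$$\text{cutoff} = \bar{b} + s_b \cdot t_{(c,\, n-1)} \sqrt{1 + 1/n}$$

with sample (n-1) standard deviation and confidence `c = 0.999` by default
(for n = 10 blanks the multiplier is ~4.507). The defining property is
*marginal* calibration: a fresh blank exceeds a freshly computed cutoff
with probability exactly 1 - c. The exceedance *conditional on one
realized cutoff* is itself a random variable, so the package's calibration
test averages over many cutoff realizations (2 000 cutoffs x 50 fresh
draws) rather than judging a single cutoff against a binomial band --
the latter would be statistically invalid.

When the blank SD is zero the cutoff degenerates to the blank mean and the
result is flagged.

### Retention and banding

Two threshold rules around a reciprocal dilution of 4 000 coexist in
practice and are both implemented (`retain_sera()`): `strict_greater`
("titers below or equal to 1:4 000 were discarded", the titer stage
default) and `greater_equal` ("equal or higher than 1:4 000 were
conserved", the prolamin-sensitivity stage). A missing titer is discarded
under both.

Cross-reactivity calls (`reactivity_band()`) follow a fixed decision
order: below the cutoff is `-`; above the cutoff but at most 0.050 OD is
`+/-`; otherwise the reading as a fraction p of the serum's maximum OD
gives `+++` (p >= 0.75), `++` (0.25 <= p < 0.75), else `+`. The published
bands leave one corner undefined -- readings above 0.050 OD but under 5% of
the serum maximum -- which the package assigns `+` and flags rather than
guessing an intent. Banding is total and exclusive: every non-negative OD
maps to exactly one band. `specificity_matrix()` pivots calls into the
serum x antigen table with `n/a` for untested cells.

## What the synthetic data does and does not emulate

`generate_grain_set()` builds GPT templates as alternating blocks:
conserved cores (shared verbatim by every grain, so the miner must mask
them) and grain-unique inserts drawn to hit one planted fate each --
`selected` (hydrophilic, run-clean, 9-16 residues), `rejected_hydrophobic`,
`rejected_repeat`, `rejected_exclusion` (the insert is copied into the
returned exclusion set), or `rejected_short` (4-5 residues, below the
segment minimum, so it must never surface). All inserts are sampled under
global 6-mer disjointness *including core/insert junctions*, which makes
the planted coordinates exactly recoverable: this is what lets the
end-to-end test demand precision = recall = 1.0 rather than "roughly
right". Families are then simulated by i.i.d. per-position substitution
(default rate 0.1, 20 sequences per family, defaults: 4 grains x 2 GPTs).
Substitution is the only mutation by default so the "alignment" is exact by
construction; a gap-injection rate exists but is excluded from
truth-recovery checks because it degrades the consensus rather than
shifting it.

With 20 sequences at substitution rate <= 0.2 the modal consensus misses a
template position only when the template residue loses a 20-way vote, a
binomial-tail event rare enough that the recovery tests demand >= 99%
identity per replicate.

What this generator deliberately does **not** model: real gluten
composition (Q/P-rich repeats beyond the planted ones), indel-driven
alignment error, database redundancy, or any relationship between a
peptide's sequence and the titer it would raise. Passing the planted-truth
tests therefore demonstrates that the pipeline's logic is faithful to its
rules, not that the rules find the best epitopes in real proteomes.

`generate_elisa_plate()` simulates ODs from a four-parameter logistic
curve, `OD(d) = D + (A-D)/(1 + (d/C)^B)`, plus Gaussian noise truncated at
zero, and blanks from a truncated normal. Defaults: upper asymptote
A = 2 OD, background D = 0.05 OD, slope B = 2, inflection C mid-ladder,
noise SD 0.02 OD, blanks N(0.05, 0.01). A = 2 and B = 2 describe a strong
indirect-ELISA serum and keep the curve nearly linear in log2-dilution
around the OD 1.0 crossing: across all crossing placements on the 2-fold
ladder the log2-interpolation bias stays below ~1.3%, within the 2%
recovery bound the noise-free tests enforce (a markedly steeper or
shallower curve would trade this bias against noise sensitivity). With
noise SD 0.02 the titer error is dominated by the crossing pair's OD
spacing (~0.65 OD per step), giving a relative-error SD of about 1.6%; the
tests require all of 1 000 noisy replicates within 10%.

## Numerical and degenerate-input choices

* Windows longer than the consensus mean "nothing can be shared": an
  all-unshared mask, not an error. An empty `others` set likewise.
* An all-gap family is an explicit empty-consensus error.
* `'.'` is accepted as a gap alias and normalized to `'-'`; `'*'` (stop) is
  rejected; lowercase is upcased; unknown letters (e.g. `J`) name the
  offending record.
* GRAVY on the empty string is an error, never NaN; the concatenation
  identity `gravy(AB) = (|A| gravy(A) + |B| gravy(B)) / (|A|+|B|)` holds to
  1e-12 and is tested.
* Candidate TSVs serialize GRAVY with 17 significant digits so read/write
  round-trips are bit-exact.
* Band boundaries are evaluated with plain floating-point comparisons;
  boundary readings (0.050 OD, the cutoff itself, 25%/75% of maximum) are
  pinned by tests on float-exact grid values.
* All generators take a `seed` and restore the caller's RNG state;
  sequence and plate generation use independent seeds.

## Problem sizes used by the test suite

The shipped checks run the default scenario (8 families x 20 sequences),
500 randomized sharedness cases against a brute-force oracle, 100 consensus
recovery replicates at substitution rate 0.2, a 100 000-draw cutoff
calibration, and 1 000 noisy titer replicates -- a few tens of seconds in
total. All sizes are stated in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` and scale linearly if larger checks are wanted.

## A worked end-to-end run

```{r end-to-end}
gs <- generate_grain_set(seed = 42)
sel <- run_selection(gs$alignments, exclusion = gs$exclusion)
glance(sel)
tidy(sel) |>
  filter(status == "candidate") |>
  select(grain, gpt, sequence, gravy, rank_score, synthesis_sequence) |>
  head(4)
```

```{r serology}
truth <- elisa_truth(c("r1", "r2", "r3"), "pep01", C = c(24000, 6000, 800))
sim <- generate_elisa_plate(truth, seed = 42)
run <- run_serology(sim$plate, sim$blanks)
tidy(run)
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(sel)
autoplot(run)
```

## Known limitations

* Sharedness is exact co-occurrence: conservative substitutions defeat it.
  This is by design but means segment counts are not comparable to
  alignment-based workflows.
* The consensus rule is purely modal; no support threshold or profile
  model. Positions with support barely above chance still enter peptides
  (the `support` vector is returned so users can post-filter).
* The serology side intentionally does not fit 4PL curves to data; the 4PL
  exists only as a generator. Titers come from the endpoint definition.
* No plate-layout handling, edge-well effects or inter-plate
  normalization.
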