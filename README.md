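# peptiter

Selecting grain-discriminating synthetic peptide haptens from gluten
protein families, and analysing the sera they raise.

Gluten assays need antibodies that distinguish the storage proteins of
wheat, barley, rye and oat. `peptiter` is an R package for the two
computational halves of that antibody-development workflow:

* **Hapten selection** — from per-family multiple sequence alignments of
  gluten protein types (GPTs), build modal consensus sequences, mine
  segments unique to one grain by exact k-mer co-occurrence, screen them
  against off-target prolamins (maize zein, soy glycinin, rice), filter on
  Kyte–Doolittle hydropathy (GRAVY < 0), single-residue repeat runs
  (≤ 3) and length (≤ 20 aa), rank the survivors (length ≥ 9 prioritized,
  then occurrence, GPT gluten proportion, length), and emit
  synthesis-ready strings (`Ac-<seq>-NH2`, N-terminal Cys added when
  absent).
* **Serology analytics** — endpoint titers on serial-dilution ELISA series
  (the highest reciprocal dilution reaching OD 1.000 at 450 nm, discrete
  or interpolated in log2-dilution space), the Frey blank cutoff
  `mean + sd · t(c, n−1) · sqrt(1 + 1/n)` at 99.9% confidence, serum
  retention around the 1:4 000 threshold (both the strict and the
  inclusive published rules), and categorical cross-reactivity banding
  (`+++` 75–100% of the serum maximum, `++` 25–75%, `+` 5–25%, `+/-`
  ≤ 0.050 OD above the cutoff, `-` below it).

A synthetic-data module generates grain families with planted ground truth
(shared cores, grain-unique inserts with controlled fates) and
four-parameter-logistic ELISA plates with analytically known titers, so the
whole pipeline is testable offline, with no database access. Everything is
tibble-in / tibble-out and composes with dplyr; results support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(peptiter)
library(dplyr)

gs  <- generate_grain_set(seed = 42)   # 4 grains x 2 GPTs, planted truth
sel <- run_selection(gs$alignments, exclusion = gs$exclusion)
glance(sel)
#>   n_families n_segments n_selected n_rejected_exclusion n_rejected_hydrophobic ...
#> 1          8         14          8                    2                      2

tidy(sel) |>
  filter(status == "candidate") |>
  select(grain, gpt, sequence, gravy, rank_score, synthesis_sequence) |>
  head(4)
#>   grain  gpt           sequence         gravy rank_score synthesis_sequence
#> 1 rye    omega_secalin PPTNNEGDGEPNEHSG -2.2           1 Ac-CPPTNNEGDGEPNEHSG-NH2
#> 2 barley b_hordein     NEHHQERKHDRDHGN  -3.37          2 Ac-CNEHHQERKHDRDHGN-NH2
#> 3 wheat  gamma_gliadin KDPPKQSQTQKSDT   -2.53          3 Ac-CKDPPKQSQTQKSDT-NH2
#> 4 rye    gamma_secalin GEGKGDPESRHDH    -2.49          4 Ac-CGEGKGDPESRHDH-NH2
```

The eight top-ranked candidates are exactly the eight planted
`selected`-fate inserts (one per family); the six decoys appear below them
as `rejected` rows carrying their planted reasons (`exclusion_shared`,
`hydrophobic`, `repeat_run`), and the two sub-6-residue decoys never
surface. All GRAVY values are negative because only hydrophilic segments
survive the filter.

```r
truth <- elisa_truth(c("r1", "r2", "r3"), "pep01", C = c(24000, 6000, 800))
sim   <- generate_elisa_plate(truth, seed = 42)
run   <- run_serology(sim$plate, sim$blanks)
run$cutoff
#> Frey blank cutoff: 0.0905 OD (mean 0.0473 + sd 0.0112 x 3.848; n = 16, 99.9% confidence)

tidy(run) |> select(serum_id, titer, censored, retained, band)
#>   serum_id  titer censored     retained band
#> 1 r1       24801. not_censored TRUE     +++
#> 2 r2        6244. not_censored TRUE     +++
#> 3 r3          NA  below_range  FALSE    +++
```

The analytic titers of the three simulated curves are 24 623, 6 156 and
821: sera r1 and r2 are recovered within ~1.5% by log2 interpolation and
retained (titer > 4 000), while r3's curve never reaches OD 1.000 on the
ladder, so its titer is "none" and it is discarded. `autoplot(sel)` draws
the selection funnel, `autoplot(run)` the dilution curves against the
target OD and cutoff.

File-based workflows use `read_alignment()` (aligned FASTA / Clustal),
`write_candidates()` / `read_candidates()` (TSV audit tables),
`load_config()` (YAML, see `inst/extdata/config_example.yaml`) and
`write_fixture_set()`, which materializes a complete synthetic demo
dataset as plain-text files.

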