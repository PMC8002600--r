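---
title: "Methods: consensus profiles, differential peaks and mass-based annotation for intact-cell MALDI-TOF biotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intact-cell MALDI-TOF profile analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmaldi)
```

## The analysis problem

Intact-cell MALDI-TOF mass spectrometry fingerprints a microbial culture by
the masses of its most abundant proteins, typically ribosomal and other
house-keeping proteins observed between m/z 1,000 and 25,000 as singly
protonated ions. Routine biotyping compares a sample's peak profile against a
library of reference profiles; stress, inhibitors, or altered growth
conditions can remodel the expressed proteome enough to degrade that match.
`icmaldi` implements the complete desk-side analysis for such experiments:

1. consensus profile (MSP, *main spectra projection*) construction from
   replicate peak lists,
2. differential peak detection (newly appeared / missing) between a treated
   culture and its control, aggregated over a dose-by-time grid into heat
   maps,
3. peak annotation by theoretical protein masses computed from a proteome
   FASTA within a ±2 Da window,
4. correlation-distance, average-linkage (UPGMA) dendrograms of profiles and
   a transparent 0–3 identification score, and
5. a synthetic-data generator that emulates dose- and time-dependent
   treatment effects so all of the above can be validated without any
   external data.

Inputs are already-picked peak lists (two-column text or CSV), not raw
spectra: peak picking, smoothing and baseline handling belong to the
acquisition software and are out of scope.

## Theoretical masses

`protein_mass()` computes neutral monoisotopic and average masses as the sum
of residue masses plus one water. Residue masses are derived at package load
from a single table of elemental compositions and atomic masses
(average = IUPAC standard atomic weights: H 1.00794, C 12.0107, N 14.0067,
O 15.9994, S 32.065; monoisotopic = lightest-isotope masses), so the two
scales cannot drift independently. `protonated_mass()` adds the hydrogen
atomic weight (1.00794) on the average scale and the proton mass (1.007276)
on the monoisotopic scale. At the ±2 Da tolerance used for matching, the
electron-mass distinction and the choice of atomic-weight revision are both
immaterial (revisions shift a 25 kDa average mass by well under 0.1 Da), but
fixing the convention keeps results reproducible. Masses are computed for
the full-length deposited chain with no modifications; initiator-methionine
excision — common in mature bacterial proteins — can be requested explicitly
(`met_excised = TRUE`) but is off by default, because which chains are
processed is unknown without experimental evidence and a silent correction
would be harder to audit than an explicit one.

Peak annotation (`build_mass_index()`, `annotate_peaks()`) matches observed
m/z against average [M+H]+ masses by default. Whether profile peaks are best
compared with neutral or protonated masses is ambiguous at a 2 Da window
(the two differ by ~1 Da); the adduct convention is therefore an exposed
parameter, with [M+H]+ as the default since the instrument axis records
protonated ions. Annotation is deliberately many-to-many: *all* index
entries within the window are reported with ranks by |Δm|, because one mass
can match several proteins and vice versa. Peaks with more than 5 candidates
are flagged `low_specificity`; mass-only assignment cannot substitute for
sequencing evidence, and the flag marks where it is weakest.

## Consensus profiles (MSPs)

Commercial biotyping builds an MSP from ~20 replicate spectra with a
proprietary algorithm; `build_msp()` defines an open equivalent. Peaks
pooled from all replicates are grouped by single-linkage chaining on the
sorted m/z axis (gap > `tol` breaks a chain). Chains wider than `2 * tol` —
possible under pathological chaining — are split recursively at their
largest internal gap, bounding consensus peak width. Each group occupied by
at least `min_frequency` of the source spectra becomes one consensus peak:
its m/z is the intensity-weighted mean of members (intense, well-measured
peaks dominate the position estimate), its intensity the mean over the
spectra that contain it (absent spectra excluded, so dropout does not bias
intensity downward), and its `frequency` the occupancy fraction. If more
than `max_peaks` groups survive, the most intense are kept.

Defaults: `tol = 2` Da (the one tolerance the whole analysis standardizes
on), `min_frequency = 0.25` (a peak must appear in ≥ 5 of 20 replicates; at
a realistic per-replicate dropout of 0.2 a true peak fails this with
probability below 10⁻⁶, while a one-off artifact is excluded), and
`max_peaks = 100`, the typical count of species-characteristic peaks in an
intact-cell profile. All three are configurable; none is estimated from
data.

Intensity normalization (`normalize_intensities()`, base-peak to 100 or TIC
to 1) is always an explicit, idempotent operation — never applied silently
on read — so raw exports stay inspectable.

## Differential peaks

`diff_profiles()` performs one-to-one matching between sample and control
peaks: all cross pairs within `tol` are sorted by |Δm| (ties toward the
lower control m/z) and accepted greedily, each peak used at most once.
Unmatched sample peaks are *newly appeared*; unmatched control peaks are
*missing*. The calls are presence/absence only — intensities are reported
but never tested, since low-abundance peaks near the detection limit make
intensity fold-changes unstable in this regime. Exact invariants:
|new| + |shared| = |sample|, |missing| + |shared| = |control|, and role
symmetry (new peaks of A vs B are the missing peaks of B vs A). When every
within-tolerance candidate pair is unambiguous (groups separated by more
than `2 * tol`), greedy matching provably attains the maximum-cardinality,
minimum-total-|Δm| assignment; the test suite verifies this against an
exhaustive oracle. On ambiguous instances greedy remains deterministic but
is not guaranteed optimal — at 2 Da tolerance and peak spacings of tens of
Da, ambiguous configurations are rare in practice.

`diff_matrix()` tabulates per-condition counts into treatment × (dose, time)
matrices rendered as heat maps (via `pheatmap`), the standard summary of a
treatment screen.

## Distances, trees, identification

`align_profiles()` base-peak-normalizes two profiles, matches their peaks as
above, and lays the union out as paired intensity vectors (0 = absent).
`correlation_distance()` is 1 − Pearson correlation of the square-root
transformed vectors; the square root stabilizes the variance of peak
intensities, which span orders of magnitude (the transform used inside
commercial biotyping software is undisclosed, so this choice is a documented
assumption; Spearman is available as an option since "correlation" could
equally denote rank correlation). Distances live in [0, 2].

`upgma()` implements unweighted average-linkage agglomeration directly:
cluster distance is the mean over cross pairs, node height is half the merge
distance, so the tree is ultrametric by construction (verified to 1e-9).
Ties are broken by lexicographic order of each cluster's smallest leaf
label, and children are ordered lexicographically in the Newick output —
the tree is a pure function of the distance matrix, independent of input
order, even when all distances are equal. `stats::hclust` offers average
linkage but unspecified tie handling; the in-package implementation trades a
few lines of code for byte-reproducible trees, and the test suite
cross-checks its cophenetic distances against `hclust` on random matrices.

`identify_profile()` scores a query against a library with
`score = (f_qr · f_rq · max(r, 0))^(1/3) · 3`, where `f_qr` / `f_rq` are the
matched fractions of query and reference peaks and `r` the Pearson
correlation of matched intensities. The geometric mean makes all three
components necessary; the 0–3 range mimics the familiar commercial scale
**but is not numerically comparable to it** — in particular, no ≥ 2.0
species-level convention carries over.

## The synthetic treatment model

The generator provides the statistical structure the analysis assumes,
plus exact ground truth for validation. It emulates a chronic-exposure
screen: concentrations of 1–10 µM and incubation times of 1–3 weeks.

- **Proteome and control template.** `generate_proteome()` draws random
  sequences (default lengths 9–230, spanning ~1–25 kDa);
  `generate_control_template()` picks 100 proteins whose average [M+H]+
  masses lie in m/z 1,000–25,000 and are mutually ≥ 5 Da apart (so every
  template peak annotates to its source at rank 1), with log-normal
  intensities (median 1000, log-SD 1 — a realistic two-orders-of-magnitude
  dynamic range).
- **Peak loss.** Each template peak is deleted with
  `p_loss = plogis(s · (log(dose/m) + t/τ))`, defaults `m = 20` µM,
  `s = 2`, `τ = 10.5` d. These grade the screened window from ~1% loss at
  (1 µM, 1 week) to ~93% at (10 µM, 3 weeks): the mildest condition is
  nearly unchanged, and the harshest loses most signals, the qualitative
  pattern such screens report. Dose 0 gives `p_loss = 0` at any time — the
  untreated control is the fixed reference. Deletions within one treatment
  are coupled through shared uniform variates, so a harsher condition
  destroys a superset of a milder one's losses (damage accumulates), while
  each condition's deletion count remains exactly Binomial(n, p_loss) —
  which is what the parameter-recovery validation measures.
- **Stress peaks.** `Poisson(gain_rate · p_loss)` novel peaks appear
  (default `gain_rate = 35`, matching the largest newly-appeared counts
  after harsh 3-week treatments). They are drawn from the front of a
  treatment-specific priority ordering of proteome members absent from the
  template — one compound induces the same stress proteins across its grid,
  only more of them as severity grows — and each stress protein carries a
  fixed per-protein intensity. Both choices mirror real stress responses
  (compound-specific induction of, e.g., high-light-inducible and chaperone
  proteins) and are what makes profiles of harsh conditions of one
  treatment resemble each other and cluster apart from controls in the
  dendrogram.
- **Replicate noise.** `emit_replicates()` applies per-peak dropout
  (default 0.2), m/z jitter (Normal, SD 0.5 Da — well inside the 2 Da
  grouping tolerance), and log-normal intensity noise (CV 0.3).

Seeding is hierarchical (experiment seed → per-treatment signature →
per-condition → per-replicate); a fixed seed reproduces every file byte for
byte.

**What the generator does not emulate:** mass-dependent resolution and
calibration drift, baseline and chemical noise, detector saturation,
correlated (non-independent) peak dropout, post-translational modifications,
and any mechanistic link between a compound's biochemistry and *which*
proteins respond. Passing validation on synthetic data therefore
demonstrates the correctness of the algorithms under the stated statistical
model — not instrument-level robustness on real spectra.

## Numerical and degenerate-input choices

- All tolerances are in Da, not ppm — appropriate for externally calibrated
  linear/reflectron biotyping spectra whose error is roughly constant in
  absolute terms across the window; ppm-based matching is out of scope.
- Duplicate m/z rows in an input file are merged by summing intensity
  (preserves total ion signal); comment (`#`) and blank lines are skipped.
- Sequences with non-standard residues (B, J, O, U, X, Z) are retained on
  read but flagged; mass operations skip them with a warning rather than
  guessing a mass.
- Zero-variance aligned intensity vectors (degenerate profiles) raise an
  error in `correlation_distance()` rather than returning NaN.
- `write_*` functions emit enough digits for faithful round-trips (1e-6
  relative) and deterministic byte-identical output.

## Validation problem sizes

The shipped validation (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) uses: 1,000 random sequences against the
molecular-formula mass oracle (< 0.01 Da average / < 0.001 Da monoisotopic;
additivity to 1e-9 Da); 500 random matching instances against an exhaustive
assignment oracle; 20-replicate MSP recovery of a 100-peak template at
dropout 0.2; 200 simulated conditions for loss-model recovery (aggregate
binomial z within ±3, expectation surface monotone in dose and time); 100
seeded clustering runs (trees ultrametric to 1e-9; the 10 µM analog
separates from controls as a clade in ≥ 95%); and byte-identical outputs on
a full pipeline rerun. One validation is expected to fail offline: checking
computed average [M+H]+ masses of published peak-protein pairs requires the
cited UniProt sequences, which are not redistributable with the package and
cannot be fetched without network access; the check runs when a local copy
of those entries is provided as
`inst/extdata/reference_assignments.fasta`.

## Known limitations

- Peak lists only; no mzML/raw parsing, no peak picking.
- Singly charged ions assumed throughout.
- Greedy matching is optimal only on unambiguous instances (see above).
- The identification score is transparent but uncalibrated: thresholds must
  be established per library.
- Annotation ignores post-translational modifications and Met excision by
  default; a ±2 Da mass match is a hypothesis, not an identification.
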