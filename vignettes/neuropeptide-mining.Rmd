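---
title: "Hallmark-motif neuropeptide mining and reduced-database spectral matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hallmark-motif neuropeptide mining and reduced-database spectral matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptimine)
```

## The problem

Mature neuropeptides are released from secreted precursor proteins by
processing enzymes whose cleavage sites — especially outside the bilaterians
— cannot be predicted reliably. A conventional peptidomics search therefore
runs "no enzyme": any substring of any protein is a candidate for every
spectrum. For a whole proteome this space reaches 10^5–10^6 candidates per
precursor mass, and significance estimates collapse. `peptimine` instead
mines the proteome for segments bearing the structural hallmarks of mature
neuropeptides, and searches spectra only against that reduced database with
intact-mass ("no cleavage") semantics.

## The hallmark model

The cnidarian engine assumes a mature peptide:

* ends in an amidation signal — a glycine followed by a basic residue
  (`GK` or `GR`), cut after the basic residue, the K/R removed, and the
  glycine retained in storage (amidation consumes it only as a *variable*
  modification downstream);
* begins with an N-terminal protection hallmark — glutamine at position 1
  (the pyroglutamate precursor state) or a proline at position 2 or 3.

Every C-terminal cut is combined with every admissible N-terminal start in
an upstream window, so one cut typically yields several nested candidates;
this mirrors the biological uncertainty about the true N-terminus, and lets
the spectra decide. The comparison (bilaterian) engine implements the
dibasic prohormone-convertase rule `(K/R)X^m(K/R) | X_k (K/R)X^n(K/R) |`
with spacers m, n ∈ {0, 2, 4, 6} and k = 6–40, storing the X_k segment.
Protein termini are *not* implicit boundaries in the dibasic engine (an
opt-in flag relaxes this), because the rule as stated requires both flanks.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| N-terminal search window | 50 | residues | the longest reference peptide is 18 residues; 50 leaves generous headroom without exploding the database |
| stored length | 4–50 | residues | peptides under 4 residues are not identifiable by MS/MS |
| dibasic spacers m, n | 0, 2, 4, 6 | residues | the classical convertase site inventory |
| dibasic k | 6–40 | residues | typical mature-peptide lengths |
| precursor tolerance | 0.4 | Da | MALDI-TOF reflectron accuracy at the precursor level |
| fragment tolerance | 0.8 | Da | TOF/TOF fragment accuracy |
| significance threshold | 0.05 | — | conventional acceptance level on the expectation-style score |
| variant cap | 64 | variants/peptide | bounds the 2^m blow-up of methionine oxidation on Met-rich background sequences |

Masses are monoisotopic throughout (reflectron MALDI context); the residue
table and PTM deltas live in plain-text TSVs under `inst/extdata/` and can
be swapped (e.g. for average masses) via `load_mass_table()` without code
changes.

## Modification chemistry

Stored sequences are glycine-extended and K/R-stripped. Variant expansion
enumerates the full legal lattice per peptide: amidation (only if the stored
sequence ends in G; the G is consumed, net −58.00548 Da vs the stored form),
pyroglutamate (only if position 1 is Q, −17.02655 Da, or E, −18.01056 Da),
and each methionine independently oxidized (+15.99491 Da). Display strings
use the compact field notation (`pQ…a`, `Mo`) and round-trip exactly through
the parser, so reports can be compared by string equality. An open question
in this design was whether search engines should receive pre-amidated
sequences or glycine-extended ones with a variable amidation; this package
commits to the latter, applying the amidation delta consistently to the
precursor mass *and* to the y-ion series.

## Matching and scoring

Candidates are precursor-filtered (|Δ MH⁺| ≤ 0.4 Da) against the variant
table, then scored by greedy nearest-peak assignment of the singly charged
b/y series (each observed peak consumed at most once; ions processed in
ascending m/z; an equidistant tie goes to the lower-m/z peak — a
deterministic, testable rule). The score is the binomial tail probability

> P( X ≥ matched ),  X ~ Binomial(total ions, p),
> p = 2 × fragment_tol × n_peaks / span(m/z)

floored at machine precision; `p` is the chance that one random theoretical
m/z lands within tolerance of some peak. Degenerate spectra (no peaks, or
zero m/z span) score 1. This score preserves the pipeline's decision logic —
a 0.05 threshold and target/decoy separation — while staying fully
transparent; it is **not** numerically comparable to proprietary search
engine E-values, which is why no such values are asserted anywhere in the
package. Ammonia-loss satellite ions (for K/R/Q/N-containing fragments) are
generated for annotation only and never enter the score, so they cannot
inflate the per-trial probability.

Decoy databases are built by per-protein residue shuffling (composition
preserved exactly, seeded) followed by the identical extraction and
expansion; `score_overlap()` reports the minimal single-threshold
misclassification rate between target and decoy best-hit score samples.
`count_no_enzyme_candidates()` brute-forces the conventional search space —
all substrings within the length bounds whose legal PTM variants reach the
query mass — to quantify the reduction.

## What the synthetic fixtures emulate

`build_precursor()` reproduces the canonical precursor architecture: an
N-terminal hydrophobic stub standing in for a signal peptide, then multiple
peptide units (de-modified mature sequence + basic flank) separated by
random linkers drawn from {A, L, S, T, V, D, E}. That alphabet excludes
P, Q, G, K and R, so linkers can neither complete a `G[KR]` cut nor supply
N-terminal hallmarks — the embedded truth table is exact, and assemblies are
verified (with bounded retries) to contain no cut site outside the embedded
units. `simulate_spectrum()` emits all b/y ions with truncated-Gaussian m/z
jitter plus seeded uniform noise peaks, and jitters the precursor within its
tolerance.

The fixtures deliberately do **not** model: isotope envelopes, matrix
adducts or in-source decay, multiply charged species, non-uniform fragment
intensity chemistry, retention behaviour, or biologically realistic signal
peptides (the stub only exercises the annotation field — signal-peptide
prediction is out of scope and carried as a pass-through flag). Passing
recovery tests therefore demonstrate the *logic* of extraction, expansion
and scoring, not instrument-level performance on real spectra.

## Numerical and design choices

* Coordinates are 0-based half-open internally; reports also print 1-based
  inclusive columns for human reading.
* `GKR`: the C-motif is glycine + basic with the cut after the basic
  residue, so only the `GK` cut applies; an optional flag additionally
  strips a trailing second basic residue (default off — the literal rule).
* Deduplication is by stored sequence string, with full provenance retained;
  multi-copy precursors would otherwise inflate the database.
* Records whose candidate windows contain non-standard letters (X, B, Z, U,
  \*) are skipped with a summary warning — their masses are undefined.
* The variant cap truncates oxidation-rich expansions keeping the
  least-modified variants, with a warning.
* The "N-terminal proline" census hallmark means proline at position 2 or 3
  (the same reading the extraction motifs encode); whether position-1
  prolines or pyroglutamate-from-Q count is togglable, since curated lists
  differ on both conventions.

## Validation scale

The test suite validates extraction against independent brute-force oracles
(a lookahead-regex reference engine) on 1000 random proteins of length up to
200; the fragment-series identity b_i + y_(n−i) = MH⁺ + proton to 1e-4 Da
across random modified peptides; false-positive calibration on 1000 pure
noise spectra; and end-to-end recovery on 200 seeded noisy spectra of the
packaged 20-peptide reference set embedded in 6 synthetic precursors among
30 background proteins, requiring ≥95% top-1 recovery and <5% target/decoy
score overlap. These sizes were chosen to exercise every code path at
desk scale.

## Known limitations

* The score is calibrated for significance logic, not for ranking across
  instruments; absolute values are not comparable to other engines.
* Only singly protonated ions are modelled — ESI-style multiply charged
  data are out of scope.
* Peptides lacking every hallmark (non-amidated, N-terminally unprotected)
  are invisible to the cnidarian engine by construction; that is the cost of
  the reduced search space.
* The two external benchmark inputs (a curated cnidarian peptide table and
  the sea-anemone proteome) are not redistributed with the package; the
  corresponding acceptance tests state where to place them.
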