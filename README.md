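# peptimine

Neuropeptides are short signalling peptides cut out of larger secreted
precursor proteins. Identifying them by tandem mass spectrometry is
notoriously hard: the processing enzymes' cleavage sites cannot be predicted
reliably, so a conventional peptidomics search must treat *every substring of
every protein* as a candidate ("no enzyme" search). That search space runs to
hundreds of thousands of candidates per precursor mass, and real
neuropeptides drown in it.

`peptimine` implements the alternative strategy for organisms — such as sea
anemones and other cnidarians — whose peptides carry strong structural
hallmarks. It is aimed at peptidomics researchers who have a protein database
(FASTA) and singly charged MALDI-TOF/TOF spectra (MGF) and want
high-confidence peptide identifications from a drastically reduced search
space.

## Method

**1. Hallmark-motif mining.** Mature cnidarian neuropeptides are almost
always C-terminally amidated — encoded as `G` followed by a basic residue —
and N-terminally protected by a glutamine (cyclizing to pyroglutamate) or an
early proline. The extractor scans each protein for C-terminal motifs

```
GK↓  or  GR↓          (glycine, required for amidation, before K or R)
```

and, within a window upstream of each cut, N-terminal motifs

```
↓Q      glutamine at position 1 (pyroglutamate formation)
↓XP     proline at position 2
↓XXP    proline at position 3
```

All motif combinations are enumerated, the C-terminal K/R is stripped, and
the glycine-extended segments become the reduced peptide database. A
comparison engine implements the classical bilaterian dibasic rule
`(K/R) Xm (K/R) ↓ Xk (K/R) Xn (K/R) ↓` with m, n ∈ {0, 2, 4, 6} and
k = 6–40.

**2. PTM expansion.** Each stored peptide is expanded into every legal
combination of C-terminal amidation of the glycine-extended terminus
(−57.02146 − 0.98402 Da), N-terminal pyroglutamate from Q (−17.02655 Da) or
E (−18.01056 Da), and methionine oxidation (+15.99491 Da), using
monoisotopic masses throughout.

**3. Reduced-space spectral matching.** Spectra are matched in "no cleavage"
(intact-mass) fashion: precursor MH⁺ filtering at ±0.4 Da, then greedy
assignment of singly charged b/y fragment ions at ±0.8 Da. The match score is
the binomial tail probability of the matched-ion count given the chance that
a random m/z lands on a peak — an expectation-style score (threshold 0.05)
that is deliberately transparent and **not** numerically comparable to
commercial search-engine E-values. Shuffled-sequence decoy databases quantify
the false-match score distribution, and a brute-force counter measures the
no-enzyme search space the reduction avoids.

A seeded synthetic-fixture generator (precursor architectures with
signal-peptide stubs, multiple peptide copies and motif-safe linkers; noisy
b/y spectra) makes the whole pipeline testable without any downloads.

## Worked example

```r
library(peptimine)

prot <- data.frame(id = "prec1", description = "toy precursor",
                   sequence = "MALWVTLLLASLLSVAAAQPPLDLGPAYFHIRGRSTDAAGPPMIKIPVRHGKAAA")
cands <- extract_cnidarian(prot)
db <- peptide_database(cands)
db
#> Reduced peptide database: 15 unique peptide(s), 52 PTM variant(s), 15 provenance row(s)
#> PTM classes: amidation, pyroglu, oxidation

v <- db$variants[db$variants$display == "pQPPLDLGPAYFHIRa", ]
sprintf("MH+ of pQPPLDLGPAYFHIRa: %.4f", v$mh)
#> "MH+ of pQPPLDLGPAYFHIRa: 1605.8536"

spec <- simulate_spectrum(v, seed = 42)   # stand-in for a real MGF spectrum
search_spectra(list(spec), db)
#>        spectrum_id          peptide        score matched total n_candidates significant
#> 1 pQPPLDLGPAYFHIRa pQPPLDLGPAYFHIRa 5.044582e-32      26    26            1        TRUE
```

The toy precursor encodes two hallmark peptides; mining finds 15 candidate
segments (every admissible N-terminus for each cut), PTM expansion yields 52
mass-bearing variants, and the simulated spectrum of the pyroglutamated,
amidated form `pQPPLDLGPAYFHIRa` (observed precursor within ±0.4 Da of its
theoretical MH⁺ 1605.8536) is matched with all 26 of its b/y ions, far below
the 0.05 significance threshold.

A shell entry point `exec/peptimine` exposes the same pipeline as
subcommands (`extract`, `decoy`, `search`, `no-enzyme-count`, `motif-stats`,
`simulate`, `report`).

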