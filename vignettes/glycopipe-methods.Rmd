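---
title: "Models and methods behind glycopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glycopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopipe)
```

`glycopipe` models the computational side of an intact N-glycopeptide
experiment: what fragments an electron-driven dissociation spectrum
should contain, how well an observed spectrum covers them, how a table
of candidate identifications is filtered to a controlled error rate, and
what the surviving site–glycan assignments say about glycan
microheterogeneity. This vignette records the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## Glycan compositions and masses

A glycan is represented purely compositionally — a multiset over the
residue symbols HexNAc, Hex, Fuc, NeuAc and Phospho — because tandem
spectra of the kind modeled here do not resolve branching or linkage.
Residue masses are sums of atomic monoisotopic masses (e.g. Hex =
C~6~H~10~O~5~ = 162.052824 Da), so composition mass is exactly additive
over multiset union; the property suite checks additivity to 1e-9 Da.
Mannose-6-phosphate glycans are written with an explicit `Phospho(1)`
count (e.g. `HexNAc(2)Hex(7)Phospho(1)`), keeping the grammar closed
over five symbols.

Class boundaries are configuration, not physics, and live in
`glycan_class_config()`: high mannose requires exactly the two core
HexNAc and ≥ 5 Hex; paucimannose is the truncated core (2 HexNAc, ≤ 4
Hex, ≤ 1 Fuc); anything else without Fuc/NeuAc/Phospho is
complex/hybrid. The exclusive precedence M6P > sialylated > fucosylated
> high-mannose > paucimannose > complex/hybrid means the sialylated
class absorbs sialylated-and-fucosylated glycans; the independent
multilabel flags preserve that information, and the multilabel typing
scheme (used by default in the domain statistics) additionally counts a
fucosylated paucimannose or fucosylated sialylated glycan under
fucosylated.

## Fragment generation

Backbone fragments are generated per cleavable bond (1…L−1) and series.
c ions add NH~3~ to the N-terminal residue sum; z ions are generated as
z-radical (z•) species — the direct electron-transfer product — adding
H~2~O − NH~3~ + H; b/y use the usual offsets. A fragment whose residue
span contains the glycosite is emitted once per requested retention
mode: the full glycan (the dominant electron-driven outcome), a single
HexNAc stub (+203.079373 Da), or nothing. Fragment counts per series
and charge are therefore L−1 distinct bond indices regardless of how
many retention variants exist.

The Y ladder is the composition lattice of the glycan restricted to
sub-compositions that are empty (Y0, the bare peptide) or retain at
least one HexNAc — encoding that the reducing-end core HexNAc is lost
last — excluding the full composition, which is the precursor. With no
topology assumed this is the complete hypothesis set for peptide+glycan
remainder ions; the constraint can be switched off. Oxonium ions come
from a user-editable catalog filtered by residue availability, so a
spectrum of a NeuAc-free glycan is never searched for sialic-acid ions.

Fragments above a configurable m/z ceiling (default 2000 Th, a typical
upper scan bound) are kept but flagged, since they are real ions an
instrument with a wider scan range would observe.

## Annotation metrics

Matching assigns each theoretical ion to the nearest peak in ppm within
tolerance (default 20 ppm for products, 10 ppm for precursors). Peaks
below the spectrum's low scan bound (default 115 Th) are never matched.
When one peak satisfies several theoretical ions it is classified once,
by the priority plain backbone > backbone with intact glycan > backbone
with stub > Y > oxonium; the priority prevents double-counting in the
explained-ion-current partition and prefers the assignment that carries
the most sequence information. Backbone coverage is the percentage of
the L−1 bonds evidenced by any matched backbone ion; glycan coverage is
the percentage of possible Y-ladder depths (0…residue count − 1,
counting Y0) observed among matched Y ions.

The diagnostic ratios are plain intensity quotients over configured ion
sets. The Neu5Ac/HexNAc ratio (m/z 274.0921 over 204.0867) flags
sialylation when strictly above 0.1. The GlcNAc/GalNAc isomer ratio
ships with default ion sets (numerator 126.0550 + 138.0550, denominator
144.0655 + 168.0655) that are deliberately exposed as configuration —
they derive from prior fragmentation studies rather than from first
principles — while the decision thresholds (< 1 ⇒ GalNAc, > 2 ⇒ GlcNAc,
otherwise ambiguous) are fixed. A zero-denominator ratio is returned as
`NA` and never silently coerced.

## The filter cascade

Ranking uses the supplied 2D score column, falling back to the search
score with a warning. The q-value estimator is the plain decoy/target
ratio d(t)/t(t) with a running minimum over decreasing score; the +1
correction is intentionally not applied, matching the convention in
which one decoy among ~300 targets reads as 0.33% FDR. Ties share the
FDR evaluated at the end of the tie group.

The six steps run in a fixed order — q ≤ 0.01, score ≥ 150, length ≥ 5,
|log₁₀ protein p| > 1 (strict), ≤ 1 glycosite, localization score ≥ 10 —
with telescoping per-step accounting. All steps after the q-value are
record-local predicates, so the final survivor set is order-invariant
(verified by test). The glycopeptide-level FDR (decoys/targets among
glycosylated PSMs) is reported both before the localization step, the
stage at which such an estimate is conventionally quoted, and after the
full cascade. The sequon check (N-X-S/T, X ≠ P, with protein context
completing C-terminal sequons) is on by default: upstream engines
already enforce it, but synthetic and third-party tables may not.

## Heterogeneity analytics

The unique-glycopeptide key is (modified peptide sequence, glycan
composition); the unique-glycosite key is (protein accession, protein
coordinate). Co-occurrence counts unordered glycan pairs per site, so
the upper-triangle total is identically Σ~sites~ C(k,2) — an invariant
the suite checks on random tables. Subcellular profiles treat each
group as a vector over the glycan database with unique (site, glycan)
occurrences as magnitudes (PSM weighting is available, since raw
occurrence counting is ambiguous between the two); a protein in k groups
contributes to all k, so group totals can exceed the observation count —
by design, mirroring multi-compartment annotations. Distances between
groups are plain Euclidean norms.

Domain statistics collapse subtype labels to their broadest common term
("Ig-like C2-type 3" → "Ig-like"), map sites into 1-based closed domain
spans, and compute the heterogeneity ratio (glycan-type–glycosite
combinations over glycosites) and percent-composition differences per
glycan type against the all-sites baseline; the six differences sum to
zero by construction. Domains with fewer than 7 glycosites (the
delineation threshold used for this style of display) pool into "other
domains". Domain ordering comes from agglomerative clustering of the
six-dimensional difference vectors with Euclidean distance and average
linkage — the linkage is configurable because the convention is not
universal — with rows pre-sorted by label so tie-breaking is
deterministic.

## The synthetic-data generator

The generator is the package's study stand-in: it emits a glycoproteome
FASTA with planted N-X-S/T sequons, domain spans and GO CC term lists;
site–glycan assignments; PSM tables with targets, decoys and planted
single-step filter violators; and MS/MS peak lists. Its defaults are
fixed once and define the simulated study conditions:

* 40 proteins of 400 residues with 3 sequons each; 85% site occupancy.
* Glycans per site ~ truncated geometric with continuation probability
  0.6 (so ~60% of sites carry more than one glycan, the qualitative
  regime reported for brain glycoproteomes), truncated at 10.
* PSMs per site–glycan pair = 1 + Poisson(2.5), giving roughly 3–4
  spectra per glycopeptide.
* Ranking scores: correct targets N(300, 80); decoys and the 10% false
  targets N(150, 50) — overlapping enough that the 1% FDR cutoff does
  real work. The decoy set is the same size as the false-target set, so
  the d/t estimator is calibrated by construction rather than tuned.
* Spectra: each theoretical fragment detected independently with
  probability 0.7, Gaussian m/z jitter of 5 ppm (a quarter of the
  matching tolerance), log-normal per-class intensities (arbitrary
  units; only ratios matter downstream) and 30 uniform noise peaks over
  the 115–2000 Th scan range.

Randomness comes from stage-specific substreams derived from the master
seed (proteome, assignments, PSMs, spectra), so each stage is
independently reproducible and a full run is byte-identical under one
seed — the determinism test compares emitted files as raw bytes.

The coverage-recovery experiments deliberately simulate one c ion per
bond at charge 1: bond evidence is then an independent Bernoulli(p)
trial and mean backbone coverage is an unbiased estimate of 100·p. With
redundant series (c and z, multiple charges) the expected coverage is
1 − (1 − p)^k per bond, which is a property of fragment redundancy, not
of the annotator.

What the generator does **not** emulate: isotope envelopes, charge
deconvolution artifacts, chimeric spectra, retention time, intensity
response curves, shared peptides between proteins, and realistic score
correlations within a spectrum. Passing tests therefore demonstrate
correctness of the calculus and bookkeeping under idealized inputs, not
performance on real instrument data; headline counts from real studies
(thousands of glycopeptides) are outside what desk-scale simulation can
or should reproduce.

## Numerical choices and degenerate inputs

* Masses: proton 1.007276466, water 18.010565, ammonia 17.026549,
  hydrogen atom 1.007825032 Da; all arithmetic in double precision; the
  fragment oracle tests agree to 1e-6 Th.
* Empty spectra annotate to zero metrics rather than erroring; empty
  compositions have mass 0; a glycan of one HexNAc has a Y ladder of Y0
  only.
* An all-decoy PSM table is an error; a decoy-free table yields q = 0
  everywhere with a warning flag.
* Ratio edge cases: numerator absent ⇒ 0; denominator absent ⇒ `NA`
  (undefined), and the sialylation flag treats `NA` as negative.
* Problem sizes in the shipped tests (hundreds of simulated PSM rows,
  hundreds of spectra, 200-seed property sweeps) were chosen to give
  three-standard-error resolution on every stochastic check while
  keeping the default suite comfortably interactive.

## Known limitations

Only compositional glycan information is handled — no topology, linkage
or structure. Internal (double-cleavage) fragments and glycan
fragmentation stacked on backbone fragments are not generated. The 2D
ranking score is consumed, not reimplemented; protein-level FDR is
assumed handled upstream. The GlcNAc/GalNAc and Ln/Nn diagnostic ion
sets are configuration with shipped defaults, not derived constants.
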