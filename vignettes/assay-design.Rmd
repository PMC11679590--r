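---
title: "Designing and validating amplicon-size diagnostic PCR panels from COI barcodes"
author: "coiDiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating amplicon-size diagnostic PCR panels from COI barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coiDiag)
```

## The problem

Larvae of closely related insect pests are often morphologically
indistinguishable while requiring different management. The soybean looper
(*Chrysodeixis includens*) and the sunflower looper (*Rachiplusia nu*) are
the motivating case: co-occurring Plusiinae defoliators whose caterpillars
cannot be told apart in the field, but whose mitochondrial COI barcodes
(the ~657-bp Folmer region) differ at many substitution sites.

The assay idea this package implements is *amplicon-size genotyping*: one
reverse primer placed in a region conserved across all panel species, plus
one forward primer per species anchored on species-diagnostic
substitutions. Each species then yields a PCR product of a different,
predictable size, and a plain agarose gel reads out the species. For the
published two-species panel the products are 199 bp (*C. includens*,
forward at alignment columns 181–207) and 299 bp (*R. nu*, forward at
81–102), both closed by the common reverse at 357–379.

## Coordinate and size conventions

All alignment coordinates are 1-based inclusive columns. An amplicon spans
from the forward primer's first template position to the reverse primer's
last, so its size is

> size = reverse end − forward start + 1,

which includes both primer footprints. This is the only convention that
reproduces the published sizes from the published coordinates
(379 − 181 + 1 = 199 and 379 − 81 + 1 = 299), and it is asserted by the
`AssayPanel` validity method whenever coordinates are recorded.

## Diagnostic sites and conserved windows

`findDiagnosticSites()` scans alignment columns where every row of the
target species shares one residue whose IUPAC base set does not intersect
any non-target row's residue. The comparison is deliberately strict:
degenerate codes that *might* match (say A against R) are treated as
non-diagnostic, trading sensitivity for specificity, because a forward
primer standing on a doubtful column could amplify the wrong species.
Columns containing any gap are never diagnostic. `findConservedWindows()`
returns maximal gap-free runs of identical columns — the candidate homes
for a common reverse primer.

## Primer QC and the design search

The original assay was designed by manual alignment inspection, with no
stated thermodynamic criteria, so the QC defaults are this package's own,
chosen to enclose the published primers while rejecting degenerate oligos:

* length 18–28 nt;
* GC content 30–60% (degenerate codes weighted by their mean G+C
  probability);
* Wallace-rule Tm (2·(A+T) + 4·(G+C) °C) between 50 and 75 °C — A/T-rich
  insect mtDNA pushes longer primers like the 27-mer *C. includens*
  forward (74 °C) toward the warm end, so the upper bound sits at 75
  rather than a blanket 70;
* homopolymer runs of at most 4;
* at least one diagnostic site within the 3′-terminal k = 5 nt of every
  species-forward;
* amplicons 80–1000 nt, pairwise separated by at least Δ = 50 nt — half
  the published panel's 100-nt separation and five times the default call
  tolerance, so adjacent bands stay resolvable on a 2% gel.

`assembleAssay()` searches (conserved-window reverse candidate) ×
(per-species forward candidates with 3′ diagnostic anchors) and ranks
feasible combinations lexicographically: first the minimum pairwise
amplicon-size separation, then the minimum per-primer QC margin (distance
of GC/Tm to the nearest constraint bound). A weighted-sum objective was
deliberately avoided: the lexicographic rule needs no arbitrary weights
and makes every ranking decision explainable. Ties break toward smaller
start coordinates and shorter primers; candidates sharing a start (hence
an amplicon size) are reduced to the best-margin one. The result is
deterministic and invariant to the row order of the input alignment, which
the test suite asserts. The winning panel is re-validated by in silico PCR
against the input rows and rejected if any off-target product appears.

## The in silico PCR binding model

A primer binds where at most `maxMismatch` positions (default 2) are
incompatible and the `threePrimeExact` terminal nucleotides (default 5)
all match, degenerate codes matching whenever their base sets intersect;
gaps never match. The 3′-exact rule is the mechanism the assay exploits:
a single diagnostic substitution under a forward primer's 3′ end abolishes
extension, so the default model makes one 3′ mismatch sufficient to kill a
product — mirroring how the wet assay discriminates. The wet assay's true
tolerance to internal mismatches cannot be known from gel results alone;
the defaults are a documented abstraction, and both knobs are exposed.
Every compatible forward/reverse site pairing within the product-size
bounds is reported, the way extra gel bands would be; an empty result is
the negative control. Templates are treated as linear fragments (barcodes
are linear amplicons, so no circular mtDNA wrap-around is modelled).

## Band calling

`callSpecies()` matches observed band sizes to expected sizes within a
tolerance (default ±10 nt, roughly 2% agarose resolution and safely below
half the 100-nt panel separation, which the configuration check enforces).
A lane calls a species only when exactly one species is matched; no match
is `no_call`, and multiple matched species are `ambiguous` — with only a
size list and no band intensities, "strongest band wins" would be
guesswork. Batch percentages are kept exact internally and rounded half
away from zero for display; that rounding is an inference from the
published 16%/84% split of 3/19 and 16/19 (15.79/84.21), which plain
round-half-even would also satisfy here, but half-away-from-zero states
the intent unambiguously.

## What the synthetic panel does and does not emulate

`makePaperPanel()` rebuilds the study conditions without any downloads:
five 657-column gap-free species rows around an A/T-rich random ancestor
(typical insect mtDNA composition; the embedded motifs dominate every
tested behaviour), the published primers embedded verbatim at their
published coordinates, a shared contrast base inside each forward's
3′-terminal window on all non-target rows, and exactly 56 substitution
columns between the two focal rows. The 56 is derived, not printed: 657
columns at the reported 91.48% identity gives 601 identical columns
(100·601/657 = 91.4764…, printed as 91.48). Replicated rows are exact
copies, encoding the reported absence of within-species variation.

The generator deliberately omits sequencing error, chromatogram noise,
indel evolution and intraspecific polymorphism. Passing tests therefore
demonstrate the *computational* fidelity of design, simulation and
calling — not robustness to dirty field data. Whether the published
alignment columns coincide with 657-bp barcode coordinates was never
reported for the original assay; the fixture adopts the identity mapping,
under which all the published numbers are mutually consistent.

`makeRandomPanel()` generates substitution-only panels from a random
ancestor and records every diagnostic column by direct bookkeeping,
providing an independent oracle for the site scanner. All generators are
bit-reproducible from a seed and restore the caller's RNG state.

## Numerical and degenerate-input choices

* Pairwise global alignment uses Needleman–Wunsch with linear gap costs
  (defaults match 1, mismatch −1, gap −2, so substitution-only divergence
  never gains from gaps) and a fixed traceback preference
  (diagonal > up > left) for deterministic output; scores are
  cross-checked against `Biostrings::pairwiseAlignment` in the tests.
* Percent identity excludes gap-containing columns from the denominator
  and is returned exact; rounding to two decimals happens only at
  presentation.
* Wallace Tm errors on degenerate bases unless a resolve policy is given;
  GC content weights each IUPAC code by its mean G+C probability.
* Problem sizes in the shipped tests (alignments up to 20 species × 1 kb,
  templates up to 2 kb) keep the whole suite under a minute while still
  exercising every brute-force oracle comparison.

## Limitations

Nearest-neighbour thermodynamics (ΔG dimer/hairpin models), TaqMan probe
design, degenerate-primer optimisation over deep taxon sets, gel-image
band detection and mixture quantitation are out of scope. The design
search ingests pre-aligned (or gap-free equal-length) panels; it does not
build multiple alignments of highly divergent sequences.
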