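---
title: "Mass theory and pair screening for genetically encoded macrocycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass theory and pair screening for genetically encoded macrocycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depsicode)
```

## The problem this package models

Codon-compressed *E. coli* strains (Syn61-derived) lack the TCG and TCA
serine codons, the amber stop codon TAG, their decoding tRNAs, and
release factor 1. Genes expressed in such cells must first be recoded to
avoid those codons; the freed codons can then be reassigned, via
engineered orthogonal aminoacyl-tRNA synthetase (aaRS)/tRNA pairs, to
non-canonical monomers — non-canonical amino acids (ncAAs) or alpha
hydroxy acids. A short macrocycle-coding gene carrying one TCG and one
TAG codon, expressed as a SUMO–intein fusion and cyclized in vitro, then
yields a macrocyclic peptide (two ncAAs) or depsipeptide (at least one
hydroxy acid, hence at least one backbone ester bond).

`depsicode` implements the computational layer of such experiments:

* elemental-formula and mass arithmetic in three modes,
* codon compression and translation under reassignment schemes,
* neutral/ion mass prediction for linear chains, macrocycles, ester
  hydrolysis products and monomer-substituted carrier proteins,
* a/b/y fragment-ion theory for cyclic molecules and peak annotation,
* automated identification of mutually orthogonal aaRS/monomer pairs
  from fluorescence activity matrices,
* gel-fluorescence quantification with internal-standard correction,
* seeded synthetic-data generators for all of the above.

## Mass modes and formula arithmetic

Every mass carries a mode: `monoisotopic` (exact mass of the most
abundant isotope), `average` (IUPAC 2021 standard atomic weights), or
`nominal` (integer mass numbers, the scale of low-resolution ESI
spectra). Atomic masses are embedded constants — no network dependency,
bit-reproducible — for C, H, N, O, S, P and I. Adding or subtracting two
`mass_value`s of different modes is a hard error, because silently mixing
monoisotopic and average masses is the classic mass-spectrometry bug.
Formula subtraction that would drive an element count negative is also
an error: it flags a chemically impossible modification (e.g. azide
reduction of a species with fewer than two nitrogens).

```{r}
formula_mass("C5H8O2", "nominal")      # the Boc-loss satellite, -100 Da
ion_mz(formula_mass("C6H13NO3", "nominal"), "M_plus_H")
```

## The monomer registry

`monomer_registry()` ships the 20 canonical amino acids plus the study's
16 non-canonical monomers: ncAAs 1–5 (AllocK, AlkynK, pIF, CbzK, pAzF)
and alpha hydroxy acids 6–16 (lysine-derived carbamate hydroxy acids,
AcK-OH, and the aromatic hydroxy acids F-OH, pIF-OH, NapA-OH). The
printed structures give no formulas, so each registry formula was derived
from the compound's systematic name or synthesis route (carbamates, for
example, are the scaffold amine acylated with the named alcohol's
chloroformate), and every entry with a printed low-resolution ESI value
was cross-checked against it (e.g. AlkynK-OH 228, ButK-OH 242, NorK-OH
296, AcK-OH 188, pIF-OH 291, NapA-OH 215, all [M−H]−). A hydroxy acid
carries `backbone_link = "ester"`: its alpha-hydroxyl, in place of the
alpha-amine, places an ester rather than an amide in the backbone.

Residue mass is free-monomer mass minus one water for every monomer
class — amide and ester condensation each lose one H2O — so linear
chains weigh the residue sum plus H2O and head-to-tail cycles weigh the
residue sum alone.

## Recoding and reassignment

`compress()` applies the synonymous substitutions TCG→AGC, TCA→AGT,
TAG→TAA, strictly at codon boundaries: the recoding applies to protein
coding sequences, so out-of-frame occurrences are untouched. The
operation is idempotent and leaves the standard-code translation
unchanged. `validate_syn61()` reports remaining in-frame violations with
**0-based** codon indices (a deliberate choice to avoid the classic
1-based "position 3" ambiguity; user-facing *residue* positions, by
contrast, are 1-based to match the field's usage).

A `reassignment_scheme()` maps TCG to monomer A and TAG to monomer B;
the eight schemes used in the study ship as `"rs1"`–`"rs8"`.
`translate_reassigned()` treats an in-frame TCA as a hard error rather
than skipping it — the decoding tRNA is deleted in these strains, and
silent acceptance would fabricate biology. A terminal TAA/TGA stop is
dropped; an internal one is an error. A trailing TAG is **not** a stop
under a scheme: it encodes monomer B, consistent with release factor 1
being absent.

```{r}
translate_reassigned("CTGTCGTAG", reassignment_scheme("rs3"))
```

## Macrocycle design and hydrolysis accounting

Templates hold one A and one B placeholder among canonical residues;
the exact macrocycle sequences live in supplementary material, so
templates are user-supplied configuration (YAML via `read_templates()`),
never package constants. Instantiation substitutes the scheme's
monomers and derives ester-bond positions. Ring bond *i* joins monomer
*i* to monomer *i+1* (wrapping); a bond is an ester when its *acceptor*
monomer is a hydroxy acid, whose alpha-OH esterifies the preceding
carbonyl — standard depsipeptide orientation, so hydrolysis splits
N-terminal | hydroxy-acid and the opened chain starts with the hydroxy
acid bearing its freed alpha-hydroxyl.

`hydrolysis_products()` enumerates one ring-opened linear product per
ester (mass = cyclic + H2O) and, for two or more esters, all pairwise
double cleavages (complementary fragments summing to cyclic + 2 H2O).
`protein_variant_mass()` applies the same chemistry to a carrier protein
with a single substituted position; the carrier construct sequences used
experimentally are supplementary-only, so none ship with the package —
the function takes any sequence, and the shipped tests exercise it on a
synthetic stand-in plus the sequence-independent identity that the
BocK-OH and AllocK-OH variants differ by exactly CH4. Whether a
deconvoluted ~27.8 kDa protein mass is average or monoisotopic is not
stated in the source; it is presumed average but the mode is always an
explicit argument, never hard-coded.

```{r}
tpl <- macrocycle_template("demo_BA", c("L", "B", "V", "A", "C"))
species_report(list(tpl), list(reassignment_scheme("rs5"),
                               reassignment_scheme("rs6")))
```

## Fragment theory for cyclic molecules

A cyclic molecule has no termini: collision-induced dissociation first
opens the ring at any of its *n* backbone bonds, giving *n* rotationally
related linear sequences, each of which then fragments. `linearize()`
enumerates them; `theoretical_ions()` computes the standard singly
protonated series over residue masses,

* b\_i = Σ residues(1..i) + proton,
* a\_i = b\_i − CO,
* y\_i = Σ residues(n−i+1..n) + H2O + proton,

identical arithmetic at ester-linked positions because residue formulas
already encode the O-for-NH difference. All ring openings share one
[M+H]+ precursor (b\_n). `annotate()` matches an observed peak list
within a tolerance (default 0.1 Da, a quadrupole-TOF scale chosen by the
package since the source states none) across all linearizations; a peak
within tolerance of several ions is reported for each and flagged
ambiguous, never silently resolved, mirroring the manual assignment
practice the theory supports. Only singly charged fragments are
predicted by default. The report carries both absolute m/z and the
offset from the precursor, since annotated spectra are often labelled
relative to [M+H]+.

## Orthogonal pair identification

`find_pairs()` implements the automated screen over an aaRS × monomer
fluorescence matrix (RFU/OD600): (aaRS1, monomer1) pairs with (aaRS2,
monomer2) when each synthetase is active (> `active_min`, default
10,000) with its own monomer and inactive (< `inactive_max`) with the
other's, and the synthetases belong to different mutual-orthogonality
groups (pairs within one group could not decode distinct codons). The
source text truncates the inactivity threshold; the package default is
2,500 RFU/OD600, prominently configurable, and the intended
re-derivation — sweeping `inactive_max` against the full transcribed
screening matrix until the published 77 pairs / 49 unique substrate
pairings are reproduced — is wired into the test suite but requires that
supplementary matrix, which is not available as text and therefore does
not ship. `apply_exclusions()` masks the six cells (aromatic hydroxy
acids × tyrosyl synthetases) whose fluorescence reports amino acid
rather than hydroxy acid incorporation; masked values are retained but
inert. Missing matrix cells are errors, not zeros — a silent zero would
fabricate inactivity.

`unique_pairings()` projects synthetase/monomer pairs onto distinct
unordered substrate combinations, the study's second bookkeeping (77
pairs vs 49 pairings).

## Quantification

`fit_standard_curve()` averages replicate band intensities per amount
and fits the line to the means (matching the stated three-replicate
protocol; amounts 0–5 nmol in the source). `quantify_band()` inverts the
curve and multiplies by an internal-standard correction factor defined
as known amount / curve-inverted observed amount — the source says only
"corrected for variation", so the multiplicative ratio form is a
documented interpretation. A band whose loading control shows no visible
signal is reported as exactly 0, the stated zero rule. Gel image
analysis (background subtraction, band integration) is out of scope;
inputs are integrated intensities.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their arguments and a seed, and
restore the caller's RNG state.

* `gen_activity_matrix()` emulates the screening-matrix structure:
  three groups of 3 + 2 + 2 synthetases × 16 monomers, active cells
  uniform on 15,000–40,000 RFU/OD600 and inactive cells on 0–1,000 —
  clear of the 10,000 / 2,500 thresholds by construction, so the
  ground-truth pair set is exact at zero noise. Gaussian noise can be
  added to study threshold crossing.
* `gen_cds()` plants exact counts of TCG/TCA/TAG in otherwise
  compliant random coding sequences.
* `gen_spectrum()` plants a chosen number of theoretical ions per
  linearization (default 3, mirroring the minimum-evidence criterion of
  at least three fragments per linear sequence) within the match
  tolerance, plus decoys guaranteed outside twice the tolerance.

These synthetic inputs validate the bookkeeping, not the biology: they
contain no expression-level effects, no metabolic interconversion of
monomers, no intensity physics in spectra (flat decoy/planted intensity
ranges), and threshold-clear fluorescence by construction. Passing tests
therefore demonstrate algorithmic correctness on inputs of the study's
shape, not recovery performance on borderline real data.

## Numerical choices and scale of the shipped checks

* Tolerances: formula-mass additivity is exact to 1e-9 Da; fragment
  theory is cross-checked against an independently derived
  free-monomer-mass oracle to 1e-3 Da (the oracle's constants are
  frozen to six decimals); peak matching defaults to 0.1 Da.
* Tie-breaks: ambiguous peak matches are all reported and flagged.
* Degenerate inputs: empty formulas weigh zero; single-monomer chains
  weigh the free monomer; one-monomer rings have one linearization;
  rank-deficient standard curves (a single amount) are errors.
* The test suite exercises compression on 1,000 random coding
  sequences of 30 codons, pair-search equivalence against an exhaustive
  oracle on 500 random matrices up to 10 × 20, and fragment identities
  on all 19,530 rings of size ≤ 6 over a five-monomer alphabet
  (exhaustiveness over linear tuples covers every ring opening, since
  each rotation is itself a tuple). These sizes keep the full suite
  around a minute on one core while covering the stated invariants
  exhaustively where the space is finite.

## Known limitations

* No isotope-pattern simulation, no adducts beyond ±H, singly charged
  fragments by default.
* Which sequence/scheme combinations express, cyclize, or hydrolyse in
  vivo is experimental fact, not computable here; the package predicts
  masses and fragments conditional on a species being made.
* The published screening matrix and carrier construct sequences exist
  only as supplementary figures/tables, not text; checks that need them
  are wired to fixture paths and run once a transcription is provided.
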