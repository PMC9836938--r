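# depsicode

Computational support for genetic-code-reassignment experiments in
codon-compressed (Syn61-derived) *Escherichia coli*: designing and
mass-verifying genetically encoded macrocyclic peptides and
depsipeptides, and screening for the mutually orthogonal
synthetase/monomer pairs that make them possible.

## Who this is for

Groups doing genetic code expansion with reassigned sense/stop codons
need the same computational plumbing over and over: recode genes so they
avoid the deleted codons (TCG, TCA, TAG), predict what a gene will
translate to under a codon reassignment scheme, predict exact masses of
the resulting macrocycles — including backbone **ester** bonds
introduced by alpha hydroxy acids, and their hydrolysis products —
enumerate theoretical a/b/y fragment ions of a *cyclic* molecule (which
must first ring-open into *n* rotationally related linear sequences),
and mine fluorescence screening matrices for mutually orthogonal
aminoacyl-tRNA synthetase (aaRS)/monomer pairs.

## The core models

* **Mass arithmetic.** Elemental formulas over C/H/N/O/S/P/I with three
  strictly separated mass modes (monoisotopic, average, nominal).
  Residue mass = free monomer − H2O for amide and ester monomers alike;
  linear chain = Σ residues + H2O; head-to-tail cycle = Σ residues.
* **Reassignment schemes.** TCG → monomer A, TAG → monomer B; the eight
  schemes used in the study ship as `rs1`–`rs8` together with a
  registry of the 16 non-canonical monomers (formulas derived from
  their names/synthesis routes and cross-checked against printed
  low-resolution ESI values).
* **Cyclic fragment theory.** A ring of n monomers opens at each of its
  n backbone bonds; for each linearization b_i = Σ residues(1..i) +
  proton, a_i = b_i − CO, y_i = Σ residues(n−i+1..n) + H2O + proton.
  All openings share one [M+H]+.
* **Orthogonal pair screen.** (aaRS1, m1) pairs with (aaRS2, m2) iff
  each synthetase is active (> 10,000 RFU/OD600) with its own monomer,
  inactive (< configurable threshold, default 2,500) with the other's,
  and the two synthetases are in different orthogonality groups.

## Worked example

```r
library(depsicode)

## translate a macrocycle gene under reassignment scheme 6
## (TCG -> AlkynK-OH (8), TAG -> pAzF (5))
translate_reassigned("CTGTAGGTTTCGTGT", reassignment_scheme("rs6"))
#> [1] "L" "5" "V" "8" "C"

## the same ring from a template, with ester bookkeeping and masses
tpl <- macrocycle_template("demo_BA", c("L", "B", "V", "A", "C"))
sp  <- instantiate(tpl, reassignment_scheme("rs6"))
sp
#> <cyclic_species>demo_BA_rs6
#>   ring: L-5-V-8-C
#>   ester bonds: 3
precursor_mz(sp)
#> [1] 715.3232

species_report(list(tpl), list(reassignment_scheme("rs5"),
                               reassignment_scheme("rs6")))
#>      name scheme      formula monoisotopic  average    mz_MH ester_count
#> 1 demo_BA    rs5 C38H57N5O11S     791.3775 791.9580 792.3848           2
#> 2 demo_BA    rs6  C33H46N8O8S     714.3159 714.8390 715.3232           1
```

The ring of five monomers contains one ester bond under `rs6` (the
hydroxy acid 8 accepts bond 3) and two under `rs5`; `mz_MH` is the
singly protonated precursor every ring opening shares. Annotating a
measured peak list against the five theoretical linearizations:

```r
spec <- gen_spectrum(sp, seed = 5)     # synthetic spectrum, known truth
annotate(spec$peaks, sp, tolerance = 0.1)
#> <annotation> precursor [M+H]+ = 715.3232, tolerance 0.1 Da
#>   matched 16 peak(s), 5 unmatched
#>   per-linearization distinct ions matched: 6, 5, 5, 6, 4
```

At least three distinct fragments per linearization is the accepted
evidence that an isolated species is cyclic with the expected monomer
order; the five unmatched peaks are the generator's decoys.

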