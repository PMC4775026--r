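---
title: "Differential diagnosis of Alport-related type IV collagenopathies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential diagnosis of Alport-related type IV collagenopathies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alportdx)
```

## Background and model

The glomerular basement membrane owes its tensile integrity to a collagen IV
network whose protomer is an obligate heterotrimer of one α3, one α4 and one
α5 chain, encoded by *COL4A3*/*COL4A4* (autosomal) and *COL4A5* (X-linked).
Because every protomer needs one functional chain of each kind, genotype
maps onto phenotype through a simple dose argument:

* a heterozygous hit in an autosomal chain halves the functional chain
  supply — about 50 % of normal triple helix remains, producing the mild,
  non-progressive picture of familial benign hematuria (FBH, overlapping
  with thin basement membrane nephropathy);
* two hits in the same autosomal gene (in trans), or a hemizygous *COL4A5*
  hit in a male, leave no fully functional protomer — Alport syndrome (AS);
* a heterozygous *COL4A5* female expresses a mosaic: the functional fraction
  equals the fraction of collagen-producing cells whose active X carries the
  wild-type allele, ~50 % under balanced X-inactivation but variable with
  skew, which is why carrier females range from asymptomatic to affected
  even within one family.

`functional_trimer_fraction()` encodes this as
`f = (a3_wt/2) * (a4_wt/2) * x`, with `x` the allele count for males and the
wild-type-active X fraction for heterozygous females. The model is
multiplicative and monotone: removing any functional allele can never
increase `f` (property-tested exhaustively over all genotypes).

The contrast that justifies the *semi-dominant* terminology is the homotypic
assembly model `homotypic_assembly_fraction(n, p) = p^n`, appropriate for
collagens whose molecules draw `n` identical chains from one gene pool. There
a heterozygote (`p = 0.5`) keeps only 25 % (dimer) or 12.5 % (trimer) of
functional molecules — a dominant-negative effect stronger than a null
allele's 50 %. The heterotrimer does not follow that model, which is the
biological argument that "autosomal dominant AS" is not a coherent genetic
category: the package's diagnosis vocabulary therefore contains
`X_LINKED_AS`, `AUTOSOMAL_AS` (semi-dominant), `FBH`, `DIGENIC_FLAG` and
`UNRESOLVED`, and nothing else.

`phenotype_class()` discretizes `f` for simulation and reporting: `NORMAL`
at `f ≥ 0.75`, `FBH_TBMN_SPECTRUM` in between, `AS_SEVERE` below `0.25`.
These cutoffs are package defaults, not literature constants — the
underlying biology is a continuous spectrum — and are configurable through
`phenotype_thresholds()`. They are chosen so that the three canonical
genotype doses (1.0, 0.5, 0.0) land in the three classes with a wide margin.

## Consequence annotation

`classify_consequence()` assigns one primary category per variant, in
priority order: splice-affecting deletion; canonical splice donor/acceptor
(intronic offset ±1/±2); intronic splice region (|offset| 3–8); deep
intronic (|offset| > 8); exonic splice region (within 3 bases of an exon
boundary, no amino-acid change); missense; synonymous. Two deliberate
choices:

* **Dual annotation.** A missense change at an exon-terminal base (e.g. a
  substitution of the first exonic base, part of the acceptor consensus)
  keeps `MISSENSE` as its primary category and carries a
  `secondary_splice_region` flag. Tallies of "missense vs splice" use the
  primary category; the rule engine treats the secondary flag as
  pathogenic-grade evidence (see below).
* **Partial transcript models.** Exon boundaries in cDNA coordinates are
  self-documented by intronic HGVS descriptions (`c.765+2` implies an exon
  ends at c.765), so the packaged models (`default_transcript_models()`)
  contain exactly the boundaries the packaged variants document, plus one
  stated boundary at c.687 of *COL4A3*. Unknown boundaries simply cannot
  trigger exonic splice-region calls; users may supply complete models via
  `transcript_from_exons()`. This keeps the package free of any reference
  genome or annotation download.

The collagenous-domain glycine rule flags substitutions of glycine within
the Gly-X-Y triple-helical region, where every third residue must be glycine
and substitutions are canonically pathogenic. The domain boundaries are
**documented approximations** (COL4A3 30–1438, COL4A4 38–1459, COL4A5
42–1456): they cover the helical region between the short N-terminal 7S and
the ~230-residue C-terminal NC1 domains, classify all eight packaged
glycine mutations (protein positions 337–1164) as collagenous, and exclude
both the p.Ala28Ser change (7S/signal region) and the NC1-domain
p.Gly1465Asp polymorphism. Override with the `domains` argument anywhere it
appears.

Deletion lengths are computed from written cDNA coordinates as
`(end − start + 1) + end_offset − start_offset`, valid for spans within one
exon plus its flanking intronic bases; spans that would cross a complete
intron are rejected, because cDNA coordinates cannot measure intron lengths.
The closed form is property-tested against a base-by-base coordinate-walking
oracle on 1,000 random spans.

## The four-criterion rule engine

A variant is concluded pathogenic when it (1) was published previously or
found in mutation databases, (2) was not found among population controls,
(3) is not a common allele, and (4) its exclusive presence among affected
family members is genetically proven. `classify_variant()` applies these as
a deterministic decision table (exhaustively tested for completeness and for
monotonicity: adding control-cohort presence can never move a call toward
pathogenic). No in-silico pathogenicity predictor enters the decision, by
design. The labels:

* `POLYMORPHISM` — in controls, or published as a polymorphism, or common
  (MAF ≥ 0.01 by default; the threshold is configurable, and every packaged
  polymorphism with a stated MAF is independently caught by the control
  criterion, so nothing rides on the exact value);
* `PATHOGENIC` — published-pathogenic with carriers confined to affected
  members where family data exist; or novel, absent from controls, not
  common, segregation-consistent, with a canonical consequence
  (collagenous-glycine missense, missense disrupting a canonical splice
  consensus, splice donor/acceptor, splice-affecting deletion, exonic
  splice region);
* `PRESUMED_PATHOGENIC` — as above but with an intronic splice-region
  consequence (no functional confirmation possible from sequence alone), or
  any novel canonical variant in an isolated individual, where criterion 4
  is recorded as *not evaluable* and caps the call;
* `VUS` — everything else, including novel variants that fail segregation.

**Exclusive segregation** is implemented one-directionally: consistency
requires that no disallowed unaffected carrier exists (any unaffected
carrier for autosomal variants in the default *strict* mode; unaffected
*male* carriers for *COL4A5*, while unaffected female carriers are expected
under X-inactivation variability and never falsify) and that at least one
affected member carries the variant when any genotyped member is affected.
An affected member who does **not** carry the variant is recorded but is not
counter-evidence. This is a considered design choice: in a
compound-heterozygous family each parent carries only one of the two causal
variants, yet both variants segregate exclusively with disease; a
bidirectional rule ("every affected member must carry it") would make
autosomal AS families unclassifiable in principle. The implementation is
verified against a brute-force per-member enumeration oracle over all
genotype × affection assignments of nuclear pedigrees up to six members.

A configuration flag (`autosomal_segregation = "penetrance_tolerant"`)
relaxes the strict rule to tolerate unaffected autosomal carriers, for
late-onset thin-membrane presentations; it is off by default because
criterion 4 is stated absolutely.

Two packaged polymorphisms carry ambiguity notes into the criteria trace
rather than different labels: a rare glycine variant observed once in a
young control whose later disease could not be excluded, and a variant
reported both as benign and as pathogenic that co-occurs with an established
pathogenic variant in the same family, so its independent effect is
unresolved. Both are listed as polymorphisms, matching their control-cohort
evidence.

## Family classification

`classify_family()` maps classified variants to a mode: any *COL4A5*
pathogenic variant → `X_LINKED_AS`; two distinct pathogenic variants in one
autosomal gene, or one homozygous → `AUTOSOMAL_AS`; exactly one heterozygous
autosomal variant → `FBH`; one pathogenic variant in each autosomal gene →
`DIGENIC_FLAG` (emitted with a warning, never silently folded into another
mode — no validated case exercises it); none → `UNRESOLVED`. Phase matters
for two same-gene variants: proven *cis* (one haplotype) means a single
functional hit and is reported as `FBH`; unknown phase reports
`AUTOSOMAL_AS` with an explicit phase caveat, since affected
compound-heterozygous offspring imply trans. Simultaneous *COL4A5* plus
autosomal hits return the X-linked diagnosis flagged composite rather than
an error.

For a heterozygous *COL4A5* female whose X-inactivation skew is unknown, the
dosage model is evaluated at the balanced value `x = 0.5`; the attainable
range is the full [0, 1] (evaluate the extremes to bound it), and reports
should treat the point value accordingly.

## Coverage QC

`coverage_summary()` reports the mean depth and the fraction of target bases
at or above each threshold; `qc_verdict()` passes a run only when strictly
more than 90 % of bases reach 100× and strictly more than 95 % reach 50×,
with a mean of at least 25× — the acceptance thresholds of the reference
amplicon panel, kept strict because they are worded as "more than". The
per-gene target sizes (5,013 / 5,073 / 5,383 bp), 197 amplicons in pools of
99 and 98, and the 29.4 kb total are descriptive metadata of a commercial
design (`reference_panel_metadata()`); nothing recomputes them, and a
sequencing run's achieved coverage is a property of that run, not a
reproducible quantity.

## The synthetic world

`simulate_family()` states an explicit generative world: a founder couple
seeded per mode (heterozygous founder mother for X-linked AS and FBH; two
heterozygous founders with different same-gene variants — trans by
construction — for autosomal AS), three generations with Poisson sibships
(mean 2.5, minimum 1), married-in spouses free of causal variants, Mendelian
transmission (X-aware: a father's X goes to every daughter and no son),
background polymorphisms drawn in founders at the packaged population MAFs
and transmitted Mendelian-fashion, and affection set to whether the member's
functional-trimer fraction leaves the `NORMAL` class. Heterozygous-female X
fractions are drawn from Beta(α, α) with α = 5 — mostly balanced
inactivation with occasional marked skew (≈5 % of carrier females fall above
the 0.75 normal threshold and are non-penetrant); the existence of skew is
biology, the distribution and α are package choices. The control-cohort
generator draws diploid (male-X haploid) genotypes at the stated MAFs and
estimates frequencies as allele count over allele number; depth tracks are
independent negative-binomial draws.

What the simulator does **not** emulate — so a green end-to-end test does
not establish robustness to it: linkage and co-occurrence structure between
background polymorphisms (loci are independent); phenocopies and
age-dependent penetrance (affection is a deterministic function of dose plus
X-skew randomness; FBH hematuria in particular has no age-of-onset model);
genotyping error; de novo mutation; consanguinity. The end-to-end
acceptance check — ≥95 % recovery of the generating mode over 200 seeded
families per mode, with every failure attributable to simulated
non-penetrant carriers — validates the rule pipeline's logic under
Mendelian inheritance, not its behaviour on messy real-world data.

## Numerical and degenerate-input choices

* All cDNA positions are 1-based HGVS coding coordinates; intron offsets are
  signed (+ after an exon end, − before an exon start), 0 meaning exonic.
* Unknown sex is rejected for genotype-bearing individuals (hemizygosity
  rules need it); unknown affection is carried but skipped by segregation.
* Inverted deletion spans and intron-crossing spans are parse/compute
  errors naming the offending token; pedigree structural violations are
  returned as data (`validate_pedigree()`), one record per breach, so
  loaders can report everything at once.
* Variant identity is the whitespace-normalized, case-preserving key
  `GENE:c.description`; the packaged tables are verified injective under it.
* Ties at QC thresholds fail (strict inequalities); ties at the phenotype
  thresholds go to the milder class (`f = 0.75` is `NORMAL`, `f = 0.25` is
  `FBH_TBMN_SPECTRUM`).
* The VCF dialect is genome-free by design (INFO `GENE=`/`CDNA=`,
  pseudo-coordinates, symbolic `<DEL>` for deletions): converting cDNA to
  genomic coordinates would require a reference annotation, which is out of
  scope. The emitted dialect is verified standard-parseable with an
  independent VCF reader in the test suite.

## Known limitations

* Consequence calling is positional; there is no splice-strength scoring,
  no protein-structure reasoning, and purely exonic deletions have no
  dedicated category (the panel's vocabulary is built around the observed
  variant classes).
* Collagenous-domain boundaries are approximations; calls within a few
  residues of a boundary deserve manual review, and the flag is carried in
  output rather than hidden.
* The rule engine requires curated inputs (control table, database status);
  it performs no live database queries and implements no ACMG/AMP scoring.
* The dosage model predicts an expected functional fraction, not clinical
  course: age of onset, progression to kidney failure, and hearing/ocular
  phenotypes are outside its scope.
* Population incidence figures and the reference panel's design statistics
  are context, not computed quantities.
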