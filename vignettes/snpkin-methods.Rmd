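---
title: "Methods: genomic inbreeding and kinship from optimized SNP panels"
author: "snpkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic inbreeding and kinship from optimized SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpkin)
```

## The problem

Pedigree-based genetic evaluation assigns every full-sib pair the same
expected kinship (0.25 with unrelated parents) although realized allele
sharing varies substantially around that expectation through Mendelian
sampling: full sibs can share zero, one or two alleles identical by
descent (IBD) at any locus. Dense SNP genotypes measure the realized
sharing directly. `snpkin` implements the full estimation pipeline for
commercial livestock lines genotyped on a medium-density chip — quality
control, selection of an unlinked ("linkage equilibrium", LE) marker set,
allele-frequency-weighted identity-by-state (IBS) kinship and inbreeding,
pedigree-based counterparts, paternity verification — and a bootstrap
procedure that answers the design question: how many SNPs does a reduced
panel need before its inbreeding and kinship estimates agree with the
full LE set?

Because real chip data of this kind are proprietary, the package also
ships a gene-dropping simulator with tracked IBD, so every estimator can
be validated against exact, known truth.

## The estimators

### Genomic kinship and inbreeding

Genotypes are coded $x \in \{0, \tfrac12, 1\}$ (other homozygote,
heterozygote, homozygote of the coded allele). With $p_k$ the coded-allele
frequency at SNP $k$ in the base population, the kinship between
individuals $i$ and $j$ is the average over SNPs non-missing in both of

$$ g_{ij} \;=\; \frac{1}{N_{ij}} \sum_k
   \frac{(x_{ik} - p_k)(x_{jk} - p_k)}{p_k (1 - p_k)}. $$

Under this scaling $E[g_{ij}]$ is the kinship coefficient: 0.25 for
parent–offspring and full sibs, 0.125 for half sibs, 0 for unrelated
pairs, and $(1+F_i)/2$ on the diagonal. Genomic inbreeding is therefore
taken as $F_i = 2 g_{ii} - 1$; the diagonal transform is forced by the
expectation above (derivable directly from the formula:
$E[(x-p)^2] = \tfrac12 p q (1+F)$ under the halved-dose coding) and
reproduces the usual sign convention, with individuals more heterozygous
than Hardy–Weinberg expectation scoring negative. The estimate is
invariant to which allele is coded at any SNP ($x \to 1-x$, $p \to 1-p$
leaves every term unchanged), which the tests assert to rounding error.

The base population is the current genotyped sample (optionally within
line): frequencies come from allele counting among non-missing genotypes.
An argument accepts external frequencies instead — the simulator's true
founder frequencies are used this way in the calibration tests, since
estimates against the founder base have exactly the textbook expectations.
Missing genotypes are handled by pairwise-complete averaging with
per-pair denominators $N_{ij}$.

### Pedigree counterparts

The numerator relationship matrix is built by the tabular method
($a_{jj} = 1 + \tfrac12 a_{s_j d_j}$,
$a_{ij} = \tfrac12 (a_{i s_j} + a_{i d_j})$), pedigree kinship is
$a_{ij}/2$, and per-individual inbreeding is computed independently by the
Meuwissen–Luo recursion, which accumulates ancestor contributions through
the $LDL'$ decomposition without forming the matrix. A third, memoized
recursion on the co-ancestry definition serves as a brute-force oracle;
the three agree to $10^{-15}$ on randomized pedigrees (these values are
dyadic rationals, which doubles represent exactly). Unknown parents are
treated as unrelated, non-inbred founders.

## Quality control

Filters run in the order of the chip-data workflow the package emulates,
each SNP attributed to the first filter that removes it, so the removal
counts are additive and deterministic:

1. **Mendelian errors**: SNPs with ≥ 30 opposing-homozygote
   inconsistencies across recorded parent–offspring duos (threshold
   configurable; counted at duo level, the only definition computable
   without intensities).
2. **MAF**: SNPs with minor-allele frequency strictly below 0.05 in *any*
   line, alleles counted within line.
3. **Call rate** strictly below 95%.
4. **Sex chromosomes**: everything outside the declared autosome set
   (default 1–18, the pig autosomes).
5. **Individuals** with more than 5% missing genotypes.

Boundary semantics are strict inequalities, so a SNP at MAF exactly 0.05
survives — asserted by a dedicated boundary test. An upstream
intensity-based quality score is part of the emulated workflow but needs
raw chip intensities, so it is out of scope here.

## LD pruning

The LE set is selected per line and chromosome by windowed pruning: a
window of 50 SNPs (by position in the sorted map) is scanned; while any
kept pair within the window has genotypic $r^2 > 0.5$ (squared Pearson
correlation of codes over pairwise-complete samples), one member of the
first offending pair is removed; the window then shifts 5 SNPs forward.
Three choices were genuinely open and are resolved as follows:

* **Which member to drop**: the lower-MAF member (tie: the later SNP in
  map order). Standard tooling leaves this unspecified; keeping the more
  informative marker is deterministic and near-equivalent since the two
  members are close copies.
* **Window indexing** follows the original sorted SNP list literally
  ("window of 50, shift 5"), skipping removed SNPs when forming pairs,
  rather than re-indexing over survivors.
* **Undefined $r^2$** (monomorphic vector among complete pairs) is
  treated as 0 — there is nothing to prune on.

The final set is a fixed point: re-running the pruner on its own output
removes nothing, and in duplicated-block fixtures exactly one survivor
remains per block. Genotypic (composite) $r^2$ is used rather than
haplotype-phase EM estimates, matching standard pruning practice.

## Paternity verification

Recorded sire–offspring pairs are screened by opposing homozygotes: a
true parent and offspring can never be homozygous for different alleles,
while an unrelated male mismatches at rate $2p^2q^2$ per SNP (≈ 12.5% at
$p = 0.5$). A pair is confirmed when its mismatch rate over ≥ 100 shared
SNPs is below 1% — tolerant of genotyping error, far below the unrelated
rate. This replaces likelihood-based parentage software operating on an
external 120-SNP panel, which is not reproducible from published
information; with hundreds of informative SNPs the exclusion count
separates true from false sires completely, which the simulation tests
verify.

## Bootstrap panel evaluation

Panels of fixed sizes (default grid 500–3000) are drawn from the LE set,
with the count per chromosome proportional to its share of LE markers
(largest-remainder rounding, ties to the earlier chromosome), so panels
stay spread across the genome. Sampling is with replacement — the
bootstrap as printed — and duplicated SNPs enter the kinship average with
their multiplicity; a without-replacement mode exists because duplicates
add no information and the literal procedure is ambiguous on intent.
Allele frequencies are inherited from the full-set estimates (they are
per-SNP quantities, identical under sample estimation either way). For
each replicate the package records the Pearson correlation between
panel-based and full-LE-set estimates: inbreeding over individuals,
kinship over a configurable pair set (all unordered pairs by default,
restrictable to the father-offspring / full-sib / half-sib classes).
Replicates with an undefined correlation are excluded and counted.
Summaries report mean, median, quartiles (linear interpolation),
extremes and the coefficient of variation; replicate seeds derive
deterministically from one master seed, making every run bit-reproducible.

## The simulator

Gene dropping on a configurable multi-generation pedigree: founder
gametes carry unique labels; each transmission draws crossovers as a
Poisson process on the centimorgan map (Haldane model, no interference —
the simplest model consistent with genetic-map-length reasoning) and
propagates labels with alleles, so realized kinship (mean IBD allele
pairs / 4) and true inbreeding (proportion of autozygous loci) are exact.
Founder coded-allele frequencies are uniform on a configurable range
(default [0.1, 0.5], safely above the MAF filter); optional LD blocks
make consecutive SNPs perfect copies of one underlying locus, giving
exact $r^2 = 1$ truth for pruning tests rather than coalescent realism.
Sexes alternate deterministically; mating is either seeded random pair
mating or a one-sire scheme producing large half-sib families; optional
artifacts set genotypes missing at a configured rate and replace recorded
sires (with a male earlier in pedigree order, keeping the file acyclic)
while the truth record keeps the real pedigree.

What the simulator does *not* emulate: coalescent haplotype diversity and
realistic LD decay, selection, genotyping-intensity artifacts, segregation
distortion, and X chromosomes (the workflow removes sex chromosomes).
Passing tests therefore demonstrate correctness of the estimators and
procedures under Mendelian inheritance with known truth — not robustness
to every feature of real chip data.

### Study-scale defaults

The default `simConfig()` describes the single-line scenario used by the
panel-evaluation checks: 16 founders, 5 bred generations of random pair
mating with 4 offspring per mating (1,008 individuals), 18 autosomes of
100 cM carrying 580 equally spaced SNPs each (10,440 SNPs, LE founders).
This reproduces the scale of the motivating application — on the order of
a thousand genotyped animals, about 10,000 unlinked markers after QC and
pruning, a genomic inbreeding spread around 0.05–0.07 (the range observed
across real lines) that is stable across seeds because it comes from the
generational gradient of a deep, narrow pedigree rather than from mating
luck, and mean pedigree inbreeding near 0.04 — while keeping a full
pipeline run around a minute. Panel checks at this scale use 100
bootstrap replicates; the full 1,000 replicates change the summaries only
in their third decimal and can be requested via `nReplicates`.

## Numerical and degenerate-input choices

* Genotype codes are validated against {0, 1/2, 1, NA}; kinship requires
  $0 < p < 1$ at every SNP and refuses monomorphic input (the MAF filter
  guarantees this upstream).
* A pair with zero jointly non-missing SNPs is an error, not an NA.
* Pedigree files may list offspring before parents; a topological order
  is computed internally and cycles are rejected naming an offending id.
  Parents mentioned but never defined become implicit founder records.
* The coded allele of a SNP read from a PED file is the first allele
  observed in file order — deterministic under filtering, unlike the
  minor-allele convention, at the cost that a round-trip can relabel
  alleles at SNPs whose first genotyped sample is the other homozygote
  (every kinship quantity is invariant to this, and the IO tests pin the
  exact behaviour).
* Seeds: every stage derives sub-stream seeds from one master seed, kept
  inside 32-bit integer range.

## Known limitations

* The MAF spectrum is uniform, not U-shaped as in real chip data after
  ascertainment; absolute inbreeding levels against the sample base
  population are therefore not comparable to chip studies, only the
  relative behaviour of estimators and panels is.
* Duo-level Mendelian checking cannot separate sire from dam errors when
  both parents are recorded, and trio-level impossible-genotype patterns
  are not used.
* The pedigree estimators assume the recorded pedigree; they inherit its
  errors by design (that sensitivity is part of what the genomic
  estimator is for).
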