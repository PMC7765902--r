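---
title: "Detecting imprinted genes from reciprocal-cross allele-specific expression"
author: "ImprintScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting imprinted genes from reciprocal-cross allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ImprintScan)
```

# The statistical model

## Parental baselines, not allelic balance

A diploid embryo inherits one genome copy from each parent, so a
non-imprinted gene is expected to show a 1m:1p allelic ratio there. The
endosperm is triploid — two maternal copies, one paternal — so its
no-imprinting expectation is 2m:1p. Imprinting is therefore a deviation
from a *tissue-specific* baseline, and the caller's null hypothesis is the
genomic dosage, never 50:50.

For a gene with pooled maternal and paternal allele-specific read (ASR)
counts $m$ and $p$, $n = m + p$, and expected maternal share $s$ (2/3 in
endosperm, 1/2 in embryo), `chiSquareRatioTest()` computes the Pearson
goodness-of-fit statistic

$$\chi^2 = \frac{(m - ns)^2}{ns} + \frac{(p - n(1-s))^2}{n(1-s)}$$

with one degree of freedom and no continuity correction. Significance is
$\chi^2 > 3.84$, the exact $\alpha = 0.05$ quantile (`chi2Critical()`
stores the full-precision value and the comparison is strict). The test
suite checks this statistic exhaustively against `stats::chisq.test()` for
every split with $n \le 50$; `chisq.test` is the cross-check only, never
the implementation.

## The call rule

Significance alone does not distinguish imprinting from noise at low
counts or from mapping bias, so the caller layers fold-change thresholds
and the reciprocal-consistency requirement on top. A gene is a **MEG**
when, in *both* crosses of the reciprocal pair, the test is significant
and $m/p > 4$ in endosperm or $m/p > 2$ in embryo; a **PEG** when, in both
crosses, the test is significant and $p/m > 1$ in endosperm or $p/m > 2$
in embryo. A zero denominator yields an infinite fold marker, which passes
any finite threshold.

Three of these choices were genuinely open and deserve their rationale:

* **The endosperm PEG fold, $p/m > 1$, is read literally.** It looks weak
  next to the MEG's 4-fold rule, but against the 1:2 paternal:maternal
  expectation even parity ($p = m$) is a strong paternal deviation. An
  alternative reading — one fold *beyond* the expectation, i.e.
  $p/m > 2$ — is available by setting
  `thresholds = list(peg_fold_endosperm = 2)` in `callImprinting()`.
* **Endosperm and embryo evidence combine by OR.** Either tissue alone can
  carry a call; `tissue_evidence` records which did. In practice almost
  all calls are endosperm calls, but the OR rule admits the occasional
  embryo-only MEG.
* **No multiple-testing correction is applied by default.** The procedure
  is a fixed-threshold screen ($\chi^2 > 3.84$ raw) whose specificity
  comes from the dual-cross consistency requirement and the fold filters,
  not from FDR control; callers wanting an adjusted screen can filter the
  returned per-gene statistics themselves.

Replicates of the same cross and tissue are pooled by summation before
testing — the test operates on one $(m, p)$ per gene, cross and tissue. A
gene must reach `minTotalAsr` (default 10) pooled reads in *each* cross of
a tissue to be testable there; with no stated depth floor in the
literature, 10 is the smallest total at which the $\chi^2$ approximation
and a 4-fold call are simultaneously meaningful. No call is ever made from
a single cross: a missing reciprocal partner makes the gene untestable,
not weakly supported.

## The detectability ledger

Genes escape the caller for reasons worth accounting: no parental SNP
(parental origin unreadable), no read across an existing SNP, or a
non-significant test. `detectabilityLedger()` assigns every gene of the
genome exactly one status per reciprocal pair — `no_SNP`, `no_ASR`,
`imprinted` or `non_significant` — and `summarizeLedger()` reproduces the
bookkeeping table whose rows sum to the assessed-gene total. The partition
is asserted property-style in the tests.

# Pseudo-genomes and coordinate transfer

When one parent has no assembly, reads from both parents are mapped
against the reference and a *pseudo-genome*: the reference with that
parent's homozygous SNPs and InDels substituted in (`applyVariants()`).
SNPs preserve coordinates; indels shift everything downstream, so the
function also returns a `LiftoverMap` of conserved blocks supporting
bidirectional transfer (`liftCoord()`).

Numerical conventions:

* **Coordinates are 1-based and closed throughout**, the
  GRanges/Biostrings/VCF convention; all interval arithmetic is done by
  IRanges, and VCF I/O needs no shifting. Internally indels are stored
  *without* the VCF anchor base (an empty alt is a deletion, an empty ref
  inserts before `pos`); the anchor is added on `writeVariantsVcf()` and
  stripped on `readVariantsVcf()`.
* For a replacement of $l_r$ reference bases by $l_a$ alternate bases, the
  common prefix of $\min(l_r, l_a)$ bases stays coordinate-matched; surplus
  reference bases are *deleted* (forward lift returns `NA`), surplus
  alternate bases are *inserted* (reverse lift returns `NA`). Lifting a
  deleted position is a value (`NA`), not an exception; only positions
  outside the chromosome are errors.
* Overlapping variants are rejected at object validation, and every
  declared reference allele is checked against the sequence before any
  substitution happens. Heterozygous parental calls are not representable:
  the variant model is strictly homozygous, and inputs must be pre-filtered
  accordingly.

The round-trip property — forward then reverse lift is the identity on
every non-deleted position — is property-tested on random variant sets.

# Cluster and conservation statistics

## Mini clusters

Two or more imprinted genes "tandemly located without an intergenic gene"
are a mini cluster. Adjacency is defined in **gene rank order** (no
annotated gene in between), not base-pair distance: rank adjacency is what
"no intervening gene" means operationally and it is robust to annotation
density. Chromosome boundaries break adjacency. `findMiniClusters()`
returns maximal runs with a type (maternal-only, paternal-only,
maternal–paternal); singletons are never clusters.

The null for the clustered fraction (`neighborNull()`) draws `nSelect`
genes uniformly without replacement and records the fraction of drawn
genes having at least one drawn immediate rank-neighbor — the quantity is
*genes in neighbor pairs*, not pairs, so the observed clustered fraction
and the null are on the same scale. Ignoring chromosome edges, the
per-gene neighbor probability is $1 - (1 - \frac{k-1}{N-1})^2$ for $k$
genes drawn from $N$, about 1% for 200 of 37,852 — the simulated mean is
checked against exhaustive enumeration on a 12-gene toy genome in the
tests.

## Overlap nulls

Conservation of imprinted-gene sets across cross combinations is judged
against permutation: sets of the observed sizes are drawn independently,
uniformly without replacement, from an annotated background, 10,000 times,
and the pairwise (or three-way) intersection size is recorded. The
background universe is an explicit argument, never inferred from the data;
the rice analyses use the 37,852-gene annotated universe. The spread
between detected set sizes (hundreds) and the background (tens of
thousands) is what makes observed overlaps of dozens decisive against
bounds of single digits.

Two conventions are fixed deliberately:

* **"95% confidence interval" means the one-sided upper 95th percentile**
  of the replicate values, computed as the inverse-ECDF (type-1) quantile
  so integer statistics give integer bounds. This convention reproduces
  the printed pairwise bounds (8, 6, 4) and the three-way bound (0) for
  the published set sizes; a two-sided variant can be had by querying
  `nullQuantile()` at 0.025/0.975.
* **Both sets are redrawn each replicate** (`drawMode = "both"`). Fixing
  one set and redrawing the other is statistically near-identical for
  uniform draws and is available as `drawMode = "fixFirst"`; the tests
  confirm both match the hypergeometric mean $ab/N$.

Verdicts are strict: an observed value exactly at the bound does not
exceed it.

## Bidirectional hit rate

Cross-species ortholog matching consumes precomputed directed similarity
tables (e.g. BLASTP bit scores) rather than running an aligner, for
determinism and independence from external databases. The published BHR
definition leaves the exact ratio construction to its citation; here
$R_f(a,b)$ is the forward score of $(a,b)$ divided by $a$'s best forward
score, $R_r(a,b)$ the reverse analogue, and $BHR = R_f \times R_r$ — the
only reading under which $BHR \in (0,1]$ and a 0.95 threshold is
meaningful. Mutual best hits score exactly 1; near-co-optimal hits that a
strict reciprocal-best rule would discard can still pass. Genes with no
hit in one direction are excluded (they cannot be normalised), and the
kept set is brute-force-verified on small score matrices in the tests.

# The synthetic-data generator

The generator exists so that every downstream stage is testable with known
ground truth. It emulates, by construction:

* a triploid-endosperm maternal fraction of exactly 2/3 and an embryo
  fraction of 1/2 for every non-imprinted gene;
* planted MEGs/PEGs with extreme endosperm fractions (defaults 0.95 and
  0.10 — the neighbourhood of fold 19 and 9 where published validations
  sit); planted genes keep the 1/2 embryo baseline, reflecting that
  imprinting in this system is essentially endosperm-specific;
* a fraction of genes with no parental SNP (`pGeneHasSnp`) and, among
  SNP-bearing genes, a fraction with no covering read
  (`pNoAsrGivenSnp`) — the two ledger loss modes;
* optional adjacent same-class planted pairs (`nClusterPairs`) emulating
  mini clusters;
* reciprocal orientation: maternal always means the cross's female parent,
  so the same parental allele is counted maternal in one cross and
  paternal in the other.

Total ASR per gene and sample is negative binomial (mean `meanDepth`,
dispersion `size = 10` by default; `Inf` gives Poisson) and the
maternal/paternal split is binomial at the gene's tissue fraction.
Overdispersion matters: with Poisson totals the $\chi^2$ null is slightly
conservative, and NB totals are what real RNA-seq depth looks like. The
depth distribution of ASRs is not published anywhere, so `meanDepth` is a
free parameter; 100 is used as the working default and in the recovery
tests.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: mapping bias between parental genomes, InDel-
induced expression artifacts, sequencing error in allele calls, correlated
expression between neighbouring genes, and biological replicate
variability beyond NB dispersion. Recovery rates on synthetic data are an
upper bound on real-data sensitivity.

All randomness flows from one seed per generator call; the pipeline
derives fixed per-stage sub-seeds from its single config seed, and a fixed
seed gives bit-identical output tables.

# Problem sizes and determinism

The test suite exercises the published simulation scales directly: 10,000
replicates for the overlap nulls on the 37,852-gene background and for the
neighbor null at 200 drawn genes (each well under a minute), and caller
recovery on a 1,000-gene pair with 50 planted MEGs and 10 PEGs at mean
depth 100, where the endosperm caller is required to reach sensitivity
$\ge 0.95$ at false-positive rate $\le 0.01$. Oracle checks (exhaustive
Pearson, hypergeometric means, toy-genome enumeration, brute-force BHR,
liftover round trips) run at small sizes where exact answers are
enumerable.

`runPipeline()` writes a manifest (thresholds, derived stage seeds, config
hash, file inventory) with every run; rerunning the same config reproduces
every report byte for byte, which the tests assert.

# Known limitations

* The caller tests pooled counts only; it does not model per-replicate
  overdispersion (no beta-binomial), so its p-values are nominal, as in
  the procedure it implements.
* Variant input must be homozygous in both parents; heterozygous sites
  should be removed upstream.
* Rank-order adjacency makes cluster calls sensitive to missing gene
  annotations (two imprinted genes separated by an unannotated gene count
  as adjacent).
* `assignReads()` implements the ASR contract at the observation level;
  alignment itself (and its biases) is out of scope — the pipeline's
  native input is the per-gene ASR count table.
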