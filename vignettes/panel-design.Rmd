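---
title: "Low-density SNP panel design: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-density SNP panel design: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dmafpanel)
```

## The problem

Distinguishing closely related livestock populations — recognized breeds,
and regional types nested within a breed — from genotype data is a
recurring need in genetic-resource conservation. Whole-genome resequencing
answers it but is far too expensive for routine identification, so the
practical instrument is a low-density targeted panel: a few thousand SNPs
chosen to be maximally population-differentiating and feasible as
hybridization-capture probes, genotyped by target sequencing.

`dmafpanel` implements the full design-and-validation loop: quality
filtering of multi-population genotypes, allele-frequency-differential
scoring, probe-feasibility gating, staged panel assembly, gene-structure
annotation, and validation via per-sample call statistics, GRM-based PCA,
identity-by-state distances and a neighbor-joining tree.

## The selection statistic

For populations $p, q$ with per-site ALT-allele frequencies $f_p, f_q$, the
pairwise differential is

$$\Delta(p, q) = |f_p - f_q|,$$

the classic δ statistic for breed classification. Two deliberate choices:

* **Unfolded frequencies.** Δ is computed on ALT-allele frequencies, not on
  per-population folded MAFs. Folding first would send a maximally
  informative site ($f_p = 0.9$ vs $f_q = 0.1$) to $\Delta = 0$. Because
  $|(1-f_p) - (1-f_q)| = |f_p - f_q|$, the unfolded differential is
  invariant under a ref/alt swap, so nothing depends on allele labelling.
  Folded MAF is still used for the MAF histogram and the optional MAF
  floor.
* **Per-population score.** The per-population selection score is
  $s_p = \max_{q \ne p} \Delta(p, q)$. "Top sites for population $p$" is
  underdetermined (max, mean and sum over pairs are all defensible); max
  targets the sites that best separate $p$ from its most confusable
  partner, which is the failure mode that matters for identification.
  Sex-chromosome ranking during capacity allocation uses the mean Δ over
  all pairs, which is stated explicitly by the design this package
  follows.

Sites where any population has zero called alleles are unscoreable and are
excluded from selection rather than imputed.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_depth` | 5 | X (mean per site) | below this, genotype calls are unreliable |
| `max_missing` | 0.10 | fraction, strict `<` | site-level callability |
| `max_het` | 0.30 | fraction of called, strict `<` | flags paralog collapse / excess heterozygosity |
| probe length | 110 | bp | capture-bait length |
| GC bounds | [0.30, 0.70] | fraction, inclusive | hybridization efficiency window |
| homology limit | 5 | central 31-mer genome hits | off-target capture control |
| `K` | 1500 | sites per population | per-population top list before union |
| `capacity` | 6000 | sites | probe-panel budget |
| `min_detection_rate` | 0.95 | fraction | empirical pruning after a test run |
| failed-sample threshold | 0.90 | missing fraction, strict `>` | library failures |
| flank | 1000 | bp | upstream/downstream annotation window |
| density window | 1e6 | bp | per-chromosome tiling |

The depth criterion is applied to the **per-site mean across samples** (the
site-level convention of vcftools-style filtering); a per-genotype variant
of the rule is not implemented. An all-missing site fails the missing
filter first, so its undefined heterozygosity fraction never decides
anything.

## Probe feasibility

The probe context is the 110 bp reference window with the variant base at
1-based offset 56 (55 bases left, 54 right) — an even length forces an
asymmetric convention, and this one is fixed and documented. Windows
running off a contig end are rejected (`edge`), as are windows whose
central base contradicts the declared ref allele (`ref_mismatch`) and any
window containing an ambiguous base.

"No more than five homologous regions" is operationalized as: count exact
occurrences of the probe's **central 31-mer** in the genome on both strands
(overlaps counted; the locus itself counts, so every probe scores ≥ 1).
This is a documented stand-in for a vendor's alignment heuristic, not a
claim about it; $k = 31$ is the conventional uniqueness k-mer scale and is
configurable. An odd $k$ cannot equal its own reverse complement, so the
two-strand count never double-counts a palindrome.

## Panel assembly

Three stages, each monotone (a site never re-enters after leaving):

1. **Top-K union** — per population, the $K$ candidates with largest $s_p$;
   duplicates collapsed; provenance (`population:rank`) recorded.
2. **Capacity allocation** — all autosomal sites are kept; residual
   capacity is filled by sex-chromosome sites in decreasing mean Δ. If
   autosomal sites alone exceed capacity they are all kept anyway, with a
   warning. Y-chromosome sites are excluded before selection (the target
   chip design carries no Y sites).
3. **Detection pruning** — sites with call rate below 0.95 in a test
   cohort are deleted.

All ties (at rank $K$, at the capacity boundary) break by (chromosome,
position) ascending under a natural chromosome order (numeric, then X,
then Y), which makes every export byte-reproducible.

## Validation statistics

Per-sample counts partition the panel exactly:
`n_missing + n_het + n_homalt + n_homref = n_sites`. The **missing rate**
is taken over all panel sites; **het / hom-alt / reference-consistency
rates are taken over called sites only**. This is the only denominator
convention consistent with the reference worked row the tests check
against (1954 het + 968 hom-alt + 2068 hom-ref = 4990 = 5002 − 12 and
1954/4990 = 39.16%).

Population summary tables report unweighted per-population means, and the
grand Mean row is the **unweighted mean of the population means** — not the
pooled per-sample mean. Both conventions are computed (the pooled one is
attached as an attribute) because they differ when populations have
unequal sizes; neither is "corrected" toward the other.

The GRM uses the GCTA estimator with pooled allele frequencies from the
analyzed cohort itself; monomorphic sites are excluded, and each sample
pair is averaged over the sites called in both. PCA eigen-decomposes the
double-centered GRM; eigenvector signs are fixed by making the
largest-magnitude loading positive. The individual-level tree uses the
allele-sharing distance $d = 1 - \mathrm{IBS}$, which is self-normalizing
on dosage data; the tree method is standard Saitou–Nei NJ with negative
branch lengths clamped to zero. Cluster–label concordance uses k-means on
the PCA coordinates (deterministically seeded, 25 restarts) scored by the
adjusted Rand index and cluster purity.

## The synthetic stated world

The simulator draws, per site, an ancestral frequency
$p \sim U(0.05, 0.95)$, breed frequencies from the Balding–Nichols law
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with $F_\text{breed} = 0.05$, and
type frequencies around the first breed's frequency with
$F_\text{type} = 0.005$ — three types nested in one breed plus two
independent breeds, 60 samples per population, 20,000 sites, per-call
missingness 0.002, Poisson(30) depth. $F$ values are engineering defaults
chosen to reproduce the separable-breeds / hard-to-separate-types regime;
they are not estimates from any dataset. Hudson's FST estimator recovers
$F_\text{breed}$ within Monte-Carlo error (its expectation under this draw
is $F$ itself, since $E[N] = 2Fp(1-p)$ and $E[D] = 2p(1-p)$).

What the generator does **not** emulate: linkage disequilibrium (sites are
independent), selection, pedigree/relatedness structure, mutation-spectrum
realism, depth–missingness correlation, and reference bias. A green test
therefore establishes algorithmic correctness on the stated statistical
structure, not performance on real resequencing data.

One measured property deserves note: at these defaults the assembled panel
retains some type-level signal — breed-level k-means concordance is perfect
(ARI = 1.0) while type-level concordance is materially lower but not
negligible (ARI ≈ 0.67 at full scale, with purity well below 1). With
6,000 independent sites even $F = 0.005$ yields a usable aggregate
signal-to-noise; real nested types, with LD shrinking the effective marker
count and the capture assay adding noise, separate worse. The acceptance
test asserts exactly what the simulation computes: perfect breed-level
concordance and a type-level deficit of at least 0.3 ARI.

## Numerical and degenerate-input choices

* Fraction thresholds outside $[0,1]$ are hard errors; strict vs inclusive
  bounds follow the filter wording (`>=` for depth, `<` for missing and
  het, closed interval for GC).
* Dosage decoding: `./.` and half-calls (`0/.`) are missing; phased
  separators are accepted as unphased; multiallelic and indel records are
  skipped with a logged count, never split.
* The MAF histogram bins $[0, 0.5]$ in 0.05 steps, first bin closed on the
  left; folding guarantees no mass above 0.5.
* Gene-structure precedence is exonic (CDS) > UTR5 > UTR3 > intronic >
  upstream/downstream > intergenic; a site 1 kb upstream of one gene and
  1 kb downstream of another is `upstream;downstream`. A combined
  `UTR5;UTR3` label (5′ UTR of one gene, 3′ UTR of another) is available
  behind `combine_utr = TRUE`; by default the eight-category scheme wins
  and UTR5 takes precedence.
* k-means and every simulation consume an explicit seed and restore the
  caller's RNG stream afterwards; identical config + seed gives
  byte-identical flat-file exports.

## Known limitations

* The homology gate is exact-k-mer, so it misses diverged paralogs that an
  aligner-based screen would catch.
* Detection-rate pruning needs a genotyped test cohort; no model predicts
  detection from sequence.
* The NJ tree carries no bootstrap support values.
* Population-level trees are available only by averaging individual
  distances within population blocks.
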