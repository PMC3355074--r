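---
title: "Germline hypomethylation, low-copy repeats, and structural mutability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Germline hypomethylation, low-copy repeats, and structural mutability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nahrmeth)
library(dplyr)
```

## The problem

Structural mutations — deletions, duplications, inversions — are not spread
evenly along mammalian genomes. Two genomic properties concentrate them.
First, *architecture*: directly-oriented paralogous low-copy repeats
(DP-LCRs, also called segmental duplications) sponsor non-allelic homologous
recombination (NAHR), which recurrently deletes or duplicates the whole
region between the repeats. Second, *epigenetic state*: regions that are
hypomethylated in the germline appear structurally hypermutable, and the
most extreme of them — **methylation deserts**, the windows in the lowest
1% of germline methylation — concentrate both evolutionary rearrangements
and polymorphic copy-number variants (CNVs).

`nahrmeth` implements the complete computational chain needed to measure
these effects on any genome for which one has (i) per-CpG bisulfite
observations, (ii) SNPs with ancestral alleles, and (iii) per-sample CNV or
rearrangement calls — and, because such data are bulky and assembly-bound, a
synthetic-data generator that plants every relevant signal with known truth
so each stage can be validated end to end.

## The pipeline layers

### Windows (`partition_genome`)

All statistics live on fixed-width windows (default 100 kb) tiled from
position 0 of each chromosome. Coordinates are 0-based half-open
throughout, written as BED. Three choices were genuinely open and are fixed
as follows:

* windows are tiled from 0 and never shifted around assembly gaps — a
  stable frame matters more than rescuing a handful of windows;
* a window is flagged *excluded* when ≥ 50% of its bases are assembly gap;
  windows with minor gap overlap stay, because the downstream
  minimum-events filter removes unsamplable windows anyway;
* the trailing partial window of each chromosome is dropped: methylation
  levels are only comparable across windows with equal sampling
  opportunity.

### Window methylome (`build_window_methylome`, `call_deserts`)

The unit of observation is the **CpG sampling event**: one read observation
of one CpG. A window's methylation level is
\[
\hat\theta_w = \frac{\sum_{\text{CpG} \in w} n_{\text{meth}}}{\sum_{\text{CpG} \in w} n_{\text{total}}},
\]
and a window is *valid* only with at least `min_events = 20` events (100
events and 100 mapped reads for the deep-coverage variant). Replicate
methylomes are averaged in level space (unweighted mean of window levels,
not pooled counts), so each donor contributes equally regardless of
coverage. Deserts are the valid windows at or below the empirical
`percentile` cutoff (1% by default, 5% as a relaxed variant); ties at the
cutoff are all included, and a call set that swallows every valid window is
flagged degenerate. Because desert calling uses ranks only, it is invariant
under any strictly monotone transformation of levels.

Estimation accuracy is quantified per window with a Clopper–Pearson
interval (exact, well-defined at the boundaries; the binomial CI method was
an open choice). A window "passes" at error bound $\epsilon$ when the CI
half-width relative to the point estimate is ≤ $\epsilon$; at
$\hat\theta_w = 0$ relative error is undefined and the absolute half-width
is used instead.

### Germline methylation index (`compute_mi`)

Methylated cytosines deaminate to thymine, so a window's historical
germline methylation leaves a fingerprint in its SNPs: C/T SNPs inside a
CpG with ancestral allele C (or, mirrored, G/A with ancestral G and a C to
the left) — **mSNPs**. The index is
\[
\mathrm{MI}_w \propto \frac{N_{\mathrm{mSNP}}(w)}{N_{\mathrm{CpG}}(w)\, N_{\mathrm{SNP}}(w)},
\]
normalised so that the mean over valid windows is exactly 1 (the
normalisation constant was not recoverable from the source material; a
fixed genome-mean scale preserves every property used downstream: MI = 0
exactly when a window has SNPs but no mSNP, ranking, and "MI > 0" strata).
Windows without SNPs carry no MI. CpGs are counted once per dinucleotide
on the reference sequence, assigned to the window of their C base; N bases
never match.

### LCR detection (`detect_lcrs`)

Low-copy repeats are found by k-mer self-comparison of the genome:

1. **Sampling.** The genome is cut into consecutive 500 bp fragments.
   Every placement of a 21 bp pattern samples 13 positions (8 unsampled),
   tolerant of mismatches. The pattern layout is a fixed configuration
   constant, chosen *symmetric* (offset $o$ sampled iff $20-o$ sampled) so
   the reverse-complement k-mer of a placement is computable in the same
   pass and inverted repeats are compared exactly. k-mers containing N are
   never hashed.
2. **Blacklist.** k-mers occurring more than 10 times inside annotated
   high copy-number repeats (LINEs/SINEs/microsatellites) and significantly
   enriched there (2×2 chi-square against genomic base totals,
   Benjamini–Hochberg FDR < 0.1) are ignored, so the self-comparison is
   not drowned by ubiquitous repeats.
3. **Matching.** Fragment pairs share a score = number of shared sampled
   k-mers (both orientations; minimum 10 by default). A reciprocal filter
   keeps a pair only if each fragment is in the other's top 50 matches and
   neither match list exceeds 1000 entries (the list-size test is applied
   before ranking; the alternative order was ambiguous).
4. **Merging.** Co-oriented matches advancing together (side-A gap
   < 1 kb, diagonal drift ≤ 250 bp) merge into pairwise LCR blocks kept at
   score density > 0.05 per side-A base.
5. **Identity.** Block identity is the match fraction of the optimal
   *local* affine-gap alignment, with a floor on the aligned fraction (80%
   of the shorter segment; any shortfall counts as mismatch). Local rather
   than fully global alignment is deliberate: detected blocks are
   fragment-quantized and can carry up to one fragment of non-homologous
   flank per edge, which a global alignment mis-scores as divergence
   (about 1–1.5 percentage points on 10–20 kb blocks), while the
   aligned-fraction floor prevents unrelated segments from scoring high on
   a short chance match. Segments beyond 5 kb are aligned in anchored
   2 kb chunks — exact under substitution-only divergence, a close
   approximation under indels.
6. **Clustering.** Pairwise LCRs cluster into paralog families by
   single-linkage connected components (the only deterministic reading of
   recursive pairwise clustering) under two criteria: k-mer content
   similarity
   $1 - (\mathrm{kmerDiff} + \ln(1+\mathrm{sizeDiff}))/\mathrm{kmerInBoth} \ge 0.5$
   (a pair's k-mer profile is the set union over its two members;
   `sizeDiff` compares summed member lengths; an empty intersection never
   clusters), or any positional overlap between members of different
   pairs. Members shorter than 1 kb or below 90% identity (against their
   own paralog — the "best paralog" reading) are then dropped.
7. **DP-LCR regions.** Same-cluster member pairs on one chromosome, in
   direct orientation, each ≥ 10 kb, ≥ 95% identity, separated by
   0–10 Mb, emit the intervening region — the NAHR-susceptible interval.
   Overlapping emissions *within a cluster* are merged (several member
   pairs of one family flank the same region); regions from different
   clusters are kept distinct even when they overlap, since nested or
   interleaved architectures are real and collapsing them would destroy
   their coordinates.

### NAHR signature (`classify_cnv`, `nahr_contingency`)

Each CNV is placed in exactly one category by a fixed precedence: spanning
≥ 2 inter-LCR regions → `complex`; inside exactly one inter-LCR region →
`whole_*` when covering ≥ 40% of the inter-repeat distance else
`scattered_*`, with the `paralogous`/`nonparalogous` suffix taken from
whether the flanking LCRs belong to one cluster; overlapping an LCR but no
region → `lcr_overlapping`; otherwise `unassociated`. The 40% threshold is
the one stated operational cutoff separating scattered from whole-region
CNVs; the inter-repeat distance is measured between the inner repeat
edges. The NAHR signature is then the 2×2 table {paralogous,
non-paralogous} × {whole, scattered}: recurrent NAHR events inflate the
whole∶scattered odds between paralogous flanks (Pearson chi-square without
continuity correction; the odds ratio is the effect size).

### Structural heterozygosity (`heterozygosity`, `het_by_stratum`)

Under the infinite-allele model at drift–mutation equilibrium, the ratio of
heterozygosities at two loci estimates the ratio of their mutation rates.
Any non-normal copy-number signal marks presence of a minor structural
allele; with variant-state frequency $q$ and $p = 1-q$, locus
heterozygosity is $2pq$. When related samples (parent and child) share a
variant, the family is counted once — in the carrier count *and* in the
effective sample count (the numerator-only variant, which keeps the full
denominator, is available in verbose mode). Loci are overlap-merged CNV
calls across samples (`merge_gap = 0`: strict overlap).

### Association statistics

* **KS association**: two-sample Kolmogorov–Smirnov on methylation levels
  of element-bearing vs remaining valid windows; $D_{\max}$ is reported
  with its asymptotic p (exact below combined n = 50).
* **Size-matched permutation**: each element is scored as the
  event-weighted mean level of the valid windows it overlaps and compared
  by KS against 100 length-matched segments drawn uniformly per element on
  the same chromosome (gap-overlapping draws redrawn, cap 100).
* **Distance decay**: 10 kb flanks placed 10–100 kb outward from element
  edges, KS-compared against flanks at the same distances from the matched
  random segments — a methylation effect confined to element-proximal
  sequence produces a decaying $D_{\max}$ series.
* **Enrichment fold**: (fraction of elements in a window stratum) /
  (fraction of valid windows in the stratum), chi-square p, with an exact
  binomial fallback on empty expected cells; a 1% stratum holding 10% of
  elements is a tenfold enrichment.
* **Relative and attributable risk**: with $a$ = element windows and $e$
  the exposure (deserts or DP-LCR windows),
  $\mathrm{RR} = P(a\mid e)/P(a\mid \bar e)$ and
  $\mathrm{AR} = (P(a) - P(a\mid\bar e))/P(a)$ (the population
  attributable fraction). The exact risk formulas were not recoverable
  from the source material; these are the standard epidemiological
  definitions consistent with computing "intersections among the groups or
  their complements", and the excess-risk variant
  $P(a\mid e)-P(a\mid\bar e)$ is also emitted.
* **Permutation enrichment** for arbitrary feature sets: length-matched
  uniform placement per chromosome, fold = observed/mean(null), p by the
  add-one estimator $(1 + \#\{null \ge obs\})/(n_{perm}+1)$ — never zero.

Every resampling operation takes an explicit seed, records it in its
result object, and leaves the ambient RNG stream untouched.

## The synthetic-data generator

`sim_config()` fixes the study conditions; all downstream validation runs
under them.

| knob | default | meaning |
|---|---|---|
| `window_size` | 100 kb | analysis frame |
| `gc` | 0.5 | background base composition (i.i.d. sequence) |
| `duplications` | 12 direct pairs, 10–50 kb, identity 95–99%, separation 0.1–8 Mb | planted LCR architecture |
| `desert_fraction` | 0.01 | planted desert windows |
| `desert_level_mean` | 0.03 | desert methylation (0 plants exactly-zero windows) |
| `background_level_mean`, `_conc` | 0.75, 12 | beta background methylation (high-methylation mode of a sperm-like methylome) |
| `events_per_window` | 200 | mean CpG sampling events (a low-coverage regime; real deep maps reach high hundreds) |
| `msnp_slope` | 0.005 | per-CpG mSNP probability per unit methylation |
| `background_snp_rate` | 1.3e-3 /bp | non-CpG SNPs with ancestral = reference, matching the human ~4M SNPs / 3 Gb density, so mSNPs stay a minority of SNPs as they do in real data |
| `element_fold` | 10 | desert enrichment of planted elements, via the placement probability $\pi = Ff/(1-f+Ff)$ |
| `n_samples`, `n_loci`, `locus_q_range` | 200, 100, 0.05–0.35 | CNV cohort; trio children inherit a carrier parent's variant with probability 1/2 |

Duplications are placed by rejection so copies never overlap; each copy
diverges by uniform substitutions at rate $1-\text{identity}$ and is
reverse-complemented when inverted. Bisulfite observations are Poisson
events per CpG site with binomial methylated counts at the window's true
level. Everything is a pure function of (config, seed).

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: a realistic repeat landscape (background
sequence is i.i.d.; high-copy tracts for blacklist tests are planted
explicitly), indel divergence between paralogs, coalescent haplotype
structure in SNPs, diploid genotypes (variant presence/absence per sample
mirrors the allele-frequency treatment of aCGH signals), bisulfite
conversion errors, and mappability structure. Results on real genomes
additionally depend on assembly quality and annotation completeness.

## Numerical choices and degenerate inputs

* Clopper–Pearson intervals via beta quantiles; exact at 0 and n.
* Desert percentile over valid windows only; `k = max(1, floor(p·n))`
  lowest levels, ties included.
* `kmer_similarity` returns `-Inf` on empty intersections (never
  clusters); natural logarithm in the size penalty.
* `compute_identity` returns 0 with a warning when segment lengths differ
  by more than 5× (degenerate pairing).
* Windows with SNPs but no CpGs get MI 0 when they also have no mSNP and
  are invalidated otherwise (contradictory input).
* Zero margins in contingency tables flag the p-value as undefined rather
  than fabricating one; empty expected cells fall back to exact tests.
* Heterozygosity with zero effective samples is flagged undefined;
  `P(a\mid\bar e) = 0` yields an explicit infinite RR with a warning.
* All permutation p-values use the add-one estimator.

## Validation geometry and problem sizes

The shipped test-suite exercises the pipeline at sizes chosen to make every
planted signal statistically decisive while keeping a full run in a few
minutes on one core: a 20 Mb two-chromosome genome with 12 direct, 6
inverted, and 6 sub-threshold duplication pairs for DP-LCR recovery
(boundary tolerance: one fragment, 500 bp); 400-window methylomes at 250
events/window for desert recovery; 200-replicate type-I calibration of the
KS, permutation, and case–control tests; 50-replicate fold recovery at
planted fold 10. One geometric note: the type-I calibration of the
size-matched permutation test scores elements on windows *finer* than the
elements (1 kb windows, 5 kb elements). With coarse windows the element and
null levels share a small discrete support and the KS test under heavy ties
becomes conservative; fine-grid scoring is the natural geometry for a test
whose purpose is precisely immunity to the fixed analysis window.

## Known limitations

* The LCR stage targets correctness at tens of megabases, not the
  performance engineering needed for gigabase genomes (no parallel diagonal
  scheduling; the k-mer join is in-memory).
* Identity under heavy indel divergence is approximate (anchored chunking).
* The NAHR classifier reasons purely geometrically; it does not use
  breakpoint microhomology and cannot separate NAHR from other mechanisms
  that produce whole-region events.
* MI's absolute scale is a package convention (genome mean 1); only
  relative statements are meaningful across datasets.
* Desert calls at a percentile are by construction relative; comparing
  desert sets across methylomes of very different coverage requires the
  accuracy profile to confirm both are estimable.

```{r session, echo=FALSE}
sessionInfo()
```
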