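---
title: "Methods: transgenerational methylome analysis with epitrace"
author: "epitrace maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transgenerational methylome analysis with epitrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

A hypomorphic maintenance DNA methyltransferase (dnmt1) allele in zebrafish
erases a large fraction of CpG methylation in homozygous animals. Sperm of
such G2 mutants is globally hypomethylated; two generations later,
genotypically wild-type males have globally restored methylomes but fall
into two phenotypic classes: G4\* males transmit impaired larval T-cell
development to roughly a third of their offspring, G4+ males do not. The
molecular correlate is a few hundred subtle sperm DMRs distinguishing G4\*
from G4+, some of which preserve the G2 hypomethylated state (persistent
epialleles), some of which arose later (novel), and a few of which flipped
sign (reversed).

epitrace implements the full analysis chain for this design on per-CpG
methylation count tables, together with a simulator that generates
pedigrees with planted ground truth so every stage can be validated without
sequencing data.

# Data model

The central container is `MethylationExperiment`, a
`RangedSummarizedExperiment` whose rows are width-1 CpG positions and whose
assays hold methylated counts `m`, total counts `c` and a per-position SNP
allelic-frequency estimate. The methylation ratio is `r = m/c`, `NA` when
`c = 0` or when the position is QC-masked. All interval containers are
`GRanges` (1-based, closed); BED input/output converts coordinates through
rtracklayer, and the package's own tab-separated methylation dialect writes
0-based starts, bedGraph-style.

# Quality masking

A position is masked genome-wide when

* its allelic-frequency estimate reaches **0.25** in any sample — a
  segregating variant invalidates the CpG for group comparison in every
  sample, hence the position-wide rule; or
* its coverage summed over all samples falls below **10 reads**
  ("aggregate coverage"). A per-sample variant (`perSample = TRUE` in
  `qcParams()`) masks positions where any single sample is below the
  threshold; the pooled reading is the default because the threshold is
  stated once for the position, not per library.

Counts are never discarded, only the ratio is `NA`-ed, so the mask is
auditable. Group-level summaries (`groupMeanRatios()`) use complete cases:
a position with an `NA` in any selected sample is dropped before the
per-group arithmetic mean is taken. Genome-wide state is summarized by the
median and the median absolute deviation of the pooled per-CpG group means;
the MAD uses the 1.4826 normal-consistency constant (the R convention), and
`madConstant = 1` gives the raw MAD.

# DMR discovery

Discovery runs on the per-CpG difference of group mean ratios
(group B − group A; with wild type as A and mutant as B, "hypomethylated"
means delta < 0).

1. **Pre-segmentation.** Maximal runs of CpGs with inter-CpG distance
   ≤ `maxGap` (300 bp); runs with fewer than `minCpG` (10) CpGs are
   dropped. These defaults are the published defaults of distance-bounded
   DMR callers; the re-evaluation stage is the binding filter, so
   candidates only need high recall.
2. **Recursive binary segmentation.** Within a block, the contiguous
   sub-interval of ≥ `minCpG` CpGs maximizing |mean difference| is found by
   exhaustive scan (O(n²) per block with prefix sums; blocks whose largest
   per-CpG |difference| is already below the floor are skipped, which is
   exact because an interval mean can never exceed the largest element).
   The sub-interval becomes a candidate when |mean| ≥ `minAbsDiff` (0.10)
   and a two-sided rank-sum test of inside vs outside differences gives
   p < 0.05 (a sub-interval spanning the whole block has no outside and is
   accepted on effect size alone). Flanks are segmented recursively. Ties
   in the maximizer are broken leftmost, then longest, making the procedure
   deterministic. A consequence of recursing on flanks is that one long
   uniform region can yield more than one abutting candidate; recovery
   accounting therefore matches planted regions to their best-overlapping
   call.
3. **Re-evaluation.** Per candidate: at least **20%** of its detected CpGs
   must remain usable after masking, and at most **1 sample** (counted
   across both groups; a per-group variant is configurable) may lack an
   interval mean. Usable CpG values are aggregated as the mean per interval
   per replicate, logit-transformed (`ln(r/(1−r))` with ratios clamped to
   `[0.005, 0.995]` so fully methylated intervals stay finite), tested with
   the moderated t-test below, BH-adjusted, and kept at **FDR < 5%**.

## The moderated t-test

For interval g with pooled two-group residual variance `s²_g` on `d_g`
degrees of freedom, the prior `(d₀, s₀²)` is fitted by method of moments on
`log s²_g`: with `e_g = log s²_g − ψ(d_g/2) + log(d_g/2)`,
`var(e) − mean(ψ′(d_g/2))` estimates `ψ′(d₀/2)`, inverted by Newton
iteration on the trigamma function; then
`s₀² = exp(mean(e) + ψ(d₀/2) − log(d₀/2))`. The posterior variance is
`s̃²_g = (d₀ s₀² + d_g s²_g)/(d₀ + d_g)` and the moderated t is referred to
a t-distribution with `d₀ + d_g` degrees of freedom, capped at the pooled
residual degrees of freedom of the collection. When the observed
log-variances are under-dispersed relative to their sampling noise
(`var(e)` ≤ expectation), the prior degrees of freedom are infinite and the
common variance is the arithmetic mean of the `s²_g` — the same convention
as the reference implementation in the limma package, against which the
test suite cross-checks to ~1e-6. Degenerate inputs: a collection in which
every interval has zero residual variance is an error (no prior can be
fitted); zero-variance intervals within a healthy collection shrink to the
prior. A single surviving interval cannot support a prior and falls back to
the ordinary pooled-variance t-test.

# Cross-generation evaluation and history classification

G4 DMRs are evaluated as fixed intervals in the G2 dataset with the same
usability rules, and called hypo/hyper only when **FDR < 2%** *and*
|delta| ≥ **0.20 on the ratio scale** (the effect threshold is a percent
difference between mutant and wild type, so it is applied to ratios, not
logits). Evaluable but non-significant intervals are `indistinguishable`;
intervals failing usability are `unassessed`. The history category is a
fixed function of (G4 direction, G2 status): same sign → `persistent`,
`indistinguishable` → `novel`, opposite sign → `reversed`. Category counts
partition the DMR total per direction.

Chromosome-level clustering is tested per chromosome with a two-sided
binomial test of the observed DMR count against expectation proportional to
the chromosome's CpG count, BH-adjusted across chromosomes. No specific
test is canonical for this display, so the CpG-weighted binomial null was
chosen as the simplest defensible option and is labelled as an extension.
Nearest-gene annotation reports signed distances (negative = upstream of
the gene's 5′ end on the gene's strand; 0 = overlap), ties broken by the
lexicographically smallest gene identifier.

# Feature segmentation

Promoters are the 500 nt upstream of each TSS on the gene's strand, kept
irrespective of overlap with any other class (the literal reading of the
source procedure), and clipped with a warning at chromosome boundaries; for
minus-strand genes "upstream" extends to higher genome coordinates. Exons
take priority where an exon of one gene overlaps an intron of another: the
exon class is the reduced union of all exons, introns are gene bodies minus
exons, intergenic is the genome minus gene bodies. The three classes are
disjoint and conserve genome bases exactly before the ≥ 5 nt length filter.
Placeholder-nucleosome regions are intersections of two peak sets (H2AZ and
H3K4me1-style) of length ≥ 100 nt; the operation is symmetric in its
inputs. CpG islands and repeats pass through as supplied.

# Phenotype statistics

The thymopoietic index of a larva is the rag1-positive in-situ signal area
divided by the gh-positive area in the same animal; gh serves as technical
and tissue-specificity control, and a zero gh area is treated as a failed
hybridization (error), not a zero index. The per-animal ratio is computed
first and clutch averages afterwards, matching per-animal dot plots. Clutch
noise is variance/mean of the per-larva indices with the sample (n−1)
variance (`population = TRUE` switches to n; the choice is not dictated by
the source and is therefore exposed). A larva is an outlier when its index
lies strictly outside mean ± 2 SD of a reference population pooled from
clutches of known non-transmitting parents; a parent is called a
transmitter when ≥ 15% of its larvae are outliers. The 15% default sits
between the ~4–5% outlier rate of a homogeneous clutch and the ~33%
deficient fraction of transmitter clutches; it is a documented choice, not
a published value, and parents with fewer than 5 larvae get no call.

# The synthetic pedigree

The simulator emulates the statistical structure the analysis assumes:

* **Counts.** Coverage per CpG and replicate is Poisson(30); methylated
  counts are beta-binomial with mean m and dispersion ρ = 0.01,
  parameterized as α = m(1−ρ)/ρ, β = (1−m)(1−ρ)/ρ, because WGBS replicate
  counts are overdispersed relative to binomial. A fraction (5%) of
  positions receives an allelic-frequency estimate ≥ 0.25 to exercise the
  SNP mask.
* **Baselines.** Wild-type sperm at 0.9762; G4+ and G4\* at 0.9757/0.9753.
  G2 mutant sperm is a per-CpG Bernoulli mixture: with probability 0.68 a
  site's baseline drops by 0.28. The mixture (rather than a uniform shift)
  reproduces a long-left-tail density; the two values were solved once so
  that the *median* of the simulated per-CpG group means lands at ~0.72 —
  the median of a mixture sits above the demethylated cluster's center, so
  the drop alone does not equal the median shift. The spatial arrangement
  of residual methylation in mutant sperm is not constrained by published
  data; independent per-CpG selection is a modeling choice.
* **Planted DMRs.** 243 ground-truth intervals of 10–20 consecutive CpGs
  with |Δ| ∈ [0.3, 0.5]; hypomethylated with probability 164/243.
  Planted intervals are restricted to CpG runs whose internal gaps are at
  most the segmentation `maxGap`, because a DMR is by definition a
  contiguous CpG cluster. Hypermethylated DMRs gain methylation at loci
  whose baseline is locally low in *all* groups (0.98 − Δ, emulating
  hypomethylated islands); a gain on a 97% baseline would be unrepresentable.
  Each DMR carries a G2 pattern: hypo DMRs are also demethylated in G2 with
  probability 101/162 (persistent), hyper DMRs with probability 17/75
  (reversed); the rest are G2-indistinguishable (novel). These proportions
  mirror the published history bookkeeping.
* **Clutches.** Thymopoietic indices are lognormal; healthy larvae at mean
  2.0 (CV 0.2), deficient larvae at mean 0.25 (CV 0.5; an 8-fold
  reduction), and transmitter clutches contain a 1/3 deficient
  sub-population. With these one-time choices the expected
  transmitter/control noise ratio is ≈ 7, consistent with the reported
  fold; the exact fold depends on effect sizes that were never published.

What the simulator does **not** emulate: bisulfite conversion error,
strand-resolved CpG pairs, read-level data, local correlation of
methylation along the genome outside planted intervals, covariate structure
between replicates, and chromosome-scale heterogeneity. Passing tests
therefore demonstrate correctness of the statistical machinery under the
assumed generative model, not performance on real libraries.

# Pipeline, determinism and problem sizes

`pipelineConfig()` validates every threshold in one record and rejects
unknown keys; the resolved configuration and seed are written into every
output directory, and `runPedigreeStudy()` reproduces all outputs
byte-identically from the same seed. All randomness is routed through a
single integer seed with fixed small offsets per stage, so each stage is
independently reproducible.

The default study simulates four chromosomes of 1.25 Mb with mean CpG
spacing 100 bp (~50,000 CpGs), three replicates per group at 30x — enough
for stable medians, FDR calibration with hundreds of candidate intervals,
and recovery of all 243 planted DMRs, while a full study completes in a few
seconds. Validation workloads use 20 null simulations for false-discovery
calibration and 100 simulated clutch pairs for the phenotype statistics;
the history-classification check runs at well-separated effect sizes
(|Δ| ≥ 0.4) where boundary effects of candidate splitting cannot push an
interval's G2 delta below the 0.20 effect threshold.

# Known limitations

* Candidate boundaries come from a greedy maximizer; long uniform regions
  may split into abutting calls, and a call can overhang a true region by a
  few CpGs, diluting its cross-generation delta. At small effect sizes
  (G2 drop near the 0.20 threshold) this can demote a persistent epiallele
  to novel.
* The FDR guarantee is empirical, not analytic: candidates are selected on
  the same data the moderated test re-evaluates. Under the simulated null
  the selection stage produces essentially no candidates, so the issue does
  not surface; with heavy-tailed real data it could.
* The binomial chromosome-enrichment test ignores spatial correlation of
  DMRs within chromosomes.
* Phenotype classification assumes a unimodal reference clutch; bimodal
  reference clutches (mis-labelled transmitters) would widen the band and
  mask true transmitters.
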