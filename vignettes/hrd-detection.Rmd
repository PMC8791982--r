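---
title: "Detecting homologous recombination deficiency in paired tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting homologous recombination deficiency in paired tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscars)
```

## The problem

Homologous recombination (HR) repairs DNA double-strand breaks with high
fidelity. Tumors that lose it — through *BRCA1/2* inactivation or otherwise —
fall back on error-prone repair and accumulate damage with a recognizable
shape, and they are the tumors most likely to respond to PARP inhibition.
`hrdscars` calls HR deficiency (HRD) from three independent molecular layers
in patient-matched primary/metastasis pairs and tests whether deficiency is
enriched in the metastatic arm. This vignette describes the models, the
tunable parameters and their defaults, the numerical choices, and what the
built-in simulations do and do not establish.

## Mutation catalogs and signature refitting

Every somatic single-base substitution is mapped to one of 96 channels: the
six pyrimidine-strand substitution classes (C>A, C>G, C>T, T>A, T>C, T>G)
crossed with the 16 flanking-base contexts, in canonical COSMIC order
(`sbs_channels()`). Purine-reference substitutions are reverse-complemented
first, so the mapping is a total function on valid SNVs; indels and
multi-allelic records are rejected at parse time and counted. Clustered
substitution runs (kataegis) can optionally be removed before binning; the
thresholds (runs of ≥ 6 same-sample SNVs with inter-mutation distance
≤ 1 kb) are configurable because published pipelines delegate this filter to
external tools without printing their parameters, and the filter is **off by
default** for the same reason.

The catalog $m \in \mathbb{N}^{96}$ is modeled as a non-negative mixture of
fixed reference signatures $S \in \mathbb{R}^{96 \times K}$ (columns sum
to 1): $\hat e = \arg\min_{e \ge 0} \lVert m - S e \rVert_2$, solved by
Lawson–Hanson NNLS. Ordinary least squares on raw counts was chosen as the
objective because it is convex, standard, and directly checkable against a
grid-search oracle; exposures are in mutation-count units.

Refitting against a fixed dictionary is ill-posed for weak signals, so point
estimates alone over-assign small exposures. The bootstrap thresholding
stage addresses this: the catalog is resampled `n_boot = 100` times
(multinomial over channels at the observed total $N$ — equivalent to
resampling individual mutations with replacement), each resample is refit,
and per signature

* the point estimate is the **median** exposure across bootstraps, and
* the **retention probability** is the fraction of bootstraps in which the
  exposure reaches `threshold_fraction` $\cdot N$ mutations
  (default 0.05, i.e. 5% of the sample's mutations).

Signatures with retention probability below `retention_p = 0.95` are zeroed
and the survivors renormalized to relative contributions summing to 1. The
0.95 rule subsumes the simpler "median below threshold" rule (a median below
the threshold forces retention probability below 0.5), so one configurable
parameter enforces both readings. A sample is *HRD-signature positive* when
the HRD-associated signature's relative contribution strictly exceeds
`cutoff = 0.9`; the cutoff is applied to the relative contribution (not to a
bootstrap probability), which is the literal reading of the benchmarked
rule, and it is configurable. A patient *gains* the signature when the
metastasis is positive and the matched primary is not.

Seeds: one top-level seed, with per-sample child seeds derived
deterministically from `(seed, sample_id)` (`derive_seed()`), so cohort
results do not depend on processing order and stay below $2^{31}$.

## Genomic scar scores

From allele-specific copy-number segments (total and minor-allele copy
number per interval, 1-based inclusive coordinates, the FACETS output
shape), three counts are computed after 3-Mb smoothing
(`smooth_segments()`: sub-threshold segments are absorbed into the
neighbor whose (total, minor) state is closer in Manhattan distance, ties to
the left; abutting equal-state segments coalesce; the operation is
idempotent):

* **LOH** — segments with `minor_cn = 0`, `total_cn ≥ 1`, length
  ≥ `loh_min_mb = 15` Mb, excluding any segment spanning an entire
  chromosome. The source convention describes score (1) once as a
  "fraction of chromosome" but sums it with the other two *counts*; we
  follow the count reading of the underlying convention, and the
  whole-chromosome exclusion comes from the same source.
* **ntAI** — allelic-imbalance segments
  (`minor_cn ≠ total_cn − minor_cn`) touching a chromosome end
  (`start = 1` or `end =` chromosome length) and not crossing the
  centromere (not spanning the full centromere interval), length
  ≥ `ntai_min_mb = 1` Mb. No published minimum length exists for this
  score; 1 Mb removes segmentation noise without touching real events and
  is configurable.
* **LST** — per chromosome arm (segments clipped at the centromere),
  breakpoints between consecutive segments in different states with both
  flanks ≥ `lst_min_seg_mb = 10` Mb and gap < `lst_max_gap_mb = 3` Mb.

The combined score is the unweighted sum HRD = LOH + TAI + LST. The
deficiency boundary is implemented as **combined ≥ 42**: the source
convention prints both "above 42" and "score > 41", and for integer scores
`≥ 42` satisfies the intent of both readings. Sex chromosomes are excluded
by default (`include_sex = FALSE`) because allele-specific states are
ill-defined for XY genomes. Chromosome geometry (lengths, centromeres)
comes from a plain-text genome build table; GRCh37 ships in
`inst/extdata/`, and `toy_genome_build()` generates compact builds for
simulation.

The paired arm comparison uses the one-sided Wilcoxon signed-rank test
(metastasis > primary), exact for small cohorts without ties or zeros and
normal-approximated otherwise; an all-zero difference vector is degenerate
and returns p = 1 with a warning rather than an error, so screens over many
score types do not abort.

## Expression scoring

`ssgsea_scores()` ranks genes per sample by decreasing expression, weights
position $i$ (of $N$) by $(N - i + 1)^\tau$, and accumulates the difference
between the weighted cumulative fraction of in-set genes and the unweighted
cumulative fraction of out-of-set genes; the score is the sum of the
pointwise differences, optionally normalized by the global max − min of the
score matrix. $\tau = 0.25$ is the original method's default (the source
does not print one). At $\tau = 0$ the statistic reduces exactly to the
classical Kolmogorov–Smirnov running sum, which the tests verify. Scores
depend only on within-sample ranks, hence are invariant to any strictly
increasing per-sample transform — the right property for cross-platform
log-scale expression.

`gsva_scores()` first maps each gene to a cohort-relative statistic by
Gaussian-kernel CDF estimation across samples (bandwidth = per-gene
SD / 4; Gaussian because the input is continuous log2 expression), then
ranks genes per sample by that statistic, weights positions symmetrically
($|N/2 - i + 1/2|$, so both tails carry weight), and runs a KS-like walk
(up by normalized weight at in-set genes, down by $1/(N-|\text{set}|)$
otherwise). The score is (maximum positive deviation) + (minimum negative
deviation) of the walk, which is confined to $[-1, 1]$ — matching the
signed score range the method is known for. At least 4 samples are required
(the cross-sample CDF is meaningless below that); smaller cohorts are
directed to ssGSEA.

One consequence worth stating plainly: because each gene's kernel-CDF
statistic averages exactly 0.5 across samples, GSVA scores measure
enrichment *relative to the cohort* — a gene set uniformly high in every
sample scores near zero everywhere, and no set can score strictly positive
in all samples. Use ssGSEA when absolute within-sample enrichment is the
question.

Gene sets load from standard GMT; members are matched to matrix rows by
case-folded exact string (no alias resolution), and sets with fewer than two
matched genes are dropped with a warning. Paired arm tests are two-sided
exact signed-rank per set; site tests (one site versus all others) are
two-sided Mann–Whitney; each family is Benjamini–Hochberg adjusted across
its sets, and families are never pooled.

## Subtype calls

`call_subtypes()` assigns each sample the centroid with maximal Spearman
correlation over shared genes (≥ 3 required), ties broken by declared
centroid order — deterministic, and invariant to monotone per-sample
transforms because only ranks enter. "Max probability" style calibration is
deliberately absent: the assignment rule is the max correlation itself.
Manual overrides (the occasional borderline call corrected after review)
are supported as an explicit, flagged input — never hard-coded.
`switching_summary()` reports per-patient switch flags, the switched
fraction, and the full transition table, whose marginals equal the two call
distributions by construction.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` generates a paired cohort with planted truth at every
stage. The defaults are the study conditions the package is designed
around: per-sample mutation counts ~ NB(mean 500, size 5) + 50 (a realistic
whole-exome range); half the patients acquire a dominant (95%) HRD
signature in the metastasis while primaries carry a 60/40 mix of two
non-HRD signatures; HR-proficient samples carry planted scar counts
(5, 3, 2) (combined 10) and HR-deficient metastases (20, 12, 11)
(combined 43, just above the 42 boundary); metastases get a +1 SD additive
shift on the HR gene set (25 of 300 genes); and about 27% of patients
switch subtype. Segment profiles are laid out **constructively** — each
planted event satisfies exactly one scorer predicate and violates the
others, events are isolated by > 3 Mb gaps, and the rest of the genome is
balanced diploid — so the scorers must recover the planted counts exactly;
this yields exact oracles rather than distributional ones. The reference
signatures used in simulation are sparse and near-orthogonal (pairwise
cosine < 0.3) so recovery experiments are well conditioned; real published
signature matrices load through the same TSV reader.

What the generator does *not* emulate: tumor purity and subclonality,
segmentation error in copy-number calls, correlated gene-gene expression
structure, batch effects, FFPE artifacts, or signatures with high mutual
similarity (flat COSMIC signatures such as SBS3/SBS5 are much harder to
separate than our synthetic columns). Passing the recovery tests therefore
demonstrates correctness of the scoring and testing machinery under the
stated generative model, not calibrated performance on real tumors.

## Numerical choices and problem sizes

Exact Wilcoxon p-values are used whenever the sample permits (no ties or
zeros, small n) and validated against full-enumeration oracles for all
n ≤ 8; larger or tied samples use the mid-rank normal approximation.
Degenerate inputs (all differences zero) return p = 1 with a warning. NNLS
tolerances are the solver's machine-level defaults; the enrichment oracles
agree to 1e-9. The test suite sizes its simulations to run in well under a
minute total: 200 random genomes for scar-oracle equivalence, 50 planted
triples for constructive recovery, 50 catalogs at N = 5000 for mixture
recovery, 20 seeded bootstrap runs for contaminant zeroing, 200 + 100
replicates for calibration and power of the paired pathway test, and a
10-patient end-to-end cohort run twice to confirm byte-identical output.
These sizes are the package's own reproducibility budget; all counts are
parameters that scale up trivially.

## Known limitations

* Scar scores consume allele-specific copy-number *calls*; no inference
  from reads, SNP pileups, purity or ploidy is attempted (FACETS or
  equivalent is assumed upstream).
* Signature refitting is against a fixed dictionary; no de-novo extraction,
  no doublet/indel signatures, no kataegis-aware refitting.
* Gene identifiers are matched by exact (case-folded) string; no alias or
  ortholog resolution.
* The GSVA-style scorer implements one member of that method family
  (Gaussian kernel, max-pos + min-neg walk statistic); other published
  variants (Poisson kernel for counts, two-sided statistics) differ in
  detail.
* The deficiency threshold (42), signature cutoff (0.9), and all length
  thresholds are calibrated conventions from the literature, not re-derived
  here; every one is a configuration value.
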