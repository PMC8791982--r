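# hrdscars

Homologous recombination deficiency (HRD) detection for paired
primary/metastasis tumor cohorts.

Tumors that have lost homologous recombination — the high-fidelity repair
pathway for DNA double-strand breaks — accumulate characteristic damage that
can be read out at three independent molecular levels. `hrdscars` implements
all three as one coherent, tested pipeline for patient-matched
primary/metastasis pairs (e.g. breast primaries and their brain metastases),
together with the cohort-level statistics used to compare the two arms:

1. **Mutational signatures.** Somatic single-base substitutions are binned
   into the 96 pyrimidine-strand trinucleotide channels
   (6 substitution classes × 16 flanking contexts, COSMIC order) and the
   catalog **m** is refit against a fixed reference signature matrix **S**
   (96 × K, column-stochastic) by non-negative least squares:

   ê = argmin<sub>e ≥ 0</sub> ‖m − S e‖₂

   Stability is assessed by bootstrapping the catalog (multinomial resampling
   at the observed total N, 100 iterations): the point estimate per signature
   is the median over bootstraps, and a signature is kept only if its
   exposure reaches 5% of N in at least 95% of bootstraps; surviving
   exposures are renormalized to relative contributions in [0, 1]. A sample
   is *HRD-signature positive* when the HRD-associated signature's relative
   contribution exceeds 0.9.

2. **Genomic scars.** From allele-specific copy-number segments
   (total and minor-allele copy number, FACETS-style):
   **LOH** = number of loss-of-heterozygosity segments ≥ 15 Mb not spanning a
   whole chromosome; **ntAI** = number of allelic-imbalance segments reaching
   a telomere without crossing the centromere; **LST** = number of
   breakpoints between adjacent ≥ 10 Mb segments in different allele-specific
   states (after 3-Mb smoothing, per chromosome arm). The combined score is
   the unweighted sum HRD = LOH + TAI + LST, and a sample is called
   *HR-deficient* when HRD ≥ 42.

3. **Transcriptome.** Rank-based single-sample enrichment of DNA-repair gene
   sets (HR, MMR, BER, NHEJ, ...) via ssGSEA (rank-weighted running sum,
   weights rank^τ, τ = 0.25) and a GSVA-style cohort-relative scorer
   (Gaussian-kernel CDF transform per gene, symmetric rank weights, KS-like
   random walk, scores in [−1, 1]). Paired arms are compared per set by the
   exact Wilcoxon signed-rank test, sites by the Mann–Whitney rank-sum test,
   both Benjamini–Hochberg adjusted across sets.

Intrinsic molecular subtypes are assigned per sample by nearest-centroid
Spearman correlation (PAM50-style; any centroid matrix in TSV form), with a
cohort subtype-switching summary for the paired arms. Tumor mutational burden
is coding mutations per captured megabase (50 Mb default).

A synthetic cohort generator plants known ground truth for **every** stage —
signature mixtures, exact (LOH, TAI, LST) event counts laid out
constructively on a toy genome, an additive expression shift on the HR gene
set in the metastasis arm, and centroid-consistent subtype profiles — so the
whole pipeline is testable end-to-end without access to restricted patient
data.

## Worked example

```r
library(hrdscars)

# 1. signature refitting with bootstrap thresholding
refs    <- synthetic_signatures()
catalog <- simulate_catalog(c(BreastA = 0.55, BreastF = 0.45), 1200, refs,
                            seed = 101, sample_id = "P01_met")
bootstrap_fit(catalog, refs, seed = 101)
#> Bootstrap signature exposure (100 iterations, threshold 5% of mutations)
#> sample: P01_met
#>         exposure rel_contribution retention_prob
#> BreastA    702.2            0.572              1
#> BreastF    525.0            0.428              1

# 2. genomic scar scores on a profile with planted (20, 12, 11) events
build <- toy_genome_build(n_chrom = 22, chrom_mb = 150,
                          cen_start_mb = 70, cen_end_mb = 75)
seg   <- simulate_segments(build, c(loh = 20, tai = 12, lst = 11),
                           seed = 101, sample_id = "P01_met")
score_scars(seg, build)
#> Genomic scar scores (combined = LOH + TAI + LST):
#>   sample loh tai lst combined deficient
#>  P01_met  20  12  11       43      TRUE

# 3. the full pipeline on a 10-patient synthetic cohort
dir <- tempfile(); simulate_cohort(dir, n_patients = 10, seed = 2026)
run_pipeline(dir, tempfile(), config = list(seed = 2026))
#> Cohort HRD report: 10 patients
#>   HRD signature (BreastF): 5 metastases positive, 5 gained over primary
#>   HR-deficient by scar score: 5 of 20 samples; paired test p = 0.0184
#>   pathway sets tested: 4
#>   subtype switching: 3 / 10 patients
```

The exposure table shows the two planted signatures recovered near their
0.55/0.45 mixing fractions with retention probability 1 (neither is zeroed
by the 5% bootstrap threshold). The scar profile scores exactly its planted
event counts; the combined score 43 crosses the deficiency threshold of 42.
On the full cohort, the five metastases simulated as HRD gain the HRD
signature, are called HR-deficient by the scar score, and the paired
one-sided signed-rank test detects the scar increase (p ≈ 0.018); the
subtype-switching count matches the planted labels.

A thin command-line wrapper with `simulate` / `validate` / `run` subcommands
ships in `inst/cli/hrdscars.R`.

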