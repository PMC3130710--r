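# itraqr

Regression-based iTRAQ protein quantification and uniform multi-omic
differential analysis for two-group (knockout vs wild-type) designs, with a
ground-truth synthetic-data generator that makes every stage testable end
to end.

## Who this is for

Proteomics/multi-omics analysts who have peptide-level iTRAQ reporter-ion
tables (one row per quantified spectrum, one intensity column per channel,
one channel holding a pooled internal standard) and want per-protein
relative concentrations plus a defensible downstream analysis: moderated-t
differential testing with FDR control applied identically to protein,
transcript and metabolite matrices, gene-set over-representation with
sample-vs-background frequency reporting, and transcript-protein
fold-change concordance.

## The model at the core

Each spectrum of a protein gives a pair (x, y): internal-standard intensity
x, sample-channel intensity y. With relative concentration r, y ≈ r·x with
no intercept, so the estimate is least-squares regression through the
origin:

    r̂ = Σ xᵢyᵢ / Σ xᵢ²,   R² = 1 − Σ(yᵢ − r̂xᵢ)² / Σ yᵢ²  (uncentered)

High-intensity pairs — the best ion statistics — inherently carry the most
weight. Around this estimator the pipeline applies isotope-impurity
correction (solving M·c = o per spectrum), automated regression-outlier
removal (|standardized residual| > 3, ≤ 2 rounds), per-run channel-bias
adjustment (geometric mean of high-confidence ratios, R² > 0.9 and ≥ 3
peptides, forced to 1), QC filtering (R² > 0.70, ≥ 2 peptides, ≥ 4
observations) and technical-replicate compositing (geometric mean; 2-fold
mismatches excluded).

Differential analysis uses the empirical-Bayes moderated t: the per-feature
variance is shrunk toward a prior (d₀, s₀²) estimated across all features
by moment-matching of log s², giving t = Δmean / (s̃·√(1/n₁+1/n₂)) on
d + d₀ degrees of freedom, BH-adjusted with significance at FDR < 0.02.
Fold changes use the signed convention (−10.2 = 10.2-fold down in the
knockout). Over-representation is the one-sided hypergeometric tail
P(X ≥ k) per gene set, reported with sample (k/n) and background (K/N)
frequencies.

## Worked example

Simulate a two-replicate iTRAQ experiment with known truth, quantify it,
and test the quantified proteins:

```r
library(itraqr)

cfg <- sim_config(n_proteins = 120, peptides_min = 4, peptides_mean = 6,
                  noise_cv = 0.2, outlier_fraction = 0.01, bias_range = 1.5,
                  n_per_group = 4, frac_de = 0.1, seed = 42)
ex    <- simulate_itraq_experiment(cfg)
quant <- quantify_run_set(ex$runs, ex$designs)
summary(quant)
#> iTRAQ quantification result
#>   2862 spectra -> 1920 protein/sample estimates -> 120 proteins x 8 samples
#>   zero-intensity pairs dropped: 0; regression outliers removed: 1
#>   estimates failing QC filter: 94; replicate mismatches excluded: 3
#>   channel bias factors:
#>     run1_rep1: 114=0.916 115=1.311 116=0.664 117=1.115 118=0.816 119=0.984 121=1.077
#>     ...

m  <- coef(quant)                       # log2 ratio matrix, proteins x samples
em <- expression_matrix(m[complete.cases(m), ],
                        ifelse(grepl("^KO", colnames(m)), "KO", "WT"),
                        scale_tag = "log2")
de <- run_de(em, fdr_threshold = 0.02)
summary(de)
#> differential analysis: 114 features, 12 significant at FDR < 0.02
#>   variance prior: d0 = 189.7, s0^2 = 0.015659
#>   top 10 by adjusted p:
#>  feature_id    adj_p signed_fc
#>    PROT0024 1.21e-60     -4.65
#>    PROT0065 5.79e-60      4.54
#>    ...
```

The quantifier recovered 120 proteins across 8 samples from ~2,900 spectra;
94 low-quality estimates and 3 replicate mismatches were dropped, the
planted per-channel bias factors (up to 1.5×) were estimated per run, and
all 12 proteins called at FDR < 0.02 are truly differential in the planted
truth. The full pipeline — including metabolites, gene-set enrichment,
transcript-protein concordance and a plain-text report — runs with
`run_pipeline(pipeline_config(...))`, or from a shell via the wrapper in
`inst/cli/itraqr.R` (subcommands `simulate`, `quant`, `de`, `enrich`,
`concord`, `report`, `all`).

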