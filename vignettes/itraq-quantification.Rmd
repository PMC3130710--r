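---
title: "Regression-based iTRAQ quantification and multi-omic differential analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression-based iTRAQ quantification and multi-omic differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itraqr)
```

## The problem

In a multiplexed iTRAQ experiment, tryptic peptides from up to eight samples
are labeled with isobaric reagents whose reporter ions (m/z 113--119 and
121) separate only in MS/MS. One channel carries a pooled internal standard
(equal protein mass from every sample), so each quantified spectrum yields a
vector of reporter intensities from which every sample's abundance can be
expressed relative to the same reference. `itraqr` implements a complete
route from these peptide-level reporter intensities to per-protein relative
concentrations, and then applies one uniform differential-analysis stage to
protein, transcript and metabolite matrices from a two-group
(knockout vs wild-type) design, followed by gene-set over-representation
and cross-layer fold-change concordance.

Because studies of this design rarely deposit reanalyzable raw data, the
package includes a first-class synthetic-data generator with known ground
truth. Every downstream stage is exercised and tested against that truth.

## The quantification model

For one protein in one run, each spectrum contributes a pair
$(x_i, y_i)$: $x_i$ is the internal-standard intensity and $y_i$ the
sample-channel intensity. If the protein's relative concentration is $r$,
then $y_i \approx r\,x_i$ with no intercept --- a zero-abundance protein
gives zero signal in every channel. The estimator is therefore
least-squares regression through the origin,

$$\hat r = \frac{\sum_i x_i y_i}{\sum_i x_i^2},$$

with fit quality reported in the uncentered convention
$R^2 = 1 - \sum_i (y_i - \hat r x_i)^2 / \sum_i y_i^2$, clipped to $[0,1]$.
Two consequences are intentional and worth stating plainly:

* **Intensity weighting.** Squared error grows with intensity, so bright
  pairs dominate the fit. High-intensity reporter ions have better
  ion statistics, so this weighting is a feature, but it also means the
  *effective* number of peptides behind a ratio is smaller than the
  nominal count when within-protein intensities are spread out.
* **Uncentered $R^2$.** The through-origin $R^2$ is not comparable to the
  centered $R^2$ of an intercept model and is typically larger; all
  thresholds in this package (0.9 for the bias set, 0.70 for the QC
  filter) refer to the uncentered definition.

### The processing chain

1. **Isotope-impurity correction.** Each reagent leaks known fractions of
   signal into neighboring masses. With a column-stochastic impurity matrix
   $M$ (columns = true channel), observed intensities satisfy
   $M c = o$; `apply_isotope_correction()` solves this linear system per
   spectrum and floors negative solutions at zero. An identity matrix is a
   no-op; a singular matrix is a configuration error.
2. **Pair construction.** One $(x, y)$ pair per spectrum per sample
   channel; pairs with a zero reference or sample intensity carry no ratio
   information and are dropped and counted rather than imputed.
3. **Automated outlier rejection.** The original interactive workflow
   highlighted regression outliers visually; a pipeline needs a
   deterministic rule. We fit, standardize residuals by their root mean
   square, remove pairs with $|r_i| > 3$, and refit, for at most 2 rounds,
   never attempting removal below 4 pairs nor leaving fewer than 3.
   A known limitation: with a single outlier among $n$ points the largest
   attainable standardized residual is about $\sqrt{n-1}$ (exactly 3.0 at
   $n = 10$ for equal-leverage points), so the strict $>3$ rule can only
   fire from $n \ge 11$ observations; gross outliers in low-count proteins
   are instead caught by the $R^2$ filter or the replicate-mismatch screen.
4. **Channel-bias adjustment.** Labeling efficiency shifts all ratios of a
   channel by a common factor. Within each run, the factor is the
   geometric mean slope of that channel's high-confidence proteins
   ($R^2 > 0.9$ and $\ge 3$ unique peptides) and is divided out, making
   the post-adjustment mean fold change of those proteins exactly 1. We
   use the geometric mean because ratios are multiplicative --- the
   arithmetic mean of a ratio and its reciprocal is not 1 --- but an
   arithmetic option is available (`quant_params(bias_mean =
   "arithmetic")`). The operation is idempotent. It assumes most proteins
   are unchanged: in a cohort where many proteins move in one direction,
   the centering would absorb part of the real signal.
5. **QC filtering.** Keep estimates with $R^2$ strictly above 0.70, at
   least 2 unique peptides and at least 4 observations (counted per run,
   not pooled across replicates). The boundary $R^2 = 0.70$ is rejected.
6. **Replicate compositing.** Each sample is measured in two technical
   replicate runs under rotated channel assignments. When both yield a
   ratio the composite is their geometric mean; when one does, the single
   value is used; when they disagree by more than 1 log2 unit (a 2-fold
   mismatch --- the threshold is configurable, as no canonical value
   exists) the protein/sample pair is flagged and excluded downstream.

`quantify_run_set()` runs the whole chain and returns the log2 composite
ratio matrix plus counts at every stage.

## The differential stage

All layers are tested on the log2 scale; positive-scale inputs (metabolite
concentrations, linear protein ratios) are log2-transformed first with a
floor at half the smallest positive value, so zeros cannot generate
infinities. For each feature the two-group statistics are the group means,
the pooled within-group variance $s^2_g$ on $d = n_{KO} + n_{WT} - 2$
degrees of freedom, and the fold change computed from the group means.

Variances are moderated empirically across features: assuming
$s^2_g \mid \sigma^2_g \sim \sigma^2_g \chi^2_d / d$ with a scaled
inverse-$\chi^2$ prior on $\sigma^2_g$ having $d_0$ degrees of freedom and
scale $s_0^2$, the posterior variance is
$\tilde s^2_g = (d_0 s_0^2 + d\, s^2_g) / (d_0 + d)$ and

$$t_g = \frac{\bar y_{KO} - \bar y_{WT}}
             {\tilde s_g \sqrt{1/n_{KO} + 1/n_{WT}}}$$

follows a $t$ distribution on $d + d_0$ degrees of freedom under the null.
The prior is estimated by method of moments on $\log s^2_g$: the empirical
mean and variance are matched to their theoretical digamma/trigamma
expressions, with $d_0$ recovered by Newton inversion of the trigamma
function. When the spread of $\log s^2_g$ does not exceed the pure
sampling floor $\psi'(d/2)$, the data are consistent with a common
variance: we set $d_0 = \infty$ (normal reference distribution) and
$s_0^2$ equal to the mean variance.

Multiplicity is controlled by Benjamini--Hochberg step-up adjustment,
with significance declared at an FDR threshold of 0.02 by default
(configurable). Fold changes are reported in the signed convention used
throughout this field's tables: $r$ when $r \ge 1$, $-1/r$ otherwise, so
$-10.2$ means 10.2-fold lower in the knockout and $|fc| \ge 1$ always.
Correlation between layers is computed on the signed-log2 transform
$\mathrm{sign}(fc)\log_2|fc|$, because the signed-fold-change scale has a
jump discontinuity at $\pm 1$ that would distort a linear correlation.

Two QC screens mirror the cohort-level practice for this design:
`pca_outlier_flags()` flags samples more than 3 robust SDs
($1.4826 \times$ MAD, so the outlier does not inflate its own yardstick)
from the component median on any leading principal component, and
`contamination_screen()` flags samples whose mean abundance over marker
proteins (e.g. hemoglobin subunits in a perfused-liver proteome) exceeds
the cohort mean by 3 SDs. The pipeline excludes flagged samples before
differential analysis.

## Over-representation and concordance

`enrich()` scores a GMT-style gene-set collection against a differential
list with the one-sided hypergeometric tail $P(X \ge k)$ (over-representation
only; the tables this reproduces report enrichments, not depletions),
BH-adjusted across the collection. Each record carries the sample
frequency $k/n$ and background frequency $K/N$ as percentages --- the
arithmetic that such tables print. Differential ids missing from the
declared universe are dropped with a count: the background defines the
sampling frame, so silently extending it would bias every test.

`match_features()` pairs the significant transcript and protein lists by
case-insensitive symbol (optionally through a mapping table), resolving
one-to-many mappings by the largest $|t|$; `fold_change_correlation()`
reports both Pearson $r$ and $r^2$ over the matched pairs, since published
summaries quote sometimes one and sometimes the other.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the emulated study design: 8-plex runs with
channel 113 as pooled internal standard; two technical replicates per
sample with channel assignment rotated between replicates (rotation makes
bias and ratio separately identifiable, since a fixed assignment confounds
them); per-channel bias drawn log-uniform within 1.5-fold; reporter noise
CV 0.2; 1% of sample-channel observations distorted by a log-uniform
3--10x factor; 34,273 transcript features of which 899 are differential;
5 transcript / 7 protein / 9 metabolite animals per group; a 205-metabolite
panel (configurable --- published counts for such panels vary between 205
and 210).

Peptide intensities are hierarchical: a lognormal protein-level abundance
(natural-log SD 1.0, the between-protein dynamic range) times a lognormal
within-protein peptide response (SD 0.35). The split matters because only
the *within*-protein spread interacts with the intensity weighting of the
regression: a wide within-protein spread collapses the effective peptide
number toward 1 and attenuates the replicate-vs-replicate regression slope
below 1 through noise in the x variable. The within-protein SD of 0.35 is
calibrated once so that synthetic technical replicates reproduce the
slope-of-1 concordance reported for real replicate runs; it is not
adjusted per experiment.

Per-feature residual variances in the expression generators are drawn from
a scaled inverse-$\chi^2$ with $d_0 = 4$, $s_0^2 = 0.05$, so the
moderated-t prior is a recoverable ground truth rather than an artifact of
convenience.

The generator starts at quantified reporter intensities. It does not
simulate spectra, chromatography, retention time, identification
confidence, missing proteins (every simulated protein is observed in every
run), shared/razor peptides, or ratio compression from co-isolation
interference. Passing tests therefore demonstrate correctness of the
estimation chain under the stated noise model, not robustness to
identification errors or interference --- on real data those effects bias
ratios toward 1 in ways no downstream estimator can undo.

## Numerical choices and degenerate inputs

* Correction matrices are applied by solving the linear system (exact
  inverse), not by a nominal-purity approximation; negative solutions are
  floored at 0.
* A protein/sample with no usable pair yields a no-estimate result and is
  skipped, not imputed.
* `fit_protein_ratio()` returns $R^2 = 1$ when residuals are identically
  zero and clips to $[0,1]$ otherwise.
* `estimate_eb_prior()` requires at least 50 positive variances; all-zero
  variances are a degenerate-input error.
* BH adjustment validates $p \in [0,1]$ and uses a stable sort, so ties
  are handled reproducibly.
* All generators take explicit integer seeds and are byte-reproducible;
  the pipeline funnels every stage seed from one configuration seed. When
  composing custom simulations, give each generator call a distinct seed
  --- re-using one seed across two draws replays the same random stream.

## Test and acceptance problem sizes

The shipped tests exercise the estimators at sizes chosen to make the
statistical checks sharp yet quick: oracle comparisons on 1,000 random
inputs (slope and BH), exhaustive hypergeometric enumeration for all
universes up to $N = 12$, prior recovery and type-I error on 10,000-feature
simulations, realized-FDR checks on 20 null simulations of 2,000 features,
quantifier recovery on 200--500 protein experiments, and the full pipeline
on a reduced study (1,500 transcripts, 80 proteins). The acceptance script
re-runs the frequency arithmetic at full published scale (34,273-feature
universe) and the replicate-concordance experiment at 200 proteins.

## Known limitations

* The outlier rule's $\sqrt{n}$ ceiling (above) makes it inert for
  proteins with few observations.
* Bias adjustment assumes a mostly-unchanged proteome within each channel.
* The moderated test assumes equal residual variance across groups and
  exchangeable features; the prior estimator assumes a common residual
  degrees of freedom, which holds for complete two-group designs but not
  after per-feature missingness (the pipeline drops incomplete proteins
  before testing for this reason).
* Enrichment treats gene sets as flat (no ontology-graph propagation), and
  adjusted p-values are comparable only within one invocation.
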