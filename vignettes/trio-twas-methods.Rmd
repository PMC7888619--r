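---
title: "Trio-based TWAS by pseudo-sibling matching: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based TWAS by pseudo-sibling matching: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triotwas)
```

## The model

A proband–parent trio carries its own perfectly matched controls: of
the four ways of combining one paternal with one maternal haplotype,
one was transmitted to the affected child and three were not. Because
the SNP predictors of a gene's expression all lie in the local
cis-window, `triotwas` assumes no crossover within the window, so each
candidate offspring genotype is one *whole* paternal haplotype joined
with one whole maternal haplotype — exactly four configurations,
labelled `f1m1`, `f1m2`, `f2m1`, `f2m2`.

Genetically regulated expression is imputed for every member as the
linear score $x = \sum_j w_j d_j$ with pre-trained eQTL/sQTL weights
$w_j$ and allele dosages $d_j$. Linearity gives two exact identities
used throughout the tests: the four configuration values sum to twice
the parental sum, and the sibling built from the two non-transmitted
haplotypes has expression $x_f + x_m - x_p$.

With error-free phasing one configuration is genotype-identical to the
proband, so the configuration whose imputed expression is closest to
the proband's (smallest absolute difference; smallest sum of squared
differences across genes in multivariate fine-mapping; ties to the
lowest configuration index) is excluded. The remaining three values are
the matched controls, and transmission disequilibrium is estimated from
the conditional likelihood

$$L(\beta)=\prod_{i=1}^{N}
  \frac{e^{x_{pi}\beta}}
       {e^{x_{pi}\beta}+e^{x_{s1i}\beta}+e^{x_{s2i}\beta}+e^{x_{s3i}\beta}}.$$

$\beta$ is the log-odds of being the affected child per unit of imputed
expression, conditioning away everything shared within a family — in
particular ancestry, which is what makes the design robust to
population stratification.

## Fitting and numerical choices

`clr_fit()` maximizes the conditional log-likelihood by Newton–Raphson
with step-halving, declaring convergence when the largest score
component falls below $10^{-8}$ (at most 50 iterations, non-convergence
reported rather than silently returned). Standard errors come from the
observed information. The implementation is vectorized over families
and handles any 1 case : K controls layout (K = 3 pseudo-sibling, K = 2
parent-control, K = 1 matched pair) and multivariate exposures for
fine-mapping.

Degenerate inputs are handled explicitly:

* families whose K+1 exposure vectors are identical carry no
  information and are dropped (both total and informative N are
  reported); at $\beta = 0$ every informative family contributes
  $-\log(K+1)$, an identity the tests check to $10^{-12}$;
* complete separation — the case is the strict extremum in every
  informative set, or the estimate runs past ±15 on standardized
  exposures — is flagged, the coefficient capped, and the p-value taken
  from the score test at $\beta = 0$;
* a numerically singular information matrix (collinear gene exposures
  under strong LD in fine-mapping) triggers a warning and a
  ridge-stabilized step, flagged on the result.

Exposures are z-scored per gene over the probands and retained pseudo
siblings using the population SD (divide by n). Whether the original
analyses standardized exposures before fitting or normalized effect
sizes afterwards is not documented; standardization is therefore a
flag (`standardize`, default TRUE), and the conditional likelihood's z
statistic is invariant under any affine exposure map, so the choice
affects only the scale on which $\beta$ is reported (per SD of imputed
expression when standardized). In fine-mapping the exclusion step uses
normalized exposures so that all genes contribute to the sum of squares
on a common scale.

The one-sibling alternative design is fitted by unconditional logistic
regression by default, matching the analysis the framework is compared
against, with a 1:1 conditional fit behind `method = "clr"`; the two
conventions disagree in the source material and both are provided
rather than resolved. Permutation p-values throughout use the
$(r+1)/(B+1)$ correction (the uncorrected proportion is available where
the original analysis reported one).

## The synthetic-trio generator

`simulate_twas_dataset()` emulates every input the pipelines read:
parental haplotypes are i.i.d. Bernoulli(MAF) per variant (default 10
SNPs at MAF 0.3), offspring receive one uniformly chosen haplotype per
parent, expression is the linear SNP score plus environmental noise
$\varepsilon \sim N(0, 0.25)$ by default, and disease follows
$P(D=1) = 1/(1+\exp(-\beta_0-\beta_1 G))$, either sampled
(`bernoulli`) or thresholded at probability 0.5 (`threshold`). Default
weights are drawn once per dataset and rescaled so the imputed
expression has unit population variance, making $\beta_1$ an effect
per SD of imputed expression. With `ascertain = TRUE` only families
with an affected proband are retained, as in real trio studies. All
randomness descends from one root seed through named substreams, so
every experiment is independently reproducible; datasets round-trip
through the package's VCF/FAM/weight-table readers.

What the generator does **not** emulate: LD between predictor SNPs,
realistic MAF spectra, recombination within the cis-window, phasing
error, and genotyping/imputation uncertainty. Passing tests therefore
certify the statistical machinery under clean Mendelian transmission,
not robustness to those data pathologies (phase error is surfaced
separately by `check_mendelian_consistency()`, and expression-level
noise by the robustness experiment below).

## Simulation experiments and their conditions

Problem sizes below are the package's study conditions, fixed in the
experiment defaults.

**Type-I error under shuffled status.** 2,000 independent null genes,
500 trios each; within every family the "case" label is reassigned
uniformly among the proband and its three matched pseudo siblings.
Exchangeability makes the null exact: the empirical rejection rate at
$\alpha = 0.05$ should sit in the binomial band around 0.05 and the
p-values should be KS-uniform.

**Noise robustness.** One ascertained dataset of 300 trios with a true
effect of 0.3 per SD (rare disease, $\beta_0 = -2.5$);
$N(0, \sigma^2)$ noise is added to every member's standardized imputed
expression for $\sigma^2 = 0.05, 0.10, \dots, 1$ (100 replicates per
level, $\alpha = 0.05$). Power decreases in $\sigma^2$; the test
asserts the trend (first ≥ last and negative Kendall rank correlation)
rather than strict pointwise monotonicity, which 100-replicate
binomial noise cannot guarantee. The companion null calibration
regenerates a fresh effect-free cohort per replicate — conditional on
a single dataset the rejection rate is not $\alpha$, marginally it is —
and checks that noise does not inflate type-I error at any level.

**Power comparison of the three designs.** 1,000 trios per replicate,
200 replicates, effects $\beta_1 \in \{0.2, 0.4, 0.8\}$, low
($\beta_0 = -2.5$, prevalence 0.076) and high ($\beta_0 = 2.25$,
prevalence 0.90) regimes, all designs fitted by conditional logistic
regression and rejected at the same nominal $\alpha = 0.05$. The
Bernoulli disease mode is the default here: under the threshold rule
both affectedness and the realized number of ascertained trios are
determined by $\beta_1$, so power curves over an effect grid are not
comparable (the threshold mode remains available). The genotype-backed
expression model is the default because it is internally consistent
with the rest of the package; the literal mode (member expressions
i.i.d. N(0,1), non-transmitted sibling = father + mother − proband) is
provided as an option, and an empirical level-matching option
(`calibrate`) recalibrates each design's threshold on a companion null
run for settings where the designs are unequally calibrated. Expected
orderings: the 3-sibling design dominates the 1-sibling design at low
prevalence (three contrasts per family instead of one), and the
parent-control design trails both at high prevalence — parents
correlate with their child, which both shrinks the contrast and makes
the nominal test conservative under ascertainment.

**Coverage.** 200 replicates of 1,000 ascertained trios with a true
effect of 0.3 per SD at $\beta_0 = -4$ (baseline prevalence ≈ 1.8%,
the realistic range for the motivating disorder). The rare-disease
regime is deliberate: the conditional softmax likelihood equals the
retrospective transmission probability only up to the rare-disease
approximation $\mathrm{expit}(\eta) \approx e^{\eta}$, so at common
prevalences the estimand is attenuated (measurably: ≈ $(1-K)\beta_1$
at prevalence $K$) and nominal coverage of the generative effect is
not the correct expectation. Environmental expression noise does not
bias this experiment — for a rare disease an additive independent
noise term multiplies every member's weight by the same factor and
cancels from the conditional likelihood.

## Aggregation and enrichment conventions

* IVW meta-analysis uses $w_i = 1/\mathrm{se}_i^2$; the
  sample-size-weighted z combination uses $w_i = \sqrt{N_i}$ with
  $N$ = informative families for trio cohorts; the two-stage pipeline
  (IVW across trio cohorts, then z-combination with replication
  cohorts that report no effect sizes) mirrors how such mixed designs
  are combined in practice.
* Significance tiers: BH FDR within tissue plus a cross-tissue
  Bonferroni cutoff $\alpha/\text{n}_\text{tests}$ (125,000 tests at
  $\alpha = 0.05$ give 4.0e-7); the total test count is a
  configuration input because it depends on the model set used.
* pTDT scales the proband-minus-midparent deviation by the sample SD
  (n−1) of midparent scores and applies a two-sided one-sample t-test.
* De novo expected counts are `2 × n × Σμ` by default — the factor 2
  converts per-chromosome mutability to a diploid per-offspring
  expectation and is exposed because published tables differ in
  convention. The MPC threshold for deleterious missense is strictly
  greater than 2. "All mutations" is the union of the three defined
  classes; unrecognized labels are counted but never tested.
* Exact tails (hypergeometric, Poisson) are computed by the standard
  distribution functions and verified against naive summation to
  $10^{-12}$ in the tests.
* The prenatal-elevation test averages log₂(RPKM+1) within (region,
  stage), splits stages at birth, and permutes stage labels within
  region; the exact permutation scheme behind the original analysis is
  unstated, so this within-region scheme is a documented choice.

## Known limitations

* The no-crossover assumption is only adequate for cis-windows;
  trans predictors would require a recombination model.
* Families whose proband matches no configuration (phase error in real
  data) are flagged and excluded per variant/gene; best-match recovery
  is not attempted.
* The conditional model carries a single exposure term per gene; there
  is no covariate adjustment beyond the matching itself, and no
  robust/sandwich variance.
* Imputation-model training, genotype QC, phasing and LD-aware PRS
  construction are upstream of this package and are expected as
  inputs.
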