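---
title: "Methods: MR and colocalisation for transcriptome-wide gene prioritisation"
author: "mrcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MR and colocalisation for transcriptome-wide gene prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcoloc)
```

# The problem

Genome-wide association studies locate disease risk loci but do not by
themselves say which gene at a locus drives risk, in which tissue, or whether
the association is causal at all. `mrcoloc` implements a summary-statistics
pipeline that treats cis-eQTLs as instrumental variables for gene expression
and asks, gene by gene, whether genetically predicted expression affects the
risk of a binary outcome (the motivating application is glioma and its
glioblastoma / non-glioblastoma subtypes, with expression measured in brain
meta-analysis and whole-blood eQTL panels, and per-tissue follow-up across up
to 13 brain tissues).

Four lines of evidence are combined for every gene x tissue x subtype unit:

1. **Two-sample MR.** With a single instrument SNP the causal log-odds per SD
   expression is the Wald ratio $\hat\theta = \hat\beta_{GY}/\hat\beta_{GX}$,
   with first-order standard error $SE = s_Y/|\hat\beta_{GX}|$ (a second-order
   form adding the exposure-side term is available). Multi-SNP instruments
   combine per-SNP ratios by fixed-effect inverse-variance weighting. With
   one or two SNPs per instrument, random-effects IVW is undefined or equal
   to fixed-effect, so fixed-effect is the default.
2. **Colocalisation.** An MR hit can be confounded by LD: a variant linked to
   the eQTL may act on the outcome directly. For each passing unit a region of
   ±500 kbp around the instrument SNP is scored under the five
   single-causal-variant hypotheses (H0 no association; H1/H2 one trait only;
   H3 two distinct variants; H4 one shared variant), using per-SNP Wakefield
   approximate Bayes factors
   $\log ABF = \tfrac12[\log(1-r) + r z^2]$, $r = W/(V+W)$, combined with
   per-SNP priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and prior effect
   SDs 0.15 (expression, SD units) and 0.2 (case-control, log-odds). H4 >= 0.80
   is "strong", 0.50-0.80 "moderate", < 0.50 "weak" evidence of a shared
   causal variant.
3. **Conditional analysis.** The coloc model assumes a single causal variant
   per region. Before colocalisation, a stepwise summary-statistics model
   selection (entry threshold 5e-8, collinearity guard r² < 0.9) looks for
   secondary signals using the LD reference; when more than one signal is
   found the region is conditioned on the secondary signals and coloc runs on
   conditional statistics, restoring the single-variant assumption. When only
   one signal exists, marginal statistics are used unchanged.
4. **Steiger directionality.** To guard against reverse causation, the
   variance explained by the instrument in exposure,
   $r^2 = z^2/(z^2 + n - 2)$ (summed over instrument SNPs), is compared with
   the variance explained in the outcome (observed scale, effective
   $n_{\mathrm{eff}} = 4/(1/n_{case} + 1/n_{control})$) via an
   independent-samples Fisher-z test. Category `true` requires the exposure
   side to dominate with P < 0.05; P >= 0.05 is `uncertain`.

A unit is **robust** when its MR P value passes at least the suggestive
threshold, its coloc tier is strong, and Steiger returns `true`.

## Multiple-testing thresholds

With $G$ genes instrumentable in the discovery panel, the strict Bonferroni
threshold is $0.05/G$ and the suggestive threshold relaxes it by the number of
follow-up tissues $T$: $0.05 \cdot T / G$. The study conditions ($G = 6849$,
$T = 13$) give:

```{r}
multipleTestingThresholds(6849, 13)
```

## Instrument selection

Only cis variants (within a closed 1 Mbp window of the gene's TSS) are
eligible; trans-eQTLs are excluded as more pleiotropy-prone. Candidates below
the significance threshold — genome-wide 5e-8 for discovery, lenient 5e-4 for
the per-tissue follow-up, where single-tissue panels of n = 114-209 rarely
reach genome-wide significance — are clumped greedily by ascending P value
(ties broken by position, then SNP id, making the output order-invariant),
accepting a SNP only if its r² with every previously accepted SNP is below
0.01. The "gene regulatory region" is anchored at the TSS because that is the
most common convention; the anchor is configurable.

# The synthetic-data generator

Every calibration claim in the package is tested against data generated by
`simulateStudyPair()` under five scenarios mirroring the coloc hypotheses:
`null`, `exposure_only`, `outcome_only`, `distinct_variants` (two causal
variants in LD) and `shared_variant` (one causal variant plus a causal
exposure-to-outcome effect `theta`).

**Study conditions.** The defaults are the conditions used throughout:
`betaGx = 0.5` SD expression per allele, `theta = 0.4` log-odds per SD,
5000 exposure individuals, 5000 cases / 5000 controls, MAF uniform on
[0.1, 0.5], AR(1) LD with rho = 0.8 in blocks. Per-tissue panels draw n from
114-209, matching single-tissue eQTL panel sizes.

**Genotypes.** The default model generates Gaussian dosages
$G = 2p + \sqrt{2p(1-p)}\,Z$ with $Z \sim MVN(0, R)$, so the realized LD
equals the target matrix exactly and $\mathrm{Var}(G) = 2p(1-p)$; this mirrors
imputed dosage data. A thresholded-haplotype model (two indicators of
correlated standard normals falling below the MAF quantile) is available as
`genotypeModel = "threshold"`, but note that dichotomisation attenuates
correlations substantially (target rho 0.8 yields genotype r of roughly
0.55-0.6 at MAF 0.3), so the supplied LD matrix is then only a rough
reference; the dosage model is the default for exactly this reason.

**Outcome model.** The exposure is $\beta_{GX} G_c$ plus normal noise scaled
to unit total variance. The outcome sample is independent (two-sample
design); its liability is `theta` times an independently re-sampled exposure
plus *standard logistic* noise, thresholded at the top case fraction. The
logistic error makes the per-SNP log-odds slope at the causal SNP equal to
$\theta \beta_{GX}$ (up to a small non-collapsibility attenuation of ~2-4%
from marginalising over the expression noise), so the Wald ratio targets
`theta` directly. With normal (probit-style) liability noise the recovered
log-odds would be inflated by the logit/probit factor ~1.6 and no estimator
could recover `theta` on the log-odds scale.

**Case-control summary statistics** use the logistic score approximation:
the per-SNP Z from the linear regression of case status on dosage, the
standard error $1/\sqrt{n\,s(1-s)\,2p(1-p)}$, and `beta = z * SE`. This
matches per-SNP logistic ML closely at these effect sizes (checked against
`glm` in development) and avoids 100 IRLS fits per region per replicate.
The effective sample size $4/(1/n_{case}+1/n_{control})$ is recorded in the
table metadata and used for outcome-side variance explained.

**What the generator does not emulate:** realistic human LD maps, imputation
error, sample overlap between exposure and outcome panels, allele-frequency
drift between panels, pleiotropic instruments, and population structure.
Passing calibration on this generator therefore demonstrates internal
consistency of the estimators under their own assumptions, not robustness to
those real-data complications.

# Conditional analysis from summary statistics

Genotype cross-products are reconstructed from marginal statistics and an LD
reference: $X'X_{jk} = n\sqrt{d_j d_k}\, r_{jk}$ with $d_j = 2p_j(1-p_j)$ and
$X'y_j = n d_j \beta_j$. The conditional effect of SNP $j$ given the selected
set $S$ is the joint-model least-squares coefficient

$$\beta_{j|S} = \frac{X_j'y - X_j'X_S (X_S'X_S)^{-1} X_S'y}
                     {X_j'X_j - X_j'X_S (X_S'X_S)^{-1} X_S'X_j},$$

i.e. the residualised numerator over the Schur complement. The simpler
convention that divides by $X_j'X_j$ alone was evaluated and rejected: under
AR(1) rho = 0.8 LD it deviates from exact multivariable least squares by up
to ~0.1 at SNPs in high LD with the condition set, whereas the Schur form
reproduces OLS exactly when the cross-products are exact. When the LD
reference also supplies per-SNP genotype variances (`varG`), they replace the
Hardy-Weinberg $2p(1-p)$ and the reconstruction is numerically exact; with
frequencies alone the agreement is within ~0.03 at n = 2000. The phenotypic
variance entering conditional SEs is estimated per SNP from
$d_j(\hat\sigma_j^2 (n-2) + \beta_j^2)$ and pooled by the median. Condition
sets with internal r² > 0.99 raise a collinearity error naming the pair;
conditioned SNPs are reported with zero effect.

# Numerical choices

- Colocalisation is evaluated entirely in log space (`logsumexp`, and a
  guarded `log(exp(a) - exp(b))` for the H3 term, which is exactly zero for
  single-SNP regions).
- 95% CIs use the normal quantile 1.959964 throughout; P values are two-sided
  normal tails. Simulated P values are floored at 1e-320 to stay inside the
  (0, 1] contract.
- Clumping ties on P are broken by position then SNP id; sign-majority voting
  in the Z-discordance detector makes no call on exact ties (logged warning).
- Harmonisation drops palindromic SNPs when both EAFs lie within 0.08 of 0.5
  (window configurable), aligns the rest by frequency, and records every drop
  with a reason. Rounded published tables make exact beta/SE/P consistency
  impossible, so the reader warns rather than fails when P disagrees with
  |beta/se| by more than a factor of 2.
- Monomorphic draws (possible only under the threshold genotype model at
  small n) trigger logged regeneration, at most 100 times.

# Tissue analyses

Cochran's Q with fixed-effect weights measures heterogeneity of per-tissue
estimates; its chi-square calibration is verified on per-tissue *exposure*
effect estimates at a shared causal SNP, which are independent across
tissues. Note that Q computed across per-tissue Wald ratios that share one
outcome GWAS (as the pipeline reports, following standard practice) is not
exactly chi-square under homogeneity because the outcome noise is common to
all tissues; the reported Q remains a useful descriptive ranking, and the
calibration test isolates the statistic itself.

The tau tissue-specificity index is
$\tau = \sum_i (1 - x_i/\max_j x_j) / (n-1)$: 0 for uniform expression, 1 for
single-tissue expression, scale-invariant, with the conventional specificity
cutoff 0.8. Whether per-tissue expression summaries are means or medians is
the caller's choice; the pipeline consumes whatever the expression table
contains.

The brain-versus-blood comparison correlates log-OR MR estimates for genes
present in both classes across the P-value ladder 0.1, 0.05, 0.01, 0.005
(one published figure caption lists 0.001 in place of 0.01; the ladder above
follows the accompanying text, and the thresholds are an argument). A gene
enters at threshold t when *either* side's MR P is below t (an AND rule is
available via `rule = "both"`); fewer than three shared genes flags the row
as not estimable rather than reporting a meaningless correlation.

# Pipeline and problem sizes

`runPipeline()` executes discovery MR -> suggestive-threshold gate ->
conditional + coloc + Steiger -> evidence classification -> tissue follow-up
-> brain/blood correlation, writing one TSV per stage plus a run log, failing
soft per unit (a failing gene x tissue x subtype is logged and skipped) and
reading cached stage TSVs so that a single stage can be re-run reproducibly.

The bundled truth-recovery benchmark (`simulateBenchmark()`) uses 20 genes
(8 shared-variant, 4 distinct-variant with the two causal SNPs in separate LD
blocks, 4 exposure-only, 4 null), each on its own 60-SNP AR(1) rho = 0.8
region at the calibration sample sizes. Calibration suites use 200 replicates
(500 for the null-uniformity KS test), with 100-SNP regions for
colocalisation and 10-20-SNP regions where only single-SNP statistics are
consumed; these sizes give Monte-Carlo standard errors comfortably inside
the tested bands while keeping a full run of the test suite and acceptance
script in the low minutes on a single core.

# Known limitations

- Steiger's outcome-side variance explained is computed on the observed
  scale with the effective sample size; a liability-scale conversion is a
  possible refinement.
- Only Wald-ratio and fixed-effect IVW estimators are provided; MR-Egger,
  weighted-median and modal estimators need more instrument SNPs than
  cis-eQTL instruments typically offer.
- Colocalisation priors are fixed, not learned; SuSiE-style multi-signal
  colocalisation is out of scope (the conditional step addresses
  multi-signal regions instead).
- The harmonisation policy (palindrome window, frequency alignment) is a
  package decision; published pipelines rarely document theirs, and results
  can be sensitive to it for palindromic instruments.
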