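# mrcoloc

Prioritising genes whose genetically predicted expression affects disease
risk, from summary statistics alone.

`mrcoloc` is for statistical geneticists and molecular epidemiologists who
have cis-eQTL summary statistics (one or more tissues), a case-control GWAS
(optionally stratified into subtypes), and an LD reference, and want a
transcriptome-wide answer to: *which genes show robust causal evidence for
this disease, in which tissue, and in which direction?* The motivating
application is glioma risk with brain- and blood-derived eQTL panels and
per-tissue follow-up across up to 13 brain tissues, but nothing in the
package is disease-specific.

## The method

For each gene × tissue × subtype unit the pipeline combines:

- **Two-sample MR** — cis instruments (closed 1 Mbp TSS window, greedy LD
  clumping at r² < 0.01, P < 5×10⁻⁸ for discovery or the lenient 5×10⁻⁴ for
  per-tissue follow-up); Wald ratio β̂ = β̂_GY/β̂_GX with SE = s_Y/|β̂_GX|
  for single-SNP instruments, fixed-effect IVW otherwise; Bonferroni
  (0.05/nGenes) and suggestive (×nTissues) thresholds.
- **Bayesian colocalisation** — Wakefield approximate Bayes factors
  log ABF = ½[log(1−r) + r·z²] with r = W/(V+W) over a ±500 kbp region,
  combined into posteriors for H0–H4; H4 ≥ 0.80 is strong evidence of a
  shared causal variant.
- **Conditional analysis** — stepwise summary-statistic model selection
  against the LD reference; regions with more than one signal are
  conditioned on the secondary signals (joint-model least squares from
  reconstructed cross-products) before colocalisation, restoring the
  single-causal-variant assumption.
- **Steiger directionality filtering** — compares variance explained
  r² = z²/(z² + n − 2) in exposure vs outcome (effective n for case-control)
  by an independent-samples Fisher-z test; `true` / `false` / `uncertain`.
- **Cross-tissue analyses** — Cochran's Q heterogeneity, per-SNP Z-score
  sign discordance, the tau tissue-specificity index (cutoff 0.8), and the
  brain-vs-blood Pearson correlation of MR estimates across a P-value
  threshold ladder (0.1, 0.05, 0.01, 0.005).

A unit is **robust** when it passes the suggestive MR threshold, has strong
colocalisation, and Steiger category `true`.

A fully seeded synthetic-data module (`simulateStudyPair`,
`simulateMultitissuePanel`, `simulateBenchmark`) generates exposure/outcome
summary statistics with known causal truth under five scenarios mirroring
the coloc hypotheses, so the whole stack is testable without any external
data. See the methods vignette (`vignettes/mrcoloc-methods.Rmd`) for the
models, assumptions and numerical choices.

## Worked example

Simulate one gene with a shared causal variant (the exposure-on-outcome
effect is θ = 0.4 log-odds per SD expression), then run every evidence layer:

```r
library(mrcoloc)

ld   <- simulateLDMatrix(60, 0.8, 20)              # AR(1) blocks, rho = 0.8
scen <- simScenario("shared_variant", causalSnpExposure = 30L)
sim  <- simulateStudyPair(scen, ld, seed = 42)

gene  <- geneAnnotation("GENE1", "1", tss = 1e6 + 29 * 1000)
instr <- selectInstruments(sim$exposure, gene, ld, "discovery", tissue = "brain")
instr
#> Instrument for GENE1 [brain]: 1 SNP(s) (p < 5e-08, r2 < 0.01)

mr <- mrForInstrument(instr, sim$outcome, subtype = "all_glioma")
mr
#> MRResult GENE1 [brain, all_glioma] wald_ratio: OR 1.721 (1.534, 1.930), P = 2.01e-20, nSNP = 1

lead <- snpIds(instr)[1]
cl <- colocABF(extractRegion(sim$exposure, lead), extractRegion(sim$outcome, lead))
cl
#> ColocResult (60 SNPs): H0 0.000 H1 0.000 H2 0.000 H3 0.000 H4 1.000 [strong]

st <- steigerForInstrument(instr, sim$outcome)
st
#> SteigerResult: r2(exposure) 0.1181 vs r2(outcome) 0.008507, z 15.338, P 4.29e-53 -> true

classifyEvidence(mr, cl, st, multipleTestingThresholds(6849, 13))
#>    GENE   SNPS TISSUE    SUBTYPE       OR   CI_LOW  CI_HIGH            P H4
#> 1 GENE1 rs0030  brain all_glioma 1.720735 1.534028 1.930166 2.007641e-20  1
#>   COLOC_TIER    STEIGER_P STEIGER_CATEGORY ROBUST
#> 1     strong 4.292302e-53             true   TRUE
```

The instrumented eQTL (OR 1.72 per SD expression, P ≈ 2×10⁻²⁰) colocalises
with the outcome signal (H4 ≈ 1.0, strong tier), the instrument explains far
more variance in expression (11.8%) than in disease (0.85%, Steiger `true`),
and the unit is classified robust — as it should be, since the data were
generated with a genuinely shared causal variant.

For a full run, `simulateBenchmark()` writes a 20-gene input set with a
truth sidecar and a ready configuration for `runPipeline()`, which writes
per-stage TSVs (`instruments`, `mr`, `coloc`, `steiger`, `evidence`,
`heterogeneity`, `tau`, `correlation`) plus a run log. A thin CLI wrapper
with subcommands `simulate` / `discovery` / `coloc` / `steiger` / `tissues` /
`correlate` / `all` lives at `inst/scripts/mrcoloc.R`.

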