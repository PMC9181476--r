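---
title: "Methods: models, estimators and design choices in tapestrip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in tapestrip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tapestrip` analyses shallow 3'-tag count data from tape-stripped skin.
This vignette is the package's own account of the statistics it implements:
the generative model behind the simulator, each estimator with its
assumptions and defaults, the numerical choices, and the places where the
design was genuinely open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Why this pipeline exists

Tape strips capture the outermost epidermis with RNA yields that vary by
orders of magnitude between people and sites, and with frequent RNA
degradation. Two consequences dominate every downstream analysis:

1. **Depth spread.** Library sizes span roughly `361` to `7.9e6` total
   counts. Any statistic that is not depth-aware is really measuring depth.
2. **Zero inflation.** Beyond the binomial sampling zeros a shallow library
   must have, degraded samples lose transcripts at *every* expression
   level. Count-likelihood models see these zeros as wildly improbable
   observations.

The package therefore couples a four-criterion sample QC and a detection
filter with normalization variants and differential-expression (DE)
engines that differ exactly in how they absorb depth and dropout — and a
benchmark harness that measures what each combination gets right against a
known gold standard.

## The simulator

`simulate_experiment()` generates a paired study: `n_subjects_AD = 30` AD
subjects, each with one lesional (LS) and one non-lesional (NL) tape
sample, `n_subjects_HC = 30` healthy controls with one sample each, and a
deep biopsy arm with `biopsy_replicates = 2` replicates per subject *and
site* (LS and NL sites for AD subjects, one site for HC).

Per gene `g`, sample `j` of subject `s`:

* baseline relative means are log-normal (`meanlog = log 5`,
  `sdlog = 1.2`); panel genes are elevated (EDC ×200, mitochondrial ×20,
  layer markers ×15–30, KRTAP ×5 with extra per-gene spread);
* a fraction `frac_DEG = 0.1` of non-panel genes carries a planted LS
  effect `2^{±β}` with `|β| ~ U(1, 3)` and 80% up; 30% of these DEGs are
  drawn from the top baseline decile (`deg_high_frac`), and six EDC genes
  (FLG2, LORICRIN, S100A7, S100A8, SPRR2E, SPRR1B) are planted upregulated
  (`edc_ad_effect`) — the disease signal of lesional epidermis sits on
  dominant barrier genes, so it moves library composition, which is what
  separates composition-robust from composition-naive normalizations;
* gene-by-subject biological effects `exp(N(0, 0.5))`
  (`bio_gene_subject_sd`), shared between a subject's tape and biopsy
  samples, provide the inter-individual variation that cross-platform
  per-gene correlations detect; layer marker panels use a larger spread
  (`layer_bio_sd = 1.5`) because differentiation genes vary strongly
  between individuals;
* tape depth: a per-*subject* base depth, log-uniform over
  `tape_libsize_range = [361, 7.9e6]` (RNA yield follows the person and
  site, which is what makes a subject random intercept meaningful), times
  tissue-state multipliers `HC/NL/LS = 1/1.5/2.5`, a per-quarter seasonal
  offset (`sd 0.1`), and per-sample jitter (`sd 0.25` on the natural log);
* counts are `NB(mean = rel · depth, dispersion φ_g)` with
  `φ_g ~ lognormal(log 0.4, 0.5)`;
* tape observations are then zeroed with probability
  `plogis(zi_intercept + u_j − zi_slope · log μ)` with `zi_intercept = 1.5`,
  `zi_slope = 1`, and per-sample degradation offsets `u_j ~ N(0, 1.5)`
  (`zi_sample_sd`) — degraded samples lose even abundant transcripts.
  Layer panels shift the intercept (corneum −4 … basale +4), the depth
  gradient a surface-sampling method induces. The biopsy arm has no
  dropout.

The planted truth is the gold standard (`truth_gold_standard()`); planted
effects act on LS only, so the NL-vs-HC contrast is empty by construction.

**What the simulator does not emulate:** amplification jackpots and other
heavy-tailed count artefacts of low-input library chemistry, batch
effects, gene–gene correlation beyond the shared subject effects, and a
realistic 20 000-gene universe (the default is 3 000). Passing tests
therefore show that the estimators behave as designed under an NB +
logistic-dropout world — not that any particular real dataset satisfies
that model. The zero-inflation and biological-variation defaults are
stated configuration, not measurements of real tape data, which the
underlying study does not quantify.

## Sample QC and detection

`score_sample_qc()` awards one point per criterion, all on raw counts and
all strict inequalities (boundary values score 0): >200 genes detected at
≥1 count; EDC sum >100; EDC fraction >5%; mitochondrial fraction <15%.
Samples with ≥3 points are kept. A zero-total sample has both fractions
defined as 0 (so the EDC-fraction point fails and the mitochondrial point
passes) and is reported. Raw counts are deliberate: QC precedes
normalization, and the EDC criteria measure absolute signal.

`detect_genes()` keeps genes with ≥2 counts ("more than 1", read
literally) in ≥80% of the QC-passing samples, then removes
non-protein-coding and mitochondrial genes. Both thresholds are arguments;
the ≥1-count alternative reading is one argument away. Detection runs
after sample filtering because the filter's denominator should be the
samples that will actually be analysed.

## Normalization

* `rle_factors()` — median over all-nonzero genes of the ratio to the
  gene's geometric mean. The `size_factor` column is that median (geometric
  mean 1); `norm_factor` divides it by library size and rescales, so a pure
  depth change gives factors of 1 and `effective_lib_size = lib_size ×
  norm_factor`. In sparse data the all-nonzero reference set collapses to a
  handful of elite genes; when those carry the disease signal the factors
  absorb it — the failure mode the benchmark exposes.
* `tmm_factors()` — reference sample by 75th-percentile proportion closest
  to the mean; gene-wise M (log2 ratio) and A (mean log2 abundance) over
  genes positive in both libraries; double trim (30% on M, 5% on A —
  published defaults, exposed); factor `2^{weighted mean M}` with inverse
  delta-method variances as weights; geometric mean 1. With
  `singleton_pairing = TRUE` (TMMwsp), genes positive in only one library
  are kept as rank-matched pseudo-pairs (largest against largest) instead
  of discarded; on zero-free data the two variants coincide by
  construction. The contract is behavioural — retain one-sided zeros via
  rank pairing — not bit-compatibility with any particular implementation.
* `log_cpm()` — `log2((count + 0.5) / (effective libsize + 1) × 1e6)`.
* `mt_ratio_normalize()` — counts divided by the sample's summed counts
  over the twelve mitochondrially encoded reference genes, treating
  mitochondrial content as an internal reference; samples with a zero
  reference sum get missing values and are flagged. In the NB-GLM the same
  idea enters as an offset, `log(MT sum)`, floored at 0.5 so a shallow
  sample without mitochondrial reads does not produce an infinite offset.

## Differential expression engines

**Designs** (`design_spec()`): contrasts are `<test>_vs_<ref>` over
HC/NL/LS. LS-vs-NL is paired — only subjects with both states are kept and
subject enters as a blocking factor; unpaired contrasts adjust for gender.
"Adjusted for" is the chosen reading of removing a nuisance factor; the
drop-it-entirely reading is `adjust = FALSE`.

**Dispersions** (`estimate_dispersion()`): per gene, the dispersion
maximising the Cox–Reid adjusted profile likelihood (the `−½ log det X'WX`
term compensates the bias a plug-in estimate suffers when subject blocking
eats half the degrees of freedom; an unadjusted estimate halves the true
dispersion under the paired design and inflates the type-I error well
above nominal). Raw estimates are shrunk toward a lowess mean–dispersion
trend with `prior_df = 10` pseudo-degrees and clipped to `[1e-6, 10]`.

**NB-GLM** (`nb_glm_test()`): per-gene log-linear NB fit at the estimated
dispersion with `log(effective libsize)` offsets, 1-df likelihood-ratio
test on the tissue-state coefficient (Wald z as the `test = "wald"`
variant), BH adjustment. All-zero genes are reported untestable, not
dropped silently. Optional observation weights (below) enter as prior
weights.

**Moderated t** (`voom_weighted_test()`): gene-wise linear models on
log-CPM; lowess of residual `sqrt(sd)` on mean log-CPM (span 0.5); each
observation's weight is the inverted fourth power of the trend at its
fitted value; empirical-Bayes variance squeezing with the prior df
estimated by method of moments on log residual variances (trigamma
inversion by Newton iteration). `quality_weights = TRUE` multiplies in a
per-sample weight — the inverse mean squared standardized residual,
geometric mean 1, two refinement passes — a deliberately simple form of
sample down-weighting.

**Non-parametric ranking** (`noiseq_rank()`): per gene, M = difference of
group-mean log-CPM and D = absolute difference of the group means on the
CPM scale; the noise distribution pools the same statistics over all
within-group sample pairs across all genes (the replicate-based flavour;
pooling across genes is stated explicitly because flavours differ); the DE
probability is the fraction of noise pairs dominated on both axes. The
pooled noise set is deterministically thinned to `n_noise_pairs = 20000`
values to bound memory and time. Ranks break ties by probability, then
|M|, then gene symbol — all orderings in the package are deterministic.
The `p = 1 − probability` column exists only for interface uniformity; the
supported cutoffs for this engine are rank-based.

**Zero-inflation weights** (`zero_inflation_weights()`): per gene, an EM
fit of an NB plus a point mass at zero, the dropout logit linear in log
effective library size (depth as the sample-level covariate). The weight
of an observation is its posterior NB-component probability — exactly 1
for nonzero counts. Genes not converging in 100 iterations keep unit
weights and are flagged. This replaces a full latent-factor zero-inflation
model with a per-observation weighting of the same intent: down-weighting
technical zeros; it shares no information across genes and makes no
attempt at latent factors.

## Benchmark and signature

`run_benchmark()` executes a grid of (normalization, engine, cutoff)
combinations on one post-QC matrix against one gold standard. The cutoff
grammar is `fc>2,p<0.05`, `fc>2,padj<0.05`, `top5%`, `top20up`, `top10up`
("FC > 2" means |log2FC| > 1; strict inequalities). Accuracy is precision:
`100 × direction-matched gold hits / called`, with up/down splits; an empty
call set has missing accuracy. A failing method is recorded and the rest
still run. Intersections of the true-positive sets are tabulated
upset-style; their counts sum to the union by construction.

The default grid has 11 methods: NB-GLM on RLE (adjusted p), TMM and
TMMwsp (raw p); the zero-inflation-weighted NB-GLM on TMM; a Wald-test
NB-GLM on RLE; the moderated-t with and without quality weights on TMM;
the mitochondrial-offset NB-GLM; and the ranking engine at its three
cutoffs.

`ensemble_signature()` aggregates the union over methods of each method's
true positives, with per-gene provenance. The union reading is the
default because an intersection across all methods is near-empty whenever
the methods disagree — which is the benchmark's central finding; the
stricter reading is `mode = "intersection"`.

## Cross-platform concordance

Biopsy replicates are always averaged (arithmetic mean per subject × site)
*before* correlating — the two orders genuinely differ and the pipeline
fixes this one. Per-sample Spearman rho (average ranks at ties) is
computed on raw counts over the detected gene list: within one sample,
depth is a constant factor and ranks remove it. The matching key is
subject × site, with a subject-only fallback for replicate maps without a
site column. Concordance is then regressed on log10 tape totals (pooled
and per state), compared between states by a two-sided rank-sum test
(`test = "t"` switches to Welch), and computed per layer-marker gene with
per-layer medians. Missing markers are reported as missing, never dropped
silently. An optional fold-change-space mode correlates per-gene LS/NL
log-ratios between platforms.

## Covariates and enrichment

`fit_total_count_lmm()` models `log10(total + 1)` — the log stabilises a
four-orders-of-magnitude response — with tissue state, quarter, gender,
hair signature and region as fixed effects and a subject random intercept,
fitted by ML; each term's p comes from a likelihood-ratio test against the
nested model without it (self-contained, no approximate denominator df).
The hair-signature covariate is the log10 KRTAP *fraction* of total
counts: the raw KRTAP sum contains the sample's depth, so using it would
regress the response on itself. Constant terms are dropped with a warning;
with no replicated subjects the model reduces to fixed effects, warned.
The model is meant for QC-passing samples.

`fisher_enrichment()` builds the 2×2 query-by-set table over the universe,
tests it two-sided with Fisher's exact test, reports the cross-product
odds ratio with 0.5 added to every cell when any cell is zero, and adjusts
across sets by BH.

## Problem sizes used by the tests

The test suite exercises the estimators at deliberately modest sizes:
unit tests use fixtures of tens of genes and 4–40 samples; calibration
checks use one 2 000-gene null study with 20 subject pairs;
benchmark-level and concordance properties use 20 replicate studies at the
default study conditions (3 000 genes, 30 + 30 subjects); the
mixed-model checks use the same. These sizes are the package's choice of
scale for routine verification; all of them are parameters of the
respective tests.

## Known limitations

* The NB + logistic-dropout generative model cannot reproduce every
  pathology of real low-input tag data (amplification jackpots, batch
  structure); conclusions about method *rankings* transfer only to the
  extent those pathologies resemble depth-linked dropout.
* The RLE engine requires at least one all-nonzero gene; on heavily
  inflated matrices it legitimately refuses to run, and the benchmark
  records that as a method failure rather than inventing factors.
* The zero-inflation weights are per-gene EM fits; with few samples the
  dropout-vs-NB-zero attribution is noisy, and flagged non-convergent
  genes silently keep unit weights downstream.
* The moderated-t quality weights use a simple two-pass moment scheme, not
  a full gamma-GLM; extreme single-sample pathologies are down-weighted
  but not removed.
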