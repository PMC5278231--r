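---
title: "Oxidative balance scores, metabolic syndrome, and gene-environment interaction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oxidative balance scores, metabolic syndrome, and gene-environment interaction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obsmets)
```

# The scientific problem

Oxidative stress arises when reactive oxygen species outrun antioxidant
defences. No single nutrient or behaviour captures a person's oxidative
balance, so epidemiologists combine several pro- and antioxidant exposures
into a single **oxidative balance score (OBS)**. `obsmets` implements a
seven-component OBS — three prooxidant exposures (total iron intake,
smoking, alcohol) and four antioxidant exposures (vitamin C, retinol,
carotene, physical activity) — and the full analysis chain that links it to
**metabolic syndrome (MetS)**: quartile logistic association models, ROC
comparison of weighting schemes, linear models for the inflammation markers
CRP and WBC, a genome-wide scan for SNP-by-OBS interaction, and a
significance-proportion-corrected gene-set enrichment of the interaction
p-values.

The cohort data this design comes from (a Korean population-based genome
cohort) are controlled-access. The package therefore ships a synthetic
study generator that reproduces the *statistical structure* the analysis
assumes, so that every stage is testable end to end, with planted ground
truth, on any machine.

# OBS construction

## Component scoring

Each continuous exposure is cut at its own empirical tertiles **within the
analysis cohort** and scored 0/1/2:

* antioxidants (vitamin C, retinol, carotene, physical activity): low
  tertile = 0, high tertile = 2;
* iron (prooxidant): low tertile = 2, high tertile = 0;
* smoking: never = 2, former = 1, current = 0;
* alcohol: heavy drinking (>= 50 g/day) = 0, otherwise 2.

Higher totals always mean antioxidant predominance. Published descriptions
of the alcohol rule disagree internally (one passage suggests a 5 g/day cut
with the opposite direction); we follow the self-consistent prooxidant
form — heavy drinkers score 0 at 50 g/day — and expose both the cut-off and
the direction as arguments of `obs_score_components()`.

Skewed exposures are log-transformed before cutting
(`obs_log_transform()`; physical activity, approximately symmetric, is
exempt). Because tertile membership is invariant under strictly monotone
transforms, the log transform cannot change any component score — the test
suite asserts this identity — but it matters when continuous exposures are
modelled directly. Columns containing zeros (alcohol in practice) use
`log(x + offset)` with a default offset of 1; strictly positive columns use
the plain log so that a column of ones maps to zeros exactly.

## Weighting schemes

* **Equal weight** (`obs_equal()`): the unweighted sum, range 0–14.
* **Beta coefficient** (`obs_beta()`): one multivariable logistic model of
  MetS on all seven component scores plus age, sex, area, BMI; the weight
  of component *j* is −1 times its fitted coefficient, so protective
  components weigh positively. We deliberately fit one joint model rather
  than seven marginal ones, and we weight the 0/1/2 component *scores*
  (the representation shared by all three schemes), not raw intakes.
* **PCA** (`obs_pca()`): component scores are standardized; principal
  components with eigenvalue > 1 are retained (a reproducible stand-in for
  scree-plot judgement); the score is the loading-weighted sum along the
  first retained component, sign-oriented so the mean loading of the four
  antioxidant components is positive.

Quartiles (`obs_quartiles()`) use type-7 (linear interpolation) empirical
quantiles with lower-inclusive bins: `(-Inf, q25]`, `(q25, q50]`,
`(q50, q75]`, `(q75, Inf)`. Q1 — prooxidant predominance — is the reference
everywhere downstream. On the integer-valued equal-weight score, boundary
ties make quartile sizes unequal (the motivating cohort showed the same
pattern); coincident cut-points raise an explicit error rather than
silently merging groups. These conventions are stated because quartile
membership feeds every downstream model.

# MetS classification

`classify_mets()` applies the NCEP-ATP III definition with Korean waist
cut-offs: waist >= 90 cm (men) / >= 85 cm (women); triglycerides
>= 150 mg/dL; HDL < 40 / < 50 mg/dL; blood pressure >= 130/85 mmHg **or**
antihypertensive medication; fasting glucose >= 100 mg/dL **or**
antidiabetic medication; MetS = at least 3 of 5. All thresholds are
inclusive on the adverse side exactly as printed and are overridable via
`mets_criteria()`. Participants missing any required trait are flagged for
exclusion (complete-case policy). Lipid-lowering medication does not enter
the TG/HDL components — the source definition does not apply it.
`classify_diabetes()` uses fasting glucose >= 126, 2-h OGTT >= 200,
HbA1c >= 6.5, or antidiabetic treatment, for the diabetes-excluded
sensitivity analysis.

# Association and inflammation models

`fit_quartile_logistic()` fits one logistic model with quartile indicators
(Q1 reference) plus age, sex, area, BMI and reports odds ratios with Wald
95% confidence intervals — Wald rather than profile-likelihood because that
is the standard of epidemiological reporting and nothing in the design
requires more. `trend_test()` re-enters the quartile as a single ordinal
1–4 score (affinely invariant). `compute_auc()` is the rank
(Mann–Whitney) concordance statistic with mid-ranks for ties; the AUC is
computed on the full fitted model, covariates included, which is why AUCs
barely move across weighting schemes — the covariates dominate.
`fit_marker_linear()` models log(CRP) (CRP is right-skewed) and raw WBC on
quartile indicators plus the same covariates.

# The interaction scan

For each SNP, `fit_gxe()` fits

```
logit P(MetS) = b0 + b_age Age + b_sex Sex + b_area Area
              + b_obs OBS + b_bmi BMI + b_g G + b_gobs (G x OBS)
```

with G the additive minor-allele dosage and OBS entered continuously —
by convention the beta-coefficient-weighted score, standardized to unit
variance so that `b_gobs` is per (allele x SD of OBS). The 1-df test of
`b_gobs = 0` is Wald by default (what array-scale scans use); a
likelihood-ratio mode is available and agrees asymptotically.
`scan_gxe()` iterates in deterministic column order, drops missing
genotypes per SNP (complete case), skips monomorphic SNPs with a log
entry, is chunk-invariant, and attaches Benjamini–Hochberg q-values
(`bh_qvalue()`, the step-up adjustment) over the converged tests.
Conventional QC defaults (`snp_qc()`): call rate >= 0.95, MAF >= 0.01,
Hardy–Weinberg exact p >= 1e-6 (exact test conditioning on allele counts).
Allele flips negate `b_g` and `b_gobs` but leave the p-value unchanged;
separation or non-convergence yields a flagged row with an absent p-value
rather than a silent drop.

# Pathway enrichment of interaction p-values

The enrichment stage reconstructs an improved-GSEA ("i-GSEA")-style
procedure; the citing literature names the method but not its internals,
so every ingredient is explicit and configurable:

1. **Mapping** (`snp_gene_map()`): a SNP maps to every gene whose body
   extended by 100 kb contains its position, boundary inclusive ("within
   100 kb" read inclusively; a SNP exactly 100,000 bp beyond a gene end
   maps, 100,001 does not). BED input is 0-based half-open and converted
   once at the reader.
2. **Gene statistic** (`gene_stats()`): max −log10(p) over the gene's
   mapped, tested SNPs; genes without a tested SNP are dropped and do not
   count as "selected". Ties in the ranking break lexicographically by
   gene id — determinism over statistical nicety.
3. **Size filter** (`filter_pathways()`): pathways with fewer than 20 or
   more than 200 genes are excluded. The filter is applied to *selected*
   (mapped) genes, since unmapped genes cannot contribute to the running
   sum; filtering on the full definition size is available via
   `count_on = "all"`.
4. **Enrichment score** (`gsea_es()`): weighted Kolmogorov–Smirnov running
   sum — increments `|stat|^exponent` (exponent 1 by default) normalized
   within the set, decrements `1/(N − N_set)`; ES is the signed maximum
   deviation.
5. **Significance proportion** (`sig_proportion()`): a gene is significant
   if one of its SNPs falls in the smallest 5% of all tested SNP p-values
   (a rank cut, hence permutation-invariant); `k` is the in-set
   significant proportion over the background proportion, and the
   corrected score is `ES* = k·ES`. The report's `a/b/c` column is
   significant/selected/all genes.
6. **Inference** (`run_igsea()`): SNP-label permutation — observed
   p-values are reassigned to SNP positions B times (B >= 100; default
   1000) and gene statistics, ES, k, ES* recomputed. Nominal
   `p = (1 + #{permuted ES* >= observed}) / (B + 1)`. Each ES* is
   normalized by the mean of its pathway's positive permuted values
   (NES), and the FDR at threshold t is the permuted fraction of NES >= t
   over the observed fraction, clipped to [0, 1].

One numerical subtlety: the raw threshold-ratio FDR is not monotone in
NES at small B — a pathway with the highest normalized score can receive a
*larger* ratio than a weaker one, purely through Monte-Carlo noise in the
numerator. We therefore report the proper q-value: the minimum estimated
FDR over all thresholds that would reject the pathway (a running minimum
down the NES ordering, exactly analogous to the step-up enforcement inside
Benjamini–Hochberg). BH over the nominal permutation p-values is also
reported (`q_bh`) since published "FDR < 0.05" statements of this design
do not say which construction they used.

# The synthetic study generator

`simulate_study()` draws, from one seed, a cohort, gene/pathway
annotation, genotypes, ground truth, and outcomes.

**Cohort** (`simulate_cohort()`): age uniform 40–75 (the design's
population is adults over 40); log-normal nutrient intakes with medians
and spreads chosen to match published cohort summaries (vitamin C ~90
mg/day, retinol ~55 ug/day, carotene ~2300 ug/day, iron ~9 mg/day);
62/19/19% never/former/current smokers; half non-drinkers with a
conditional log-normal intake putting ~5% of the cohort at or above the
50 g/day heavy-drinking cut; physical activity normal (82 +/- 21 MET/day)
truncated at zero; medication flags at 8%/5%/1%.

**Annotation and genotypes**: non-overlapping gene bodies of 10–30 kb on
two chromosomes with inter-gene gaps wide enough that "inside", "near"
(<= 100 kb) and "far" SNP placements are unambiguous; dosages are
Binomial(2, maf) with maf uniform in the configured range — independent
SNPs by default, since the scan treats SNPs marginally (no LD emulation).
Pathways are uniform random gene sets; causal pathways receive their
causal SNPs from inside their genes, so the mapping invariant holds by
construction.

**Outcomes** come in two modes, and the distinction is a deliberate design
choice:

* **Liability mode** (default, `simulate_outcomes()`): each of the five
  MetS components has a latent liability — covariate effects +
  `obs_main_beta` x standardized antioxidant index + planted SNP main and
  interaction effects + Gaussian noise — thresholded at the empirical
  quantile that yields the configured prevalence (for blood pressure and
  glucose the medicated are counted positive and the threshold for the
  rest is adjusted so total prevalence is preserved). Continuous traits
  are emitted linearly around each clinical cut-off with a small guard
  band, so `classify_mets()` reproduces the intended binary states
  *exactly* — making phenotype classification testable against truth.
  The "true antioxidant index" that all effects are planted on is the
  standardized equal-weight OBS: the simplest scheme, keeping the truth
  independent of any fitted weighting.
* **Logistic mode** (`simulate_gxe_status()`): case status drawn directly
  from the scan's own logistic model. Thresholded liabilities are a
  probit-like, non-logit-linear mechanism, so a logistic estimator cannot
  be unbiased for a liability-scale coefficient; estimator calibration
  and power studies need the generative model and the fitted model to
  coincide. All bias/coverage/power results below use this mode;
  liability mode remains the full-cohort emulation.

Default effect sizes were fixed once: `obs_main_beta = -0.1` per SD of the
index on each component liability, which yields a synthetic Q4-vs-Q1 MetS
odds ratio in the 0.5–0.7 range that cohort studies of this design report;
component prevalences (34/31/57/22/19%) and marker slopes (CRP −0.15 on
the log scale, WBC −0.35 per SD) likewise mirror published cohort
summaries.

What the generator does **not** emulate: linkage disequilibrium,
population structure and relatedness, genotyping error and missingness
patterns, FFQ measurement error, and correlated nutrient intakes. Passing
tests therefore demonstrate correctness of the estimators and pipeline
under clean assumptions, not robustness to those real-data features.

# Verification strategy and problem sizes

The test suite pairs every nontrivial computation with an independent
oracle: BH q-values against a hand step-up loop (exhaustively over all
subsets of 8 p-values), the enrichment score against pencil-and-paper
running sums and a brute-force loop, SNP-gene mapping against an all-pairs
interval check, crude odds ratios against the closed-form cross-product,
the AUC against the O(n^2) concordant-pair count and against pROC, the
Hardy–Weinberg exact test against direct enumeration, and the PLINK reader
against an independently written binary fixture.

Statistical checks run at sizes chosen to keep the whole suite within a
few minutes on one core while leaving Monte-Carlo error well inside the
asserted bounds: type-I calibration at 2,000 null SNPs and n = 1,000
(rate within 3 binomial SEs of 0.05, Kolmogorov–Smirnov uniformity);
coefficient recovery at a planted interaction of 0.4 (MAF 0.3, n = 2,000)
over 600 replicates — 200 replicates leave the binomial error of the
coverage estimate wider than the margin of the asserted [0.92, 0.97]
band, so we use 600 — giving bias ~0.003 and coverage ~0.955; enrichment
power with one causal pathway (10 SNPs at interaction 0.5, n = 2,000, 50
pathways, B = 200) over 25 replicates, where the planted pathway attains
the smallest FDR in 92% (the exceptions are pathways that share causal
host genes through random set overlap); and fully null enrichment runs
averaging under 5% of pathways at FDR < 0.05.

# Known limitations

* The enrichment internals are a reconstruction: the named method's
  publication chain does not pin down the gene statistic, the
  significance cut, or the permutation unit. Every choice is exposed in
  `igsea_config()` so alternatives are one argument away.
* Permutation FDR at B = 200 is coarse (granularity 1/201 on nominal p);
  for reporting-quality runs use B = 1000 or more.
* The beta-weighting scheme fits its logistic model on the same cohort it
  scores, so downstream association p-values for that scheme are
  optimistic; the equal-weight scheme is immune.
* X-chromosome dosage conventions, imputed dosages, and mixed-model
  relatedness corrections are out of scope.
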