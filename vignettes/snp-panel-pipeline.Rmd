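---
title: "Methods: case-control SNP-panel analysis with snppanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control SNP-panel analysis with snppanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snppanel)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and their defaults,
what the synthetic cohort generator does and does not emulate, the numerical
choices, and the design decisions taken where the methodology was genuinely
open.

## The staged design

The pipeline mirrors the staged structure of candidate-SNP replication
studies. A panel of previously reported risk alleles is genotyped in an
initial case-control sample and filtered by call-rate QC (stage 1); markers
with uncorrected p ≤ 0.05 are followed up in an enlarged sample and probed
for genotype-phenotype interactions and combined predictive value (stage 2);
finally the full cohort's questionnaire data are analysed epidemiologically
(stage 3). `run_pipeline()` wires the stages `simulate → qc → assoc →
qvalue → grs → roc → power → epi` over plain TSV/JSON stage outputs so every
reported number is traceable to a file. There is no shell entry point: the
exported functions, this vignette and `scripts/acceptance.R` are the
interface, which suits a library used from R.

## Quality control

Samples and SNPs are retained when their call rate *exceeds* the threshold
(default 0.9 for both margins). The comparison is deliberately strict — a
margin at exactly 0.9 is excluded — matching the usual "call rate > 0.9"
inclusion phrasing. Samples are filtered before SNPs; a SNP whose only
minor-allele carriers sat in excluded samples is therefore caught by the
subsequent monomorphism rule (MAF = 0 among retained samples). The
alternative order would change MAF = 0 detection; the choice is fixed and
tested rather than configurable. GenTrain array-clustering scores are a
pass-through annotation with an optional threshold (default 0.5); the score
itself is proprietary and never computed. Each excluded id carries exactly
one primary reason, assigned in the order call rate, GenTrain, monomorphic.

## Allelic association

The primary per-SNP estimate is the cross-product odds ratio of the 2×2
allele-count table, with the Woolf log-scale interval; a per-allele dosage
logistic estimate (IRLS via `stats::glm.fit`, tolerance 1e-10, 50
iterations) is reported alongside, because both estimators are in routine
use and they differ slightly in finite samples. Frequencies are reported for
the *risk* allele, with a flag recording whether it is also the minor allele
in controls. Significance is the two-sided Fisher exact p under the
point-probability convention — the sum of hypergeometric probabilities of
all tables (margins fixed) no more probable than the observed one, with a
relative tolerance of 1e-7 on the comparison to absorb floating-point
noise; a zero-margin table is uninformative and returns p = 1. Zero cells in
the odds ratio trigger the Haldane–Anscombe +0.5 correction, flagged in the
result. Wald (not profile-likelihood) intervals are used throughout the
logistic and multinomial fits, matching the conventions of the era of
software this pipeline replicates; complete or quasi-complete separation is
detected as a diverging coefficient (|β| > 15 on the logit scale) and
reported as non-convergence rather than silently returned.

## Multiple testing

Two q-value methods are provided because the staged design uses both: the
large stage-1 family (≈38 tests) uses Storey–Tibshirani smoothed q-values,
while small follow-up families use Benjamini–Hochberg. The π₀ smoother
follows the published recipe: π₀(λ) = #{p > λ}/(m(1−λ)) on the grid λ = 0,
0.01, …, 0.95, a cubic smoothing spline with 3 equivalent degrees of freedom,
evaluated at λ = 0.95 and clipped to [1/m, 1] (the lower guard prevents zero
q-values; the grid and df are arguments). Storey q-values are exactly π₀
times the BH step-up quantity, an identity the tests assert. Below 20 tests
the right tail of the p-value histogram is too sparse to smooth and the
method falls back to π₀ = 1 with a warning.

## Genetic risk scores

Three models over a SNP subset: the allele count (model 1), the
ln(OR)-weighted dosage sum (model 2), and the relative population risk
(model 3), Πᵢ ORᵢ^gᵢ / mᵢ with mᵢ = Σ_g HWE(g)·ORᵢ^g. Design choices:

* *Population frequencies in model 3* are Hardy–Weinberg at the control
  risk-allele frequency — "population" means the study's own control
  series. Observed control genotype frequencies would be an alternative; the
  HWE form is the standard reading and makes the expected control score
  exactly 1 per SNP (asserted in tests).
* *Multi-SNP combination* in model 3 is multiplicative across SNPs,
  consistent with simulating and testing SNPs independently (no LD).
* *Weights are estimated in-cohort* (per-SNP allelic ORs and control
  frequencies from the same samples being scored). This circularity is
  deliberate and recorded in the score object's provenance: the scores
  describe the cohort's internal risk gradient and their AUCs are
  optimistic relative to external validation. Externally supplied weights
  are accepted via the `weights` argument.
* *Missing genotypes*: scores are computed over the non-missing SNPs with no
  rescaling, and the number of contributing SNPs is recorded; mean-dosage
  imputation is available as a sensitivity mode (`impute = "mean"`). With
  complete data ln(model 3) = model 2 − a per-subset constant, so the two
  share a ROC curve exactly; under missingness the per-sample constants
  differ and the identity (and AUC equality) holds only approximately.

Subsets follow the staged logic via `grs_subsets()`: the full post-QC panel,
the SNPs at p ≤ 0.05, and the smallest-p three — nested by construction.

## ROC, AUC and biomarker combination

The AUC is the Mann–Whitney pair statistic with ties counted ½ — ties are
common because the count score is integer-valued. Variances and the paired
test for AUC differences use DeLong's structural components (placements),
with a two-sided normal p. The biomarker combination fits a logistic model
of status on ln(PSA + 1) and the GRS and scores by the linear predictor; the
log transform reflects PSA spanning orders of magnitude (values ≥ 100 μg/L
occur in aggressive-disease cohorts) and raw PSA is available by argument.
A constant component is dropped with a message, so an uninformative GRS
reduces the combination exactly to PSA alone. Note that a *jointly fitted*
in-sample combination cannot undercut its best component; reports of a
combined AUC below the biomarker alone imply some other combination rule,
which is why combined-AUC values are treated as data-dependent rather than
reproducible targets.

## Power and sample size

The two-proportion normal approximation with pooled-null and
unpooled-alternative standard errors, optional continuity correction (which
can only increase the required n), and the odds-ratio-to-proportion map
p₁ = OR·p₀/(1 + p₀(OR−1)). The default parameterisation is subject-level
exposure (probability of exposure in controls); an allele-level mode treats
each subject as two observations at a given allele frequency. The two
parameterisations answer different questions and can differ several-fold in
required n — at OR 1.4 the exposure-0.1 subject-level reading requires
1,356 cases per arm for 80% power, while an allele-level reading at MAF 0.2
requires far fewer — so both are exposed rather than guessing which a given
report used. Sample size is the smallest integer n whose computed power
meets the target (closed-form seed plus integer search), so power and
sample size are exact inverses by construction.

## Epidemiological models

Crude tests: Yates-corrected chi-square for dichotomous variables (the
correction capped so a deviation below 0.5 contributes zero), plain Pearson
chi-square for wider tables, Welch t for continuous variables. Adjusted
models: logistic regression of status on the variable plus confounders
(default: age, family history of prostate cancer, population group), with
complete-case analysis per variable and the n used recorded per row — no
imputation. For categorical variables with more than two levels the
reference is the level whose within-group shares are most nearly equal
between cases and controls (ties broken lexicographically, logged); binary
yes/no variables use "no"; PSA is analysed as ordered bins at 4, 10, 20 and
100 μg/L against "<4". Case-only outcomes band Gleason scores into <7, =7,
>7 (reference <7) and grade into well/moderate/poor (reference well), fitted
by multinomial logit (`nnet::multinom`, tightened tolerances), which the
tests verify collapses to binary logistic regression when only two
categories survive.

## The synthetic cohort generator

The generator exists so that every stage has inputs and known truth without
restricted participant data. It emulates:

* a cohort of 522 cases and 315 controls (the pilot cohort's composition;
  any sizes can be configured),
* 46 panel SNPs with control risk-allele frequencies in 0.05–0.45; the six
  followed-up markers keep their observed control frequencies and stage-1
  odds ratios (e.g. 0.372/1.54) as generative truth, the rest are null,
* Hardy–Weinberg control genotypes and exponentially tilted case genotypes
  P(g) ∝ HWE(g)·OR^g — the distribution implied by a per-allele logistic
  model, making the allelic OR recoverable in expectation and parameter
  recovery exact asymptotically,
* log-normal PSA per status; the location/scale defaults (meanlog log 5 /
  log 40, sdlog 1.0 / 1.2) are *chosen*, not estimated, to land in the
  regime where PSA alone discriminates with AUC ≈ 0.9, and are documented as
  synthetic,
* binary and categorical questionnaire covariates with control prevalences
  and conditional odds ratios mirroring the adjusted associations the
  pipeline estimates (family history of cancer 2.60, diabetes 1.83, sexual
  activity 0.48, ED 1.53, aspirin 1.68, frontal+vertex balding 1.60),
  aggressive-biased Gleason/grade distributions for cases, and 2% uniform
  genotype missingness.

It deliberately does **not** emulate linkage disequilibrium between SNPs,
population structure or admixture, age-dependent incidence,
informative/structured missingness, or any correlation between PSA and
genotype beyond what case status induces. Passing tests therefore
demonstrate correctness of the estimators under the model's own assumptions
(independent SNPs, multiplicative per-allele risk, MCAR missingness) — not
robustness to the violations real cohorts exhibit. Determinism: a
`simulation_spec()` seed fixes the whole cohort byte-for-byte; stage
functions derive sub-seeds by fixed offsets.

## Numerical choices and degenerate inputs

IRLS convergence at epsilon 1e-10 with 50 iterations and separation flagged
at |β| > 15; rank-deficient designs are an error naming the collinear
columns; multinomial fits run with reltol 1e-14. Fisher's test returns p = 1
on zero-margin tables; odds ratios error on zero margins and apply +0.5 on
single zero cells. Allele counts reconstructed from printed frequencies use
round-half-away-from-zero, the convention that inverts fixed-decimal
printing. Model 3 accumulates on the log scale to avoid overflow across
many SNPs. Call-rate fixtures blank the minimal number of leading cells
needed to force a margin strictly below target, keeping fixtures
deterministic.

## Problem sizes used by the tests and acceptance script

Statistical assertions run at sizes chosen to make their Monte-Carlo error
small relative to the tolerance being asserted: null calibration uses 400
replicates of 38 null SNPs at 179/144 samples (binomial SE of the rejection
rate ≈ 0.2%); interval coverage uses 500 replicates of one SNP at the same
sizes (SE ≈ 1%); covariate recovery uses one cohort of 10,000; the Fisher
implementation is swept against full enumeration over all ~243,000 tables
with row margins up to 30; the AUC implementation against a pairwise oracle
over an exhaustive family of small integer-score datasets; the DeLong
standard error against a 10,000-replicate paired bootstrap on a fixed
100-sample dataset.

## Known limitations

Single-SNP tests only (no haplotypes, no trend tests beyond the per-allele
model, no exact logistic regression); Wald intervals can misbehave near
separation; Storey's smoother is unstable below a few dozen tests (hence the
fallback); the minimal VCF dialect reads biallelic GT-only records and
ignores phasing; in-cohort GRS weights overstate external predictive
performance by construction; and the power module's normal approximation is
anti-conservative for very rare exposures, where an exact method should be
preferred.
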