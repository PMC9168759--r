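---
title: "Methods: quantifying sex differences in the tumor microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sex differences in the tumor microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sextme)
```

# The analysis in one paragraph

Given a cohort with bulk expression, somatic mutations and clinical
annotation, `sextme` summarises each tumor's microenvironment as a feature
vector — tumor mutational burden (TMB), immune and stromal enrichment
scores, tumor purity, and one single-sample GSEA (ssGSEA) score per
immune-cell signature — and then asks, for every feature and every derived
structure (correlations, pathways, mutations, survival models, biomarker
performance), whether male and female patients differ. The design follows
the standard practice of immunogenomic pan-cancer studies; this vignette
records the modelling choices, defaults, and their justifications.

# Cohort assembly

Samples enter the analysis if they have expression data, a recorded sex,
age between 18 and 85 inclusive, and at least moderate immune
infiltration. The infiltration criterion is consumed as a boolean
`immune_infiltrated` flag — in TCGA-style work it is typically produced
upstream by a deconvolution fit (e.g. an empirical deconvolution P < 0.05);
recomputing that fit is out of scope here, so the flag is an input. When
the column is absent entirely we assume all samples pass, with a warning.
A missing age does not exclude a sample (only a documented out-of-range
age does). Cohorts need at least one patient per sex to assemble and at
least ten per sex for sex-bias tests to be reported without a low-power
warning.

Genes whose expression is zero in **more than** 90% of samples are
removed — the boundary (exactly 90%) is kept, reading the threshold as a
strict inequality — and the surviving FPKM values are transformed to
`log2(FPKM + 1)`. The zero filter runs on the assembled cohort, after
sample filtering; the alternative order is defensible but makes the gene
universe depend on samples later discarded. Duplicate gene rows in input
files collapse by the per-sample maximum: a deterministic rule that keeps
the strongest signal for ambiguous probes.

# Per-sample scores

**TMB.** `N_mutation / 38`, where the numerator counts records in the nine
non-silent MAF classes (nonsense, missense, splice site, stop-codon
read-through, start-codon change, frame-shift insertion/deletion, in-frame
insertion/deletion) and 38 Mb is the conventional estimate of the coding
exome captured by whole-exome sequencing. The denominator is a parameter
(`coding_mb`) for panels of other sizes.

**ssGSEA.** For one sample, genes are ranked by decreasing expression
(ties broken by gene identifier, giving bit-reproducible scores; ties are
rare in FPKM data). Walking the ranked list, in-set genes step up by
`rank^alpha` normalized over the set, out-of-set genes step down by
`1/(N − |set|)`, and the enrichment score is the *sum* of the running
difference over all positions (the integrated form, not the maximal
deviation). The weight default `alpha = 0.25` is the established
single-sample default. Because only within-sample ranks enter, the score
is invariant under any strictly monotone transform of a sample's profile —
so the downstream rank-based statistics are unaffected by whether FPKM,
TPM or their logs are supplied. Scores are *not* rescaled across samples;
absolute magnitudes are therefore cohort-dependent and only comparisons
within a cohort are meaningful.

One consequence worth knowing: single-sample rank scores are
compositional. Pushing one signature's genes up in some samples
necessarily pushes every other gene down in rank there, so a strong
planted (or real) shift in one cell type induces small opposite-direction
shifts in the other cell scores. This is a property of all rank-based
per-sample scoring, not an implementation artifact; interpret weak
secondary calls accordingly.

**ESTIMATE scores and purity.** Immune and stromal scores are ssGSEA
scores (`alpha = 0.25`) of user-supplied immune and stromal gene sets;
their sum is the ESTIMATE score, mapped to tumor purity by the published
non-linear calibration `cos(0.6049872018 + 0.0001467884 · score)`. We
clamp purity to [0, 1] and warn when the cosine argument leaves [0, π],
where the original calibration is not meaningful; the original fit leaves
this region undefined.

# Sex-bias testing

Summary features (TMB, immune, stromal, purity) are compared with
two-sided Wilcoxon rank-sum tests — they are skewed and the rank test is
the field's default — at P < 0.05. Cell scores and checkpoint-gene
expression are compared with Welch t tests (unequal variances; the safer
default when groups differ in size and spread), sign convention
female − male so that positive t means female-biased. FDR is controlled
by Benjamini–Hochberg separately within each family (cells; checkpoint
genes; pathways), matching the per-analysis FDR < 0.25 convention, because
the families are scientifically distinct and differently powered.

The strong/weak call counts seven binary features: the four summary
P-values, plus one flag each for cells, checkpoint genes and pathways. A
fraction-type flag is true when at least one member of the family passes
FDR < 0.25 — the minimal reading of "a non-zero fraction of significant
features" — and a cohort with ≥ 4 of 7 flags is classified *strong*. The
rule is monotone by construction.

# Differential correlation of TMB with TME features

Within each sex, Spearman correlation (average ranks for ties — ties in
TMB are common at low mutation counts) of TMB against each feature;
significance by the t approximation `t = r·sqrt((n−2)/(1−r²))`, with an
exact full-enumeration mode for n ≤ 8. The two coefficients are compared
on the Fisher scale: `z = atanh(r)` has approximate variance `1/(n−3)`,
so `Z = (z_m − z_f)/sqrt(1/(n₁−3) + 1/(n₂−3))` is approximately standard
normal under equality.

**Sidedness.** The comparison reports `P = 1 − Φ(|Z|)`, the upper-tail
probability of the absolute score. This one-sided-on-|Z| convention is
deliberate: it is the convention under which the method's reference
worked example (r = 0.04 at n = 83 versus r = −0.36 at n = 29, |Z| ≈ 1.85,
P = 0.03) reproduces; the two-sided value would be ≈ 0.065. The testable
consequence — that under an equal-correlation null the rate of `p < α` is
`2α` — is verified by simulation in the test suite (bivariate Gaussian,
ρ = 0.3, n = 80/30, 2000 replicates). `two_sided = TRUE` switches the
convention. No multiplicity adjustment is applied across features here;
flagged features are reported at raw P < 0.05.

# Pathway GSEA

Genes are ranked by the female-minus-male Welch t score and each pathway
is scored with the classic weighted Kolmogorov–Smirnov statistic (weight
1, maximal signed deviation of the running sum) — the maximal-deviation
form, not the integrated one, because the question is enrichment at the
extremes of a ranked list. The null distribution permutes *sex labels*
(preserving gene–gene correlation, the conservative choice) and recomputes
the full ranking each time; 1000 permutations by default, minimum 100.
P-values use an add-one estimator over the same-sign null pool, NES
divides the observed score by the mean same-sign |null ES|, and FDR is the
sign-matched ratio-of-tails over the pooled null NES, capped at 1. Results
are bit-reproducible given the seed.

# Sex-biased mutations and their cell associations

The binary mutation matrix marks a gene/sample pair when at least one
non-silent record exists; genes with cohort frequency strictly above 5%
are tested (2×2 Pearson chi-square of mutation × sex). "Continuity
correction if needed" is operationalized as: apply Yates when any expected
cell count is below 5 — the common textbook rule — and the applied choice
is reported per gene (`corrected`), with `correct = "always"/"never"`
overrides. BH FDR across tested genes, significance at FDR < 0.25.

For each sex-biased gene, a multivariate logistic regression uses
*mutation status as the outcome* and all standardized cell scores as joint
predictors. The scientific phrasing ("effect of mutations on cells") is
causally the other way round, but a logistic model needs the binary
variable on the left; the reported direction ("cell up/down in mutated
patients") is unaffected. Standardizing predictors makes coefficients
comparable across cells. Non-converged fits (perfect separation) are
excluded with a warning rather than reported with meaningless Wald tests.

# Survival models

Each cell is screened in each sex stratum with a univariate Cox model
(Efron tie handling — the standard modern default; the partial likelihood
is maximized to tolerance 1e−9, ≤ 50 iterations). Cells with Wald
P < 0.05 form the sex-specific signature, and the risk score is the
signature-weighted sum of the patient's infiltration levels using the
*univariate* coefficients — deliberately not a joint refit, keeping each
weight interpretable as that cell's marginal hazard. Patients are split at
the stratum median (ties at the median to low-risk, a deterministic,
logged rule), Kaplan–Meier curves are compared by the two-group log-rank
test, and the risk score is adjusted for age and ordinal stage (I–IV → 1–4;
missing stage drops a patient from the multivariable fit only). The
chi-square log-rank P is an approximation: at very small n (≤ 10 total)
it can differ from an exact relabeling-permutation P by more than the
permutation granularity itself, so tiny-stratum P-values should be read
qualitatively.

# ICB response

TMB's predictive value for checkpoint-blockade response is the
sex-stratified AUC, computed by the Mann–Whitney identity (fraction of
responder/non-responder pairs ranked correctly, half credit for ties).
Response labels are consumed pre-dichotomized (responder/nonresponder);
mapping RECIST categories is the user's responsibility.

# The synthetic-cohort generator

`simulate_cohort()` generates all four inputs from one seed, with planted
ground truth written alongside:

- **Latent cell abundances**: per patient, a shared Gaussian "immune tone"
  (SD 0.5) plus an independent per-cell Gaussian (SD 0.5), exponentiated
  to log-normal abundances. The shared tone produces the cell–cell
  correlation characteristic of bulk immune infiltration and defines the
  latent immune abundance other components couple to. Sex effects are
  additive shifts on a cell's latent mean for females
  (`sex_cell_effects`).
- **Expression**: gene baselines `N(3, 1)` on the log2 scale, signature
  genes add `signature_effect` (default 1) times their cell's abundance,
  plus `N(0, 0.5)` noise, exponentiated to an FPKM-like scale; the lowest
  5% of values are thresholded to zero so the zero-expression gene filter
  is exercised. Signatures are mutually disjoint 30-gene blocks (24 cells
  by default, plus immune and stromal sets driven by the tone and an
  independent stromal latent). Real marker signatures overlap; disjointness
  is a deliberate simplification that makes recovery attribution
  unambiguous.
- **Mutations**: per-gene Bernoulli with background rate 0.02 (per-sex
  overrides for chosen genes), multiplied by a per-patient log-normal rate
  factor whose Gaussian is copula-correlated with the standardized immune
  tone at a sex-specific target `tmb_tme_corr` — so "TMB coupled to
  immunity in one sex only" is a plantable condition. With 2000 genes this
  yields a TMB around 1 mutation/Mb, a realistic mid-range burden. A 15%
  admixture of silent records exercises the non-silent filters.
- **Survival**: exponential baseline (median ≈ 1000 days) with log-hazard
  `Σ hazard_gammas · abundance`; censoring times are uniform with the
  scale solved numerically so the expected censored fraction matches
  `censor_fraction` (default 30%).
- **ICB response**: Bernoulli with logit `intercept + effect · TMB`,
  per sex.

Defaults (100 patients per sex, 2000 genes, 24 × 30-gene signatures,
latent and noise SDs of 0.5, unit signature effect) are chosen to resemble
a mid-sized solid-tumor cohort with clearly resolvable but not trivial
effects. What the generator does *not* emulate: realistic marginal FPKM
distributions, overlapping signatures, copy-number or subtype structure,
batch effects, or informative censoring. Passing recovery tests therefore
demonstrates the statistical machinery is correct and calibrated, not that
any particular real cohort will behave as cleanly.

# Validation strategy and problem sizes

The test suite validates each statistic against an independent oracle
computed by a different route: ssGSEA against an explicit two-ECDF
construction (200 random instances, 1e−9), BH against the longhand
step-up, exact Spearman against full permutation enumeration (n ≤ 6), AUC
against brute-force pair counting, Cox coefficients against a grid-search
maximizer of the partial likelihood (within 1e−3), the log-rank statistic
against explicit risk-set bookkeeping, and the 2×2 chi-square against its
closed form. Calibration is checked by simulation: the differential-
correlation null (2000 replicates), per-cell type-I rates on all-null
cohorts (100 cohorts × 24 cells, expected 3–7% at P < 0.05), and GSEA
P uniformity on random sets. Recovery is checked on planted effects: a +1
female latent shift on one cell (20 cohorts of 100 + 100), hazardous and
protective cells γ = ±0.8 (50 strata of 300), each required to be
recovered with correct sign in ≥ 90% of replicates. These sizes keep the
whole suite under a few minutes while leaving comfortable statistical
margins.

# Known limitations

- Rank-based per-sample scores are compositional (see above); strong
  shifts in one cell type bleed, attenuated and sign-flipped, into others.
- The Fisher-z comparison assumes approximate normality of transformed
  Spearman coefficients; at very small strata (n < 10) its P-values are
  rough.
- The fraction-type classification flags use the minimal "any significant
  member" rule; cohorts near the 4-of-7 boundary can flip with a single
  marginal feature.
- No covariate adjustment (age, stage) is applied to the sex-bias or
  differential-correlation tests; confounding between sex and, e.g.,
  smoking-related mutational burden must be handled by the user's cohort
  design.
- The ICB module evaluates TMB only; it does not model combined
  biomarkers.
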