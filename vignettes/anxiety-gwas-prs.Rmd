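---
title: "Methods: association and risk modeling for a bounded anxiety score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association and risk modeling for a bounded anxiety score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anxgwas)
```

# What this package models

`anxgwas` implements a complete association pipeline for an anxiety
phenotype measured on the HADS-A questionnaire subscale: an integer score
from 0 to 21, with scores of 11 or more conventionally read as clinically
significant anxiety. The pipeline covers variant quality control,
population-structure principal components, per-variant association scans
(logistic on the binary label, linear on the raw score), a polygenic risk
score built from GWAS summary statistics with ridge regression, and the
non-genetic association statistics of a survey cohort (odds ratios,
genotype-defined metabolism groups, Bonferroni adjustment).

Because individual-level cohort data of this kind cannot ship with a
package, every stage is exercised against a synthetic cohort generator
with known ground truth. The generator is first-class, tested code: its
defaults *are* the study conditions the rest of the test suite relies on.

# The synthetic cohort

## Genotypes

Genotypes follow the Balding–Nichols model. Each variant draws an
ancestral allele frequency $p \sim \mathrm{U}(\text{maf\_range})$; each of
$K$ subpopulations draws its own frequency from
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, so the
between-population variance is $F\,p(1-p)$ with $F$ the fixation index
FST; individuals carry $\mathrm{Binomial}(2, p_k)$ ALT dosages. Setting
$F=0$ collapses to one panmictic population, which the tests use as the
Hardy–Weinberg null. The tests verify the realized differentiation against
Hudson's FST estimator computed directly from the simulated
per-population frequencies. Missing calls are injected completely at
random; the cohort the package emulates reports no genotype missingness
mechanism, so nothing more structured is claimed.

Default differentiation is `fst = 0.02` with two subpopulations — modest,
within-country-scale structure that is nevertheless strong enough for the
first principal component to recover, which is exactly the regime the PC
covariates are meant to handle.

## Phenotypes

The phenotype model is a liability threshold model with a bounded integer
observation layer. The latent liability is

$$L = G^\ast + \beta^\top C + \varepsilon,\qquad
  \varepsilon \sim \mathcal N(0, 1),$$

where $G^\ast$ is the causal genetic score (a weighted sum of causal
dosages, standardized to unit variance), and $C$ collects covariate
terms: age (per decade, centered at 50), sex (female = 1), nightly sleep
hours, daily coffee cups, alcohol-behavior group, current smoking, and
the caffeine/alcohol metabolism marker groups. The observed anxiety score
is then drawn as

$$\text{score} \sim \mathrm{Binomial}\!\left(21,\;
  \mathrm{logit}^{-1}(b_0 + s\,L)\right),$$

so it is a genuine integer in $[0, 21]$ with no ad hoc rounding — a
truncated-Gaussian alternative was rejected for exactly that reason. The
binary anxiety label is `score >= 11`.

Two parameters tie the generator to the cohort it emulates. The baseline
logit $b_0$ and the liability scale $s$ were calibrated jointly — once, by
bisection on $b_0$ at a grid of $s$ — so that at $n = 30{,}000$ the
simulated cohort reproduces a mean score of about 6 and a label
prevalence of about 14%. The frozen defaults are $b_0 = -1.41$,
$s = 0.6$. The female liability coefficient default (0.62) was chosen in
the same calibration so that the crude female:male odds ratio for the
label is approximately 2, and the female share defaults to 62.6%. The
package exports `calibrate_baseline_logit()` so the calibration is
reproducible.

Note one consequence of standardizing $G^\ast$: the absolute scale of
`causal_effect_sd` is inert (only the relative spread of causal effects
matters), and the total genetic share of liability variance is fixed at
half the non-covariate variance. Per-SNP detectability is therefore
governed by `n_causal` and the sample size, not by the effect-size scale.

What the generator does *not* emulate: linkage disequilibrium (variants
are independent), real chromosome maps or array manifests, non-random
missingness, household/geographic clustering, and questionnaire
measurement error beyond the Binomial layer. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
generative model, not robustness to every artifact of real survey-genetic
data.

# Variant quality control

Filters run in a fixed order — FILTER status not `PASS`, multiallelic
records, Hardy–Weinberg exact-test $p < 10^{-6}$, minor allele frequency
below 1% — and each removal reason is counted against the set surviving
the previous filters, so the report's counts are auditable and the
operation is idempotent. A variant at exactly 1% MAF is retained
(strictly-below removal). Multiallelic records are retained at *read*
time and flagged with their ALT arity; removing them is QC's job, which
keeps the counts honest. HWE is computed on all samples; restricting to
controls is a defensible alternative but not what this pipeline does.
Missing genotypes contribute to neither the MAF nor the HWE counts.

The HWE test is the exact conditional test: given the allele counts, the
heterozygote count $h$ has probability proportional to
$2^h / (n_{AA}!\,h!\,n_{aa}!)$, and the p-value sums all configurations no
more probable than the observed one. Probabilities are accumulated by the
$P(h+2)/P(h)$ recurrence in log space; the test suite checks it against a
direct factorial-formula enumeration for every genotype table of up to 50
individuals at $10^{-12}$. A mid-p variant is deliberately not used. For
minor-allele counts beyond a configurable bound the 1-df chi-square
approximation substitutes (flagged in the return attribute); the default
bound is high enough that cohort-scale data never reach it.

# Population structure

PCA runs on a uniform random subsample of QC-passed variants with MAF of
at least 5% (default 15,000 — the array-manifest SNP list this stands in
for is not reproducible, so random subsampling is documented as the
substitute). Missing dosages are mean-imputed per variant, columns are
centered and scaled to unit sample standard deviation (allele-frequency
$\sqrt{2p(1-p)}$ scaling would also be defensible; sample SD is simpler
and the choice is configurable at the code level), and the top components
come from the eigendecomposition of the smaller Gram matrix. Signs are
fixed by making each component's largest-magnitude loading positive, so
results are deterministic.

Stability across subsamples is measured as the mean over runs and
components of $1 - |r|$, where $r$ is the Pearson correlation between
matched component scores of a run and the reference run; below 0.05
counts as stable. This metric is scale- and sign-invariant and directly
thresholdable, which is why it was chosen over Procrustes-style
alternatives. One caveat discovered in testing and worth stating: when
two components have nearly equal variances (e.g. the two structure axes
of three symmetric subpopulations), the subspace is free to rotate
between subsample runs and per-component matching legitimately reports
instability. The stability check is therefore most meaningful for
components with well-separated variances, and the test suite pins it on
the unique structure axis of a two-population cohort.

# Association scans

Per variant, the binary model is maximum-likelihood logistic regression
(IRLS, tolerance $10^{-8}$, at most 100 iterations, via `glm.fit`) of the
label on dosage, age, sex, and the leading PCs; the continuous model is
OLS on the raw 0–21 score. Both report the two-sided Wald test on the
dosage coefficient — Wald rather than score or likelihood-ratio tests
because the stored standard error is itself needed downstream. The raw
score is used untransformed; rank-normalization was considered and
rejected as an undocumented extra step. Missing dosages are handled
complete-case per variant. Non-convergence, separation, or rank
deficiency yields a row flagged unfit rather than an error or an inflated
estimate — important because the PRS selection score divides by the
p-value and would otherwise be dominated by pathological fits. P-values
that underflow are floored at the smallest positive double so they remain
in $(0, 1]$.

Genome-wide significance is a strict inequality at $5\times 10^{-8}$.
The genomic inflation factor is the median implied 1-df chi-square over
its null median ($\approx 0.4549$). The acceptance suite verifies, at
10,000 null variants, $\lambda_{GC} \in [0.95, 1.05]$ and nominal type-I
error, and that a deliberately confounded two-population simulation is
inflated without PC covariates and calibrated with them.

# The polygenic risk score

The procedure, end to end, with leakage controlled by construction:

1. **Split first.** 10% of samples are carved out as the test set,
   stratified by label; the remainder splits 80/20 into training and
   validation, also stratified. All three sets are disjoint, exhaustive,
   and reproducible from the seed.
2. **Score on training data only.** The GWAS used for SNP selection runs
   on the training split alone. (An earlier draft of this package used
   train+validation; the validation AUC then systematically overstated
   the selected model and the held-out test AUC exposed the gap. The
   train-only rule is the correct reading and the audit log records that
   test indices never touch any fitting step.)
3. **Per-SNP selection score.** Each fitted row combines into
   $(\beta_{SNP}/p)\cdot\beta_{age} + \beta_{sex} + \text{intercept}$
   (the default "literal" parse; the printed source formula is
   typographically ambiguous, and a "magnitude" parse
   $(\beta_{SNP}/p)(\beta_{age}+\beta_{sex}+\text{intercept})$ is
   available behind a switch — neither is presented as certainly
   intended). P-values are floored at $10^{-300}$; unfit rows are never
   selected. Note the score is signed and dominated by $\beta_{SNP}/p$,
   so strongly associated SNPs land in *both* extreme tails depending on
   effect sign: a one-sided threshold necessarily recruits only one sign
   of strong effect, a structural property of the formula worth knowing
   when interpreting selected sets.
4. **Threshold sweep.** Thresholds default to score quantiles at 20
   geometrically spaced selected-set sizes, from all scored SNPs down to
   one. The randomized threshold search this stands in for is made
   deterministic for reproducibility; geometric (not even) spacing is
   used because useful models concentrate in the extreme upper tail of
   the score distribution — an evenly spaced quantile grid cannot select
   fewer than 5% of variants, while sparse models (a fraction of a
   percent of the panel, as in the study this emulates) are exactly
   where validation performance peaks on planted-signal cohorts.
5. **Ridge fit.** For each threshold, features are the selected dosages
   (mean-imputed with training-set means) plus age, sex, and 10 PCs. The
   fit minimizes $\sum_i (y_i - \hat y_i)^2 + \lambda \sum_j \beta_j^2$
   with the intercept unpenalized, solved in closed form (primal or dual,
   whichever Gram matrix is smaller) on internally standardized features,
   with weights returned on the original scale. The binary outcome is fit
   with this squared-error objective — a linear-probability ridge, not
   logistic ridge — faithful to the stated objective; predictions serve
   only as ranking scores for AUC, where calibration is irrelevant.
   $\lambda$ defaults to 1.0 on standardized features and is *not* tuned
   inside the sweep (only the threshold is tuned); it is configurable.
6. **Select and test.** The threshold with the highest validation ROC
   AUC wins; ties break toward fewer SNPs. The winning model is evaluated
   exactly once on the held-out test set. ROC AUC is the midrank
   Mann–Whitney statistic (ties count one half), checked in the tests
   against exhaustive pair counting and against an independent library
   implementation.

Covariate-only baselines (age+sex, and age+sex+PCs) run through the same
ridge machinery on the same split; a genotype-based model is only
credited with the lift of its test AUC over these baselines.

On Monte Carlo error in the null check: with 3,000 samples the test set
holds about 42 cases, and a single held-out AUC draw under permuted
labels has a standard error near 0.08. The acceptance suite therefore
measures chance behavior as the mean test AUC over five independent label
permutations rather than a single draw.

# Epidemiological statistics

Crude odds ratios come from the 2×2 table as $(ad)/(bc)$ with a Woolf
log-scale 95% CI and a chi-square p-value (continuity-corrected when any
cell is below 5); a Haldane–Anscombe 0.5 correction applies only when a
zero cell occurs and is flagged. The tests pin the crude computation to
the published sex-by-anxiety counts of the cohort this package emulates
(odds ratios 2.14 and 0.47) and verify equivalence with
exp(coefficient) of the unadjusted logistic fit. Adjusted odds ratios
come from logistic regression with age and sex as covariates. Published
"adjusted" odds ratios of that cohort's lifestyle tables are not
recomputable from their printed marginals, so no test pins them.

Metabolism marker groups are pure total functions over their genotype
alphabets: caffeine intolerance counts a slow-metabolizer rs762551
genotype (AC/CC) and the caffeine-sensitive rs5751876 TT; alcohol
intolerance counts rs671 AA/AG and rs1229984 TT/CT. Group score
summaries use a one-sample t-test of each group against the overall
cohort mean — the comparison described by the source material's table
caption; since each group also contributes to the overall mean, the test
is slightly conservative for groups that are a large share of the cohort,
and exact only in the small-share limit. Bonferroni adjustment is
`min(1, m p)`. The multivariate phenotype model is a single logistic fit
on age, sex, children, marital status, alcohol group, coffee cups and
sleep hours, with stated reference levels (no children, never married,
alcohol group 1) and an in-sample ROC AUC, matching the apparent source
protocol; in-sample AUC carries optimism of order the parameter count
over the case count, which the null tests budget for explicitly.

# Numerical choices and degenerate inputs

* P-values are kept strictly in $(0, 1]$ (underflow floored).
* The HWE enumeration uses a log-space recurrence; the observed
  configuration is included in the tail sum with a $1+10^{-12}$ relative
  guard against ties lost to rounding.
* Ridge standardization maps zero-variance features to zero
  coefficients; a singular penalty-free system raises an error advising
  $\lambda > 0$.
* Empty variant sets, all-missing variants, single-class outcomes,
  constant dosages, and duplicated covariates all produce defined
  behavior (empty outputs, unfit flags, or informative errors), never
  crashes.
* Problem sizes in the test and acceptance suites (10,000 null variants
  at $n=1{,}000$; 3,000 samples by 5,000 variants for the risk model;
  full HWE enumeration to $n=50$) were chosen so the whole suite runs in
  minutes on one core while keeping Monte Carlo error well inside each
  check's tolerance.

# Known limitations

* No linkage disequilibrium in the generator, hence no LD clumping in the
  PRS; selected SNP counts on real data would behave differently.
* The linear-probability ridge is not a calibrated risk model; only its
  ranking is used.
* Sample-level QC (call rate, heterozygosity, relatedness) is out of
  scope, as is mixed-model association and variant annotation.
* The headline accuracy of the real cohort this package emulates is not
  reproducible without that cohort's data, and the package makes no
  synthetic claim to match it.

# A worked miniature

```{r example, eval = FALSE}
spec <- simulation_spec(n_samples = 1000, n_variants = 2000, seed = 1)
sim <- simulate_genotypes(spec)
pheno <- simulate_phenotypes(sim$genotypes, sim$truth, spec)

qc <- apply_qc(sim$genotypes)
ids <- select_pca_snps(qc$genotypes, n_snps = 1000)
pcs <- compute_pcs(qc$genotypes, ids, k = 10)

scan <- gwas_scan(qc$genotypes, pheno, pcs, model = "binary")
lambda_gc(scan)
call_significant(scan)

prs <- run_prs_pipeline(qc$genotypes, pheno, pcs,
                        prs_config(ridge_lambda = 10, seed = 1))
prs$model
prs$baselines
```
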