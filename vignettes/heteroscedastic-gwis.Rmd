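---
title: "Heteroscedastic mixed-model scans for gene-by-smoking interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heteroscedastic mixed-model scans for gene-by-smoking interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetgwis)
```

## The problem

Cigarette smoking is the dominant environmental determinant of lung
function, and both the *mean* and the *variance* of spirometric
measurements such as FEV1 (forced expiratory volume in one second, in
liters) differ by smoking status.  A genome-wide scan for SNP-by-smoking
interaction that models a single residual variance across never, former
and current smokers misattributes this variance heterogeneity to the
interaction terms: its test statistics are inflated and its type-I error
is not controlled.  `hetgwis` implements a scan built around mixed models
that give each smoking stratum its own covariance.

## The model

For subject $i$ in variance group $g$ (never vs ever smokers) observed at
visits $j = 1, \dots, n_i$:

$$
y_{gij} = x_{ij}'\beta + b_{gi} + \varepsilon_{gij}, \qquad
b_{gi} \sim N(0, \sigma_g^2), \qquad
(\varepsilon_{gi1}, \dots, \varepsilon_{gin_i})' \sim MVN(0,
\Sigma_g[v_i, v_i]),
$$

where $x_{ij}$ collects baseline age, sex, height, BMI, elapsed time
since baseline, pack-years, a sex-by-age product, smoking-status dummies
and their interactions with age/sex/height/time, ancestry principal
components, and — in SNP models — the dosage, dosage-by-status and
dosage-by-pack-years terms.  $v_i$ is the subject's observed visit
pattern; subjects missing interior visits contribute the matching
principal submatrix of $\Sigma_g$.

Three covariance structures are supported per group: `independence`
($\sigma^2 I$), `random_intercept` ($\sigma^2 J$ plus a per-visit
diagonal), and `unstructured`.  One identifiability point deserves
emphasis: a random intercept *added to* an unstructured residual
covariance is not identified, because $\sigma_g^2 J + \Sigma_g$ is itself
just another unstructured matrix.  When `unstructured` is requested the
package therefore estimates the single marginal matrix $V_g$ directly and
reports the random intercept as absorbed.  This preserves exactly the
likelihood being maximized while removing a flat direction from the
optimizer.

### The two-phase scan

**Filtering step** (`three_df_test()`): never and ever smokers are fitted
separately, each with its own covariance.  The ever-smoker model with and
without (SNP, SNP-by-pack-years) gives a 2-DF likelihood-ratio test; the
never-smoker model with and without SNP gives a 1-DF test (pack-years are
identically zero for never smokers, so no interaction exists there).
Their sum is referred to $\chi^2_3$.  Stratified fitting makes
heteroscedasticity structural rather than parametric.  A pooled
`homoscedastic_test()` — shared covariance, shared covariate coefficients,
3-DF LRT on the SNP terms — is computed alongside as the inflation
comparator.

**Testing step** (`pooled_heteroscedastic_test()`): the top-ranked SNPs
are refitted on pooled data with group-specific covariance, giving
separate Wald tests for the SNP main effect, each SNP-by-status dummy and
SNP-by-pack-years, plus their joint F test ("overall effects").  Pooling
is what permits estimation of the interaction coefficients, which the
stratified filtering statistic cannot separate.

### Estimation

All fits are full maximum likelihood, *not* REML: both the filtering LRTs
and the AIC model selection compare models differing in fixed effects,
and neither comparison is valid under REML.  Fixed effects are profiled
out by GLS at each covariance proposal; covariance parameters are
optimized on unconstrained scales (log variances, log-Cholesky factors
for unstructured matrices, which keeps every iterate positive definite)
by quasi-Newton with analytic gradients.  Because subjects sharing a
(group, visit-pattern) cell share a covariance matrix, the likelihood is
accumulated from per-cell cross-product statistics
$C_{ab} = \sum_i x_{ia} x_{ib}'$, making each objective evaluation
independent of cohort size; this is what makes per-SNP warm-started
refits cheap enough for genome-wide loops in plain R.

Numerical conventions:

* convergence: profile-deviance gradient infinity-norm below
  $10^{-6} \times n_{obs}$ (per-observation scaling; an absolute
  $10^{-6}$ is not reliably attainable in double precision once the
  deviance is of order $10^4$), after an `nlminb` run and, if needed, a
  BFGS polish;
* non-convergent SNPs are flagged (`converged = FALSE`), excluded from
  ranking, and never abort a scan;
* warm starts: per-SNP full models start from the SNP-free reduced fit's
  covariance parameters, which also guarantees non-negative LRTs;
* LRT statistics are clipped at zero; a full-model log-likelihood
  materially *below* the reduced one raises an optimization-quality
  error rather than reporting a negative statistic;
* the overall F test uses residual denominator degrees of freedom
  $n_{obs} - \mathrm{rank}(X)$, an explicit approximation to unstated
  software defaults; the $\chi^2$ form is reported alongside;
* ties in the filtering ranking break by larger statistic, then SNP id.

### Screening, PCs and thresholds

Monomorphic SNPs are excluded; the exact Hardy-Weinberg test (full
conditional enumeration, preferred over the chi-square for small counts)
is *reported*, not filtered on, since no screening threshold is part of
the published analysis.  Ancestry principal components come from the
eigendecomposition of the genetic relationship matrix
$ZZ'/M$ on $2f(1-f)$-standardized dosages, computed once on the full
sample and reused in both strata.  The genome-wide significance threshold
is Bonferroni, $\alpha / n_{tests}$.

### Genomic control

`genomic_inflation()` maps every p-value to a 1-DF chi-square quantile
and reports the median ratio to 0.4549364.  The 1-DF convention is
deliberate even for the 3-DF test: it is df-agnostic, matches standard
genomic-control methodology, and makes the homoscedastic-vs-stratified
comparison read on one scale.  A mean-based variant is exposed as an
option since the convention used for the published inflation factors is
not stated.

### Model selection and replication

`select_model()` fits a configurable grid of smoking codings (never/ever;
never/former/current; former/current for cohorts without never smokers)
crossed with covariance structures and shared-vs-per-group variance —
always *without* SNP terms, enforced as a contract, so selection cannot
bias SNP inference.  The minimum-AIC specification wins; ties break
toward fewer parameters.  `replicate_snps()` then fits the selected model
plus SNP terms and tests each term one-tailed in the discovery direction
(`one_tailed_p()`: half the two-tailed p when the sign matches, one minus
that half otherwise).  For former/current-only cohorts no
never-referenced discovery direction transfers, so all tests are
two-tailed and the status dummy is former-referenced.

## The synthetic-cohort generator

No individual-level cohort data are redistributable, so every downstream
stage is exercised on `sim_scenario()` worlds whose statistical structure
is exactly what the analysis assumes: Hardy-Weinberg genotypes with
declared MAFs; the pooled covariate-by-smoking mean model as generative
truth; group-specific $b_{gi} + \varepsilon_{gij}$ noise; and optional
SNP main/interaction effects whose zero setting is *exactly* the null of
the 3-DF test.  Presets mirror four published study designs (sample
sizes, stratum proportions, visit structure), including a
longitudinal three-visit design with never/former/current proportions
0.577/0.204/0.219 and heavy-smoker single-visit designs without never
smokers.  Choices the source material does not pin down, made once:

* covariate distributions are loosely calibrated to published
  descriptive statistics (age uniform on 40–69, height
  $N(160, 8.7^2)$ cm, BMI $N(24.6, 3.1^2)$, male fraction 0.5) and are
  fully configurable — tests never depend on them, only on declared
  scenario parameters;
* ever-smoker variances default to four times never-smoker variances,
  the contrast used throughout the calibration suites;
* pack-years are lognormal (median 15) for ever smokers and accumulate
  at 0.75 packs/day-equivalents for current smokers across follow-up
  (a `"baseline"` carry-forward mode is exposed, since whether
  pack-years were visit-updated is unstated);
* dropout is independent per post-baseline visit
  (missing-completely-at-random), so interior visit gaps such as
  $\{1,3\}$ arise by design and exercise the submatrix covariance path;
  smoking status is fixed at baseline, matching its subject-level
  subscript in the model.

What a green test on synthetic data does **not** establish: robustness to
linkage disequilibrium, population substructure (PCs are exercised as
null covariates on independent-SNP panels), informative dropout,
status switching, measurement error in self-reported smoking, or
non-linear smoking-response relationships.

## Design decisions made where the source was open

* **Units**: liters throughout.  The source alternates between mL in one
  methods header and liters in every table; the coefficient magnitudes
  (−0.025 L per allele) are only plausible in liters.
* **Missing dosages**: SNP-wise complete-case analysis, the simplest
  reading consistent with per-SNP sample counts in GWAS practice.
* **Phenotype gaps**: a missing *baseline* visit or duplicated visit
  index is a validation error; interior gaps are data, not errors.
* **Homoscedastic comparator coding**: two-level (never/ever), keeping
  its joint test at 3 DF.
* **HWE boundary check**: the all-heterozygote configuration first drops
  below p = 0.05 at n = 7 under the exact test (computed by full
  enumeration; an often-quoted larger boundary applies to the asymptotic
  test, not this one).
* **Config and manifests are JSON** (no YAML dependency is available in
  the supported environment); manifests deliberately omit timestamps so
  identical (config, seed) runs are byte-identical.

## Acceptance properties

The test suite's acceptance criteria are property-based and recomputed
from scratch on every run: the printed genome-wide Bonferroni threshold
($0.05 / 310{,}515 = 1.61\times10^{-7}$); dense-oracle equivalence of the
likelihood; type-I error and genomic inflation of the 3-DF test within
binomial/calibration bands under the heteroscedastic null
($n = 1{,}000$ subjects, 1,000 null SNPs); the homoscedastic model's
inflation exceeding the stratified test's in at least 45 of 50 disjoint
100-SNP panels of the same pooled scan; recovery of literature-scale effects
(−0.025 main, −0.029 interaction) within two standard errors in at least
45 of 50 replicates at $n = 8{,}000$; exact agreement of the HWE test
with enumeration for all genotype triples with total at most 50; AIC
selection of the true two-level heteroscedastic structure in at least 40
of 50 replicates at $n = 2{,}000$; and exact decomposition of the 3-DF
statistic into its stratum LRTs.  The vignette states no empirical result
those tests do not themselves compute.

## Known limitations

Denominator degrees of freedom for the F test are approximate; small-
stratum unstructured fits (tens of subjects) can sit on ill-conditioned
optima and are reported as non-converged rather than silently accepted;
the generator does not simulate LD, so filtering-rank behaviour under
correlated SNPs is untested; and REML-based software will legitimately
report different variance estimates (though not different LRT
conclusions) than these ML fits.
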