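---
title: "Methods: variance decomposition and exposure scans for longitudinal CVL immune data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance decomposition and exposure scans for longitudinal CVL immune data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvimmune)
library(dplyr)
```

## 1. The statistical model

Every analysis in `cvimmune` is built on the one-way random-intercept
model for analyte $a$, woman $i$, visit $j$:

$$\log_{10} y_{aij} = \mu_a + b_{ai} + e_{aij},\qquad
b_{ai} \sim N(0, \sigma_B^2),\quad e_{aij} \sim N(0, \sigma_W^2).$$

The intraclass correlation coefficient
$\mathrm{ICC}_a = \sigma_B^2 / (\sigma_B^2 + \sigma_W^2)$ measures how
much of an analyte's variability is a stable between-woman trait. Immune
protein concentrations are approximately log-normal over their
physiological range, which is why the decomposition is done on the
$\log_{10}$ scale throughout.

Exposure effects are fixed-effect shifts on the same structure:
`value ~ exposure (+ covariates) + (1 | woman)`. For analytes detected
in at most 85% of samples the continuous model is unreliable (the
imputed point mass at half the LLOQ dominates), so the outcome is
dichotomised to detected/undetected and fitted as a random-intercept
logistic model.

## 2. Estimators

### 2.1 ANOVA (method of moments)

`anova_components()` uses the classical one-way decomposition:
$\hat\sigma_W^2 = \mathrm{MSW}$,
$\hat\sigma_B^2 = \max\{0, (\mathrm{MSB} - \mathrm{MSW}) / n_0\}$ with
$n_0 = (N - \sum_i n_i^2 / N)/(k - 1)$ for unbalanced designs, and the
F statistic $\mathrm{MSB}/\mathrm{MSW}$ on $(k-1, N-k)$ degrees of
freedom. A worked example with groups $\{1,3\}$ and $\{5,7\}$ gives
$\hat\sigma_B^2 = 7$, $\hat\sigma_W^2 = 2$, ICC $= 7/9 \approx 0.778$,
$F = 8$; it is pinned in the test suite.

### 2.2 Profile REML

`reml_fit()` maximises the restricted likelihood. The problem is
profiled to one dimension in the variance ratio
$\lambda = \sigma_B^2/\sigma_W^2$: with $w_i = n_i/(1 + \lambda n_i)$,
$\hat\mu = \sum w_i \bar y_i / \sum w_i$ and
$Q(\lambda) = \mathrm{SSW} + \sum_i w_i (\bar y_i - \hat\mu)^2$, the
profiled restricted log-likelihood is

$$\ell_R(\lambda) = -\tfrac12\Big[(N-1)\log Q
  + \sum_i \log(1 + \lambda n_i) + \log \sum_i w_i\Big] + \text{const},
\qquad \hat\sigma_W^2 = Q(\hat\lambda)/(N-1).$$

Numerical choices:

- The gradient of $\ell_R$ in $\lambda$ is analytic (using
  $\partial Q/\partial\lambda = -\sum w_i^2(\bar y_i - \hat\mu)^2$), so
  the optimum is a bracketed root solve (`uniroot`, tolerance `1e-10`)
  seeded by a Brent search on $\log\lambda$ — no generic multivariate
  optimiser, no convergence-by-default.
- The boundary $\sigma_B^2 = 0$ is detected exactly from the gradient
  sign at $\lambda = 0$ and reported with a `boundary` flag; the ICC
  interval is `NA` there because the Wald approximation breaks down on
  the boundary.
- The 95% interval on the ICC comes from the delta method applied to the
  numerically differentiated observed information of the full restricted
  likelihood in $(\sigma_B^2, \sigma_W^2)$, clipped to $[0, 1]$.

The test suite verifies agreement with `anova_components()` on balanced
designs (where the two coincide at interior optima), with
`lme4::lmer()` on unbalanced designs including the absolute restricted
log-likelihood, interval coverage of 90–98% at ICC 0.2/0.5/0.8, and
recovery bias below 0.03.

### 2.3 Random-intercept logistic models

`fit_relogit()` delegates to `lme4::glmer()` with adaptive Gauss–Hermite
quadrature, 15 nodes by default. Fifteen nodes is past the point of
diminishing returns for a scalar random intercept: the suite checks that
the log-likelihood at the fitted parameters changes by less than
$10^{-6}$ when re-evaluated with 51 nodes, and that fits with zero
estimated intercept variance reproduce plain `glm()` coefficients to
$10^{-4}$. Degenerate designs — constant exposure, constant outcome, or
a binary-exposure arm that is entirely detected or undetected (the odds
ratio is then inestimable) — return structured skip records instead of
estimates; `signature_scan()` never drops an analyte silently.

### 2.4 Quantile convention

`icc_summary()` uses the $(n+1)p$ interpolation convention (R quantile
type 6), the convention of the epidemiological literature whose summary
statistics the panel registry encodes; base R's default type 7 gives a
slightly narrower IQR on 46 values.

## 3. Healthy-visit cascade and exposures

A *healthy* visit is attended, non-menstruating, negative for HSV
shedding, bacterial vaginosis and yeast, in a woman negative for
C. trachomatis, N. gonorrhoeae and T. vaginalis at the first and last
visit (a positive at either excludes all her visits; indeterminate
results exclude conservatively). `cascade_table()` reports each step as
a percentage of the previous one, rounded half away from zero to match
published table style.

Thirteen exposures are scanned: cycle phase, DMPA, COC, PSA (seminal
exposure, ordered 0–2), soap cleansing, cloth cleansing, insertion of
substances, cervical ectopy, colposcopic abnormality (examination visits
only), vaginal pH (strip values binned 0/1/2), neutrophil count
(ordered 0–3), lymphocytes, and haemoglobin (ordered 0–3). The a priori
adjustment set is age, recent sex and haemoglobin presence; PSA omits
recent sex (it lies on PSA's causal path) and haemoglobin omits itself.
Intravaginal-practice comparisons use as reference the healthy visits
with no cleansing or water-only cleansing, and always exclude visits at
which prescribed medication was inserted.

## 4. Cycle-phase classification

Urinary PDG (pregnanediol-3-glucuronide) is divided by creatinine to
correct for urine dilution, and each woman's ratio series is indexed to
her study minimum, making the classifier invariant to PDG rescaling. A
cycle is called ovulatory when any indexed ratio strictly exceeds 4.0
(modified Kassam method; exactly 4.0 does not qualify). Phases are
assigned only for ovulatory cycles with exactly one observed
menstruation episode: visits after the episode are pre-ovulation until
the first *sustained* rise above threshold (the following visit must
also exceed it, unless the rise is at the last visit; a lone one-visit
spike is not ovulation — `min_sustained = 1` relaxes this), and
post-ovulation from the rise onward. Women using hormonal contraception
(DMPA/COC) are never phase-assigned.

## 5. The synthetic cohort generator

Because the motivating study's raw data were never deposited, the
package ships a calibrated generator (`sim_config()`,
`simulate_cohort()`) whose defaults mirror a 100-woman, 12-visit,
thrice-weekly design: 92% attendance, contraception mix, STI/BV/yeast
prevalences, exposure frequencies, and a 46-analyte panel whose
medians, between-/within-woman standard deviations and detection
fractions reproduce published summary statistics. Quantification limits
are back-calculated from each analyte's detection fraction: with
$\sigma = \sqrt{\sigma_B^2 + \sigma_W^2}$ and detection $d$, the latent
mean is $\mu = \log_{10}(\text{median}) - \sigma\,\Phi^{-1}(1 - d/2)$
(undoing the truncation of the observed median) and
$\mathrm{LLOQ} = 10^{\mu + \Phi^{-1}(1-d)\sigma}$, so simulated
detection fractions match the reference ones by construction.

PDG trajectories are a deliberate simplification: a step rise by a
configurable fold (default 6×) at the ovulation day (13–15), falling
two days before the next menses, with bounded multiplicative noise
factors in $[1/\sqrt{B}, \sqrt{B}]$, $B = 1.4$ by default. The bound is
chosen so classification is *provably* exact against the generator's
truth: an anovulatory series has maximum indexed ratio at most
$B = 1.4 < 4$, and an ovulatory series has minimum luteal indexed ratio
at least $6/1.4 \approx 4.3 > 4$. The generator therefore validates the
classifier's logic, not the biology of hormone kinetics — it does not
emulate gradual luteal rises, luteal-phase defects or assay drift.

Effects are planted as additive shifts on the $\log_{10}$ scale via a
named `effects` list (e.g. `list(dmpa = c("IL-8" = 0.4))`), and the
returned `truth` tables (random intercepts, per-visit true phase, true
ovulatory status) support parameter-recovery and type-I-error testing.
All randomness flows from a single `set.seed()` call per
`simulate_cohort()`, so a (config, seed) pair is fully reproducible.

Problem sizes in the test suite (cohort sizes, replicate counts) are the
package's own choices, balancing statistical resolution against a
test-suite runtime of a few minutes.

## 6. Worked example

```{r example, eval = FALSE}
co <- simulate_cohort(sim_config(), seed = 1)
flags <- flag_healthy_visits(co$visits, co$women)
filter_report(flags)

vc <- icc_scan(co$measurements, flags, default_panel())
icc_summary(vc$icc)
plot_icc(vc)

scan <- signature_scan(co, "dmpa", flags = flags, adjusted = TRUE)
subset(scan, significant)
autoplot(scan)
```

## 7. Limitations

- Substitution imputation (half-LLOQ / twice-ULOQ) is simple and
  matches the motivating analysis, but is known to bias variance
  estimates when censoring is heavy; the >85% routing rule exists
  precisely to keep heavily censored analytes off the continuous route.
- The Wald interval on the ICC is a large-sample approximation and is
  suppressed (reported `NA`) at boundary fits.
- The generator's cycle model is a step function; it supports exactness
  proofs for the classifier but not realism studies of borderline
  hormone profiles.
- Signature scans fit one exposure at a time with a fixed confounder
  set; they are screening tools, not causal estimates.
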