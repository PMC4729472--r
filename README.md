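# cvimmune

Longitudinal variance decomposition and exposure-signature analysis of
soluble immune mediators in cervicovaginal lavage (CVL).

## The scientific problem

Concentrations of cytokines, chemokines, antimicrobial proteins and
immunoglobulins in the female genital tract fluctuate within a woman —
with the menstrual cycle, sexual activity, intravaginal practices and
subclinical conditions — and differ systematically between women. Any
study that uses a genital immune marker as an endpoint needs to know how
much of its variability is a stable personal trait and how much is
visit-to-visit noise, and which measurable exposures drive the
within-woman part.

`cvimmune` implements the full analysis pipeline for a thrice-weekly,
multi-visit CVL cohort:

- **Panel registry** for 46 analytes (45 immune proteins + total protein)
  with per-analyte quantification limits (`default_panel()`,
  `load_panel()`).
- **Calibrated synthetic cohort generator** with truth tables for
  estimator validation (`sim_config()`, `simulate_cohort()`).
- **Healthy-visit filter cascade** — attended, non-menstruating, negative
  for HSV shedding / BV / yeast, in women negative for CT/NG/TV
  (`flag_healthy_visits()`, `filter_report()`).
- **Censoring policy**: half-LLOQ / twice-ULOQ substitution, detection
  proportions, and strict >85% routing between continuous and
  detected/undetected modelling (`impute_censored()`, `select_route()`).
- **Cycle-phase classification** from urinary PDG/CRT ratios (modified
  Kassam method, strict 4.0 threshold; `call_cycle_phases()`).
- **Variance components**: own ANOVA and profile-REML estimators of the
  one-way random-intercept model, ICC with Wald interval, F test
  (`anova_components()`, `reml_fit()`, `icc_scan()`).
- **Signature scans**: per-analyte random-intercept linear (lme4 REML) or
  logistic (adaptive Gauss–Hermite quadrature) models against 13
  exposures with a priori confounder sets (`signature_scan()`).
- **Reporting**: analyte summary tables, within-panel Spearman
  cross-reactivity screen, cohort table, forest/ICC plots, broom-style
  `tidy()`/`glance()` methods, and a one-call pipeline
  (`run_pipeline()`) plus a thin command-line interface
  (`inst/cli/cvimmune.R`).

## The model

For analyte *a*, woman *i*, visit *j*, on well-detected analytes:

    log10 y_aij = mu_a + b_ai + e_aij,   b_ai ~ N(0, sigma_B^2),  e_aij ~ N(0, sigma_W^2)

The intraclass correlation coefficient

    ICC_a = sigma_B^2 / (sigma_B^2 + sigma_W^2)

is the share of total log10-scale variance attributable to stable
between-woman differences. Exposure effects enter as fixed effects on the
same random-intercept structure; analytes detected in ≤85% of samples
are modelled as detected/undetected with a random-intercept logistic
model instead.

## Worked example

```r
library(cvimmune)

co <- simulate_cohort(sim_config(n_women = 20), seed = 4)
flags <- flag_healthy_visits(co$visits, co$women)
filter_report(flags)
#> # A tibble: 4 × 3
#>   step                 n pct_of_previous
#>   <chr>            <int>           <dbl>
#> 1 scheduled          240              NA
#> 2 attended           217              90
#> 3 non_menstruating   192              88
#> 4 healthy             77              40

m <- subset(co$measurements, analyte == "IL-8")
reml_fit(log10(m$value), m$woman_id)
#> <cvl_vc>
#>    sigma_b2 = 0.1088, sigma_w2 = 0.1548, ICC = 0.413
#>    F = 7.79, p = 3.82e-15 (20 women, 192 obs)
```

A full run — filter, phases, ICC table, signature scans, summary tables,
manifest — is one call:

```r
res <- run_pipeline(sim_config(), outdir = "run1", seed = 1,
                    exposures = c("phase", "dmpa", "psa"))
icc_summary(res$vc$icc)
plot_icc(res$vc)
autoplot(res$scans$dmpa)
```

or from the shell:

```sh
Rscript inst/cli/cvimmune.R run --seed 1 --outdir run1 --exposures phase,dmpa,psa
```

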