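# growthsens

Sensitivity analysis for linear latent growth models with missing data.

Longitudinal panels in education and psychology routinely lose a large
share of their participants to dropout and wave non-response. Estimates of
change over time then hinge on an untestable assumption: is missingness
ignorable given the observed data (MAR), or related to the very values
that went unobserved (MNAR)? `growthsens` is for researchers who want to
stop guessing and instead *report how much the answer moves* across
techniques that assume different mechanisms — the workflow methodologists
recommend but applied studies rarely run.

For a three-wave (or T-wave) outcome with slope loadings
`λ = (0, λ₂, …, λ_T)` the model is

    y_it = I_i + λ_t · S_i + ε_it,   (I_i, S_i) ~ N((μ_I, μ_S), Ψ),
    ε_it ~ N(0, θ_t),

with Ψ = [[ψ_II, ψ_IS], [ψ_IS, ψ_SS]]. The package fits this model under
eight missing-data techniques and classifies their agreement:

* **LD** — listwise deletion (assumes MCAR),
* **ML / MLaux** — full-information maximum likelihood, without / with
  saturated-correlates auxiliary variables (assume MAR),
* **MI / MIaux** — joint-normal multiple imputation (data augmentation,
  Rubin's rules), auxiliaries optionally in the imputation model
  (assume MAR),
* **H&G / Neighbouring / Available** — pattern-mixture models for dropout
  with a shared variance structure: the two-group completers-vs-dropouts
  model and the three-group identifying-restriction models (assume MNAR;
  a complete-case restriction exists behind an explicit opt-in).

Around the fits: Little's MCAR chi-square test via EM, dropout-group
ANOVA with Tukey follow-up, auxiliary-variable screening (Nagelkerke
pseudo-R², outcome R², |r| ≥ .10 counts), Rubin pooling, delta-method
pooling of pattern-mixture means with multinomial weight uncertainty, a
reporting-guideline classifier, and a seeded synthetic-data generator
with controllable MCAR/MAR/MNAR dropout for validation against known
truth.

## Worked example

Emulate a heavily incomplete three-wave cohort whose dropout is driven by
the (unobserved) latent slope, then run the full sensitivity analysis:

```r
library(growthsens)

g <- generate_study_dataset(seed = 2026, mechanism = "MNAR")
response_summary(g$data)
#> observed per wave: 1033, 434, 270
#> complete cases: 215 of 1072 (20.1%)

little_mcar_test(g$data)
#> Little's MCAR test: Chi2 = 8.715, df = 9, p = 0.464
#> ( 7 missingness patterns )

spec <- growth_spec(c(0, 1.17, 2.17))   # 14- and 12-month wave spacings
sens <- run_sensitivity(g$data, spec,
                        config = list(seed = 2026, m = 20, burn_in = 200,
                                      thin = 20, scale_label = "emulated"))
sens
#>     technique             mu_I           mu_S           psi_II        psi_SS
#>            LD 3.276 (0.053)***  0.009 (0.027) 0.333 (0.077)*** 0.000 (0.032)
#>            ML 3.246 (0.026)*** -0.012 (0.020) 0.413 (0.067)*** 0.010 (0.030)
#>         MLaux 3.246 (0.026)*** -0.016 (0.020) 0.412 (0.067)*** 0.009 (0.030)
#>            MI 3.244 (0.028)*** -0.011 (0.023) 0.433 (0.057)*** 0.023 (0.025)
#>         MIaux 3.247 (0.028)*** -0.020 (0.024) 0.423 (0.058)*** 0.018 (0.025)
#>           H&G 3.248 (0.026)*** -0.037 (0.033) 0.414 (0.067)*** 0.010 (0.030)
#>  Neighbouring 3.248 (0.026)*** -0.044 (0.036) 0.414 (0.067)*** 0.010 (0.030)
#>     Available 3.248 (0.026)*** -0.025 (0.025) 0.414 (0.067)*** 0.010 (0.030)

classify_agreement(sens)[, c("parameter", "category", "option")]
#>  parameter category option
#>       mu_I        =      2
#>       mu_S        =      2
#>     psi_II        =      2
#>     ...
```

Reading the table: the generating truth has a mean slope of −0.06 per
year, but decliners were deleted preferentially, so every MAR-class
estimate is attenuated toward zero (−0.011 to −0.020) while the
pattern-mixture models, which stratify by dropout group, sit closer to
the truth (−0.025 to −0.044). Listwise deletion shows the classic
complete-case signature: a shrunken intercept variance (0.333 vs ≈ 0.41)
from analysing a selected subsample. Note also that Little's test did
*not* reject MCAR (p = .46) even though the mechanism is MNAR by
construction — a non-significant MCAR test is no licence to skip the
sensitivity analysis. In this particular draw no parameter changes
significance across classes, so every parameter classifies as guideline
option 2 ("MAR models in detail; add: not contradicted by MNAR"); with a
stronger divergence the slope classifies as option 1 and the classifier
tells you to present both model classes and choose cautiously.

`render_report(sens, classify_agreement(sens), format = "csv")` writes
the same content as a deterministic machine-readable report.

## Package layout

* `R/dataio.R` — wide-CSV reader/writer, missingness patterns, response
  summaries
* `R/synthetic.R` — growth simulator, MCAR/MAR/MNAR masking, study preset
* `R/diagnostics.R` — EM for the incomplete multivariate normal, Little's
  test, dropout-group ANOVA, auxiliary screen
* `R/lgm.R` — growth spec, implied moments, FIML likelihood and fitters
* `R/imputation.R` — data-augmentation imputer, per-imputation fits,
  Rubin pooling
* `R/pattern_mixture.R` — dropout grouping, two-group and
  identifying-restriction models, proportion-weighted pooling
* `R/sensitivity.R` — orchestration, agreement classification, reports

The methods vignette (`vignettes/missing-data-sensitivity.Rmd`) documents
the model, the assumptions behind every technique, the generator's design
and its limits, and all numerical choices.
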