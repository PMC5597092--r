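---
title: "Sensitivity analysis for latent growth models with missing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity analysis for latent growth models with missing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Longitudinal panels in education and psychology almost always lose
participants: students drop out of a programme, skip a questionnaire wave,
or leave items blank. Whether the resulting estimates of *change over time*
can be trusted depends on why the data are missing. Three mechanisms are
usually distinguished:

* **MCAR** — missing completely at random: missingness is unrelated to the
  data. Testable (against MAR) with Little's chi-square test.
* **MAR** — missing at random: missingness depends only on values that were
  observed (an earlier wave's score, a covariate). Not testable against
  MNAR.
* **MNAR** — missing not at random: missingness depends on the unobserved
  values themselves, e.g. students whose scores were *about to* drop are
  the ones who disappear.

Because MAR versus MNAR cannot be decided from the data, the defensible
practice is a *sensitivity analysis*: estimate the same growth model under
several techniques whose validity rests on different mechanisms, and report
how much the substantive conclusion moves. `growthsens` packages that
workflow for the linear latent growth model, together with a synthetic-data
generator that makes every stage testable against known truth.

## The model

For subject $i$ at wave $t$ with slope loading $\lambda_t$,

$$y_{it} = I_i + \lambda_t S_i + \varepsilon_{it}, \qquad
  (I_i, S_i) \sim N\!\left(\begin{pmatrix}\mu_I\\\mu_S\end{pmatrix},
  \begin{pmatrix}\psi_{II} & \psi_{IS}\\ \psi_{IS} &
  \psi_{SS}\end{pmatrix}\right), \qquad
  \varepsilon_{it} \sim N(0, \theta_t).$$

The implied moments are $\mathrm{E}(y_t) = \mu_I + \lambda_t\mu_S$ and
$\mathrm{Cov}(y_t, y_s) = \psi_{II} + \lambda_t\lambda_s\psi_{SS} +
(\lambda_t + \lambda_s)\psi_{IS} + [t{=}s]\,\theta_t$. Loadings are in
years since the first wave; with unequal spacings of 14 and 12 months they
are $(0, 14/12, 14/12 + 1) = (0, 1.17, 2.17)$, so $\mu_S$ is change per
12 months. `growth_spec()` fixes the skeleton: per-wave or homogeneous
residual variances, and whether $\psi_{SS}$ and $\psi_{IS}$ are free.
Fixing $\psi_{IS} = 0$ (`cov_IS_free = FALSE`) mirrors the common reporting
convention of only freeing the covariance once both variances are of
interest.

## The eight techniques

| label | assumption | implementation |
|---|---|---|
| LD | MCAR | ML on complete cases only |
| ML | MAR | full-information ML over each subject's observed waves |
| MLaux | MAR | FIML with saturated-correlates auxiliary variables |
| MI | MAR | joint-normal multiple imputation over the waves, Rubin pooling |
| MIaux | MAR | as MI, auxiliaries added to the imputation model only |
| H&G | MNAR | two-group pattern mixture, shared variance structure |
| Neighbouring | MNAR | three-group pattern mixture, neighbouring-case restriction |
| Available | MNAR | three-group pattern mixture, available-case restriction |

A complete-case restriction is also implemented but runs only behind
`allow_complete_case = TRUE`: equating the earliest dropouts' trend to the
completers' trend is usually the least defensible restriction exactly when
dropout is suspected to be outcome-related, so it must be an explicit
choice.

**FIML.** Each subject contributes the normal log-density of their observed
sub-vector under the corresponding sub-moments; subjects observed at a
single wave still inform the means and variances. Standard errors come from
the observed information matrix (central finite differences, step
$10^{-5}\max(|\hat\theta|, 1)$), with normal-theory $z$ and $p$.

**Saturated correlates.** Auxiliaries join the outcome vector; their means,
covariances and cross-covariances with the waves are all free, so the
growth structure is untouched while the auxiliaries sharpen the implicit
prediction of what is missing. A warning cites the heuristic of keeping the
number of auxiliaries below one third of the complete cases.

**Multiple imputation.** A data-augmentation sampler for the unstructured
multivariate normal: the I-step draws missing cells from their conditional
normal, the P-step draws $(\mu, \Sigma)$ from the Jeffreys-prior posterior
(inverse-Wishart on $n-1$ degrees of freedom). Defaults are $m = 100$
completed datasets, 500 burn-in iterations and 100 between-draw thinning;
$m$ follows the tutorial convention for heavily incomplete data, while
burn-in and thinning are deliberately generous for a sampler whose
autocorrelation is modest — they can be reduced for exploratory runs.
Pooling uses the classical rules: $\bar Q$, $T = W + (1 + 1/m)B$, and
$\nu = (m-1)(1 + W/((1+1/m)B))^2$ degrees of freedom without the
small-sample correction (documented; the correction matters for tiny $m$,
not $m = 100$).

**Pattern mixture.** Subjects are stratified by dropout pattern —
administrative enrolment labels when available (the trustworthy "true"
dropout record), otherwise the last observed wave. All groups share
$\Psi$ and $\Theta$ (the completers identify what the incomplete groups
cannot); latent means are group-specific. The wave-1-only group's slope
mean is substituted *inside the likelihood* by its identifying restriction
(complete-case, neighbouring-case, or the case-weighted available-case
average), so the constraint holds exactly rather than approximately.
Population values are the proportion-weighted averages of the group means;
their delta-method standard errors combine the parameter covariance with
the multinomial covariance of the estimated proportions
($C_{gg} = \pi_g(1-\pi_g)/N$, $C_{gh} = -\pi_g\pi_h/N$). Because the paper
trail rarely states whether proportions were treated as known, a
fixed-weights standard error is reported alongside.

## Diagnostics before modelling

`little_mcar_test()` compares each missingness pattern's observed means
with the EM grand means, scaled by the EM covariance; df is the total
number of observed variables over patterns minus the number of variables.
`dropout_group_anova()` compares dropout groups wave by wave (Tukey HSD
follow-up — the convention adopted here since pairwise comparisons need
*some* correction and none is canonical). `screen_auxiliaries()` rates
candidate auxiliaries by Nagelkerke pseudo-$R^2$ for predicting
missingness, linear $R^2$ for predicting the outcome, and the count of
auxiliaries correlated at $|r| \ge .10$. A per-wave t-test screen
(`mcar_t_tests()`) is reported descriptively but never used for gating:
the chi-square test is the decision tool, and even a non-significant result
does not establish MCAR.

## Reading the comparison

`classify_agreement()` operates on significance concordance at
$\alpha = .05$ (CI overlap is the secondary, magnitude-based check):

1. MAR-class and MNAR-class techniques disagree → present both, choose
   cautiously.
2. The classes agree → report the MAR models in detail, note the MNAR
   models do not contradict them.
3. ML alone disagrees while MI, MLaux, MIaux and the MNAR models agree →
   prefer the MI/MLaux/MIaux and MNAR results (ML and MI should converge
   for large $m$; when they do not, the majority voice is the safer
   report).

$p$-values in $[.05, .10)$ are flagged as borderline ("at the verge"), not
significant. Listwise deletion is additionally flagged when its confidence
interval excludes the FIML estimate — the signature of complete-case
selection bias. Splits matching no option (e.g. MI-class significant, ML
borderline, MNAR not) are reported as the raw significance pattern with no
option forced; inventing a rule the guidelines do not state would be false
precision.

## The synthetic generator

`simulate_growth()` draws trajectories from the model above;
`impose_missingness()` deletes values under a chosen mechanism. Dropout is
a per-wave logistic hazard given survival (monotone attrition, starting at
wave 2); intermittent non-response is an independent Bernoulli overlay.
The hazard predictor is nothing (MCAR), the most recent observed score or
a fully observed auxiliary (MAR), or the subject's latent slope / current
unobserved score (MNAR). The per-subject latent values are returned on a
separate channel for oracle checks and never reach the estimators.

`study_emulation_preset()` freezes the conditions of a three-wave cohort
with heavy attrition: $n = 1072$ subjects each observed at least once,
loadings $(0, 1.17, 2.17)$, growth parameters
$\mu_I = 3.28, \mu_S = -0.06, \psi_{II} = 0.41, \psi_{SS} = 0.02,
\psi_{IS} = -0.01, \theta = 0.30$ (Likert subscale means around 3 with
SD $\approx 0.84$ and a slow decline), and dropout plus non-response rates
calibrated once, by simulation before freezing, so that roughly 21% of
subjects are complete and the per-wave observed counts fall near
1029/442/278. The MAR variant routes the hazard through a fully observed
auxiliary (`gpa`, correlated .35 with the intercept): this keeps the MAR
predictor observed in the output even for subjects with wave-1
non-response, which a previous-score predictor cannot. The MNAR variant
loads the hazard negatively on the latent slope, so decliners drop out.

What the generator does *not* emulate: Likert discreteness and bounds
(values are continuous and unbounded), item-level non-response (subscale
scores are taken as given; the upstream rule that a subscale score exists
only when all its items were answered is documented, not implemented),
non-normal latent distributions, and cohort-level events that make
missingness dependent across subjects. Passing tests therefore certify the
estimators under a normal, independent-subjects world — not robustness to
violations of it.

## Numerical choices

* EM for the unstructured normal: relative log-likelihood change
  $< 10^{-10}$ or 5000 iterations; deterministic start from complete-case
  moments (available-case fallback); the log-likelihood trace is kept and
  asserted non-decreasing in tests.
* Optimiser: `nlminb` quasi-Newton with variance parameters bounded below
  at $10^{-8}$; three deterministic restarts from moment-based starts with
  variance entries jittered by factors (1, 1.4, 0.6); best log-likelihood
  wins, ties to the first, followed by one polishing pass from the winning
  optimum. A non-positive-definite implied covariance returns a large
  penalty, never an error, during the search. "Singular convergence" — the
  optimiser's label for an optimum with a flat or boundary direction, e.g.
  a variance estimated at zero — is reported as converged, since the
  iterates have stabilised; genuine failures stay flagged.
* Degenerate noise-free input (zero sample covariance) makes the
  likelihood unbounded in the variances; the variances are then started
  and left on their lower bounds and the means are recovered exactly.
* A non-invertible observed information matrix falls back to a
  pseudo-inverse with a warning; negative curvature yields `NA` standard
  errors rather than fabricated ones.
* Sampler divergence (a non-positive-definite posterior draw) retries with
  a small ridge and fails loudly after bounded retries.
* One master integer seed drives everything; sub-streams are derived with
  `derive_seed()` so that, e.g., the two imputation runs inside
  `run_sensitivity()` are independent but reproducible.

## Problem sizes used by the test suite

The suite exercises calibration claims at sizes chosen to keep the whole
run comfortably on one CPU: parameter recovery uses 200 replicates at
$n = 1000$; the bias-direction sign tests use 200 replicates at $n = 400$;
the type-I-error check of the MCAR test uses 1000 replicates at $n = 300$;
the MNAR-divergence sign check uses 100 replicates at the full emulated
cohort size. Monte-Carlo tolerances are stated in the tests as multiples
of the corresponding simulation standard errors, never as free constants.

## Known limitations

* Estimation is normal-theory throughout; no robust (sandwich) errors, no
  fit indices, no categorical-outcome support.
* Selection models (the other MNAR family) and latent-class pattern
  mixtures are out of scope; the pattern-mixture family with explicit
  restrictions was chosen precisely because its untestable assumptions are
  visible and swappable.
* The two-group and three-group pattern-mixture models share the full
  variance structure across groups; per-group residual variances exist as
  an option but are off by default, and intercept variances are always
  shared.
* With only three waves, the two-group model and the restriction models
  borrow almost the same information, so their results track each other
  closely; more waves would separate them.
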