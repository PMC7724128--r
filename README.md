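# doublelist

Analysis of (double) list experiments for the measurement of sensitive
health behaviours.

Self-reports of stigmatised behaviours — condom use by sex workers,
intimate partner violence (IPV), illicit drug use — suffer from social
desirability bias: respondents over-report desirable acts and under-report
stigmatised ones, so prevalence estimates from direct survey questions can
be badly wrong. The **list experiment** (item count technique) elicits the
behaviour indirectly: a respondent is read a short list of non-sensitive
statements and reports only *how many* they agree with. A randomly chosen
half (the treated group) gets the same list plus the sensitive statement.
Because no one reveals which statements they agreed with, the treated
respondents can include the sensitive item truthfully, and the prevalence of
the behaviour is identified by the treated-minus-control difference in mean
counts.

`doublelist` implements the full analysis pipeline for the **double-list**
variant, in which two different lists of non-sensitive items share one
sensitive item and every respondent is treated on exactly one list and is a
control on the other — an internal replication that also roughly halves the
estimator variance. The package is aimed at epidemiologists and survey
methodologists who design or analyse such experiments.

## The model

For list *l* ∈ {A, B}, with Yᵢ the reported count and Tᵢ the treatment
indicator,

    Yᵢ = λ + βˡ Tᵢ + εᵢ                                   (single list)
    Yᵢ = λ + β Tᵢ + 1(List = A) + εᵢ                      (pooled, SE clustered by respondent)

β is the prevalence of the sensitive behaviour (OLS with one binary
regressor is exactly the difference in arm means). Subgroup prevalences
come from adding a binary moderator S and its interaction with T: β is the
prevalence at S = 0 and β + α the prevalence at S = 1. Three Wald tests are
provided: list estimate vs. the direct self-report (the misreporting test),
βᴬ = βᴮ (internal consistency, via a stacked regression with
respondent-clustered covariance), and subgroup variants of both.

Identification rests on three assumptions, each with a diagnostic:

1. **Randomisation balance** — covariate mean comparisons plus a joint
   F test (`balance_test`);
2. **No design effect** — adding the sensitive item must not change answers
   to the non-sensitive items, which implies two families of stochastic-
   dominance inequalities between the treated and control count CDFs,
   tested with one-sided z statistics and a Bonferroni-corrected minimum p
   (`design_effect_test`);
3. **No ceiling/floor pressure** — the control-arm shares at Y = 0 and
   Y = J must be small or treated respondents at the extremes lose privacy
   (`ceiling_floor`).

Finally, the **bias–variance trade-off**: the direct question is precise
but biased by B; the list estimate is unbiased but noisy, with variance
falling like C/(N−1), C = π\*(1−π\*) + 4·Var[Y(0)]. `nmin_solve` solves the
MSE-crossover quadratic

    B² x² + [(2π* − 1)B − 4·Var[Y(0)]] x − C = 0,   x = N − 1,

for the minimum sample size N_min above which the list experiment
outperforms the direct question.

A synthetic respondent simulator (`simulate_survey`, with `study_preset`
configurations emulating a Senegal condom-use survey, n = 495, π\* = 0.80,
and a Burkina Faso IPV survey, n = 1706, π\* = 0.24) generates data with
the assumed statistical structure — and with controllable violations — so
the whole pipeline is testable without access to field data.

## Worked example

```r
library(doublelist)
cfg    <- study_preset("burkina", seed = 42)   # IPV-style survey, n = 1706
report <- run_pipeline(cfg, subgroups = "polygamous", quiet = TRUE)
report$table1
#        scope n_obs mean_treated mean_control estimate     se ci_low ci_high
#       List A  1706         1.73         1.47    0.256 0.0385  0.180   0.331
#       List B  1706         1.77         1.46    0.307 0.0399  0.229   0.385
#  Lists A & B  3412         1.75         1.47    0.281 0.0245  0.233   0.329
#  direct misreporting  p_value
#   0.061        0.195 5.80e-07
#   0.061        0.246 1.05e-09
#   0.061        0.220 2.03e-18
```

Each list recovers a prevalence near the simulated truth of 0.24 while the
direct question yields 0.061 — an under-reporting gap of about 20
percentage points, flagged by the Wald p-values. `report$table3` shows the
double-list design cutting the standard error by roughly 36–39% relative to
either single list, and `report$table4` gives the minimum sample size at
which the list experiment beats the direct question. The sample-size tool
also works directly from published summary statistics:

```r
nmin_solve(sample_size_problem(0.800, 0.673, direct_mean = 0.968))
# Minimum sample size: N_min = 94
#   quadratic 0.028224 x^2 + -2.591200 x + -2.852000 = 0, root x = 92.896 (C = 2.852)
#   inputs: pi* = 0.800, Var[Y(0)] = 0.673, B = 0.168
```

With a misreporting bias of 0.168, fewer than a hundred respondents already
make the noisy-but-unbiased list estimate the better instrument.

## Package layout

- `R/synthetic-cohort.R` — simulator: list designs, behaviour/misreporting
  models, assumption violations, study presets;
- `R/survey-data.R` — CSV input/validation, wide ⇄ long reshaping;
- `R/estimation.R` — prevalence estimators and Wald tests;
- `R/diagnostics.R` — balance, design-effect and ceiling/floor checks;
- `R/design-tools.R` — efficiency accounting and N_min;
- `R/reporting.R` — `run_pipeline()` / `render_tables()` orchestration;
- `vignettes/doublelist-methods.Rmd` — the methods vignette.
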