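---
title: "Methods: double-list experiment analysis and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double-list experiment analysis and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doublelist)
```

# The estimand and the design

A list experiment asks a respondent to report only the *number* of
statements they agree with out of J non-sensitive items; a randomly treated
half receives the same items plus one sensitive statement. If treatment
assignment is random, the sensitive item does not alter answers to the
other items, and nobody sits at the ends of the count scale, then

$$\beta = E[Y \mid T=1] - E[Y \mid T=0]$$

is the prevalence of the sensitive behaviour. We estimate it by OLS of the
count on a treatment dummy, which reproduces the difference in arm means
exactly; the algebra is trivial, but the regression form makes robust and
clustered covariances, subgroup interactions and Wald contrasts uniform.

The double-list design uses two item lists sharing the sensitive item.
Group 1 (odd arrival numbers) is treated on list A and control on list B;
group 2 the reverse. Every respondent therefore contributes one treated and
one control observation, and the pooled regression

$$Y_i = \lambda + \beta T_i + \mathbf{1}(\mathrm{List}=A) + \varepsilon_i$$

uses both, with standard errors clustered at the respondent level. With
equal group sizes the pooled $\hat\beta$ is exactly the average of the two
single-list estimates.

# Standard errors

* Single-list fits default to heteroskedasticity-robust (HC1) covariance:
  the treated arm's count adds a Bernoulli component, so arm variances
  differ by construction. Classical covariance is available for comparison.
* Pooled fits default to the cluster-robust sandwich with the conventional
  small-sample factor $\frac{G}{G-1}\cdot\frac{N-1}{N-K}$ over respondents
  $G$; the package delegates the sandwich algebra to the `sandwich` package
  and the tests cross-check it against an explicitly hand-rolled CR1
  estimator.
* All inference uses the normal reference distribution. The designs this
  package targets have hundreds to thousands of respondents, where the
  normal and t references are indistinguishable; no t correction is
  applied. Confidence intervals are fixed at 95%.

# The Wald tests

**Misreporting.** The contrast between the direct-question proportion
$\hat p$ and the list estimate $\hat\beta$ is tested with
$z = (\hat p - \hat\beta)/\sqrt{\mathrm{se}_\beta^2 + \hat p(1-\hat p)/n}$.
Treating the two as independent is the default because it is computable
from published summary statistics alone. Since the same respondents answer
both instruments, a second method ("stacked") estimates the covariance
between the two statistics from respondent-level influence functions; in
practice the covariance is small (the direct answer correlates with the
latent trait, which enters the list count only through the treated half)
and the two methods agree closely.

**Internal consistency.** $\hat\beta^A = \hat\beta^B$ is tested by default
from a stacked regression with list-specific treatment effects and
respondent-clustered covariance, because each respondent appears in both
estimates in opposite roles, making the two estimates negatively
correlated; ignoring that correlation (the independent option, again the
only one available from printed estimates) is conservative here. Subgroup
versions restrict to the S = 1 respondents, which by the saturation
identity equals the interaction-model prevalence $\beta + \alpha$.

# Assumption diagnostics

**Balance.** Per-covariate two-sample z tests (unpooled variances) between
the parity groups, plus a joint F test from a linear probability model of
the group indicator on all covariates. Categorical covariates are expanded
to indicators against the modal reference level.

**Design effects.** If the sensitive item does not change non-sensitive
answers, the control and treated count CDFs obey
$F_0(y) \ge F_1(y)$ for $y = 0..J$ and $F_1(y) \ge F_0(y-1)$ for
$y = 1..J+1$. The package tests exactly these printed inequalities with
one-sided z statistics using unpooled binomial variances and summarises
them by the Bonferroni-corrected minimum p over the $2(J+1)$ inequalities
(the top inequality of the second family is vacuous — both CDFs equal 1 —
and is reported with p = 1). A likelihood-based design-effect test would be
an alternative; the moment/CDF formulation was chosen because it maps
one-to-one onto the identifying inequalities and needs no distributional
model of the counts. Degenerate boundary cells (estimated variance zero)
return p = 0 when the inequality is strictly violated and p = 1 otherwise.
No continuity correction is applied by default.

**Ceiling and floor.** The control-arm shares at $Y=0$ and $Y=J$ are
reported with warning thresholds of 5% and 10% respectively — the bands
within which well-behaved published applications of the method fall — both
configurable.

# The bias–variance minimum sample size

With true prevalence $\pi^*$, direct-question bias $B$ and control-count
variance $\mathrm{Var}[Y(0)]$, the direct question's MSE is
$B^2 + p(1-p)/N$ (with $p = \pi^* - B$) while the single-list experiment's
is $C/(N-1)$, $C = \pi^*(1-\pi^*) + 4\,\mathrm{Var}[Y(0)]$. Setting them
equal in $x = N-1$ yields

$$B^2x^2 + \big[(2\pi^*-1)B - 4\,\mathrm{Var}[Y(0)]\big]x - C = 0,$$

whose positive root gives $N_{\min} = \mathrm{round}(x) + 1$. Numerical
choices: the quadratic is solved in closed form from the discriminant
(never iteratively), coefficients are never rounded at intermediate steps,
and the nearest-integer convention is used for the final count — the tests
verify the whole construction against a brute-force grid search for the MSE
crossover, which agrees to within one respondent across a 100-point
parameter grid. $B = 0$ has no finite solution (the unbiased precise
instrument always wins) and is signalled as an error. The formula is
applied verbatim with $p = \pi^* - B$ regardless of the misreporting
direction, i.e. also for over-reported behaviours where the observed direct
mean is $\pi^* + B$; this keeps results computable from the standard
summary triple $(\pi^*, \mathrm{Var}[Y(0)], B)$ and is documented rather
than hidden. Because the leading coefficient is $B^2$, the root is
sensitive to rounding in $B$: with inputs printed at three decimals the
computed $N_{\min}$ can differ from a full-precision computation by a few
respondents when $B$ is small.

# The synthetic cohort

The simulator generates, per respondent: a latent sensitive trait
$Z \sim \mathrm{Bernoulli}(\pi_i)$ (with optional additive subgroup
shifts), independent Bernoulli item agreements for both lists, per-list
counts (the treated list adds $Z$), and a direct report equal to $Z$
distorted by the misreporting model ($E[\mathrm{direct}] = \pi(1-q)$ under
under-reporting, $\pi + q(1-\pi)$ under over-reporting). Group assignment
alternates with row order, mirroring arrival-parity randomisation; no
enumerator structure is modelled.

Two presets encode the study conditions the package is validated against:
a condom-use survey (n = 495, $\pi^* = 0.80$, direct report ≈ 0.968, so
q = 0.84 over-reporting) and an IPV survey (n = 1706, $\pi^* = 0.24$,
direct report ≈ 0.054, so q = 0.775 under-reporting). Both use J = 3 items
per list with agreement profile (0.9, 0.5, 0.1) — the "most agree / most
disagree" guideline; the middle value is a choice, as published designs
report only the qualitative profile.

**Within-respondent correlation.** Field data show double-list standard
errors falling by substantially more than the $1 - 1/\sqrt 2 \approx 29\%$
that independent item answers would allow: reported reductions around
35–45% imply positively correlated counts across a respondent's two lists,
which makes the two single-list estimates negatively correlated and the
pooled estimate better than the independence bound. The simulator therefore
draws a respondent-level agreement propensity $u_i \sim N(0, 0.15^2)$ added
to every item probability on both lists (clamped to $[0,1]$). The default
0.15 was derived from that observed reduction band: with cross-list count
covariance $\approx J^2 s^2$ and per-arm variances near 0.5–0.7, a ~40%
reduction requires $s \approx 0.15$. Setting `respondent_sd = 0` restores
the fully independent model (used by the tests that check the control count
against its exact Poisson-binomial law).

**Violations for testing the diagnostics.** `design_effect_shift` adds a
constant to the treated respondents' item probabilities (a design effect by
construction; negative shifts — treated respondents deflating their
non-sensitive answers — are the variant the CDF inequalities detect most
directly). `liar_mode = "deflate_at_ceiling"` makes a treated trait-holder
who would report $J+1$ report $J$ instead, the classic ceiling violation.
Shifted probabilities are clamped with a warning.

What the simulator does **not** emulate: interviewer effects, item-order
effects, non-response, measurement error in the marble-count mechanics, and
any dependence of misreporting on covariates. Passing tests therefore
demonstrate the estimators' correctness under the design's identifying
assumptions and realistic cross-list correlation — not robustness of the
method on field data where those assumptions may fail.

# Problem sizes used in validation

The test suite validates parameter recovery and CI coverage of the pooled
estimator over 500 simulated surveys at the larger study's size (n = 1706),
checks the design-effect test's level over 500 null replicates and its
power over 200 replicates with a −0.15 shift at the same size, verifies the
double-list efficiency gain over 200 replicates, and sizes the
internal-consistency test over 1000 replicates at n = 400. Exact identities
(OLS vs. cell means, pooled vs. averaged single-list estimates, the
sample-size quadratic vs. printed worked rows) are asserted at machine
precision or to the printed number of decimals.

# Known limitations

* Only the difference-in-means family of estimators is provided; maximum
  likelihood and nonlinear least-squares list-experiment estimators are out
  of scope, as is covariate adjustment beyond one binary interaction.
* The design-effect test is the moment/CDF formulation; it is conservative
  under Bonferroni correction and its per-inequality normal approximation
  is rough in tiny arms.
* Single-list data are supported by leaving one count missing per
  respondent, but the efficiency and internal-consistency machinery
  requires complete double-list data.
* The sample-size quadratic treats $\pi^*$ as known (it is itself a noisy
  list estimate); no uncertainty is propagated into $N_{\min}$.
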