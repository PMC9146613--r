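---
title: "Models and methods: GA dating uncertainty and predictor performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: GA dating uncertainty and predictor performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gadating)
```

## The model

Spontaneous preterm birth (sPTB) is defined on the gestational-age (GA)
scale: a delivery before 37 completed weeks (259 days). GA itself is an
estimate. The package models each dating method's due-date error as a
zero-mean Gaussian whose standard deviation comes from the guideline
convention that a method's published accuracy — the half-width $h$ of a
95% confidence interval — is a two-standard-deviation interval:

$$\varepsilon_m \sim N(0, \sigma_m^2), \qquad \sigma_m = h_m / 2 .$$

Defaults, in days: 1st-trimester ultrasound $h=7$ ($\sigma=3.5$), early
2nd-trimester $h=10$ ($\sigma=5$), late 2nd-trimester $h=14$
($\sigma=7$), 3rd-trimester $h=21$, known LMP $h=29$ ($\sigma=14.5$),
LMP confirmed by ultrasound $h=14$ ($\sigma=7$). The 53-day interval
reported for uncertain LMP recall is accepted by
`dating_error_model(c(LMP_ONLY = 53))` but is not a default: the
simulations concern LMP dates good enough to survive ultrasound
confirmation, which derive from the known-LMP spread.

### Confirmed-LMP error

A clinical protocol keeps an LMP date only if it falls strictly within a
tolerance of an ultrasound date (7/10/14/21 days by ultrasound window;
ties go to ultrasound). With independent errors
$X \sim N(0, \sigma_{LMP}^2)$ and $Y \sim N(0, \sigma_{US}^2)$ sharing
the same centre, confirmation is the event $|X - Y| < \tau$, and the
quantities of interest are

$$p_{acc} = P(|X - Y| < \tau), \qquad
  \sigma_{conf} = \mathrm{SD}(X \mid |X - Y| < \tau).$$

`confirmed_lmp_stats()` computes both by Monte Carlo and by a
deterministic route: conditioning on $X = x$, the acceptance probability
is $\Phi\!\big(\tfrac{x+\tau}{\sigma_{US}}\big) -
\Phi\!\big(\tfrac{x-\tau}{\sigma_{US}}\big)$, leaving one-dimensional
integrals evaluated by adaptive quadrature (`stats::integrate`,
rel.tol 1e-10); $E[X \mid acc] = 0$ by symmetry, so the conditional
variance is $E[X^2 \mid acc]$. With $\sigma_{LMP} = 14.5$,
$\sigma_{US} = 5$, $\tau = 10$: $p_{acc} = 0.486$ ("about half") and
$2\sigma_{conf} = 13.78 \approx 14$ days — confirmation shrinks the
29-day LMP interval to 14 days, the value the default error model
assigns to `LMP_CONFIRMED`. Conditioning can only remove variance
($\sigma_{conf} \le \sigma_{LMP}$), and both statistics are monotone in
$\tau$; the test suite checks these properties and the agreement of the
two modes within three Monte Carlo standard errors.

### From weekly counts to a daily birth distribution

National GA-at-birth tables are published per completed week; the
simulation needs days. `interpolate_to_days()` interpolates the
*cumulative* distribution at the week boundaries with a monotone
shape-preserving cubic spline (Hyman filtering of a cubic Hermite
spline) and differences it into daily masses. Interpolating the CDF
rather than the PMF is deliberate: monotone CDF interpolation guarantees
non-negative daily masses and reproduces every week's total share
exactly, which a naive cubic spline through weekly bar heights does not.
Each week's count is treated as mass on $[7w, 7w+7)$ days (completed
weeks). Residual negative mass can only arise from floating-point
rounding; it is clipped and the PMF renormalised, and clipping beyond 1%
of total mass is treated as a pathological-input error rather than
silently repaired.

The bundled table (`synthetic_ga_distribution()`) is a **synthetic**
approximation of the U.S. 2019 singleton GA-at-birth distribution,
constructed once from published marginal shares — ~8.6% preterm, ~6.4%
late preterm (34–36 weeks), ~26.5% early term (37–38), modal week 39 —
over weeks 20–44. It is not an extract of the national natality file,
and analyses meant to reproduce national figures exactly should load the
real weekly table with `read_weekly_counts()`.

### The perfect-predictor experiment

`run_dating_simulation()` isolates the effect of dating error on
*observed* predictor performance. Per replicate (default: 20 replicates
of 0.1% of 3.7 million births ≈ 3,700 subjects):

1. draw true GAs at birth from the daily PMF;
2. assign dating methods — half confirmed-LMP, half pure ultrasound with
   the 1st / early-2nd / late-2nd-trimester shares 37.3 : 11.0 : 2.1
   renormalised to the ultrasound half;
3. add each subject's method-specific Gaussian error and round to whole
   days (classification happens on the integer-day scale; the error
   itself stays continuous);
4. score every birth with the perfect predictor on the **true** GA
   (1 below 259 days, 0 otherwise) and relabel outcomes from the
   **noisy** GA;
5. compute per-group Mann–Whitney AUCs of score against noisy label.

The direction of the comparison is fixed by design: scores follow truth,
labels follow noise. For a two-valued score the ROC has a single
interior vertex and AUC $= (se + sp)/2$; the generic rank-based AUC
routine is required (and tested) to agree with this closed form to
1e-12, and with an exhaustive pairwise-comparison oracle exactly. Group
means are compared with a paired two-sided Wilcoxon signed-rank test
across replicates (the test family is the package's choice; only the
paired design is dictated by the experiment). The ROC band interpolates
each replicate's curve onto a fixed 1-specificity grid (step 0.01) and
takes pointwise 2.5th/97.5th percentiles. A replicate whose noisy labels
collapse to one class within a group is excluded from that group's
summaries and counted.

On the bundled distribution, confirmed-LMP dating (σ = 7 d) pulls the
mean AUC of a *perfect* predictor down to ≈ 0.81 and the ultrasound mix
to ≈ 0.89 (p < 0.001, seeds as in the README). The loss depends mainly
on the probability mass within a few σ of the 259-day boundary, so a
weekly table with a different late-preterm/early-term balance shifts
both numbers together.

### Case-control performance metrics

`performance_report()` evaluates a continuous score at a fixed threshold
(default −1.37, the validated cut-point of the IBP4/SHBG proteomic
predictor, with scores exactly at the threshold called higher-risk —
the boundary convention is fixed and documented, not configurable).
Sensitivity and specificity get Wilson score intervals. PPV and NPV are
anchored to an external prevalence (default 7.3%) because a case-control
sample's case mix estimates nothing:

$$PPV = \frac{se\,p}{se\,p + (1-sp)(1-p)}, \qquad
  NPV = \frac{sp\,(1-p)}{sp\,(1-p) + (1-se)\,p}.$$

Their confidence intervals propagate the binomial variances of $se$
(over cases) and $sp$ (over controls) by the delta method on the logit
scale, holding $p$ fixed; zero cells get a 0.5 continuity correction.
The delta linearization is asymptotic: at counts of a few dozen its
interval endpoints can sit a few hundredths away from a parametric
bootstrap's percentiles (the tests quantify this at small and at 10×
counts). The AUC interval uses DeLong's method via pROC; the point
estimate is the package's own Mann–Whitney statistic, cross-checked
against pROC. The regression test of classification is the
likelihood-ratio chi-square of a single-predictor logistic regression —
for a binary call this equals the G-statistic of the 2×2 table, which
also serves as the closed-form fallback under complete separation. Two
reports are compared metric-by-metric with the CI-containment rule
(significant iff either point estimate falls outside the other's 95%
interval), which is symmetric by construction. Baseline-table
comparisons (`cohort_compare()`) use two-sided Wilcoxon rank-sum tests
for continuous variables and two-sided Fisher exact tests on the 2×K
level table for categorical ones; for 2×2 tables both the sample odds
ratio and Fisher's conditional-MLE odds ratio are reported, since they
differ.

An optional "snap-to-threshold" equivalence rule (scores within a stated
analytic error of the threshold treated as equivalent) is deliberately
not enabled: the analytic-error magnitude of the assay is not published,
so the package has no defensible default and classification is strict.

### Expected label misclassification

For a subject with observed GA at birth $g$ dated with SD $\sigma$, the
posterior probability of being truly term combines the population prior
$\pi(t)$ over integer days with the Gaussian likelihood:

$$P(T \ge 259 \mid g) =
  \frac{\sum_{t \ge 259} \pi(t)\, \phi(g - t; 0, \sigma)}
       {\sum_{t} \pi(t)\, \phi(g - t; 0, \sigma)} .$$

Summing posteriors over sPTB-labelled subjects gives the expected number
of false preterm labels; summing complements over term-labelled subjects
gives expected false terms. Integration is a sum over the prior's
integer-day support (no continuous quadrature; the prior is intrinsically
daily), and $\sigma \le 0.5$ day is treated as exact dating. Subjects
with no recorded dating method fall back to the early-2nd-trimester
ultrasound SD (5 d): unrecorded methods are grouped with the
excluding-LMP population downstream, and the early-2nd value is the
interior of that group's SD range (3.5–7 d). Because term births
outnumber preterm ones roughly nine-fold near the boundary, false
preterm labels dominate false terms — the asymmetry that inflates
apparent false-positive rates of any preterm predictor under poor
dating.

### Synthetic cohorts

`generate_cohort()` builds case-control cohorts with known ground truth
from a Gaussian copula. A latent standard bivariate normal $(Z_1, Z_2)$
with correlation $\rho$ maps $Z_1$ through the GA PMF's quantile
function to the true GA at birth and scales $Z_2$ to the score marginal.
Because the score is linear in the latent pair, the output Pearson
correlation is $\rho \cdot c_1$ with
$c_1 = \mathrm{corr}(Z_1, Q(\Phi(Z_1)))$ a constant of the GA
distribution computed by quadrature, so the latent $\rho$ achieving a
target output correlation is obtained in closed form — no iterative
calibration. Draws are rejection-sampled into exact case/control quotas
(cases = round(n × prevalence), labels from **true** GA < 259 d), which
leaves score-given-GA intact and perturbs the output correlation only
through the mild re-weighting from the PMF's 8.6% preterm mass to the
7.3% target; the recovery tests (±0.03) absorb this.

Observed GA adds method noise (methods drawn at the 49.5 / 37.3 / 11.0 /
2.1% shares plus 0.1% UNKNOWN to exercise the unknown-method path) and
is truncated below at the blood-draw day plus one — a birth cannot be
observed before the draw that enrolled it; the truncation binds only for
extreme preterm births with large negative LMP noise. Blood-draw GA is
uniform on 18^0/7–20^6/7 weeks (days 126–146). The score marginal is
Gaussian (mean −2.0, SD 0.6 on the ln response-ratio scale), placed so
that ~15% of subjects exceed the −1.37 threshold, matching the
threshold's published 15%-risk anchor; no distributional form for real
scores is published, so Gaussian is an assumption, configurable in
`cohort_gen_config()`. BMI is Gaussian (mean 28, SD 5.5, clipped to
15–55), consistent with reported cohort medians/IQRs, and exists only to
exercise BMI-stratified filtering (>22 to ≤37 kg/m²); no other
demographics are modelled.

What passing tests on these cohorts show — and what they do not: the
generator reproduces the *statistical couplings* the pipeline computes
on (prevalence, score–GA correlation, method mix, draw window, label
noise through dating error), so it validates the estimators'
correctness and directional behaviour. It does not emulate assay
analytics, demographic confounding, or the true joint distribution of
biomarker and GA, so numerical performance values on synthetic cohorts
are not estimates of any real predictor's performance.

## Problem sizes and numerical choices

Simulations default to the study-scale conditions (20 × 3,700 subjects;
1e6 Monte Carlo pairs for the confirmed-LMP statistics; 1e5–1e6 draws in
sampling-consistency and posterior-oracle tests). Property tests that
sweep parameter grids use 1–2 million total births per run, which keeps
the full suite under ten seconds while leaving binomial noise well
inside the asserted tolerances. Quadratures use `stats::integrate` at
rel.tol 1e-10 over infinite ranges; the copula attenuation constant uses
a 32,001-point grid on ±8. Noisy GAs are rounded to integer days before
label assignment; dating errors themselves stay continuous. Ties at the
classification threshold are higher-risk; ties at the LMP-confirmation
tolerance go to ultrasound.

## Known limitations

- Dating error is modelled as unbiased Gaussian; recall failure,
  digit-preference and systematic bias in LMP dating are not modelled.
- The misclassification estimator conditions on one observed GA per
  subject; it cannot use within-subject multi-method dating, which the
  underlying data do not provide either.
- The delta-method PPV/NPV intervals are asymptotic; at very small
  cohorts a bootstrap is the better tool.
- The bundled GA distribution is a synthetic approximation; national
  figures require the real weekly table.
- The score↔risk calibration curve beyond the −1.37 ↔ 15% anchor is out
  of scope.
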