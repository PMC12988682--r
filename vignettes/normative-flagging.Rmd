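---
title: "Quantile-regression normative limits: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-regression normative limits: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrlnorm)
```

## The problem

OCT glaucoma reports summarize a scan into thickness metrics -- most
prominently the global circumpapillary RNFL (g-cpRNFL) and the global
ganglion cell layer plus inner plexiform layer (g-GCL+) -- and color
them against a reference database (RDB) of healthy eyes: yellow when
the value falls below the age-conditional 5th percentile of the
reference population, red when it falls below the 1st.  Commercial
RDBs are small (a few hundred eyes), so those percentile lines carry
substantial sampling error, and two RDBs drawn from the same
population can flag *different individual eyes* even when their
overall sensitivity and specificity barely differ.  This package
implements the full analysis pipeline for studying that phenomenon:
percentile-line estimation, a Gaussian null model, flag assignment,
flag-transition accounting between two RDBs, and a Monte Carlo
subsampling study that asks whether a small RDB's percentile lines are
explainable by sample size alone.

## The quantile model

For a metric $y$ and quantile level $\tau$, the quantile regression
line (QRL) is the linear model
$$ Q_\tau(y \mid x) = \beta_0(\tau) + \beta_{\text{age}}(\tau)\,
   \text{age} + \beta_{\text{disc}}(\tau)\, \text{disc area} $$
minimizing the pinball loss $\sum_i \rho_\tau(y_i - x_i'\beta)$,
$\rho_\tau(u) = u(\tau - \mathbf{1}[u<0])$.  Following the covariate
convention of the commercial normative software, all 17 cpRNFL-family
metrics condition on age and disc area; the 7 GCL+-family metrics on
age alone (`metric_registry()`).

The minimization is the classic linear program.  `rq_solve()` solves
its bounded dual ($\max y'a$ s.t. $X'a = (1-\tau)X'\mathbf{1}$,
$0 \le a \le 1$) with a Frisch--Newton primal--dual interior-point
iteration (Mehrotra predictor--corrector), then *polishes* the result:
the LP optimum is attained at a basic solution interpolating $p$
observations, so the $p+4$ observations with the smallest
interior-point residuals are searched for the exact optimal vertex.
The returned loss therefore equals the global optimum to near machine
precision -- the test suite verifies equality against brute-force
enumeration of every basic solution on small instances, and agreement
with an independent implementation on large ones.  When several bases
achieve the same loss (ties are measure-zero for continuous data) the
deterministic candidate order decides, and the fit is marked
`degenerate`.

**Numerical choices.** The interior point iterates until the duality
gap falls below $10^{-12} n(1+\overline{|y|})$; the polish accepts a
vertex only if it does not worsen the loss by more than a $10^{-12}$
relative tolerance.  Singular designs (e.g. all ages equal) are
rejected up front rather than regularized.

### In-sample quantile property

Any exact fit satisfies $\#\{r_i < 0\} \le n\tau$ and
$\#\{r_i \le 0\} \ge n\tau - p$.  This is what makes "flag the lowest
5%" meaningful in-sample, and the property-based tests assert it on
every fit.

## Confidence intervals

`coefficient_ci()` offers two routes.

**Rank inversion** tests $H_0: \beta_j = b$ with the regression
rank-score statistic built from sign scores $a_i = \tau -
\mathbf{1}[r_i < 0]$ of the *refitted* restricted model, standardized
by $\sqrt{\tau(1-\tau)\,\tilde x_j'\tilde x_j}$ where $\tilde x_j$ is
the part of $x_j$ orthogonal to the other covariates; the interval is
the set of non-rejected $b$, found by bisection.  We refit the
restricted model under each hypothesized value (rather than freezing
the nuisance coefficients at their point estimates) because freezing
mis-centers the restricted residuals; the refitted version attains
nominal coverage in simulation (95.2% over 500 cohorts of n = 398 at
the 95% level, recomputed by the acceptance script).  Two caveats are
intrinsic to the method and documented rather than patched: the
statistic is a step function of $b$, so endpoints are resolved to the
bisection tolerance; and in the far tail at small $n$ the bounded
sign-score statistic may never reach the critical value, in which case
the corresponding endpoint is honestly $\pm\infty$.  Above $n = 1000$
the function warns and recommends the bootstrap.

**Bootstrap** intervals use case resampling with the percentile rule.
The replicate coefficient draws are kept, so `cutoff_band()` can form
a *pointwise* band on the cutoff line as the percentile interval of
replicate line evaluations at each age.  (Bands are pointwise, not
simultaneous, and are labelled as such.)  For rank-inversion
intervals, which carry no joint information, the band falls back to
the conservative interval hull of the per-coefficient box, clipped to
contain the point line.

## The Gaussian null model

The null against which QRLs are compared assumes thickness is Gaussian
about a linear mean with *constant* variance: cutoffs are then
parallel offsets $\hat\mu(x) + z_\tau\hat\sigma$
(`fit_gaussian_model()`, `gaussian_cutoff()`).  Two consequences are
testable: cutoffs at different levels are uniformly separated by
$(z_a - z_b)\hat\sigma$, and on homoscedastic Gaussian data the QRLs
converge to these lines as $n$ grows (`qrl_gaussian_divergence()`
measures the gap; at $n = 10^5$ it is below 0.1 µm in our tests).  The
Gaussian model uses the *same covariate set* as the quantile model for
each metric -- the only comparison that isolates the distributional
assumption rather than mixing it with a design change.

## Flagging

`cutoff_set()` bundles the 50th/5th/1st percentile fits for one metric
and one RDB; `flag_cohort()` evaluates them at each eye's covariates
and applies the strict-below rule: red iff value < 1st-percentile
cutoff, yellow iff below the 5th but not the 1st, green otherwise.  A
value exactly on a cutoff is green/yellow accordingly ("below" is
strict); ties have probability zero for continuous data and the
convention is stated here once.

**Quantile crossing.** First-percentile QRLs from a 398-eye RDB are
noisy enough that the 1st-percentile line occasionally lies *above*
the 5th-percentile line at some eyes' covariates.  We do not rearrange
the fitted lines: crossing inside the observed range is detected and
recorded by `cutoff_set()` (warning plus a `crossings` table), and
`classify_eye()` refuses to classify at crossed cutoffs by default.
For pipeline runs that must proceed, `on_crossing = "clamp"` flags
against `min(cutoff_1, cutoff_5)` and reports exactly which eyes were
affected -- a logged repair, never a silent one.

## The synthetic-cohort generator

No eye-level data are distributed, so the generator emulates the four
cohorts of the study design from their printed marginals:

| cohort | n | age (years) | role |
|---|---|---|---|
| small RDB | 398 | 46.2 ± 16.3, range 18--88 | commercial-style reference |
| large RDB | 4830 | 48.6 ± 17.0, range 18--90 | real-world reference |
| healthy test | 175 | 49.3, range 22--86 | specificity side |
| disease test | 183 | 68.5 ± 7.5, range 60--92 | sensitivity side |

Ages and disc areas (normal, mean 2.0 mm², SD 0.4, truncated below at
0.8 mm²; published normative papers rarely print disc-area marginals,
so these are field-typical values) are drawn by exact rejection
sampling -- the truncation ranges are wide, so the rejection rate is
low.  Each metric is linear in age (and disc area for cpRNFL metrics)
plus Gaussian noise.  Because age *slopes* are likewise not printed,
they are configurable defaults (-0.2 µm/year cpRNFL, -0.1 µm/year
GCL+, +2.0 µm/mm² disc); the intercept and residual SD of every metric
are then *calibrated in closed form* (truncated-normal moments) so the
marginal mean and SD under the large-RDB age structure equal the
printed values -- 103.3 ± 10.9 µm for g-cpRNFL, 71.1 ± 5.8 µm for
g-GCL+, with field-typical values for the 22 regional metrics.  All
four cohorts share one population model: differences between the
generated RDBs are pure sampling differences, which is precisely the
null hypothesis the Monte Carlo study examines.  The statistical
properties verified by the tests (quantile property, Gaussian-limit
recovery, CI coverage) hold for any slope choice.

Disease eyes receive one truncated-normal severity draw per eye,
subtracted from every metric after scaling by family (1 for cpRNFL;
`gcl_scale` ≈ 0.42 for the thinner GCL+ layer).  A single per-eye
severity makes damage correlated across metrics, as diffuse
glaucomatous loss is; the scale pair is calibrated so the generated
cohort reproduces both printed disease marginals (g-cpRNFL mean 81.0
µm, g-GCL+ mean 61.3 µm).  The severity spectrum of the real cohort
("suspects to advanced") is not published in distributional form; the
truncated normal is a stand-in, not a claim about the study
population.

**What the generator does not emulate** -- and hence what passing
tests do *not* show about real data: spatially structured arcuate
defects (sector correlations come only through the shared severity),
bilateral eye correlation (one eye per subject throughout),
non-Gaussian thickness tails, instrument segmentation error, and
race/axial-length structure.  An optional heteroscedasticity dial
(`hetero_slope`, fractional SD change per year from age 50; default 0)
exists specifically to break the Gaussian null's constant-variance
assumption in tests.

## Monte Carlo subsampling

`run_subsample_study()` draws (by default) 1000 subsamples of 398 eyes
*without replacement* from the large RDB, refits the 5th and 1st
percentile QRLs on each, and summarizes each coefficient's empirical
distribution by its 2.5th--97.5th percentile interval (linear
interpolation of order statistics, R's type-7 scheme -- endpoint
differences between schemes are O(1/iterations) and the choice is
fixed here).  `membership_check()` then asks whether a small RDB's
coefficients fall inside those intervals, with closed endpoints.  In
the packaged synthetic study, an independent generator-matched 398-eye
cohort lands inside the 95% intervals for 39 of 44 regional slope
checks -- the sample-size explanation in action.  Note one deliberate
asymmetry: subsampling 398 of 4830 without replacement underestimates
the variability of a truly independent 398-eye sample by the finite
population correction (about 4% in SD at these sizes), so membership
rates run slightly below the nominal level; with a source much larger
than the subsample the effect vanishes, which is how the coverage
property is tested.

## Comparing the flagging of two RDBs

`transition_table()` cross-tabulates per-eye colors under the two
RDBs as a full 3x3 matrix (the usual four published rows G→Y, Y→G,
Y→R, R→Y are projections; G→R and R→G are retained for completeness).
`delta_confusion()` converts net flows into sensitivity, specificity
and accuracy changes -- at the 5% level "positive" means yellow-or-red,
at 1% it means red.  Published accuracy gains are sometimes quoted
from the true-positive change alone, so both `delta_accuracy` (TP+TN
convention) and `delta_accuracy_tp_only` are emitted; for the g-GCL+
first-percentile worked example these give +3.1% and +2.8%
respectively, and the package adjudicates neither.  Percentages
display with one decimal, halves rounded away from zero (16.39% →
16.4%); full-precision fractions are always available alongside.
`screening_projection()` translates a sensitivity change into detected
cases in a hypothetical screening population (1000 people at 3%
prevalence in the packaged example).

## The orchestrated study

`run_full_study()` chains the stages: generate → fit QRLs on both RDBs
→ Gaussian null per RDB → flag both test cohorts under both RDBs →
transition/delta/discordance/screening accounting → subsampling study
with membership check.  All randomness derives from one master seed
(`(seed * 7919 + stage) mod (2^31 - 1)` per stage), the manifest
records the derived seeds and sizes, and a re-run with the same config
is identical object-for-object.  Stage failures abort with the stage
name; partial outputs already serialized (when `out_dir` is set)
remain on disk.

With the default study conditions the qualitative headline reproduces
robustly: the disease cohort's flag discordance between the 398- and
4830-eye RDBs is several-fold the healthy cohort's, because disease
eyes pile up near the cutoff lines where reference-database sampling
error matters most.

## Problem sizes used in the checks

The packaged verification uses: exhaustive vertex enumeration on
instances of n ≤ 12; Gaussian-limit recovery at n = 100,000 (0.5 µm
tolerance over ages 20--80); rank-inversion coverage over 500 cohorts
of n = 398; subsampling membership at 150 iterations per regional
metric (44 slope checks); and full-study replications at the printed
cohort sizes.  These sizes are the package's own verification design;
the underlying routines accept any size.

## Known limitations

* Linear quantile curves only; no spline/GAM centiles, no smoothing
  across clock hours, no crossing repair.
* Pointwise (not simultaneous) confidence bands; rank-inversion bands
  use a conservative coefficient-box hull.
* Rank-inversion intervals can be half-open in far-tail/small-n
  regimes (reported as infinite, by design).
* The generator's independence and linearity assumptions listed above;
  flags are computed on full-precision values, not the integers shown
  on instrument printouts.
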