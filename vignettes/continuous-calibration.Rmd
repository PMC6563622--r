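---
title: "Continuous item pool calibration for adaptive testing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous item pool calibration for adaptive testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccscat)
```

## The problem

Computerized adaptive testing (CAT) needs a calibrated item pool, but in
settings such as higher-education exams or clinical diagnosis there is no
room for a separate calibration study: cohorts are small and items must go
operational immediately. The continuous calibration strategy (CCS) builds
the pool *during* operational testing. The first test cycle (the initial
phase) administers one fixed 60-item form to everyone and calibrates it;
every later cycle mixes three clusters into each examinee's 60-item test:

* a **linking cluster** of 15 common items drawn from the already
  calibrated pool, identical for all examinees, which carries the scale
  across cycles;
* a **calibration cluster** of 20 brand-new items, identical for all
  examinees, through which the pool grows by 20 items per cycle
  (so it holds $60 + (t-1)\cdot 20$ items after cycle $t$, 240 after ten
  cycles);
* an **adaptive cluster** of 25 items selected per examinee by maximum
  information at the interim ability estimate.

Because consecutive cohorts differ in ability (nonequivalent groups), each
cycle must be *equated* back onto the base scale established by the
initial calibration. `ccscat` implements the whole loop and a Monte Carlo
harness for evaluating equating setups.

## Measurement model

Responses follow the two-parameter logistic (2PL) model in
slope/intercept form,
$$P(u_{ij}=1\mid\theta_j) = \frac{\exp(a_i\theta_j + d_i)}
 {1 + \exp(a_i\theta_j + d_i)},$$
with discrimination $a_i$ and easiness $d_i$; the conventional difficulty
is $b_i = -d_i/a_i$. Item calibration is marginal maximum likelihood
(MML): the latent ability is integrated against a standard normal prior
over 61 equally spaced quadrature nodes on $[-6, 6]$ with renormalized
normal weights — fine enough for the admissible easiness range
$|d| \le 5$. The EM algorithm's M-step runs a small number of projected
Newton steps per item (compiled code) with backtracking, so the marginal
log-likelihood never decreases; estimates are constrained to
$a \in [-1, 5]$ and $d \in [-5, 5]$, hard bounds that also catch
degenerate items (e.g. an item answered correctly by everyone lands at
the upper easiness bound instead of diverging). Convergence is declared
when no parameter moves by more than $10^{-4}$ between EM cycles, with a
cap of 500 cycles (non-convergence is flagged, not fatal). Abilities are
estimated by the posterior mode (MAP) under the standard normal prior;
the log-posterior is strictly concave, so Newton iteration is exact for
practical purposes.

Standard errors of $(\hat a_i, \hat d_i)$ come from the per-item
information in cross-product form: outer products of the per-person
*marginal* score vectors accumulated over the quadrature-weighted
posterior ability distribution. This reflects the information lost to the
latent trait — a complete-data (posterior-weighted Fisher) form would
understate the sampling variance noticeably, which matters downstream
because the drift test consumes these covariances. Anchored items carry
a zero matrix. Joint covariance blocks across items are available
separately (see the drift-test section below).

## Equating: scale transformation and drift purification

If the 2PL holds in two groups $K$ (current cycle) and $L$ (base scale),
the scales differ by a linear map $\theta_L = A\theta_K + B$, with item
parameters transforming as $a_L = a_K/A$ and $b_L = A b_K + B$. Four
estimators of $(A, B)$ are provided: the moment methods mean/mean
($A = \bar a_K/\bar a_L$) and mean/sigma ($A = s(b_L)/s(b_K)$, both with
$B = \bar b_L - A\bar b_K$), and the characteristic-curve methods of
Haebara (item characteristic curves) and Stocking–Lord (test
characteristic curve), which minimize squared curve discrepancies over 61
uniform-weight nodes on $[-4, 4]$. Only the $K\to L$ direction enters the
criterion (the classic non-symmetric definitions). The curve criteria are
minimized by Nelder–Mead on $(\log A, B)$ — the log keeps $A$ positive
without box constraints — started at the identity link, so the returned
loss can never exceed the identity loss; an optimizer failure falls back
to the mean/mean constants with a warning.

Drift detection is a Lord-type $\chi^2$ test on
$\delta_i = (\hat a_{Li}, \hat b_{Li}) -
(\hat a_{Ki}/A,\; A\hat b_{Ki} + B)$ with
$\delta_i^\top \Sigma_i^{-1}\delta_i \sim \chi^2_2$ under no drift. By
default $\Sigma_i$ carries the full delta method: besides the two
item-level covariances it propagates the sampling variance of the
estimated constants and their covariance with the item estimates (every
common item contributes to $\hat A, \hat B$). The estimator Jacobian is
obtained by finite differences of the closed forms for the moment
methods and by the implicit function theorem (with an analytic criterion
gradient) for the curve methods. Cross-item covariance of the estimates
(items are coupled through the shared latent posterior) is ignored by the
pipeline's test, per-item blocks being both the conventional choice and,
in our checks, the better calibrated one for the anchored cumulative
calibrations of the CCS; joint covariance blocks remain available through
`joint_vcov_block()` (observed information by Louis' identity, falling
back to the outer-product form for very large calibrations) and can be
fed to `common_item_pairs()` for sensitivity analyses. This accounting matters: with the naive
two-term covariance the empirical type-I rate of the test runs well above
its nominal level for the moment methods, whereas the full form tracks
the 0.05 level. `purify()` alternates estimation and testing, removing
one item per iteration (the largest statistic — the most conservative,
order-stable reading of iterative purification) until no item is flagged
or fewer than two items remain; the latter is a *breakdown*, after which
a concurrent recalibration of all stacked responses establishes a fresh
scale lineage. Items whose pooled covariance is singular are retained
untested with a warning rather than dropped.

The retained common items are then anchored at their base-scale values in
a fixed common-item parameter (FCIP) calibration over the cumulative
responses of all cycles (structural missingness from non-administration is
simply absent from the likelihood; it is missing by design). The anchors
carry the old scale, so the latent prior stays standard normal; all
non-anchor items — including previously calibrated ones and any common
item dropped as drifted — are re-estimated freely. The transformed
constants themselves are only used for drift decisions (and to warm-start
new items); parameters enter the bank exclusively through the FCIP run.

## Design choices the sources leave open

Several operational details are not pinned down by the method's
description; the package fixes them as follows and treats them as part of
its own specification:

* **Cluster order and interim ability.** Clusters are administered
  linking → calibration → adaptive. The interim MAP that drives adaptive
  selection starts from the linking-cluster responses — the only fixed
  items that *have* parameter estimates at administration time (the
  calibration cluster is brand new) — and is updated after every adaptive
  response. Ties in information are broken toward the smaller item id so
  administration is reproducible.
* **Common-item categories.** The "very low … very high" easiness
  categories of the normal scheme are cut at the 2/15, 5/15, 10/15, 13/15
  quantiles of the eligible items' current easiness estimates, so the
  2/3/5/3/2 draw is always possible; the uniform scheme uses 15
  equal-probability quantile bins (one item each); the bimodal scheme
  draws 7 + 8 (direction by fair coin) from the 11 easiest and 11 hardest
  eligible items. Eligibility excludes items that served as common items
  in the immediately preceding cycle.
* **Temporary estimation scope.** The within-cycle calibration covers all
  items administered in that cycle (new, linking and adaptive), free of
  anchors, warm-started from the bank estimates where available.
* **Generating distributions.** Discriminations are
  $a \sim \log N(0, 0.25)$ and easiness
  $d \sim N(0, 1.5)$ truncated to $(-2.5, 2.5)$, reading the second
  parameters as standard deviations (the conventional notation in
  psychometric simulation); a switch flips them to variances. Truncation
  is by rejection, not clipping, so no probability mass piles up at the
  boundaries. Cohort abilities are standard normal in cycle 1 and
  $N(\mu_t, \sigma_t)$ afterwards with $\mu_t \in \{-0.5, 0, 0.5\}$ and
  $\sigma_t \in \{0.7, 1.0, 1.3\}$ drawn independently and uniformly each
  cycle. No item parameter drift is simulated: every flagged item is a
  false positive, which is what makes the drift-rate criterion a type-I
  error check.
* **Easiness intervals.** Conditional precision uses the seven-interval
  partition $(-\infty,-2], (-2,-1], (-1,-0.25], (-0.25,0.25], (0.25,1],
  (1,2], (2,\infty)$ of the true easiness — the unique symmetric,
  monotone repair of the interval list as usually printed. Empty bins are
  reported as absent, never as zero error.
* **Randomness.** Functions take an optional `seed`; one seed reproduces
  a whole replication. `run_study()` derives per-(condition, replication)
  child seeds from its master seed upfront, so results are identical
  regardless of execution order.

## Evaluation criteria

After each cycle $t$ the study records the mean squared error of
$\hat a$ and $\hat d$ against the true generating values (overall and
within the seven easiness bins, by *true* easiness), whether the equating
was feasible, how many common items survived purification, and — for
feasible equatings only — the signed errors
$\hat A_t - A_t$ and $\hat B_t - B_t$, where the true constants come from
the true generated abilities: $A_t = \sigma(\theta_t)/\sigma(\theta_p)$,
$B_t = \mu(\theta_t) - A_t\,\mu(\theta_p)$, with $\theta_p$ pooling all
prior cycles. Averaged over replications these errors are the bias of the
constants. The full factorial design crosses common-item difficulty
distribution (bimodal, normal, uniform) × transformation method
(mean/mean, mean/sigma, Haebara, Stocking–Lord) × cycle sample size
(50, 100, 300) into 36 conditions.

```{r, eval = FALSE}
des <- ccs_design(replications = 200)   # the full 36-condition study
study <- run_study(des, seed = 1)
summary(study)
```

At full scale (200 replications × 36 conditions × 10 cycles) this is an
overnight computation. The package's test suite and the bundled
`scripts/acceptance.R` therefore work at desk scale: 20 replications of
the Stocking–Lord / normal / $N = 100$ condition plus 20 replications at
$N = 50$ for each remaining transformation method — enough to pin the
structural contracts exactly and the stochastic criteria (feasibility,
surviving common items, type-I drift rate, bias of the constants) within
Monte-Carlo tolerance.

## What the simulation does and does not emulate

The generator reproduces the nonequivalent-groups situation that makes
equating necessary: cohort means and variances jump between cycles. It
does **not** simulate item parameter drift, content constraints, exposure
control, response times, or misfit of the 2PL itself. Passing tests
therefore certify the mechanics of the CCS under a correctly specified
model — parameter recovery, scale maintenance, nominal test levels — not
robustness to violations of it. Known limitations worth keeping in mind:

* with $N = 50$ per cycle, early-cycle estimates of extreme items are
  poor and the adaptive cluster rarely selects them again, so their
  precision recovers only slowly;
* the drift test's covariances are asymptotic; at very small samples the
  test tends to be conservative, and its rejection rate climbs toward
  (and for the moment methods past) the nominal level as $N$ grows;
* moment-method constants are exact algebra and can be wild when
  common-item estimates are noisy — the characteristic-curve methods are
  the stable choice, with Stocking–Lord marginally the best behaved. In
  rare cycles a common item is estimated with a near-zero discrimination,
  its difficulty $b = -d/a$ explodes, and the mean/sigma slope collapses;
  the delta-method variance of that item is so large that the drift test
  cannot flag it, and good items are purged instead. This linearization
  failure is inherent to difficulty-metric moment linking at small
  samples;
* the slope error $\hat A_t - A_t$ is not exactly centred on zero by
  construction: $\hat A_t$ estimates the map onto the *maintained base
  scale* (population value $\sigma_t$), while the reference value
  $A_t = \sigma(\theta_t)/\sigma(\theta_p)$ divides by the pooled spread
  of all earlier cohorts, which exceeds 1 once cohort means start
  varying. The resulting offset (about $+0.07$ at mid cycles under the
  default drift model, zero at the first continuous cycle) is a property
  of the evaluation definition, not an estimation error; the shift
  error $\hat B_t - B_t$ is free of it because the cohort means average
  to zero.
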