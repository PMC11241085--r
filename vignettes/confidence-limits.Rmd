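---
title: "Estimating lower confidence limits for PBmax as a function of PTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lower confidence limits for PBmax as a function of PTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechCL)
```

## The estimation problem

The maximum speech identification score (PBmax) declines with the degree of
sensorineural hearing loss, summarised by the pure-tone average (PTA). The
clinically useful quantity is not the mean trend but an extreme conditional
quantile: the one-tailed lower 95% confidence limit, i.e. the conditional
5% quantile of PBmax given PTA. Estimating a 5% quantile is harder than
estimating a mean — it is sensitive to the shape of the score distribution,
which in real cohorts is strongly left-skewed near the ceiling of 100%,
discretised to multiples of 4 (25-item lists), and heteroscedastic (the SD
grows from about 5 to above 20 percentage points as PTA rises).

All three estimators in this package express the limit through the same
link curve

$$\mathrm{PB}_{max}(\mathrm{PTA}) = \beta_1\,\bigl(2 -
e^{\beta_2\,\mathrm{PTA}^{\beta_3}}\bigr),$$

clamped to $\beta_1$ for PTA $< 0$ and to $0$ below zero. $\beta_1$ (in
percent, bounded to $(0, 110]$) is the curve's value at PTA $= 0$;
$\beta_2 \in [0, 1]$ and $\beta_3 \in [0, 5]$ jointly set how fast and how
abruptly the curve falls. Unlike a flattening-off form, this curve lets the
limit plunge toward zero at severe losses (near 90 dB HL), which the data
demand. At PTA $= 0$ the term $\mathrm{PTA}^{\beta_3}$ is defined as 0 even
when $\beta_3 = 0$, so the $\beta_1$ anchor is exact; the parameter bounds
are enforced by a logistic transform during optimisation, which also
prevents overflow of the exponential.

## The three methods

**Simulation (censored normal).** Ears are binned by PTA
(`pta_scheme()`); each bin's scores are modelled as Normal(mean, SD) with
the bin's measured moments; 50,000 draws are clamped into $[0, 100]$
("set to 100 / set to 0", not resampled); the empirical 5th percentile —
the order statistic at rank $\lceil 0.05\,n \rceil$, immaterial among
percentile definitions at $n = 50{,}000$ — is rounded to the nearest
multiple of 4. The bin-wise limits are then smoothed by an unweighted
least-squares fit of the link curve against the bins' mean PTAs. Clamping
at the ceiling cannot move the 5th percentile (as long as less than 95% of
the mass is clamped), so before rounding the estimate sits at
$\mathrm{mean} + z_{0.05}\,\mathrm{SD}$ up to Monte-Carlo error — a useful
analytic cross-check, and the reason this method inherits a bias whenever
the true score distribution is not normal. The companion standard error of
each bin's limit is the asymptotic order-statistic form
$\sqrt{p(1-p)/N}/f(q_p)$ with $f$ the fitted normal density and $N$ the
bin's number of ears (not the number of Monte-Carlo draws): the Monte-Carlo
error is negligible by design, the sampling error of the bin is not.

**Harrell–Davis.** A distribution-free estimator: the $q$-quantile estimate
is $\sum_i W_i\,x_{(i)}$ with $W_i$ the mass the
Beta$\bigl((n+1)q, (n+1)(1-q)\bigr)$ distribution assigns to
$[(i-1)/n, i/n]$. Weights are computed from the regularised incomplete Beta
function (`pbeta`), cached per $(n, q)$. Smoothing across all order
statistics is what makes the estimator usable at $q = 0.05$ in bins of a
few dozen ears, where a raw order statistic would be a single noisy
observation. Standard errors come from an ordinary bootstrap (default 1000
resamples; run-to-run SE variation is below 5% at that size). Bin limits
are smoothed by the same least-squares link-curve fit.

**Nonlinear quantile regression (nQR).** The link curve is fitted directly
to per-ear records by minimising the total check loss
$\sum_i \rho_\tau\bigl(y_i - \widehat{y}(x_i)\bigr)$,
$\rho_\tau(r) = r(\tau - 1[r<0])$, at $\tau = 0.05$ (and $0.5$ for the
median curve). No sub-grouping is involved, removing the arbitrary binning
choice entirely. Because the curve is nonlinear in $\beta$ and the loss is
non-smooth, interior-point methods for linear quantile regression do not
apply; the package minimises the loss by Nelder–Mead from a fixed
27-point multi-start grid ($\beta_1 \in \{80, 90, 100\}$,
$\beta_2 \in \{10^{-5}, 10^{-3}, 10^{-2}\}$,
$\beta_3 \in \{1.0, 1.5, 2.2\}$, spanning the range of fitted values seen
in practice) on the transformed scale, with a long polish pass (relative
tolerance $10^{-12}$, two restarts) from the best start. The grid is fixed,
so the fit is deterministic. Goodness of fit is $R^1(\tau) = 1 -$ (fitted
check loss)/(check loss of the constant sample-$\tau$-quantile model), the
quantile-regression analogue of $R^2$; the "1 −" orientation makes larger
values better, matching how the measure is reported in practice. Parameter
standard errors, when requested, come from a participant-level bootstrap
(the procedure behind published SEs for such fits is rarely stated;
resampling participants keeps paired ears together).

## The synthetic-cohort generator

Per-ear norms cohorts are generally not shareable, so validation rests on
a generator whose conditional law of PBmax given PTA is fully known
(`cohort_model()`, `gen_cohort()`, `true_quantile()`). PTA is drawn from a
bin-weighted mixture (uniform within bin — the least-informative choice
consistent with knowing only bin counts — snapped to the 1.25-dB audiometric
step), and the score from one of two families at the interpolated
conditional mean $\mu(\mathrm{PTA})$ and SD $\sigma(\mathrm{PTA})$:

* `censored_normal`: Normal($\mu, \sigma$) clamped into $[0, 100]$ — the
  simulation method's own assumption, making that method unbiased by
  construction (a null check);
* `skewed_beta` (default): a moment-matched Beta rescaled to $[0, 100]$ —
  left-skewed near the ceiling, as real score distributions are, so it
  exposes the simulation method's normality bias.

The default calibration tabulates $\mu$, $\sigma$ and the bin weights from
the distribution summaries of a published 642-participant clinic cohort
(right-ear values: means falling from 96.2 to 21.6 and SDs rising from 5.6
to about 20 across nine 10-dB bins; bin counts 151 down to 16). Defaults
the data do not pin down were chosen once: ears are generated i.i.d. (a
Gaussian-copula correlation knob exists but defaults to 0, since the
analyses treat ears separately), and scores are discretised to the 4%
lattice by default. What the generator does *not* emulate: cross-ear
correlation in PTA, age structure, measurement error in PTA, and any
PTA-score dependence beyond the first two conditional moments — passing
tests demonstrate estimator correctness under the stated law, not clinical
validity of any particular cohort's norms.

The exact conditional quantile (`true_quantile()`) is the oracle for
recovery tests. One subtlety: with the default real-data calibration the
true 5% quantile curve is *not* itself a member of the link-curve family
(the tabulated moment curves are piecewise linear), so every estimator —
however good — shows a few percentage points of family-misspecification
error against the oracle. Estimator-recovery tests therefore use a
link-calibrated model in which the conditional mean and the conditional 5%
quantile are both link curves and $\sigma$ is derived from their gap; the
realistic calibration is used for the coverage and accuracy tests, where
family membership is irrelevant.

## The evaluation harness

Accuracy and consistency are measured by repeated split-half
cross-validation: 25 random 50/50 splits *by participant* (both ears of a
participant stay together, avoiding leakage of paired information), fitting
each method's 95% CL curve on one half and computing on the other half
$\mathrm{DEV} = 5 - (\%\ \text{of test ears strictly below the curve})$.
Strict inequality matters because scores are discrete and ties with the
curve occur. Mean DEV over draws measures accuracy (0 is ideal; negative
means the curve sits too high and over-flags), the SD measures consistency.
Per-sub-group DEV uses the test-half members of each bin; a bin emptied by
a draw contributes a missing value rather than a zero. The nQR fit ignores
the binning scheme, which the harness verifies by the overall DEV being
bit-identical across schemes.

Sub-grouping sensitivity (`grouping_sensitivity()`) refits the binned
methods under alternative schemes (four are built in: 10-dB bins, the same
shifted by 5 dB, 5-dB bins, and 15-dB bins — labelled `group1`–`group4`)
and reports RMS differences of the fitted curves over a 0–90 dB grid in
1-dB steps. Because the conventional bin labels leave gaps ("<15" then
"16–25"), bins are implemented as contiguous intervals cut at label
midpoints (15.5, 25.5, ...); PTAs are multiples of 1.25 dB, so no
observable value falls on a cut point and every record is assignable.

## Numerical and design choices

* **Censor, never truncate-and-resample**: out-of-range simulated scores
  are clamped. A truncated law would have different moments; clamping is
  what the method definition prescribes.
* **SDs from the data**: the simulation method uses each bin's measured SD.
  The historical variant (1.62 × the binomial SD of a 25-item list) is
  retained as `sd_mode = "binomial_x1.62"` for comparison only.
* **Sample SD (n−1)** throughout; skewness and kurtosis are third and
  fourth standardised moments, kurtosis *non-excess* (normal → 3), the
  convention that matches how near-normal sub-groups are tabulated in the
  norms literature.
* **Tie rule**: lattice rounding sends exact half-distances away from zero.
* **Per-bin Monte-Carlo seeds** are derived as master seed + bin index, so
  adding a bin leaves the other bins' draws untouched.
* **Least-squares curve fits** use bounded Levenberg–Marquardt
  (`minpack.lm::nlsLM`) from the same fixed start grid, with a
  derivative-free fallback for degenerate inputs (e.g. all-ceiling bins,
  where the fit collapses to a flat curve at $\beta_1 \approx 100$,
  $\beta_2 \approx 0$). Fits are unweighted by bin size; a weighted variant
  would be a one-line change but is deliberately not the default, to keep
  the bin estimates' roles symmetric.
* **Degenerate inputs**: zero-SD bins return the rounded mean as the limit
  with a note; flat cohorts return a flat curve with a warning; splits that
  would empty a side are rejected.

## Problem sizes used in the shipped checks

The package's own validation uses cohorts of 642 participants (the
published design size) for coverage and accuracy checks, 2,500–5,000
participants for oracle-recovery checks, 25 split-half draws, 10 replicate
seeds for the method-ordering comparison, 50,000 Monte-Carlo draws per
sub-group, and 200–1,000 bootstrap resamples. These sizes give Monte-Carlo
error comfortably inside the test tolerances while keeping the full suite
quick to run.

## Known limitations

* The link curve is monotone non-increasing for positive parameters; a
  cohort with non-monotone conditional quantiles (unusual clinically) would
  be misfit by all three methods.
* The Harrell–Davis estimator at $q = 0.05$ in bins with fewer than ~10
  ears is dominated by the smallest order statistics and is flagged with a
  small-sample message; the binned methods also inherit a pooling bias when
  the quantile curve is steep within a wide bin (visible in the
  sensitivity analysis).
* Bootstrap SEs for nQR parameters assume the fit succeeds on most
  resamples; more than 20% failures abort with an error rather than return
  an optimistic SE.
* `quantile_se()` is an asymptotic normal-theory form; for heavily skewed
  bins it is an approximation, reported for comparability rather than as a
  guaranteed frequentist SE.
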