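---
title: "Methods behind pfsratio: estimation and design for PFS-ratio trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind pfsratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfsratio)
```

## The endpoint

In a PFS-ratio trial every patient contributes a pair of failure times:
`pfs1`, the progression-free survival on the last prior therapy, and `pfs2`,
the PFS on the investigational therapy. Enrolment requires progression on the
prior line, so PFS1 is always an observed event; PFS2 is right-censored
whenever follow-up ends first. The estimand is the ratio survival function

$$S(\delta) = P(\mathrm{PFS2}/\mathrm{PFS1} \ge \delta),$$

and the trial is declared supportive of efficacy when the lower confidence
bound of $S(\delta)$ exceeds a pre-specified minimal proportion $p_0$
(strictly). Throughout the package the "at or above $\delta$" convention is
used: survival curves are evaluated at $\delta^-$, so a ratio tied with
$\delta$ counts as a success.

## Why the ratio is informatively censored

Let $C_2$ be the line-2 censoring time. The observed ratio is
$\min(T_2, C_2)/T_1$, i.e. the ratio is censored at $C_2/T_1$. Both the ratio
$T_2/T_1$ and its censoring variable $C_2/T_1$ contain $T_1$, so they are
dependent whenever $T_1$ has positive variance — *even if $C_2$ is completely
independent of the pair*. Standard survival estimators assume independent
censoring and are therefore asymptotically biased on ratios; the direction
and size of the bias depend on the censoring mechanism (see the benchmark
below).

## The five estimators

**Count-based** (`estimate_count`). Among *informative* pairs — events, plus
censored ratios already at or above $\delta$ (their true ratio is even
larger) — the proportion with ratio $\ge \delta$, with a Clopper–Pearson
interval. Censored pairs below $\delta$ are excluded; this discards
information and, under PFS1-dependent censoring, distorts the estimate.

**Kaplan–Meier** (`estimate_km`). The product-limit curve of the censored
ratios via `survival::survfit`, complementary log-log intervals, evaluated at
$\delta^-$. The median ratio and its CI use the CI-crossing rule. Valid only
under independent ratio censoring, which the previous section shows is
structurally violated.

**Parametric** (`estimate_parametric`). If the pair follows the Weibull-Gamma
frailty model with common shape $\kappa$ (below), the frailty cancels in the
ratio and the ratio is log-logistic with shape $\kappa$ and median
$R = (\lambda_1/\lambda_2)^{1/\kappa}$:
$S(x) = 1/(1 + (x/R)^{\kappa})$. The package fits (shape, median) by censored
maximum likelihood on the log scale (BFGS, relative tolerance $10^{-12}$) and
propagates the curvature through the delta method on
$q = \mathrm{shape}\,(\log\delta - \log R)$. At $\delta = R$ the estimate is
exactly one half, by construction. At least two distinct event ratios are
required; non-convergence is flagged on the returned fit.

**Midrank** (`estimate_midrank`). A censored ratio's true rank is only known
to lie between its rank at the censoring value and the top of the sample. In
the $\delta$-augmented ranking the estimator spreads each censored
observation's unit mass uniformly over that admissible range and sums the
mass at or above $\delta$'s position. With no censoring this is exactly the
count estimate; with every ratio censored below $\delta$ it stays strictly
inside $(0,1)$ rather than failing. This concrete scheme is an approximation
to the Hudgens–Satten midrank procedure (the original construction assumes
equal censoring distributions in both margins, which the paired-PFS design
violates outright); it reproduces that estimator's qualitative behaviour —
upward distortion under one-sided censoring — and is included for comparison,
not recommendation. CI by seeded pairs bootstrap.

**Kernel-based Kaplan–Meier** (`estimate_kernel_km`), the recommended method.
A two-stage procedure:

1. *Conditional stage.* For each observed PFS1 value $x_j$, a kernel-weighted
   product-limit (Beran) estimate of the conditional ratio survival
   $S(\delta \mid \mathrm{PFS1} = x_j)$, with weights
   $w_i(x_j) \propto K((u_i - u_j)/h)$.
2. *Marginalization.* $\hat S(\delta) = \frac1n \sum_j \hat S(\delta \mid x_j)$.

Given PFS1, the ratio's censoring variable $C_2/\mathrm{PFS1}$ is independent
of the ratio whenever $C_2$ is independently censored given PFS1 — so stage 1
only needs an assumption that realistic trials satisfy, and stage 2 adds
none.

Three concrete choices deserve explanation:

* *Kernel.* The truncated Silverman kernel
  $K(u) = \tfrac12 e^{-|u|/\sqrt2}\sin(|u|/\sqrt2 + \pi/4)$, cut at its first
  zero ($|u| = 3\pi\sqrt2/4$) and renormalized. It is flatter than the
  Gaussian, which keeps kernel-weighted risk sets away from near-zero
  denominators; the truncation removes the oscillating negative lobes so all
  weights are non-negative. The kernel is an argument and can be replaced.
* *Rank-scale weighting.* The covariate entering the kernel is the PFS1
  *rank* scaled to $(0,1]$, not raw PFS1. The PFS1 marginal implied by
  frailty mixing is strongly right-skewed (with $\theta = 1$, $\kappa = 1$
  it is a Lomax with infinite variance), so raw-scale bandwidths give
  boundary anchors degenerate local risk sets and the estimator converges
  slowly; nearest-neighbour-type (rank) weighting keeps every local risk set
  comparable. Raw-scale weighting remains available (`rank_scale = FALSE`).
  The default bandwidth is the normal-reference rule on the working scale,
  $h = 1.06\,\hat\sigma\,n^{-1/5}$, with $\hat\sigma = 1/\sqrt{12}$ for ranks
  and $\min(\mathrm{sd}, \mathrm{IQR}/1.349)$ for raw PFS1; the cited kernel
  literature does not fix a selector, so the bandwidth is user-overridable.
* *Doubly stochastic balancing.* Row-normalized kernel weights alone make
  each conditional curve a proper weighted product-limit, but boundary-rank
  patients then carry unequal *total* mass in the stage-2 average. The
  symmetric weight matrix is therefore balanced to doubly stochastic
  (Sinkhorn scaling, tolerance $10^{-12}$): every patient contributes unit
  mass across the conditional curves. This removes the stage-2 edge bias and
  yields an exact finite-sample reduction — with no censoring the estimator
  telescopes to the empirical proportion at *any* bandwidth, which is also
  the property the test suite checks. As the bandwidth grows the weights
  become uniform and the estimator collapses to the plain Kaplan–Meier.

If some anchor receives zero total kernel mass the bandwidth is doubled once;
if mass is still degenerate, the estimator stops with an error rather than
silently extrapolating. Confidence intervals for the kernel and midrank
estimators use a seeded pairs (patient-level) bootstrap with percentile
intervals, 2000 resamples by default; the asymptotic variance expressions of
the cited literature are not reproduced here.

At censoring rates of 20% or more the dispatcher (`estimate_pfsratio`,
`analyze_cohort`) warns that the kernel method should be preferred; at 50% or
more it refuses to estimate unless forced, since no method remains reliable.

## Diagnostics

`weibull_check` plots (numerically) $\log(-\log S(t))$ of each margin's
Kaplan–Meier estimate against $\log t$: under a Weibull margin this is linear
with slope $\kappa$, and a shared shape gives parallel lines. The function
reports slopes, $R^2$ and the slope ratio and deliberately attaches no formal
accept/reject rule — the judgement is the analyst's, and the parametric
estimator is the only component that depends on it.

`fit_weibull_gamma` fits the shared-frailty model with joint survival

$$S(t_1, t_2) = \left[1 + \theta(\lambda_1 t_1^{\kappa} + \lambda_2
t_2^{\kappa})\right]^{-1/\theta},$$

i.e. conditional Weibull margins multiplied by a gamma frailty with mean 1
and variance $\theta$ (Clayton-type dependence). The likelihood uses the
mixed partial derivative for doubly observed pairs and the $t_1$-partial when
PFS2 is censored; PFS1 is always an event. Optimization is Nelder–Mead on the
log scale of all four parameters from three deterministic starts (plus an
optional user start), relative tolerance $10^{-8}$ or better, with a second
polishing pass; $\theta$ below $10^{-6}$ is reported as exact independence.
Kendall's tau is the *derived* quantity $\tau = \theta/(\theta+2)$ — never
estimated separately, so the identity holds exactly on every fit. At
$\theta = 0$ the likelihood factorizes into independent Weibull margins,
which the tests cross-check against `survival::survreg`.

## Trial design

The analysis behind the sample size is a one-sided test, on the informative
pairs, of $P(\mathrm{ratio} \ge \delta_0) = 1/2$ against $> 1/2$ — a sign
test: under the null the true median ratio *is* $\delta_0$, so the null GTE
is exactly one half (it can be overridden for the direct-GTE mode). The
alternative GTE comes from one of two models:

* **GBVE** — exponential margins with joint survival
  $\exp\{-[(\lambda_1 t_1)^{1/\gamma} + (\lambda_2 t_2)^{1/\gamma}]^{\gamma}\}$.
  Conditional on the positive-stable frailty of the Gumbel–Hougaard
  representation, $(\delta_0 t_1)$ and $t_2$ are competing exponential
  clocks, giving $GTE_1 = 1/(1 + (\delta_0/\delta_1)^{1/\gamma})$. The
  dependence parameter is obtained from the Pearson correlation by inverting
  $\rho = \gamma\,\Gamma(\gamma)^2/\Gamma(2\gamma) - 1$ (bracketed
  root-finding; $\gamma(0) = 1$, strictly decreasing). Negative $\rho$ is
  rejected as clinically implausible.
* **Weibull-Gamma** — the ratio is log-logistic with shape $\kappa$, so
  $GTE_1 = 1/(1 + (\delta_0/\delta_1)^{\kappa})$; the frailty cancels and the
  correlation does not enter. With $\kappa = 1$ the two models coincide.

Both closed forms are verified against million-pair Monte Carlo from the
package's own simulators in the acceptance checks.

The default size formula is the classical unpooled normal approximation
$n = \lceil (z_{1-\alpha}\sqrt{g_0(1-g_0)} +
z_{1-\beta}\sqrt{g_1(1-g_1)})^2/(g_1-g_0)^2 \rceil$, inflated to
$N = \lceil n/(1-p) \rceil$ for the expected non-informative proportion.
$\alpha$ is **one-sided**, default 0.05. A caveat the package surfaces
deliberately: at phase II sizes the binomial critical value is coarse, so the
normal-approximation $n$ can miss the nominal power by several points (the
discreteness gap). `sample_size(..., exact = TRUE)` instead returns the
smallest $n$ whose exact one-sided binomial test of size $\le \alpha$ reaches
the requested power; the acceptance suite validates the simulated power of
that design against its nominal value. `trial_power` is the reverse
calculation (deflate $N$, evaluate the analytic or exact power); designed
sizes round-trip to at least the requested power.

## Synthetic cohorts and the bias benchmark

The simulators are first-class, tested code and define the package's study
conditions. Defaults, chosen once to mirror reported precision-oncology
cohorts: median PFS1 of 3 months; true median ratio 1.3; exponential-type
hazards ($\kappa = 1$; the surveyed trials fail the Weibull diagnostic, so no
sharper shape is privileged); frailty variance $\theta = 1$, i.e. Kendall's
tau $1/3$, the upper end of the dependence reported across such trials
(roughly 0.17–0.35).

`sim_gbve` samples the GBVE model through its positive-stable frailty
(Chambers–Mallows–Stuck), so the joint law is exact, Kendall's tau is
$1-\gamma$ and margins are exactly exponential. `sim_weibull_gamma` samples
the gamma frailty directly; the rates are set so the marginal PFS1 median and
the median ratio equal their targets whatever $\theta$. Seeds make cohorts
byte-for-byte reproducible.

`apply_censoring` provides two mechanisms, both calibrated deterministically
by root-finding on the cohort's empirical censoring probability (achieved
rates are within about $\pm 0.03$ of target for $n \ge 500$):

* **exponential** — $C_2 \sim \mathrm{Exp}$, independent of the pair
  (dropout, e.g. toxicity).
* **administrative** — trial emulation of "end of study reached" with
  enrolment at initiation of the prior line: total follow-up
  $B \sim U(f_0, f_0 + A)$ (minimum follow-up $f_0 = 6$ months by default
  plus accrual stagger $A$), and line-2 follow-up $C_2 = \max(B - T_1,
  \varepsilon)$. Patients whose PFS1 consumes the whole follow-up are
  censored essentially immediately on line 2, like their real counterparts.
  Targets beyond the attainable maximum raise a calibration error.

The distinction matters more than it looks. A structural fact the package's
development uncovered: under *pair-independent* censoring (the exponential
mechanism) the count-based estimator is exactly asymptotically unbiased in
both model classes — conditional on the frailty, $\delta T_1$ and $T_2$ are
competing exponential clocks, the minimum of such clocks is independent of
which clock wins, and the censoring weight $G(\min(\delta T_1, T_2))$ cancels
between the success and failure contributions. The biases reported for
count/midrank-type estimators on real trials therefore require the censoring
time to *depend on PFS1*, which is precisely what end-of-study censoring
does: the later a patient progresses on line 1, the less follow-up line 2
gets. The administrative mechanism is accordingly the benchmark default; the
kernel estimator remains valid under it (conditional independence given PFS1
still holds, since $B$ is independent of everything), while the plain
Kaplan–Meier, count and midrank estimators do not. `benchmark_bias` tabulates
mean bias, SD, mean absolute bias and CI coverage over seeded replicates; its
default grid crosses censoring 10/20/30%, $\delta \in \{1.3, 1.5, 2\}$ and
$n \in \{100, 200\}$. Under the 30%-censoring scenario at $\delta = 1.3$ the
kernel-based estimator's mean absolute bias is the smallest of the
nonparametric estimators and its mean bias is within $\pm 0.02$ of zero —
the package's operational rendering of "asymptotically unbiased, while the
other methods deviate"; the acceptance script recomputes these numbers on
every run.

## Modified PFS ratio

Two pre-analysis transforms address extreme denominators and long
responders. The `mock` scheme floors PFS1 at 2 months (strictly shorter
converts) and replaces PFS2 strictly longer than 6 months by 24 months. The
`alternative` scheme keeps the PFS1 floor but, for patients whose PFS2 is
already clinically satisfying (default at least 6 months) yet whose ratio
falls below $\delta$, resets PFS2 to $\mathrm{PFS1}\cdot\delta + 0.25$ — the
quarter-month bonus is about one week, a minimal advantage that avoids
knife-edge ties; such patients always end with ratio $\ge \delta$. Thresholds
follow the rules' wording (floor strictly below 2; convert strictly above 6);
whether the original rule used a weak or strict inequality at 6 months is not
documented anywhere we know of, so the strict reading is pinned. Transforms
return a new cohort, never mutate, and never touch the censoring indicator.
Both are descriptive, clinically motivated devices — the vignette's advice
mirrors the estimators': report them alongside, not instead of, the
untransformed analysis.

## Numerical and interface choices

* Durations must be strictly positive; zeros are rejected (the ratio would be
  undefined) — floor first via a transform if the data contain them.
  `event2` accepts only 0/1; yes/no and TRUE/FALSE dialects are rejected
  rather than coerced, to avoid silently inverted censoring.
* Ties between event and censored ratios at the same value follow the usual
  product-limit convention (events first); tied events are handled as a
  group, which also makes the kernel estimator invariant to patient
  relabeling.
* Kendall's tau for the large simulated cohorts uses an $O(n\log n)$
  inversion-counting implementation in C++ (tau-a, continuous data); small or
  tied samples fall back to `stats::cor`.
* All bootstrap and simulation entry points take explicit seeds, restore the
  caller's RNG state, and record the seed in reports.
* Test-suite problem sizes: concordance and workflow checks run at
  $n = 50$–$200$; dependence recovery at $n = 500$ over 20 replicate cohorts
  and $n = 10^5$ for copula tau; GTE closed forms against $10^6$-pair Monte
  Carlo; the bias benchmark at $n = 200$ with 200 replicates. These sizes
  make Monte-Carlo error comfortably smaller than the asserted tolerances.

## Limitations

* Failure times are treated as continuous; the interval censoring induced by
  scheduled tumor assessments (scans every 6–12 weeks) is not modelled, and
  is a known source of distortion when assessment schedules differ between
  the two lines.
* Single-arm only: no two-arm ratio comparisons or covariate adjustment.
* The midrank scheme is a pinned approximation (see above), and the exact
  form of the "modified Silverman kernel" in the cited kernel literature is
  not public — both the kernel and the bandwidth are injectable so an exact
  match can be dropped in.
* The synthetic cohorts emulate the dependence, margins and censoring
  structure the methods assume, but not everything real trials do: no
  assessment-schedule artefacts, no heterogeneity across tumor strata, no
  association between censoring and prognosis beyond the PFS1 channel. A
  passing benchmark shows the estimators behave as claimed under the stated
  models, not that any given trial satisfies those models — which is exactly
  why the diagnostics module ships alongside the estimators.
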