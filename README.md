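# pfsratio

Design and analysis of single-arm phase II oncology trials that use the
**PFS ratio** — also called the growth modulation index (GMI) or
time-to-progression ratio — as their primary endpoint. Each patient serves as
their own control: the endpoint compares progression-free survival on the
investigational therapy (PFS2) with PFS on the immediately preceding line
(PFS1), within the same patient. This is the natural design for precision
oncology, where each combination of tumor, molecular alteration and targeted
agent is rare and a randomized comparison is rarely feasible.

## The estimand and why it is hard

A trial estimates

```
S(δ) = P(PFS2 / PFS1 ≥ δ)
```

for an effectiveness cutoff δ set by the investigator (δ = 1.3 is typical),
and declares efficacy when the lower confidence bound of S(δ) exceeds a
minimal proportion p₀. Patients always progress on the prior line — PFS1 is
never censored — but PFS2 is censored whenever follow-up stops first, and then
the *ratio* is censored at C₂/PFS1, where C₂ is the line-2 censoring time.
Because the ratio and its censoring variable share PFS1, the ratio is
**informatively censored even when PFS2 itself is independently censored**,
which biases standard survival methods applied to the ratios.

The package implements five estimators of S(δ):

| method       | idea                                                   | censoring handling |
|--------------|--------------------------------------------------------|--------------------|
| `count`      | proportion of ratios ≥ δ among informative pairs       | excludes censored-below-δ pairs |
| `km`         | Kaplan–Meier on the ratios, evaluated at δ⁻            | assumes independent ratio censoring (violated) |
| `parametric` | censored MLE of a log-logistic ratio distribution      | model-based |
| `midrank`    | rank-based with censored mass spread over admissible ranks | assumes equal censoring of both margins (violated) |
| `kernel_km`  | **two-stage kernel conditional Kaplan–Meier**: Beran estimate of the ratio's survival given PFS1, averaged over observed PFS1 | needs only conditional independence given PFS1 — valid |

The kernel-based estimator conditions on PFS1 (kernel weights on the PFS1
ranks, truncated Silverman kernel, doubly-stochastic weight balancing so each
patient carries unit mass), which restores the independent-censoring
assumption where it actually holds, and is the recommended method once the
censoring rate reaches 10–20%.

Trial design uses the generalized treatment effect
`GTE = P(PFS2 ≥ δ₀·PFS1)` under a hypothesized alternative, in closed form
under two bivariate survival models — Gumbel type-B bivariate exponential
(GBVE, parameterized by the PFS1–PFS2 Pearson correlation ρ) and
Weibull-Gamma shared frailty (shape κ) — with non-informative-pair inflation
`N = ⌈n/(1−p)⌉`, a reverse power calculator, and an exact-binomial variant.
Built-in simulators for both models (with calibrated dropout-type and
trial-emulating end-of-study censoring) drive a bias benchmark of all five
estimators.

## Worked example

Design a trial expecting a median ratio of 1.3 against δ₀ = 0.8 (PFS
deteriorates across lines, so matching the prior line is already meaningful),
with weak intra-patient correlation and 10% non-informative pairs; then
analyze a simulated cohort of the designed size:

```r
library(pfsratio)

design <- sample_size(alpha = 0.05, power = 0.8, delta0 = 0.8, delta1 = 1.3,
                      model = "gbve", rho = 0.3, p_noninformative = 0.1)
design
#> PFS-ratio design (gbve): GTE0=0.500 GTE1=0.661 -> n=58 informative pairs,
#> N=65 patients (alpha=0.05 one-sided, power=0.80, p_noninf=0.10)

coh <- simulate_cohort("weibull_gamma", n = design$n_total, theta = 0.8,
                       censoring = "administrative",
                       target_censoring_rate = 0.15, seed = 42)
analyze_cohort(coh, delta = 0.8, p0 = 0.5, n_boot = 1000, seed = 42)
#> PFS-ratio analysis report (delta = 0.8)
#>   N = 65, PFS2 censoring 17%
#>   median PFS1 4.28 (2.60-6.97), median PFS2 4.16 (2.56-6.79) months
#>   Weibull check: slopes 0.80 / 0.69 (r2 0.957 / 0.982), slope ratio 0.86
#>   Kendall's tau (Weibull-Gamma frailty): 0.226
#> S_PFSratio(0.8) = 0.627 (95% CI 0.491-0.750) [count, 59/65 informative]
#> S_PFSratio(0.8) = 0.632 (95% CI 0.497-0.740) [km, 65/65 informative]
#> S_PFSratio(0.8) = 0.619 (95% CI 0.497-0.740) [kernel_km, 65/65 informative]
#> S_PFSratio(0.8) = 0.600 (95% CI 0.489-0.701) [parametric, 65/65 informative]
#> S_PFSratio(0.8) = 0.629 (95% CI 0.507-0.743) [midrank, 65/65 informative]
#>   median PFSratio 1.22 (0.80-2.33) [kernel_km]
#> Efficacy vs p0 = 0.50: S(0.8) = 0.619, lower bound 0.497 -> NOT supportive [kernel_km]
```

Reading the report: GTE1 = 0.661 is the probability, under the design model,
that a patient's PFS2 reaches at least 0.8 of their PFS1 when the true median
ratio is 1.3. In the analysis, 62% of patients met the δ = 0.8 bar
(kernel-based estimate 0.619), the estimated median ratio is 1.22, and with
the lower confidence bound at 0.497 the trial just misses the demanding
p₀ = 50% target. Note the count method quietly dropped 6 of 65 patients
(non-informative pairs), and at 17% censoring the kernel-based row is the one
to trust.

Cohorts are plain CSVs (`id, pfs1, pfs2, event2`, months, `event2 = 0` for
censored PFS2) read with `read_cohort()`; `s_curve()` exports tidy
S(δ)-vs-δ tables and `write_report()` emits the JSON/CSV analysis bundle.

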