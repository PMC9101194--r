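---
title: "Confidence-limit-based fuzzy evaluation of physical fitness indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-limit-based fuzzy evaluation of physical fitness indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfindex)
```

## The measurement model

A subject repeats each fitness item a handful of times — the packaged
example uses ten trials per item over two weeks. Measurements of item $h$
are modelled i.i.d. normal, $X_h \sim N(\mu_h, \sigma_h^2)$, and each item
carries a one-sided specification: an upper limit $U$ for a
smaller-the-better characteristic (run-walk time), a lower limit $L$ for a
larger-the-better one (sit-up count, jump distance, flexion distance). The
population index

$$PF = \frac{U-\mu}{\sigma} \quad\text{or}\quad \frac{\mu-L}{\sigma}$$

is dimensionless; $\Phi(PF)$ is the probability a single performance meets
the limit (`compliance_ratio()`), so $PF = 6$ corresponds to essentially
certain compliance and $PF = 0$ to a coin flip. The evaluation question is
the one-sided hypothesis $H_0: PF \ge k$.

Body-mass index is deliberately not part of the item set: it barely moves
over a testing window of weeks, so a repeated-measures index adds nothing
for it.

## Estimation and the upper confidence limit

From a sample of size $n$, `summarize_sample()` computes $\bar{x}$ and $s$
and `estimate_index()` forms $PF^* = (U-\bar{x})/s$ (orientation-mirrored
for lower limits). Two conventions for $s$ exist; this package defaults to
the $n-1$ denominator, which is the convention the worked example's
reported statistics follow, and exposes `sd_denominator = "n"` for
comparison. $PF^*$ may be negative (mean beyond the limit) and is never
clipped.

Exact confidence limits for $PF$ are awkward because $\bar{X}$ and $S$
enter jointly; the package uses the conservative construction: a
$1-\alpha/2$ chi-square bound on $1/\sigma$ and a $1-\alpha/2$ normal bound
on the mean term, intersected via Boole's inequality, give

$$P\!\left(PF \le PF^*\sqrt{\tfrac{\chi^2_{1-\alpha/2;\,n-1}}{n}} +
\tfrac{z_{\alpha/2}}{\sqrt{n}}\right) \ge 1-\alpha .$$

`upper_confidence_limit()` evaluates the right-hand bound. Conservatism is
a feature here: with $n = 10$ the realized coverage sits near 0.98–0.99 at
$\alpha = 0.05$ (see the simulation section), so the procedure errs toward
*not* absolving a deficient item by chance.

## The half-triangular fuzzy number and its membership function

`build_fuzzy_index()` turns $PF^*$ into a fuzzy number whose
$\alpha$-cuts are the confidence-limit intervals at nested levels:

* apex $PF_M = PF^*\sqrt{\chi^2_{0.5;\,n-1}/n}$ (membership 1) — the
  median-unbiased rescaling of the estimate; for $PF^* > 0$ it sits below
  $PF^*$ because the chi-square median is below $n-1 < n$;
* right endpoint $PF_R$ = the $100(1-\alpha)\%$ upper confidence limit
  (membership 0).

For $PF_M < x < PF_R$ the membership grade is the level $a$ solving

$$x = PF^*\sqrt{\chi^2_{1-a/2;\,n-1}/n} + z_{a/2}/\sqrt{n},$$

a strictly decreasing map in $a$ (larger $a$, smaller quantiles).
`membership()` inverts it with Brent's method (`stats::uniroot`) on
$a \in [0.05, 1]$ at tolerance $10^{-9}$; the bracket is guaranteed a sign
change by monotonicity, and non-convergence raises a typed numerical error
with diagnostics rather than returning a silent wrong value. Three
boundary conventions are implemented literally from the cut definition:

* cuts below $a = 0.05$ reuse the 0.05-level interval, so interior grades
  never fall below 0.05, and for fuzzy numbers built with `alpha < 0.05`
  the stretch beyond the 0.05-level endpoint returns the capped grade 0.05;
* the function is 0 at $x \ge PF_R$ exactly, making it discontinuous at
  $PF_R$ (interior limit 0.05, value 0) — a quirk of the cut definition we
  keep rather than smooth away;
* membership is 1 only at $x = PF_M$ exactly.

## The fuzzy test and its thresholds

The classical fuzzy-test statistic would compare the area of the fuzzy set
right of $k$ with its total area; this construction replaces areas with
base lengths:

$$\frac{d_R}{d_T} = \frac{PF_R - k}{PF_R - PF_M},$$

computed by `fuzzy_test()`. The ratio is reported unclamped — negative
when even the upper confidence limit misses $k$, above 1 when $k$ sits
left of the apex — because the magnitude is informative; only the decision
is discretized:

* ratio $\le \phi_1$: **improve** (reject $H_0$);
* ratio $\ge \phi_2$: **maintain** (retain $H_0$);
* otherwise: **re-evaluate**.

Defaults are $\phi_1 = 0.4$ and $\phi_2 = 0.8$. The first is the
threshold the worked example actually exercises. No value for $\phi_2$ is
prescribed by the source method, so the package picks 0.8 — symmetric with
$\phi_1$ around 0.6 and high enough that "maintain" requires four fifths
of the fuzzy base beyond the requirement; both thresholds are plain
arguments and a config file can override them per item.

Degenerate inputs are typed errors, not NaNs: $s = 0$ (all trials
identical) makes the index undefined
(`pf_degenerate_sample`), and a strongly negative $PF^*$ — below
$-z_{\alpha/2}/\big(\sqrt{\chi^2_{1-\alpha/2;n-1}/n}-\sqrt{\chi^2_{0.5;n-1}/n}\big)$,
about $-1.33$ at $n=10$, $\alpha=0.05$ — inverts the endpoint ordering and
raises `pf_degenerate_fuzzy`. With ten trials of a genuinely measured
quantity neither arises in practice.

## Rounding and the two input routes

Report tables round the index estimate to 2 decimals and fuzzy quantities
to 3. The package computes at full precision internally, but the packaged
example ships *three* input forms — raw measurement lists, the reported
summary statistics, and the reported 2-decimal estimates — because they
are not mutually consistent: the jump item's raw values have mean 190.3
where the summary table reports 192, and the flexion item's raw sd is
0.137 against a reported 0.099. Downstream fuzzy numbers built from the
2-decimal estimates differ from full-precision ones in the third decimal
(e.g. apex 3.681 vs 3.678 for the cardio item). Analyses should state
which form they start from; the tests assert the discrepancy so it cannot
silently disappear.

```{r example}
specs <- read_spec_config(example_path("example_spec.yaml"))
ms <- read_summaries(example_path("example_summary.csv"), specs)
evaluate(ms, specs)
```

## What the simulation module emulates — and what it does not

`simulation_scenario()` fixes $(\mu, \sigma)$, the spec, $n$ per sample,
the replicate count and a seed; `generate_measurements()` draws i.i.d.
normal samples, one L'Ecuyer-CMRG stream per replicate
(`parallel::nextRNGStream`), so the same seed reproduces every replicate
bit-for-bit regardless of execution order and without touching the
caller's RNG state. `estimate_coverage()` pushes every replicate through
the public pipeline and reports the empirical coverage of the upper
confidence limit, the three outcome rates at the scenario's $k$, and the
mean ratio; replicates with $s = 0$ are counted and excluded with a
warning, never dropped silently.

The generator emulates exactly the model the method assumes: independent,
identically distributed normal trials with a stable mean and variance. It
does **not** emulate learning or fatigue across a two-week testing window,
day-to-day autocorrelation, rounding of recorded values (integer sit-up
counts), or non-normal tails — so passing coverage and operating-
characteristic checks validate the method *under its own assumptions*, not
robustness to their violation. Non-normal extensions are out of scope.

Problem sizes used by the shipped checks: the coverage study runs 10,000
replicates of $n = 10$ at three $(\mu, \sigma)$ settings;
operating-characteristic shape checks use 1,000–2,000 replicates over a
$PF_{true}$ grid spanning $k \pm 3$ and $n \in \{10, 30, 100\}$. At these
sizes the binomial standard error on a coverage estimate is about 0.002,
small enough to separate conservative coverage (≈0.98) from the nominal
0.95. A classical-test comparison comes free: the maintain decision
implies $PF_R > k$, i.e. whenever the fuzzy test maintains, the classical
UCL test also retains $H_0$; the converse fails exactly in the interesting
cases (the worked example's cardio item: UCL 6.17 > 6 retains, fuzzy ratio
0.069 demands improvement), and the simulation reports both behaviours
side by side, leaving the judgement between them to the user.

## Known limitations

* The normality assumption is untested by the package (no built-in
  normality diagnostics); with $n \approx 10$ such tests have little power
  anyway.
* The Boole-inequality limit is conservative; users wanting exact
  one-sided coverage for this index family need a noncentral-t
  construction, which is outside this method.
* $\phi_2$ and the treatment of out-of-range ratios are package choices
  (documented above), not prescriptions of the source method.
* The discontinuity of the membership function at $PF_R$ means grades just
  inside the endpoint are 0.05, not arbitrarily small.
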