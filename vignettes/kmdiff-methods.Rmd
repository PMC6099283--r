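---
title: "Quantile survival time difference curves: model, algorithms and design notes"
author: "kmdiff developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile survival time difference curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4.5)
library(kmdiff)
```

## The problem

Kaplan-Meier plots are read along two axes. The *vertical* gap between two
curves at a fixed time is a survival probability difference; the
*horizontal* gap at a fixed survival probability $p$ is a difference of
survival times — how much longer one group takes to fall to the same
survival level. Clinicians and patients usually find time differences the
more intuitive quantity (the median survival time difference is the
special case $p = 0.5$), yet the diagonal layout of a KM plot makes
horizontal gaps very hard to judge by eye: visual perception tends to
track the shortest Euclidean distance between the curves instead.

`kmdiff` makes the horizontal gap a first-class curve. For survival
functions $S$ and $S'$ with quantile survival times $Q(p)$ and $Q'(p)$
(the time at which the survival function reaches $p$; equivalently the
conventional $(1-p)$th distribution quantile), the *quantile survival time
difference curve* is
$$D(p) = Q(p) - Q'(p), \qquad 0 < p \le 1 .$$
It is plotted with $p$ on the vertical axis — the same axis as the KM
plot — so the two figures can be read side by side. The tool is
*exploratory*: the band it draws is pointwise, and using it for
confirmatory claims would require pre-specified hypotheses and
multiplicity adjustment.

## Estimation

**Kaplan-Meier step curves.** With observed times $x_1 \dots x_n$ and
event indicators $a_1 \dots a_n$, the product-limit estimate over the $K$
distinct failure times $t_1 < \dots < t_K$ is
$\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$, with $d_i$ failures out of
the risk set $n_i$. Two conventions are hard-coded:

* *Ties*: when an event and a censoring share a time, the censoring stays
  in that event's risk set (events precede censorings). This matches
  `survival::survfit`, which the test suite uses as an independent oracle.
* *Beyond $t_K$*: the curve is **not defined** for $t > t_K$ (rather than
  carried flat to the last censoring time). `survival_at()` returns `NA`
  there. Consequently a sample with no events ($K = 0$) has a legal curve
  that is 1 at $t = 0$ and undefined for every $t > 0$; such curves are
  representable but rejected by `difference_curve()`, because quantiles
  never exist for them — we also treat $\hat Q(1)$ of a $K = 0$ curve as
  undefined.

**Quantiles.** For $\hat S(t_K) \le p \le 1$,
$\hat Q(p) = \min\{ t_j : \hat S(t_j) \le p \}$. The comparison
$\hat S(t_j) \le p$ uses an absolute tolerance of $10^{-12}$ (levels live
in $[0,1]$, so absolute and relative coincide for practical purposes):
a $p$ exactly equal to a stored level — say $0.5$ versus a computed
$1 - 1/2$ — must select the *earlier* time, as the minimum intends, and
floating-point products would otherwise make that a coin flip.

**The difference curve.** $\hat D(p) = \hat Q(p) - \hat Q'(p)$ exists on
$[p^0, 1]$ with $p^0 = \max(\hat S(t_K), \hat S'(u_L))$, the smallest
probability at which both quantiles exist. When $p^0 = 0$,
$\hat D(0) = t_K - u_L$ falls out of the same formula. $\hat D$ is a step
function of $p$; its breakpoints are the merged level sets of the two
curves, and each value holds on the interval *closed at the lower level*,
$[\ell_i, \ell_{i-1})$ — the same convention used when drawing. The step
representation is cached eagerly for plotting and serialization, but
`evaluate_difference()` recomputes from the source curves so that values
at breakpoints are exact; a property test asserts the two routes agree
everywhere.

## Bootstrap inference

Both variability displays rest on Efron's classical bootstrap for
censored data: each replicate redraws $n$ pairs $(x_i, a_i)$ with
replacement within group 1 and $m$ pairs within group 2, refits both KM
curves, and recomputes the difference curve $\hat D^{*i}(p)$ with its own
domain bound $p^{*i}$ (defined like $p^0$).

**Bundle.** Overlaying 40–200 replicate curves in light grey under the
green estimate gives a direct visual impression of sampling variability.
When both a bundle and a band are requested, the bundle is the *head* of
the single band-sized resampling pass — one RNG stream, mutually
consistent figures.

**Pointwise band.** For $p \ge p^*_{\max} = \max_i p^{*i}$ every replicate
is defined and the $100(1-\alpha)\%$ limits are the $\alpha/2$ and
$1-\alpha/2$ empirical quantiles of $\hat D^{*1}(p), \dots,
\hat D^{*B}(p)$. The rule of thumb for $B$ is $B \ge 100/\alpha$ (2000
for 95%). That core interval $[p^*_{\max}, 1]$ can be short — it is
governed by the single bootstrap KM curve that drops least — so the band
is *conservatively extended* down to $p^*_{1-\alpha}$, a specific
$(1-\alpha)$ quantile of the $p^{*i}$: when $(1-\alpha)B$ is an integer
$r$, the upper endpoint $x_{(r+1)}$ of the usual ambiguity interval is
taken (clipped to $x_{(B)}$), otherwise $x_{(\lceil (1-\alpha)B \rceil)}$.
At a $p$ in the extended region each defined replicate gets weight $1/B$
while each undefined replicate is replaced by *two* sentinel values $-M$
and $+M$ with weight $0.5/B$ each, $M$ any number exceeding all defined
$|\hat D^{*i}(p)|$; the limits are the same two quantiles of this weighted
distribution, and a limit that lands on a sentinel is reported as
undefined rather than as a number.

Numerical choices worth recording:

* **Quantile definition.** The core region uses the same left-continuous
  inverse-CDF rule (smallest value whose cumulative weight reaches $q$)
  as the weighted extension, with equal weights $1/B$. The source
  material names no empirical quantile type for the core region; using
  one rule for both makes the band continuous across $p^*_{\max}$ when
  the number of undefined replicates goes to zero.
* **Choice of $M$.** $M$ is data-dependent per evaluation point
  (largest defined $|\hat D^{*i}(p)|$ plus 1). Any larger value is
  equivalent; the suite asserts results are unchanged under $10 M$.
* **Replicates with no events.** A resample can lose all events in a
  group; then $p^{*i}$ does not exist. Such replicates are excluded from
  the $p^{*}$ order statistics but contribute sentinel mass at *every*
  $p$, and their count is reported as a diagnostic. The formulas
  presuppose $K > 0$, so this is a package decision, made conservative
  on purpose.
* **Evaluation grid.** The exact band is a step function whose
  breakpoints are the union of all replicate level sets — enormous for
  $B = 2000$. The default grid is the observed curve's levels, all
  $p^{*i}$, and 1001 uniform points on $[0,1]$; `grid = "exact"` is
  available. The two are visually indistinguishable.
* **Seeds.** `seed = 0` means "draw a fresh seed and record it in the
  output metadata", mirroring the original macro's default; any fixed
  seed reproduces bundle, band and figures bit for bit.

## What the synthetic-data generator emulates

`simulation_spec()` draws event times from exponential, Weibull or
piecewise-exponential families, censored independently by the same
families, by an administrative cutoff, or not at all — the standard
random-censorship model. Continuous times make ties a measure-zero event,
so a `round_digits` knob exists purely to manufacture ties and exercise
the tie conventions. Closed-form `true_quantile()`/`true_difference()`
provide population oracles, e.g. exponential(1) vs exponential(2) has
true median difference $\ln 2 \cdot (1 - 1/2) \approx 0.3466$.

What it deliberately does **not** emulate: covariate-dependent or
informative censoring, cohort heterogeneity, calendar-time entry, or the
discrete recording of real registries (GBSG-style data in days). A green
simulation test therefore establishes correctness of the estimator and
band algebra under independent censoring — not robustness to violations
of that model.

The suite's stochastic checks run at the stated world: coverage of the
95% band at $p = 0.5$ under a null of two exponential(1) groups
($n = m = 100$, exponential(0.3) censoring, $B = 400$, 300 simulations)
must land in $[0.90, 0.99]$ — deliberately tolerant, since with very
small samples and risk sets the actual coverage of bootstrap quantile
intervals is known to drift from the nominal level; the same caveat
applies to reading the bundle in small samples.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 5 (percent) | pointwise two-sided level; converted to a fraction once, at the boundary |
| `boot` | 2000, min 100 | band replicates; keep $\ge 100/\alpha$ |
| `bundle` | 200 | replicates drawn in the bundle figures (0 skips them); 40–200 is sensible |
| `seedval` | 0 | bootstrap seed; 0 = entropy, recorded in `run_metadata.json` |
| `censval` | "0" | status codes read as censored (comma list on the CLI) |
| `timeunit` | "years" | axis annotation only; the math is unit-free (scale-equivariant) |

## Degenerate inputs and edge behaviour

* One repeated observation pair: every resample is identical, the band
  has zero width, and the whole grid is core — asserted in the suite.
* All observations censored: `km_estimate()` returns the $K = 0$ curve;
  `difference_curve()` refuses it with a clear error.
* `p` outside a curve's domain is always an error, never an extrapolation;
  undefined band limits serialize as empty CSV fields, never as $\pm M$.
* Group codes are compared as trimmed strings, so numeric and text codes
  both work (the original macro required numeric codes; relaxed here).

## Known limitations

The band is pointwise — simultaneous coverage over the whole curve is
not controlled, and no BCa/studentized variants are offered. Variance
formulas (Greenwood), log-rank testing and covariate adjustment are out
of scope. Normal-approximation and smoothed empirical-likelihood
intervals for quantile differences exist as alternatives but are not
implemented: the former needs moderate-to-large samples, the latter a
cross-validated bandwidth, and both were outside this package's remit.

## A small worked run

```{r example}
set.seed(2026)
spA <- simulation_spec("weibull", list(shape = 1.2, scale = 2.0),
                       censoring = list(family = "exponential",
                                        params = list(rate = 0.2)), n = 150)
spB <- simulation_spec("exponential", list(rate = 0.8),
                       censoring = list(family = "exponential",
                                        params = list(rate = 0.2)), n = 150)
s1 <- simulate_censored_sample(spA)
s2 <- simulate_censored_sample(spB)
boot <- bootstrap_differences(s1, s2, B = 400, seed = 20260910)
boot
band <- confidence_band(boot, alpha = 0.05)
band
evaluate_difference(boot$observed, 0.5)     # estimated median difference
true_difference(spA, spB, 0.5)              # population value
```

```{r figures, fig.show = "hold"}
plot_km(km_estimate(s1), km_estimate(s2), labels = c("A", "B"))
plot_difference(boot$observed, band = band, labels = c("A", "B"))
```
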