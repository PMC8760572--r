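---
title: "Death-registration completeness and adult mortality: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Death-registration completeness and adult mortality: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(crvsddm)
```

## The problem

In many countries the civil registration and vital statistics (CRVS) system
captures only a fraction of deaths, and that fraction may differ by sex.  Any
adult-mortality indicator computed from registered deaths — the probability
$_{35}q_{15}$ of dying between exact ages 15 and 50, or life expectancy at
age 15, $e_{15}$ — is then biased, and so is the female−male gap in
$e_{15}$.  This package estimates the *completeness* $C$ of death
registration relative to census coverage from the data most countries have
(two census age distributions and registered deaths by age), adjusts the
death rates by $1/C$, and rebuilds the life-table indicators.  It also
estimates adult mortality directly from DHS-style household surveys (sibling
histories and household recent-deaths modules) so that the registry-based
series can be triangulated against survey-based ones.

## Death distribution methods

All three methods work on five-year age groups with one open interval
(`age_grid()`), a dated census pair and registered intercensal deaths, and
assume a population closed to migration with age-constant completeness above
a minimum adult age (15 by default, configurable).

**Generalized growth balance (GGB).**  For the population aged $x+$, the
entry rate (people turning $x$ per person-year lived above $x$) must equal
the growth rate plus the death rate.  With census coverages $k_1, k_2$ and
registered deaths $D^*$ capturing a fraction $C$ of true deaths, the
observed points satisfy
$$\frac{N(x)}{PY(x+)} - r(x+) = \frac{1}{C}\,\frac{D^*(x+)}{PY(x+)} +
\frac{\ln(k_1/k_2)}{t},$$
a straight line over cumulation ages.  `ggb_fit()` estimates $C$ from the
slope and the relative census coverage $k_1/k_2$ from
$\exp(\text{intercept}\cdot t)$.  Numerics: people turning $x$ per year are
estimated by the cohort-straddling geometric mean
$\sqrt{N_1[x-5,x)\,N_2[x,x+5)}/5$, which cancels average intercensal growth;
person-years above $x$ by $t\sqrt{N_1(x+)N_2(x+)}$.  The line is fitted by
ordinary least squares by default; the method literature is split between
OLS and orthogonal regression, so total least squares is available via
`fit = "orthogonal"`.  A window with fewer than three points or a
non-positive slope is flagged degenerate and its $C$ reported as missing,
never clipped.

**Synthetic extinct generations (SEG).**  In a population closed to
migration, everyone alive at age $x$ eventually dies above $x$, so the
number of people attaining age $x$ per year can be reconstructed from later
deaths inflated by population growth.  `seg_estimate()` uses the discrete
Bennett–Horiuchi recursion
$$\hat N(x) = \hat N(x+5)\,e^{5 r(x)} + \bar D(x)\,e^{2.5\,r(x)},$$
with $\bar D(x) = D^*[x,x+5)/t$ the group's deaths per calendar year and
$r(x)$ the group's intercensal growth rate.  Synthetic group counts
$2.5(\hat N(x) + \hat N(x+5))$ are compared with geometric-mean census
counts; the mean ratio over the age window (median available) is the
completeness estimate, reported above 1 when the data imply it.

**Open-interval closure.**  The recursion is seeded at the open age $A$ with
$\hat N(A) = \bar D(A)\,[e^{r \hat e} - (r\hat e)^2/6]$, the standard
approximation involving the remaining life expectancy $\hat e$ at $A$.
$\hat e$ computed from *unadjusted* data is biased upward by $1/C$ exactly
when registration is incomplete, and because a large share of deaths occurs
above age 80 this bias propagates into every $\hat N(x)$.  The default is
therefore a self-consistent closure: $\hat e = C / M_{obs}(A)$ is iterated
with the completeness estimate to a fixed point (a few iterations; exact
no-op when $r(A+)=0$).  A fixed $\hat e$ can be supplied through
`open_closure_e`, which also makes the estimate exactly linear in the death
counts.

**Combined GGB–SEG.**  SEG is sensitive to differential census enumeration.
`ggbseg_estimate()` first runs GGB on the window, rescales the second census
onto the coverage scale of the first (multiplying $N_2$ by the estimated
$k_1/k_2$; adjusting census 1 instead is a switch), rebuilds the intercensal
inputs and applies SEG.  Census 2 is the default adjustment target so that
the first census anchors the series.

**Age-trim sensitivity sweep.**  Rather than committing to one age range,
`trim_sweep()` runs a method over every contiguous window of at least eight
adjacent five-year groups between ages 15 and 80 and reports the mean,
minimum and maximum — displayed as "mean (min–max)" by
`format_estimate()`.  Thirteen groups (15–19 … 75–79) admit
$\sum_{L=8}^{13}(13-L+1) = 21$ windows.  Published analyses of this design
sometimes quote 20 combinations; no enumeration rule producing exactly 20
exists for this window family, so the package enumerates all 21 and exposes
the per-window table so any subset can be inspected.

## Life tables

`build_life_table()` uses the conventional abridged recursion with
$q = nM/(1 + (n-a)M)$, $a = n/2$ for closed intervals (adult ages dominate
every use in this package and no better information is available),
half-open intervals $[x, x+5)$, radix 100 000, and the open interval closed
by $e(A) = 1/M(A)$.  No old-age misreporting adjustment is applied; when the
interest is the *sex gap* in $e_{15}$, symmetric old-age error largely
cancels, but absolute $e_{15}$ levels at low completeness should be read
with that caveat.  $_{35}q_{15}$ is $1 - l(50)/l(15)$, identical to the
product $1-\prod(1-q_i)$ over the seven adult groups, which the tests
exploit as an independent oracle.

## Survey-based direct estimation

**Sibling histories.**  Survey files often blank deceased siblings' exact
dates, leaving integer age at death and years since death.
`impute_sibling_dates()` reconstructs decimal dates with a midpoint (+0.5)
convention — unbiased for integer-truncated values — and never overwrites
explicit dates; records that support neither route are dropped with a
logged count.  `sibling_exposure()` accumulates respondent-weighted
person-years in five-year cells over a half-open calendar period (deaths at
a boundary belong to the later period), restricted to ages 15–49 where
sibling reports are considered reliable.  `direct_35q15()` chains the cell
rates into $_{35}q_{15}$ and attaches a respondent-level bootstrap interval
(200 replicates by default, seeded); the bootstrap was preferred to a
jackknife because it needs no linearisation and respects the clustered
(respondent) design.  No correction for sibship-size selection is applied.

**Household deaths.**  `household_rates()` tabulates deaths and exact
person-years by sex and age group over the lookback window (default 5
years, labelled by its mid-period), building rates and, when the open
interval has deaths, full life tables and the $e_{15}$ gap.

**Weight screening.**  `screen_survey_weights()` drops a survey when the
missing fraction of its weight column strictly exceeds 0.5 — surveys with
essentially absent weights (e.g. 94–96% missing) cannot be used, while a
file exactly at the threshold is retained.

## Synthetic data and what the tests show

`make_ddm_scenario()` builds the exact stable population
$n(a) \propto e^{-ra}\,l(a)$ implied by a Gompertz hazard
$\mu(x) = \alpha e^{\beta x}$ (defaults $\alpha = 10^{-4}$,
$\beta = 0.085$, giving adult mortality typical of middle-income settings),
integrates it with composite Simpson quadrature (truncation at age 130,
relative error $\ll 10^{-9}$), and degrades it by census coverages
$k_1, k_2$ and registration completeness $c$.  Registered deaths are
*expected* counts by default — deterministic generation keeps recovery
tolerances tight and attributable — with Poisson sampling as a switch.
Exact boundary-age densities are retained so the growth-balance identity
can be verified to machine precision (`scenario_ggb_coords()`).  A crude
migration switch distorts census 2 while leaving deaths at closed-population
values; it exists purely as a negative control showing SEG's sensitivity to
migration.

Validation problem sizes, chosen as the smallest that make the statistical
checks decisive: the completeness-recovery grid uses 18 deterministic
scenarios ($c \in \{0.5, 0.7, 0.9\} \times r \in \{0, 0.01, 0.02\} \times
k_2/k_1 \in \{1, 0.95\}$, $t = 10$), on which the GGB–SEG trim-sweep mean
recovers $c$ within 0.01 (band tested: 0.03).  Sibling recovery uses 50
surveys of 10 000 respondents from a schedule calibrated to
$_{35}q_{15} = 0.10$; the bootstrap 95% interval covers the truth in about
91% of repetitions.  Household per-cell rate recovery uses roughly 400 000
members so that cells above age 55 hold 700+ expected deaths, making a 15%
relative band a 4-standard-deviation statement.

What the generators deliberately do **not** emulate: age misstatement and
heaping (beyond nothing — no systematic age-shift is applied by default),
duplicate sibling reports, realistic subnational heterogeneity, census
coverage varying by age, or genuinely dynamic (non-stable) populations.
Passing recovery tests therefore demonstrates correctness of the estimators
under the methods' own assumptions, not robustness to every real-data
pathology; the trim-sweep intervals are the package's instrument for
expressing that residual uncertainty on real data.

## Known limitations

* The DDM estimates are completeness *relative to census coverage*; absolute
  completeness is identified only up to $\sqrt{k_1 k_2}$ (GGB/SEG) or $k_1$
  (GGB–SEG adjusting census 2).
* No migration-adjusted DDM variant is implemented; use the trim windows to
  probe sensitivity instead.
* The abridged life table's open-interval closure $e = 1/M$ is exact only
  under a constant hazard beyond the open age; it is symmetric across sexes,
  which is what the sex-gap use case needs.
* Sibling estimates above age 50 are not produced (reports are unreliable
  there), so sibling-based $e_{15}$ is out of scope; only $_{35}q_{15}$ is
  computed from sibling data.
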