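---
title: "The IED model: scoring the intrinsic immunogenicity of radiotherapy schedules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The IED model: scoring the intrinsic immunogenicity of radiotherapy schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iedose)
```

## Why a time-aware dose metric

Classic radiobiology compares fractionation schedules through the
linear-quadratic (LQ) cell-kill model: the surviving fraction after a dose
$D$ is $e^{-\alpha D - \beta D^2}$, and schedule-level currencies such as
BED, $\sum_i d_i (1 + d_i / (\alpha/\beta))$, and EQD2,
$\mathrm{BED}/(1 + 2/(\alpha/\beta))$, summarize total cell kill. These
metrics are blind to *when* the fractions are given. Out-of-field
(abscopal) tumour responses, however, are thought to be immune-mediated:
irradiation releases tumour antigens that recruit and activate immune
effectors inside the tumour micro-environment (TME) — and those effectors
are themselves extremely radiosensitive, so the *next* fraction can wipe
out the response the previous one started. Two schedules with identical
BED can therefore have very different immunogenicity, and the interfraction
time becomes a first-class variable.

The Immunologically Effective Dose (IED) model implemented here scores that
intrinsic, schedule-driven component of immunogenicity. It deliberately
ignores everything patient- or drug-specific (tumour burden, choice of
checkpoint inhibitor, hot vs cold TME beyond what the $T_{IR}$ parameter
expresses): it isolates what the dosing regimen alone contributes.

## The model

A schedule is an ordered list of irradiation events $(T_i, d_i)$,
$i = 1 \dots N$, times in days, doses in Gy. Four parameters enter:

| parameter | meaning | units | default |
|---|---|---|---|
| $\alpha$ | LQ linear kill coefficient | Gy$^{-1}$ | 0.15 |
| $\alpha/\beta$ | LQ ratio ($\beta$ derived) | Gy | 4 |
| $T_D$ | time to death: half of the antigens of a killed cohort are released after $T_D$ | days | 3 |
| $T_{IR}$ | time to immune response: immune activation is half complete $T_{IR}$ after a release | days | 7 |

The defaults are the worked-example values used for every number quoted in
this vignette and in the package's reports; all are overridable everywhere.

Two kinetic curves in dimensionless time $x$ shape the cascade:
$f(x) = 1 - (1/2)^{x^2}$, the cumulative completion of a process that is
half done at $x = 1$, and its derivative
$g(x) = 2\ln 2 \, x \, (1/2)^{x^2}$. $g\!\big((t - T_i)/T_D\big)$ is the
antigen release rate of the cohort killed at $T_i$;
$f\!\big((T_{j+1} - t)/T_{IR}\big)$ is the fraction of the activation
triggered by a release at $t$ that completes before fraction $j{+}1$
arrives and kills the recruited effectors. Any similarly shaped sigmoid
pair would serve; the behaviour of the model comes from the convolution
structure, not the particular algebraic form.

Per-fraction immunogenic contributions are $E = S\,\Theta\,K$:

* $K_i = 1 - e^{-\alpha d_i - \beta d_i^2}$, the kill fraction of fraction $i$;
* $S_{ii} = \prod_{m<i} (1 - K_m)$, the tumour fraction still alive just
  before fraction $i$ (the geometric decay that makes early fractions
  dominate);
* $\Theta$ is upper-triangular with
  $\theta_{ij} = \int_{T_j}^{T_{j+1}}
  \frac{1}{T_D} g\!\Big(\frac{t - T_i}{T_D}\Big)
  f\!\Big(\frac{T_{j+1} - t}{T_{IR}}\Big) dt$ for $i \le j < N$, and
  $\theta_{iN} = 1 - f\!\big((T_N - T_i)/T_D\big)$ for the open-ended last
  window (nothing interrupts the activation after the final fraction, so
  only the residual release mass matters).

IED efficacy is $\Sigma E \in [0, 1)$ — the fraction of the initial tumour
volume converted into immunogenic antigens — and the IED itself back-solves
$1 - e^{-\alpha \cdot IED} = \Sigma E$: the single dose at infinitely low
dose rate (pure linear kill) with the same immunogenic yield. For a single
instantaneous dose the identities $\Sigma E = K_1$ and
$IED = D + (\beta/\alpha) D^2$ hold exactly; the test suite asserts both.

### The $1/T_D$ normalization

The release term is used as a probability density in absolute time $t$,
which requires the $1/T_D$ Jacobian of the substitution $x = (t-T_i)/T_D$.
Without it, row sums of $\Theta$ would scale with $T_D$ and exceed 1.
With it, three independent anchors line up: each row of $\Theta$ sums to at
most 1; the last-column closed form is the complement of the release CDF,
so the slow-death limit ($T_D \to \infty$: timing becomes irrelevant,
$\theta_{ij} \to 0$ for $j < N$ and $\theta_{iN} \to 1$, efficacy $\to$
total kill fraction) falls out analytically; and the reference worked
examples below are reproduced. Reproducing those examples was the first
implementation milestone.

## What the reference computations show

With the default parameters, `ied_evaluate()` gives:

* 3 × 8 Gy on days 0–2: BED 72 Gy, EQD2 48 Gy, IED efficacy **74%**;
* 5 × 6 Gy on days 0–4: BED 75 Gy, EQD2 50 Gy, IED efficacy **32%**;
* 25 × 2 Gy on weekdays over 32 days (`schedule_weekday(25, 2)`):
  BED 75 Gy, EQD2 50 Gy, IED efficacy **2%**.

The first two courses are nearly identical in classic currency yet differ
by more than a factor of two in efficacy — exactly the kind of distinction
BED cannot make. The two-fraction interfraction sweep
(`interfraction_sweep(2, 2, 0.25, 21)`) shows the characteristic shape: a
steep drop once the gap exceeds $T_D$ (the second fraction arrives while
effectors are being recruited) and a shallower recovery once the gap
exceeds roughly $T_D + T_{IR}$. The spread of that curve shrinks as
radiosensitivity falls: for the sweep's two standard settings the package
converts SF2 (surviving fraction at 2 Gy) to $(\alpha, \beta)$ by fixing
$\alpha/\beta = 4$ Gy and solving $e^{-2\alpha - 4\beta} = SF2$, since SF2
alone under-determines the pair; the assumed ratio is an explicit argument
of `sf2_params()`.

## Numerical choices

* **Quadrature.** Each $\theta_{ij}$ with $j < N$ uses adaptive
  Gauss–Kronrod quadrature (`stats::integrate`) at absolute and relative
  tolerance $10^{-10}$. The window is split at the release-density mode
  $T_i + T_D/\sqrt{2\ln 2}$ when it falls inside, so a spike that is
  narrow relative to a long window (gaps of weeks, $T_D$ of days) cannot
  be stepped over. Both kernels clamp to 0 for negative arguments. The
  test suite cross-checks the adaptive path against an independently
  written fixed-grid trapezoid rule ($10^5$ points per window, improper
  tail truncated at $T_N + 20\,T_D$) on 50 randomized schedules at
  $10^{-6}$ absolute.
* **Last column in closed form.** $\theta_{iN}$ is evaluated analytically
  rather than by truncated quadrature; the truncation lives only in the
  oracle.
* **Coincident events.** Events closer than $10^{-9}$ d merge into one
  event with the summed dose. The LQ model is nonlinear in dose, so this
  is a modelling choice, not an identity: two truly simultaneous fractions
  are treated as one delivery, and a zero-width integration window (which
  would silently contribute $\theta = 0$) can never arise.
* **Unequal doses.** The matrix formulation is stated for equal doses; the
  implementation carries per-fraction $K_i$ and the running product
  $S_{ii}$, which reduces exactly to the equal-dose powers and is required
  for hybrid courses mixing 2 and 3 Gy fractions.
* **Back-solve guard.** $\Sigma E < 1$ holds for every finite schedule;
  the solver still clamps at $1 - 10^{-15}$ to keep the logarithm finite
  against roundoff.
* **Rounding.** Human-facing reports round efficacy to the nearest whole
  percent (the field's reporting convention); machine formats (TSV, JSON)
  and all return values keep full precision.

## Scheduling conventions

Times are decimal days (a 6 h bifractionation offset is 0.25 d) and the
course starts at day 0; only relative times matter, and $\Theta$ is
invariant under a uniform time shift (tested to $10^{-12}$). Weekday
courses start on a Monday-equivalent: five treatment days, a two-day gap,
repeating — the only convention under which 25 daily 2 Gy fractions "over
five weeks" span exactly 32 days. Gaps in the interfraction sweep are
continuous values with no calendar.

## The schedule search

`constrained_search()` systematizes the manual exercise of designing a
split/bifractionated course that matches a reference course's BED, EQD2
and overall duration while scoring a higher efficacy. The candidate space
is deliberately a small exhaustive grid (`hybrid_candidates()`): lead-block
doses in {2, 3} Gy, whole-day breaks, a fixed 0.25 d bifractionation
offset, weekday-aligned normofractionated tails. This contains the
patterns of practical interest while keeping enumeration desk-scale;
ranking is by efficacy with lexicographic tie-breaking on the event list so
results are fully reproducible.

## Split-course captions and why no canonical values are claimed

Published prose descriptions of hybrid courses ("one bifractionated day, a
10-day break, nine bifractionated days, two normofractionated weeks") are
under-determined: the dose accounting of such a course does not match a
50 Gy / 25-fraction reference it is said to equal in BED and EQD2, and the
weekend handling inside bifractionated blocks is unstated. The acceptance
suite demonstrates that two defensible readings of the same description
yield different efficacies. The builders (`rt_segment()`,
`compose_segments()`) can express any plausible reading; the package
claims no canonical fixture or efficacy value for such courses.

## Decisions on open model questions

* The ad-hoc downward adjustment sometimes applied above 10 Gy/fraction
  has no published formula; `ied_evaluate()` exposes a `dose_transform`
  hook where a user-supplied transform can be injected, and ships no
  default. The transform affects only the kill/IED pathway; BED and EQD2
  stay physical.
* No non-LQ cell loss between fractions (e.g. tumour regression) is
  modelled in $S$; nothing in the model's source material constrains it.
* BED carries no repopulation/time factor and no dose-rate or
  repair-kinetics (Lea–Catcheside) correction — the time-free form is what
  the reference BED/EQD2 values assume.

## Problem sizes and limitations

Every quantity in the test suite and acceptance script is desk-scale: the
largest routine evaluation is the 25-fraction weekday course (a 25 × 25
$\Theta$, ~300 adaptive integrals, well under a second), the oracle
comparison uses 50 random schedules of up to 10 fractions, and the sweep
grids use 9–50 points. These sizes were chosen because they fully exercise
the model; nothing in the implementation limits N beyond the
$O(N^2)$ quadrature cost.

What passing tests show — and what they do not: the suite verifies the
mathematics (kernel calculus, matrix structure, limits, closed forms,
quadrature accuracy) and the reproduction of the reference worked
examples. It cannot validate the biology: $T_D = 3$ d and $T_{IR} = 7$ d
are order-of-magnitude estimates, the model deliberately omits every
patient-level covariate, and above 10 Gy/fraction the LQ model itself and
the model's immunogenicity predictions are both questionable. IED efficacy
ranks schedules under the model's assumptions; it is not a validated
clinical predictor.
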