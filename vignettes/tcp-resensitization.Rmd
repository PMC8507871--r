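---
title: "Population TCP modelling with resensitization kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population TCP modelling with resensitization kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zmtcp)
```

## The question the package addresses

High-dose-rate (HDR) mono-brachytherapy delivers prostate radiotherapy in
very few, very large fractions. Clinical registries report that a
three-fraction regimen spread over four weeks (3 × 11 Gy) controls
low-to-intermediate-risk disease better than a two-fraction regimen over two
weeks (2 × 14 Gy) — the opposite of what plain repopulation arguments
predict, since a longer treatment gives the tumor more time to regrow. One
mechanistic explanation is initial tumor hypoxia: a hypoxic tumor is
radioresistant at the start of treatment and *resensitizes* as it
reoxygenates, so later fractions — and only sufficiently *late* fractions —
meet a more vulnerable target. `zmtcp` implements a complete, testable
version of that analysis: an individual tumor-control-probability (TCP)
model with time-dependent radiosensitivity, population TCP distributions
under inter-patient parameter spread, calibration of the population
parameters to observed control rates, and the scenario grids (schedule
length × resensitization rate × dose per fraction) needed to compare
regimens.

## The individual TCP model

Tumor control is modelled as extinction of the clonogen population in a
birth-death process (the Zaider-Minerbo solution for fractionated delivery).
With fractions at times $T_1 = 0 < T_2 < \dots < T_n$ (days), doses $d_i$
(Gy), initial clonogen number $N_0$ and birth (repopulation) rate $\lambda$
(day$^{-1}$),

$$
\mathrm{TCP} \;=\; \left[\, 1 -
\frac{S(T_n)\, e^{\lambda T_n}}
     {1 + S(T_n)\, e^{\lambda T_n}
        \sum_{k=1}^{n-1} S^{-1}(T_k) \left(e^{-\lambda T_k} -
        e^{-\lambda T_{k+1}}\right)}
\right]^{N_0},
$$

where $S(T_k)$ is the cumulative survival after the first $k$ fractions.
The inner sum is empty for a single fraction, and for $\lambda = 0$ the
expression telescopes to the Poisson-type closed form $(1 - S)^{N_0}$; both
limits are unit-tested exactly. The formula is also cross-checked against an
independent stochastic simulation of the same branching process
(`simulate_extinction()`): a Yule pure-birth process between fractions
(whose increment has an exact negative-binomial law, so the simulation is
exact, not discretised) plus binomial thinning at each fraction. Agreement
within three binomial standard errors at $10^5$ replicates is part of the
test suite.

Cell kill follows the linear-quadratic (LQ) model with complete
inter-fraction repair,
$\log S = -\sum_{i} \alpha(T_i)\, d_i + \beta(T_i)\, d_i^2$,
with both coefficients evaluated at each fraction's delivery time.
Resensitization enters through

$$
\alpha(t) = \alpha_0\, e^{-b t^2/2} + \alpha_m \left(1 - e^{-b t^2/2}\right),
\qquad
\beta(t) = \beta_0 \left(\frac{\alpha(t)}{\alpha_0}\right)^{2}.
$$

$\alpha_0$ is the hypoxic starting sensitivity, $\alpha_m$ the fully
reoxygenated asymptote, and $b$ (day$^{-2}$) the resensitization rate. The
$\beta$ tie expresses the oxygen enhancement ratio acting linearly on
$\alpha$ and quadratically on $\beta$, the convention consistent with
$\beta$ scaling as the square of induced damage; it implies
$\alpha(t)/\beta(t) = \alpha_0^2 / (\beta_0\, \alpha(t))$, so the $\alpha/\beta$
ratio *falls* during treatment as the tumor resensitizes. A consequence
worth knowing: the quadratic tie makes late fractions far more effective
than early ones, which is what drives all schedule contrasts below.

Survival is carried on the log scale throughout (per-fraction survival can
be $e^{-22}$), exponentiation happens only inside the TCP formula with
`log1p` guards, and the repopulation sum is accumulated by log-sum-exp, so
no intermediate overflows or underflows occur even for $N_0 = 10^8$.

## From individuals to populations

Patients differ. The package models inter-patient variability by drawing
$(\alpha_0, \alpha_m, \beta_0)$ independently from normal distributions;
the population TCP is the mean individual TCP, which equals the expected
cure fraction of the cohort. The shipped defaults are the calibrated study
configuration:

| parameter | default | units | role |
|---|---|---|---|
| $\bar\alpha_0$, $\sigma_{\alpha_0}$ | 0.12, 0.02 | Gy$^{-1}$ | hypoxic linear sensitivity |
| $\bar\alpha_m$, $\sigma_{\alpha_m}$ | 0.23, 0.02 | Gy$^{-1}$ | resensitized asymptote |
| $\bar\beta_0$, $\sigma_{\beta_0}$ | $\bar\alpha_0/4.5$, 0.01 | Gy$^{-2}$ | quadratic sensitivity; mean tied via the most probable prostate $\alpha/\beta$ of 4.5 Gy |
| $\alpha/\beta$ window | (3.5, 6) | Gy | plausibility filter (below) |
| $N_0$ | $10^8$ | cells | fixed across individuals |
| $\lambda$ | 0.02 | day$^{-1}$ | slow prostate repopulation |
| $b$ | 0.066 | day$^{-2}$ | slow resensitization; 1 day$^{-2}$ models fast |

Three sampling rules matter:

* **Resampling, not clipping.** Draws violating positivity or
  $\alpha_m \ge \alpha_0$ are redrawn, keeping the accepted marginals
  near-normal rather than piling mass at a boundary.
* **The $\alpha/\beta$ plausibility window.** Individuals whose
  time-averaged $\alpha(T_i)/\beta(T_i)$ over the treated schedule falls
  outside 3.5-6 Gy are rejected and resampled. Because $\beta_0$ is drawn
  independently of $\alpha_0$, the raw ratio spread is wide; the window
  removes radiobiologically implausible combinations. Acceptance runs at
  roughly 30% under the defaults and is reported in every result; the
  sampler aborts with a diagnostic if acceptance falls below $10^{-3}$.
* **Common random numbers.** The cohort is a deterministic function of the
  population's seed, so scenario contrasts (schedules, doses, $b$ values)
  that share a population are paired: differences between scenarios are not
  inflated by sampling noise. Dose sweeps reuse literally the same cohort,
  which also makes the dose-TCP map monotone and safely invertible by
  bisection (`find_iso_tcp_dose()`, 0.1 Gy resolution).

`beta0` is drawn from its own normal rather than derived from each
individual's `alpha0`: the configuration ties only the *means*. This is the
simplest reading consistent with separate SDs for the two parameters; the
induced ratio spread is then filtered by the window.

The individual-TCP distribution is strongly non-normal. Under the defaults
the two-fraction clinical schedule produces a near-dichotomous shape — most
patients close to certain control plus a small subgroup near zero — while
the three-fraction schedule does not. `tcp_histogram()` reports the
fraction of individuals below TCP 0.05 as a standing diagnostic for this
dichotomy, and the test suite asserts that the two-fraction schedule always
carries more of that near-zero mass.

## Calibration and identifiability

`random_search()` reverses the pipeline: given two observed control rates
(the clinical anchors are 85.4% for 2 × 14 Gy/14 d and 95.3% for
3 × 11 Gy/28 d), it samples candidate population parameter sets uniformly
from a box, scores each by the worse of the two absolute TCP errors, and
returns the best candidate with its full evaluation trace. Search defaults —
box $\bar\alpha_0 \in (0.05, 0.3)$, $\bar\alpha_m \in (0.1, 0.5)$, SDs up to
0.05 (0.03 for $\sigma_{\beta_0}$), 500 evaluations, acceptance tolerance
0.02 — bracket the calibrated point generously while staying in plausible
Gy$^{-1}$ ranges. Candidates are scored on reduced cohorts (2,000) under
common random numbers and the winner is re-scored at full size.

This procedure is *not* a robust estimator of the individual parameters, and
the package does not claim identifiability: `profile_objective()` shows the
objective is much flatter along $\bar\alpha_0$ than along $\bar\alpha_m$
(the asymptotic sensitivity does most of the killing in late fractions, so
it is the best-determined direction). Recovery is therefore tested on the
TCP scale only: cohorts simulated from a known configuration yield targets
that a bracketing search recovers within 2 pp of TCP.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of the clinical registry data:
it samples `n_patients` individuals (window included), computes each
individual's TCP, and draws a biochemical failure as Bernoulli(1 − TCP).
Biochemical (PSA) failure is equated with loss of local control, as in the
source registries; follow-up duration, censoring, lead time and risk-group
covariates are deliberately out of scope. What passing tests show is
therefore that the *outcome-count machinery* is binomially consistent with
the simulated individual TCPs — not that real registries lack structure
(case mix, dosimetry variation, $N_0$ spread) the generator does not model.
`summarize_cohort()` is exact integer arithmetic with a Clopper-Pearson 95%
CI (appropriate at these small failure counts), and
`compare_to_clinical()` is an exact binomial test of an observed failure
count against a simulated failure probability.

## Design choices where the design was open

* **Clinical fraction times.** The regimens are described by their overall
  durations ("two weeks", "four weeks"); equal spacing — days {0, 14} and
  {0, 14, 28} — is the only reading consistent with the 7-day-interval
  shortened variants, and is what the package fixes.
* **Sensitivity at the instant of irradiation.** Fraction $i$'s kill uses
  $\alpha(T_i)$, $\beta(T_i)$ evaluated *at* its delivery time; the first
  fraction is always delivered at exactly $(\alpha_0, \beta_0)$, consistent
  with the initially-hypoxic framing.
* **TCP at end of treatment.** Control is evaluated at the last fraction;
  post-treatment dynamics and time-to-failure are not modelled.
* **Pure birth between fractions.** Death occurs only through irradiation;
  $\lambda$ is a net birth rate.
* **Window and cohort reuse.** The window is evaluated on the schedule
  being simulated; scenarios sharing a population reuse the same seed, so
  cohorts coincide wherever their windows do.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed, and `run_study()` derives all
stage seeds from the single config seed, hashes the configuration into its
manifest, and writes byte-identical CSVs on reruns. The analysis sizes the
package commits to are cohorts of 10,000 individuals for population TCPs
(Monte-Carlo SE below 0.5 pp), $10^5$ replicates for the birth-death oracle,
and a 10-16 Gy sweep in 0.2 Gy steps; all run in seconds on one core. Unit
tests use smaller cohorts (hundreds to a few thousand) since they test
logic, not precision.

## Known limitations

* The target is homogeneous in cell density and sensitivity and is
  irradiated homogeneously; no spatial hypoxia structure, no dose
  heterogeneity.
* Only the LQ survival model is offered (no LQL/LPL), with complete
  inter-fraction repair and no incomplete-repair correction.
* $N_0$, $\lambda$ and $b$ carry no inter-patient spread (hooks exist in
  the types but are untested surface, matching the study conditions).
* Organ-at-risk complication probabilities for dose-escalated variants are
  out of scope; the 14.8 Gy escalation result is a tumor-control statement
  only.
* The calibration's random search documents, rather than resolves, the weak
  identifiability of the population parameters.
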