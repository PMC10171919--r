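---
title: "Methods: a Markov cohort cost-effectiveness model for immunotherapy in MSI-H/dMMR colorectal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-effectiveness model for immunotherapy in MSI-H/dMMR colorectal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
decision model, the evidence-synthesis steps feeding it, the parameters that
matter, the numerical choices, and what the synthetic study conditions do and
do not establish.

## The decision problem

Patients with previously treated, unresectable or metastatic MSI-H/dMMR
colorectal cancer respond strongly to immune checkpoint inhibition: a
fraction become long-term survivors, visible as an L-shaped plateau on the
overall-survival curve. The economic question is whether an anti-PD-1
antibody (serplulimab: 3 mg/kg intravenously every two weeks, for up to two
years) is cost-effective against the small-molecule standard (regorafenib:
160 mg daily for the first 21 days of each 28-day cycle, until progression),
judged by the incremental cost per QALY against a willingness-to-pay
threshold of $36,036/QALY (triple GDP per capita). All monetary values are
2022 US dollars at 6.7413 yuan per dollar.

The two treatments were never compared head to head, and the comparator's
patient-level data are unpublished. That forces the two evidence-synthesis
steps the package implements: pseudo individual-patient-data (IPD)
reconstruction from digitized Kaplan-Meier figures, and an unanchored
matching-adjusted indirect comparison (MAIC).

## Evidence synthesis

**KM reconstruction (`reconstruct_ipd()`).** Input is a digitized curve
(time, survival) plus the numbers-at-risk table printed under published
figures. Within each risk-table interval the algorithm solves for integer
event and censoring counts whose product-limit estimate reproduces the
digitized values and whose implied number at risk matches the next published
one, iterating on the interval's censoring count. Events are placed at the
digitized step times; censorings are spread evenly inside their interval and
ordered after tied events (the standard KM convention). Digitized times are
taken as exact; the only repair is clamping survival to be nonincreasing,
with the number of repaired points logged. A published total event count, if
available, steers the final interval's censoring, within the censoring
budget that interval actually has; both with-total and without-total modes
exist because published risk tables and event totals vary.

**MAIC (`fit_weights()`).** The intervention arm's IPD are reweighted into
the comparator population: weights `w_i = exp(alpha'(x_i - x_target))` with
`alpha` chosen so weighted baseline moments equal the comparator's published
moments — the gradient condition of the strictly convex objective
`sum_i exp(alpha'(x_i - x_target))`. The solver is BFGS followed by Newton
polishing to an infinity-norm gradient below 1e-8. Matched covariates are
age, sex, ECOG status, adenocarcinoma histology, liver metastasis (the
"metastatic site" category reduced to one defensible indicator), >=2 prior
treatment lines and prior targeted therapy, entered as means/proportions.
Weights are rescaled to sum to `n` (frequency-weight convention) so that
downstream likelihoods and risk sets do not overstate information content;
the effective sample size `(sum w)^2 / sum w^2` is reported and should always
be examined. Matching fails loudly when a target sits outside the sample's
convex hull or covariates are collinear.

## Survival extrapolation

Six parametric families are fitted by weighted censored-data maximum
likelihood, with fixed parameterizations (exponential rate; Weibull
shape/scale with `S = exp(-(t/scale)^shape)`; gamma shape/rate; log-normal
meanlog/sdlog; log-logistic scale/shape with `S = 1/(1+(t/scale)^shape)`;
Gompertz rate/shape with hazard `rate * exp(shape * t)`). Optimization runs
on unconstrained scales (log for positive parameters, logit for the cure
fraction) from moment-based starts with two perturbed restarts; the
parameter covariance is the inverse observed information at the MLE, on the
same unconstrained scale — deliberately, because the probabilistic
sensitivity analysis draws correlated parameter vectors on exactly that
scale. Candidates are ranked by AIC with BIC reported; ties within 0.01 AIC
go to the fewer-parameter model, and the ranking can be overridden by
configuration, reflecting the field's practice of combining information
criteria with visual inspection.

The immunotherapy OS curve uses a mixture cure model
`S(t) = pi + (1 - pi) S_u(t)` with a log-normal uncured component, fitted
over `(logit pi, latent parameters)` with a multi-start over
`pi in {0.1, ..., 0.7}`; a boundary warning fires when `pi` pins near 0 or 1
and an identifiability warning when no censored follow-up extends past the
last event. The packaged base-case family choices are: intervention PFS
Gompertz, intervention OS log-normal mixture cure, comparator PFS and OS
log-logistic.

**Background-mortality floor (`apply_mortality_floor()`).** Cure-model
plateaus must not imply immortality. On the 28-day grid, each cycle's model
conditional death probability `1 - S(t_{j+1})/S(t_j)` is floored at
`1 - (1 - d_pop)^k`, where `d_pop` converts the sex-mix-averaged annual death
probability at the attained age via `1 - (1 - qx)^(28/365.25)`. The k-fold
assumption is therefore applied as a k-th power on per-cycle population
survival — a conditional-probability composition, not a hazard
multiplication, because the model lives on a discrete grid. `k = 2` in the
base case, `k = 4` in a scenario, identically for both arms (the source
analysis states the increased risk was applied to both). Attained age
advances deterministically from the starting age; the sex mix is fixed at
baseline (cohort model, not microsimulation). The packaged life table is
synthetic: Gompertz-Makeham mortality calibrated to modern Chinese period
life expectancy (about 74.7 years male, 80.5 female), closed at age 100 with
`qx = 1`. It is a constructed stand-in, clearly labelled, not official
statistics.

## The cohort model

Three states — progression-free (PFS), progressed (PD), death — on 28-day
cycles. Death risk is state-independent and comes from the OS curve
(`p_death = 1 - S_os[j+1]/S_os[j]`); progression absorbs the remainder of
the PFS curve's per-cycle drop (`p_prog = max(0, drop - p_death)`). This is
the one reading of "transitions estimated from the survival curves" under
which the trace reproduces both input curves exactly on cycle boundaries
(partitioned-survival equivalence), which the tests assert to 1e-12. The
published analysis does not disclose whether PD mortality differed from PFS
mortality; equal risk is recorded here as an assumption, not a fact. Curve
crossings after independent extrapolation are repaired by
`S_pfs := min(S_pfs, S_os)` with a logged count. The cohort starts fully in
PFS and runs until over 99% have died (the 36-month scenario stops at 39
complete cycles, the largest whole number of 28-day cycles inside 36
months). No half-cycle correction is applied in the base configuration — the
source analysis never mentions one — and the trace is computed by cumulative
products, which is algebraically identical to the per-cycle recursion
because death risk is state-independent; a 100,000-walker microsimulation
oracle checks the recursion semantics in the tests.

## Costs, utilities, discounting

All cost and utility constants live in versioned CSV fixtures under
`inst/extdata/`, never in code. Highlights, with the reasoning where the
source was silent:

* **Drug acquisition.** Serplulimab: 3 mg/kg at the 65 kg reference weight is
  195 mg, billed as 2 whole 100 mg vials ($828.92 each — vial sharing
  disallowed, which reproduces the printed $3,315.68 per cycle exactly),
  twice per 4-week cycle, for at most 26 cycles (the nearest whole cycle to
  the two-year stopping rule). Regorafenib: 21 daily doses at $102.34 while
  progression-free; the printed per-cycle constant ($2,149.19) differs from
  the dosing arithmetic ($2,149.14) by 5 cents — the printed value is used
  as the packaged constant and the discrepancy documented here.
* **Monitoring** is banded: years 0-3 in PFS, years 4-5, after year 5, and a
  PD band, per-cycle dollar values transcribed verbatim.
* **Adverse events** (grade >= 3, incidence >= 1%) are one-off — expected
  cost and a one-cycle disutility applied at cycle 0 — except hypertension,
  which is periodic: its trial-horizon incidence is converted to a per-cycle
  probability via `r = -log(1 - incidence)/horizon`,
  `p = 1 - exp(-r * 28/30.4375)`. The conversion horizon defaults to each
  arm's median treatment duration (9.83 and 3.2 months, the printed trial
  medians) because the source does not state the exposure window; this is
  the one rate-conversion input a reanalysis should revisit first. The
  transcription retains the source's own quirks verbatim (hospitalization
  values slightly inconsistent with days x daily rate; a nonzero PD
  administration cost for an oral drug; an AE whose management cost is
  listed under a myalgia label but whose incidence under creatine-kinase
  elevation — merged into one row here).
* **Utilities** 0.84/0.57 (base), 0.94/0.87 and 0.73/0.59 (scenario sets).
* **Discounting** at 5%/year for costs and effects, applied continuously in
  cycle time as `(1+r)^(-t)` evaluated at cycle start; a documented
  convention, switchable by passing a different rate, chosen because the
  source states only the annual rate.

## Uncertainty analysis

* **OWSA**: every economic parameter plus both discount rates, +/-20%
  multiplicative bounds (utilities capped at 1), recomputed on the fixed
  traces — economic parameters cannot alter state occupancy, which makes the
  tornado exact and fast. Degenerate bounds reproduce the base ICER
  identically.
* **PSA** (1000 draws): beta distributions for incidences and (dis)utilities,
  gamma for costs, hyperparameters by moment matching with SD = 20% of the
  base value; zero-valued parameters and discount rates stay fixed. Survival
  parameters are drawn jointly per fit block as multivariate normal on the
  unconstrained scale through the Cholesky factor of the fit covariance, and
  every draw re-derives floored curves, transitions, trace and economics —
  fit uncertainty propagates through the model structure, not through
  perturbed curves. Fixed seeds make the PSA bit-reproducible.
* **Scenarios**: direct comparison without MAIC (unit weights), 36-month
  horizon (39 cycles), 4x death risk, and the two alternative utility sets
  (which by construction change QALYs only — costs and life-years are
  identical to the base case).

## The synthetic study conditions

The real intervention-arm IPD are not public, so the packaged configurations
emulate the assumed data-generating structure: an intervention arm of
`n = 74` (inferred from the printed incidence granularity, 1.35% = 1/74;
configurable, not asserted as fact) with cure fraction 0.55, log-normal
latent OS for the uncured, Weibull PFS with median near 9.8 months, logistic
covariate shifts on the cure probability and AFT shifts on latent OS, 12
months of uniform accrual and a 36-month follow-up window; and a comparator
arm of `n = 136` without a cured component, log-logistic OS (median 8.8
months) and PFS (median 3.2 months — the comparator trial's published
medians used as calibration), slightly older, more male, more pretreated.
Cured subjects also carry durable PFS with probability 0.7, reproducing the
double plateau. The starting age (55) and sex mix (55% male) of the modelled
cohort are required configuration with no claim of fidelity — the source
does not print them.

What passing tests show: the pipeline's operations are correct on data with
the assumed structure (plateaus recovered, moments matched to 1e-6, curves
reproduced to <0.02 sup-norm, conservation to 1e-12, printed arithmetic
identities to the cent). What they do not show: agreement with the published
trial-based totals, which depend on the non-public IPD and the exact
digitized comparator curves; the headline synthetic ICER is therefore a
demonstration quantity, not a reproduction. Real trial data also carry
features the generator omits: non-administrative dropout patterns, covariate
correlations, non-proportional censoring, measurement error in digitization.

## Numerical choices and problem sizes

Convergence: BFGS with relative tolerance 1e-12 and up to 500 iterations,
three starts per fit, seven cure-fraction starts for the mixture model;
MAIC Newton polish to gradient norm 1e-8. Survival and density evaluations
are guarded (log-scale tail evaluation for the log-logistic and Gompertz;
densities floored at 1e-300) so extreme optimizer iterates are rejected
rather than propagated as NaN. The extrapolation grid is 780 cycles (about
60 years), long enough for the 99% stopping rule from age 55 under the
2-fold floor. Test problem sizes were chosen to make Monte Carlo bounds
sharp while keeping the default suite a few minutes long: 100 replicates at
n = 2000 for parameter-recovery and selection-consistency studies, 500
subjects for reconstruction fidelity, 100,000 walkers for the
microsimulation oracle (compared under a familywise 0.1% band — a pointwise
3-SE band across ~400 correlated boundaries would reject valid draws), and
1000 PSA draws in the acceptance script.

## Known limitations

* Unanchored MAIC carries its usual burden: it adjusts only for the listed
  observables and assumes they capture all cross-trial differences.
* The equal-mortality reading of the two-curve evidence is an assumption;
  tunnel states or state-specific mortality are out of scope.
* The periodic-AE conversion horizon and the one-cycle duration of one-off
  AE disutilities are documented choices where the source is silent.
* Exact reproduction of the published totals is out of reach by design
  (non-public IPD); the package instead proves the machinery on synthetic
  conditions and the printed arithmetic identities.
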