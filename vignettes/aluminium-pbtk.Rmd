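---
title: "An age-dependent toxicokinetic model of aluminium from diet and subcutaneous immunotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An age-dependent toxicokinetic model of aluminium from diet and subcutaneous immunotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Aluminium (Al) hydroxide adjuvants in subcutaneous allergen immunotherapy
(SCIT) deliver up to 1.25 mg Al per injection, every four weeks, for years.
Whether the resulting body burden approaches tissue levels of toxicological
concern — particularly in children, and particularly in the two Al storage
organs, bone and brain — cannot be answered by clinical sampling: tissue Al
is not measurable in vivo at these exposures. `alupbtk` provides a
physiologically based toxicokinetic (PBTK) simulator to explore this
question: a whole-body compartment model of Al that grows from birth to age
50, a dosing layer for continuous dietary intake and zero-order
injection-site depots, a virtual population with lognormal inter-individual
variability, and an assessment layer that reduces the simulated population
to the percentile statistics and threshold comparisons used in regulatory
risk assessment.

## Model structure

Amounts $A_i(t)$ (µg) are tracked in plasma, bone, brain, liver, kidney and
rest-of-body, plus cumulative urine. With $C_{pl} = A_{pl}/V_{pl}(a)$ the
plasma concentration (µg/L) at age $a$:

$$\frac{dA_{pl}}{dt} = r_{diet}(a) + r_{depot}(t)
  + \sum_{i \in \{li,ki,re\}} k_{out,i} A_i + k_{rel}(a) A_{bone}
  - \Big(\textstyle\sum_i CL_i(a) + CL_{brain}(a) + \kappa\,F_{Ca}(a)
  + f_R \cdot GFR(a)\Big) C_{pl}$$

$$\frac{dA_{bone}}{dt} = \kappa\, F_{Ca}(a)\, C_{pl} - k_{rel}(a) A_{bone},
\qquad \frac{dA_{brain}}{dt} = CL_{brain}(a)\, C_{pl}, \qquad
\frac{dA_{urine}}{dt} = f_R \cdot GFR(a)\, C_{pl}$$

Key structural assumptions:

* **Amount-based equations with growing organs.** Concentrations are
  amounts divided by age-dependent organ masses, so growth dilution is
  implicit. This is what produces the neonatal decline of plasma and tissue
  concentrations after the high in-utero-derived birth levels, before the
  increasing dietary intake takes over.
* **Renal elimination only.** Elimination is `renal_extraction * GFR *
  C_plasma`; `renal_extraction` (~0.06 after calibration) is the
  filterable fraction of plasma Al, consistent with extensive protein
  binding. GFR matures after birth as a Hill sigmoid on post-menstrual age
  (halftime 1.06 y PMA, Hill 3.33 — i.e. ~50% of the size-adjusted adult
  value around 4 months after term birth) scaled by body weight to the
  power 0.75. The sigmoid is placed on post-menstrual rather than postnatal
  age so that newborn filtration is small but positive.
* **Bone follows calcium.** Al uptake into bone is proportional to the Ca
  accretion flux $F_{Ca}(a)$ (mg Ca/day) and to $C_{pl}$, with a single
  coupling constant $\kappa$; release is first-order with the fractional Ca
  release rate $k_{rel}(a)$ of bone remodelling. The default accretion
  curve is an adult plateau (250 mg/day) plus an infant component and a
  Gaussian pubertal peak (centre 12.5 y, sd 1.5 y, female); the release
  rate declines from 3e-3/day in infancy to 3.5e-4/day in adults (turnover
  ~7.8 y). Both curves can be replaced by tabulated alternatives
  (`read_ca_table()`).
* **Brain is a sink.** Uptake is a small clearance with no return flux, so
  brain Al accumulates for life; this is why treatment-attributable brain
  increments persist to age 50 while bone increments wash out.
* **Liver, kidney, rest** exchange with plasma by first-order uptake
  clearances and fractional returns. Uptake clearances (and the brain
  clearance) are scaled by current/adult organ mass during growth
  (`scale_uptake_with_mass`), keeping perfusion-limited exchange
  proportional to organ size; adult behaviour is unaffected.

## Dosing

* **Diet** is a continuous zero-order input: 0.1, 0.2, 0.4 and 0.8 mg
  Al/kg/week for ages 0–3, 4–6, 7–9 and 10–12 months and 0.8 mg/kg/week
  (80% of the tolerable weekly intake of 1 mg/kg/week) thereafter, times
  body weight, with oral bioavailability 0.17%. Absorbed adult input is
  ≈11.7 µg/day.
* **Subcutaneous depots** release a constant `dose × k` per day until
  exhaustion at `1/k` days (zero-order, 100% injection-site
  bioavailability): `k = 0.0024864`/day for commercial Alhydrogel-type
  adjuvant (Ahy, ~402 days ≈ one year) and `0.0082392`/day for in-situ
  precipitated hydroxide (Ains, ~121 days ≈ four months). Overlapping
  depots superpose; at the four-weekly maintenance rhythm ~14 Ahy depots
  are simultaneously active and the mean absorbed input is `1250/28 ≈
  44.6` µg/day — about four times the dietary input, which is why plasma
  and bone rise markedly during treatment.
* **Schedules**: 13 doses per 364-day treatment-year at the 28-day
  interval, so 5, 10 and 40 treatment-years give exactly 65, 130 and 520
  doses (101.25/162.5/650 mg would otherwise not come out exactly);
  consecutive blocks are back-to-back, parallel products are simultaneous
  rows sharing the individual's release-rate draw. Updosing phases carry
  negligible Al and are omitted.

## Virtual population

`sample_population()` draws lognormal multipliers with median 1 for oral
bioavailability, GFR, a shared tissue-distribution factor (CV 0.30 each;
configuration values, assumed independent) and the depot release rate
(CV 0.50). One population object is reused across all scenarios of a
comparison — common random numbers — so percentile ratios compare the same
500 individuals with and without treatment. The typical individual (all
multipliers 1) equals the no-variability model because the multipliers have
median 1.

## Assessment

Per tissue and timepoint the population is reduced to median, p5 and p95
(quantile type 7, linear interpolation between order statistics — fixed so
results reproduce across languages), with a seeded nonparametric bootstrap
(percentile method, B = 1000) for the 90% CI of p95; an order-statistic CI
would be a reasonable alternative, the bootstrap was chosen for
distribution-freeness and because it directly captures the sampling impact
at n = 500. Three p95 ratios contrast a treated scenario with the baseline
on the paired population: five years after treatment start vs baseline at
the same age (5/5), vs baseline at age 50 (5/50), and both at age 50
(50/50). Dry-weight literature values are converted to the model's
wet-weight scale with tissue factors (bone 0.497, brain 0.23; the liver
factor 0.25 is derived from published paired dry/wet values and flagged as
such). Thresholds (bone ULN 5, critical 7, disease 30 µg/g ww; brain ULN 1;
liver 4; kidney 1.6) enter only this layer — simulations never depend on
them.

## Calibration and oracles

Dietary tiers, bioavailability, depot rates, conversion factors and
thresholds are literature-anchored constants. The remaining rate constants
are not published; `calibrate()` fits `renal_extraction`, `kappa_bone`,
`k_brain_in` and the liver/kidney uptake clearances to adult
background-exposure levels of the typical individual (plasma 1.4 µg/L at
40; bone 0.6 µg/g ww at 40 and 50; brain 0.23/0.28 µg/g ww at 40/50; liver
1 and kidney 0.5 µg/g ww) by Nelder-Mead least squares on the log scale.
Because targets are typical-individual medians the objective is
deterministic; the fitted set ships as `inst/extdata/params_default.json`
(all targets within 2.4%) and a synthetic-recovery test confirms the fitted
subset is identifiable (parameters regenerated from model-generated targets
within 5%). These anchors constrain but do not uniquely identify every
constant: `k_in_rest`, the return rates `k_out` and the birth amounts are
conventions, fixed in the fixture and documented there.

Verification uses two independent oracles: the exact piecewise solution of
the one-compartment reduction (tissue exchange zeroed, flat physiology),
and a classical RK4 fixed-step integrator over the same right-hand side
with the same event bracketing (automatic step halving on instability —
the plasma compartment has eigenvalues of several per day, so dt = 0.25 d
sits near the explicit stability boundary during infancy).

## Numerical choices

* Stiff-capable adaptive solver (`deSolve::lsoda`) with the analytic
  Jacobian of the linear system; rtol 1e-8 / atol 1e-10 µg for single
  simulations. Population runs default to rtol 1e-6 / atol 1e-8:
  percentile summaries agree to better than 1e-4 while run time drops
  ~3-fold.
* Every dose time, depot exhaustion time and dietary-tier boundary is an
  exact integration restart; within a segment all forcing is constant, so
  the piecewise-constant inputs are never smeared across a step. Disabling
  the bracketing measurably degrades mass balance (regression-guarded).
* Mass balance is audited against solver-independent inputs: adaptive
  quadrature of the dietary input plus the closed-form cumulative depot
  release; default runs close to better than 1e-6 relative.
* Age-dependent coefficients are precomputed on a fine age grid (0.02 y in
  infancy) and linearly interpolated inside the right-hand side; organ
  masses use monotone piecewise-cubic Hermite interpolation on log mass,
  so tabulated monotone growth stays monotone and derivatives are
  continuous.
* Time unit days, ages reported in years (365.25 d); the 364-day
  treatment-year is used only for schedule construction.

## Problem sizes

Scenario comparisons and the packaged summary statistic use N = 500
individuals, the population size the variability design is meant for (the
bootstrap CI of p95 quantifies the sampling impact at that size).
Qualitative shape checks in the test suite run at N = 50, and structural
properties (superposition, linearity, oracle agreement) on single
individuals over shortened horizons — those properties are scale-free.

## What the generator does and does not emulate

The virtual population emulates between-subject variability in absorption,
elimination and distribution around a single reference female anatomy. It
does not emulate: covariance between body size and kinetic parameters (all
individuals share the growth table), measurement error, renal impairment,
sexes mixed in one population, pregnancy, or exposure beyond age 50. A
passing suite therefore demonstrates internal consistency of the model and
its statistics, not predictive accuracy for any real cohort; the
calibration anchors are population-typical adult levels, and the
treatment-period increments follow mechanistically from the absorbed input
rates above.

## Known limitations

* The growth table and Ca curves are packaged reference fixtures
  (synthetic, standard anthropometry), not subject data.
* Bone is a single well-mixed compartment; no surface/volume
  sub-compartments or mineral mass balance.
* Brain is an absolute sink; any slow efflux would lower late-life brain
  predictions.
* The p95 of heavy-tailed tissue distributions is noisy at small n; at
  N = 50 seed-to-seed variation of the p95 itself is substantial (the
  reason the shape checks assert orderings, not absolute levels).

## A worked comparison

```{r example}
library(alupbtk)

pop <- sample_population(n = 500, seed = 1)
base <- run_population(pop, get_scenario("food_only"),
                       out_ages = c(10, 50))
trt <- run_population(pop, get_scenario("child_high_ahy_5"),
                      out_ages = c(10, 50))

summarize_run(base)
p95_ratios(trt, base, t_start = 5, tissue = "bone")

tab <- build_table1(list(food_only = base, child_high_ahy_5 = trt),
                    start_ages = c(child_high_ahy_5 = 5))
write_table1(tab, "table1.csv", "table1.json")
```
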