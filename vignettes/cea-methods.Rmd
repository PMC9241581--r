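---
title: "Methods: a weekly-cycle Markov model for first-line EGFR-mutated NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a weekly-cycle Markov model for first-line EGFR-mutated NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrcea)
```

## The decision problem

Patients with advanced EGFR-mutated non-small cell lung cancer can start any
of up to twelve first-line strategies whose efficacy was compared in a single
network meta-analysis: six tyrosine kinase inhibitors (TKIs), four
combinations, and two chemotherapy doublets, with pemetrexed-free
chemotherapy (PfCT) as the common reference. The question a payer asks is not
"which treatment is best" but "which treatment buys health most efficiently"
— in the UK at £20000–£50000 per QALY, in China at £8000–£24000 per QALY
(about one and three times GDP per capita). `egfrcea` implements the full
model chain from survival curves to acceptability curves.

## Survival model

Reference-arm progression-free survival (PFS) and overall survival (OS)
follow Weibull curves

$$S(t) = \exp(-\lambda t^{\gamma}),$$

with **t in months**. The published parameter table does not state the time
unit; months is the only reading consistent with the rest of the print:
the implied median reference PFS is `r round(weibull_median(uk_inputs()$pfs_ref), 2)`
months and the mean OS `r round(weibull_mean(uk_inputs()$os_ref), 1)` months
(≈ 2.79 undiscounted life years, matching the reference arm's printed ~2.6
discounted LYs), whereas a weekly unit would imply clinically impossible
curves. Weekly model cycles convert through $t_{months} = weeks \times
7/30.4375$, and all annual↔weekly conversions use 52.18 weeks per year
(365.25/7).

Comparator arms share the reference shape $\gamma$ and scale
$\lambda_{alt} = \lambda_{ref} \times HR$, the proportional-hazards identity.
`fit_parametric()` additionally provides right-censored maximum-likelihood
fitting of the exponential, Weibull, Gompertz ($h(t)=a e^{bt}$), log-logistic
and log-normal families for reconstructed pseudo-patient-level data, with
`select_model()` choosing by BIC (ties: AIC, then the conventional family
order). Digitisation of published Kaplan–Meier figures is out of scope; the
fitting operations accept already-reconstructed datasets.

## Markov engine

Three exclusive states — progression-free (PF), progressed disease (PD),
dead — on weekly cycles for 1043 weeks (20 years, labelled "lifetime"; the
cohort starts at age 71.4 (UK) / 61.6 (China), so under 1% remains alive at
the horizon). Each cycle:

1. PF exits follow the PFS curve: $q = 1 - S(t_{k+1})/S(t_k)$.
2. PF→dead is floored by age-specific background mortality from the life
   table (annual $q$ converted to weekly via $1-(1-q)^{1/52.18}$; integer age
   floor, ages above the table clamp to its last row).
3. PD→dead is solved so cumulative deaths track $1 - S_{OS}(t_{k+1})$,
   clipped to $[0, 1]$. This is the standard conversion from partitioned
   survival curves to a state-transition model; the source states only that
   an "elevated mortality rate" applies in PD. The number of clipped cycles
   is recorded in the trace (`clipped_cycles`); clipping is structural for
   arms whose PFS hazard ratio is far stronger than their OS hazard ratio
   (early cycles have almost no PD occupancy to absorb the OS-implied
   deaths) and does not disturb occupancy conservation, which is asserted to
   1e-9 for every arm in the test suite.

No half-cycle correction is applied: with weekly cycles the correction is
below the rounding of every reported quantity.

### Costing

The published cost table prints acquisition costs "per cycle"; the model
cycle is one week, and the package charges each regimen's printed row per
weekly cycle while the component is active: oral TKIs until progression,
chemotherapy components for at most four 3-week cycles (12 weeks), and
monoclonal antibodies until progression. Combination rows are charged at the
printed combination rate during the chemotherapy window and drop to the
printed TKI-alone rate afterwards — this uses only printed numbers and
reproduces the published total-cost ordering closely (e.g. UK osimertinib
£142.6k modelled vs £139.5k printed). Administration costs follow the same
activity flags (TKI administration weekly while an oral component runs;
infusion administration weekly while an infusion component runs).

After progression, the stated uptake fraction (61.0% UK, 52.8% China)
receives active second-line treatment — pemetrexed + platinum for 12 weeks,
then docetaxel for 12 weeks, then best supportive care (BSC) for TKI-class
arms; docetaxel then BSC for chemotherapy-class arms — and the remainder
receives BSC immediately. BSC costs apply only after active lines end, and
terminal care is charged once per death from either alive state (both points
the source leaves open). Because this pathway cost depends on time since
progression, the engine tracks PD entrants through an exact 24-week tunnel
plus a pooled late-PD state (the cost profile is piecewise constant with no
break beyond 24 weeks); the tunnel recursion is verified in the tests against
a brute-force per-entrant oracle. An earlier FFT-convolution implementation
was abandoned: when the OS calibration clips repeatedly the within-PD
survival product underflows and the convolution loses all precision.

SAE management costs and utility decrements are applied once, at model
entry, as incidence-weighted one-off amounts — matching the per-event
costing ("£ per event") and single-number QALY-loss reporting of the source.
QALYs accrue as $(u_{PF} \cdot pf + u_{PD} \cdot pd)/52.18$ per week, and
cycle-$k$ increments are discounted by $(1+r)^{-k/52.18}$.

## Incremental analysis

`build_frontier()` sorts strategies by cost, removes strictly dominated ones
(weak dominance: no worse on both axes, strictly better on one; exact ties
keep the first by input order), then iteratively removes any strategy whose
ICER against the previous retained strategy *exceeds* that of the next
(extended dominance). Exactly collinear points are kept, so a line of
positive slope survives intact. The result is the lower-left convex hull of
the cost-QALY plane; the tests verify equivalence with a brute-force
convex-combination oracle on 400 random planes. Applied to the published
base-case table, the algorithm reproduces the four-arm frontier (gefitinib,
gefitinib + pemetrexed, gefitinib + PbCT, osimertinib) and every printed
dominance label in both countries.

Sequential ICERs recomputed from printed, rounded costs and QALYs can
deviate from the printed sequential ICERs by more than rounding of the ICER
itself suggests — most visibly where the QALY gap is small (osimertinib vs
gefitinib + PbCT in China: gap 0.017, recomputed 230235 vs printed 224999).
Comparisons in the acceptance tests therefore allow the larger of 0.5%
relative and the interval implied by half-ulp perturbation of the printed
inputs; this is the precision of the print, not a loosened criterion.

## Sensitivity and uncertainty

**One-way DSA** varies a single registered parameter to its stated low/high
bound (base ±20% where no range is printed) and re-runs the deterministic
model; `tornado()` ranks by ICER spread. For gefitinib + PbCT vs PfCT in the
UK the three largest bars are the PFS hazard ratio, the PF utility and the
OS hazard ratio, reproducing the published finding. The Weibull reference
parameters are not varied one-way (their printed uncertainty is a Cholesky
matrix, not a range); they are sampled jointly in the PSA.

**Scenarios.** Four registered scenarios re-run the model under documented
overrides. Two require values the main text does not print and use documented
stand-ins: `flaura_os_update` sets the osimertinib-vs-reference OS hazard
ratio to 0.57 (the mature-FLAURA update raised osimertinib QALYs by ~0.06;
the trial's own HR of ~0.8 is against gefitinib/erlotinib and cannot be used
against the chemotherapy reference directly), and `bnf_prices_uk` uses BNF
list-price placeholders for the eMIT-priced oral drugs. `alt_utilities`
raises the PD utility to 0.473 (the only alternative utility the source
prints) in both countries. `t790m_osimertinib_second_line` routes 60% of
second-line-treated TKI-class patients to osimertinib until death and the
rest to PbCT.

**PSA** draws gamma costs, lognormal hazard ratios, beta
utilities/proportions, uniform discount rates, and the Weibull pairs jointly
on the log scale: marginal SDs are back-solved from the printed 95% ranges
and the $(\ln\lambda, \ln\gamma)$ correlation defaults to −0.5, the typical
negative correlation of Weibull fits (the source prints no covariance; both
are configurable through `weibull_params`). The life table and the SAE
incidence proportions stay fixed — the former has no printed distribution,
the latter are themselves placeholders (below). A master seed spawns
per-iteration sub-seeds, recorded in the output for replay. `ceac()` reports
the fraction of iterations in which each arm attains maximal net monetary
benefit, ties split equally.

## What the packaged fixtures are — and are not

All parameters printed in the source's input tables are transcribed exactly,
and a load-time audit verifies that each distribution's central value (gamma
mean, beta mean, lognormal median) reproduces its printed expected value.
The audit tolerance is 2% relative *or* 1.0 currency unit absolute: several
small integer-printed costs (docetaxel £5, TKI administration £3, Chinese
diarrhoea/rash £4) have gamma scales rounded to two decimals, which moves
their implied mean by up to 20% of a very small base while remaining within
half-ulp of both printed numbers. The annual discount rate is exempt: its
printed uniform PSA range (0–6% / 0–8%) is deliberately not centred on the
base (3.5% / 5%).

Three ingredients are **not** printed in the main text and ship as
documented synthetic stand-ins:

- per-arm SAE incidences — the five values quoted for gefitinib ± PbCT
  (fatigue 4.76%/0.61%, neutropenia 27.14%/0.20%, leukopenia 17.14%/0.10%,
  anaemia 17.14%/0.40%, thrombocytopenia 13.81%/0.00%) are used verbatim;
  the rest are placeholders consistent with the reported safety ordering
  (icotinib best, erlotinib + bevacizumab worst);
- per-event SAE disutilities — literature-style values (0.03–0.09 per
  event);
- national life tables — Gompertz–Makeham curves
  $q(age) = 1-\exp(-(a + c e^{b\,age}))$ calibrated to ≈2% annual mortality
  at the UK start age and ≈1.2% at the China start age.

Consequently the package reproduces the published *relative* structure —
QALY ranking (osimertinib and gefitinib + PbCT highest, the chemotherapies
lowest), the four-arm frontier, the CEAC winners at the decision thresholds
(gefitinib at the lower threshold, gefitinib + PbCT at the upper one) — and
comes within a few percent on most absolute totals, but absolute costs and
QALYs are *not* validation targets: a green suite establishes the model
mechanics and the printed-table arithmetic, not the unavailable supplementary
inputs. One visible consequence: UK gefitinib lands £396 above the reference
chemotherapy where the print has it £470 below — inside the resolution of
the SAE-cost placeholders.

The synthetic-data module generates censored Weibull datasets (uniform
censoring with the maximum solved numerically to hit a target censored
fraction — administrative censoring, not dropout), random cost-QALY planes,
life tables and complete randomized input sets; all generators are seeded and
bitwise reproducible. It emulates the statistical shapes the pipeline
assumes, not trial-specific recruitment or dropout.

## Numerical choices

- OS-calibration clip bounded at $1 - 10^{-9}$ so within-PD survival stays
  positive; clip counts recorded per trace.
- Extended-dominance removal uses strict inequality (collinear points kept).
- Degenerate ICERs (zero QALY difference) are flagged, never returned as a
  number.
- `fit_parametric` errors on non-convergence (Gompertz) and on all-censored
  or sub-10-observation data.
- Currency is 2019 GBP throughout; the £1 = CNY 8.78 conversion is metadata
  only.

## Known limitations

Cohort-level modelling only (no microsimulation, no separate
time-on-treatment curve); SAE burden applied at entry rather than spread
over the treatment course; second-line pathway durations fixed at four
cycles; the placeholders listed above. These match the scope of the source
analysis rather than gaps relative to it.
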