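# egfrcea

Cost-effectiveness modelling of first-line treatments for advanced
EGFR-mutated non-small cell lung cancer (NSCLC), from the perspectives of the
UK NHS and the Chinese health-care system.

Twelve first-line strategies compete for the same patients: six EGFR tyrosine
kinase inhibitors (osimertinib, dacomitinib, afatinib, erlotinib, gefitinib,
icotinib — the last licensed in China only), four combinations (afatinib +
cetuximab, erlotinib + bevacizumab, gefitinib + pemetrexed, gefitinib +
pemetrexed-based chemotherapy "PbCT") and two chemotherapies (PbCT and
pemetrexed-free chemotherapy "PfCT", the reference). `egfrcea` implements the
full decision model needed to compare them:

- **Survival extrapolation.** Reference-arm progression-free and overall
  survival follow Weibull curves, S(t) = exp(−λ t^γ) with t in months
  (PFS: λ = 0.0474, γ = 1.559; OS: λ = 0.0075, γ = 1.360). Comparator curves
  share γ and scale λ by the network-meta-analysis hazard ratio (proportional
  hazards). Parametric fitting of reconstructed patient-level data
  (exponential / Weibull / Gompertz / log-logistic / log-normal, right-censored
  MLE) with AIC/BIC model selection is included.
- **Markov cohort engine.** Three states — progression-free (PF), progressed
  disease (PD), dead — on weekly cycles over a 20-year "lifetime" horizon.
  PF exits follow the PFS curve with an age-specific background-mortality
  floor from a life table; PD→dead is calibrated each cycle so cumulative
  deaths track the OS curve. Accrual covers drug acquisition and
  administration (oral components until progression, chemotherapy limited to
  four 3-week cycles, antibodies until progression), disease management,
  uptake-weighted second/third-line pathways, terminal care, one-off serious
  adverse-event (SAE) costs and disutilities, and discounted QALYs/LYs
  (3.5%/yr UK, 5%/yr China).
- **Incremental analysis.** ICERs, net monetary benefit, and the
  cost-effectiveness frontier under strict and extended dominance with
  sequential ICERs.
- **Uncertainty.** One-way DSA with tornado ranking, four scenario analyses,
  and probabilistic sensitivity analysis (gamma costs, lognormal hazard
  ratios, beta utilities/proportions, jointly sampled Weibull parameters via
  a Cholesky factor) with cost-effectiveness acceptability curves (CEACs).

Packaged input sets transcribe the published UK and China parameter tables;
per-arm SAE incidences, per-event disutilities and the national life tables
are not printed in the source and ship as documented synthetic placeholders
(see the methods vignette for exactly what that does and does not validate).

## Worked example

```r
library(egfrcea)

inputs <- china_inputs()            # 12 arms, validated
res <- run_all(inputs)              # deterministic base case
res[, c("arm", "cost", "qaly", "ly")]
#>                      arm  cost   qaly    ly
#> 1              Gefitinib 12912 1.2805 2.494
#> 2            Osimertinib 25104 1.8742 3.343
#> ...
#> 10        Gefitinib+PbCT 18724 1.8210 3.480
#> 12                  PfCT 14474 0.9805 2.527

build_frontier(res)
#>                     arm  cost    qaly     classification seq_icer
#> 1             Gefitinib 12912 1.28051        on_frontier       NA
#> 6        Gefitinib+PbCT 18724 1.82103        on_frontier    10752
#> 9           Osimertinib 25104 1.87424        on_frontier   119918
#> ... (others dominated / extended_dominated)
```

Gefitinib is the cheapest strategy (£12912 for 1.28 QALYs); moving up the
frontier, gefitinib + PbCT buys each extra QALY for about £10.8k —
well inside China's £8000–£24000/QALY willingness-to-pay band — while the
step up to osimertinib costs ~£120k per QALY and is not cost-effective.
Probabilistic uncertainty:

```r
ps <- run_psa(inputs, n = 5000, seed = 1)
ceac(ps, thresholds = seq(0, 30000, by = 2000))
```

One-way sensitivity and scenarios:

```r
tornado(uk_inputs(), comparison = c("Gefitinib+PbCT", "PfCT"))
run_scenario(uk_inputs(), "alt_utilities")
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/cea-cli.R` (`run`, `frontier`, `dsa`, `psa`, `fit-survival`).

## Acceptance script

`scripts/acceptance.R` rebuilds the cost-effectiveness frontier from the
packaged published base-case table (costs/QALYs of every strategy in both
countries) with the package's own dominance algorithm, and reports the
resulting frontier size and sequential ICERs:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
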