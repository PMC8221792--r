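# maintflux

Constraint-based metabolic models of Chinese hamster ovary (CHO) cells
predict growth rates well, but their intracellular flux predictions —
especially in the TCA cycle — are systematically underestimated because the
models lack a non-growth-associated maintenance energy demand (mATP): the
ATP spent on macromolecule turnover and ion gradients even at zero growth.
`maintflux` implements the full analysis chain for quantifying this demand
in a genome-scale metabolic model (GSMM), for modellers who want to
estimate, impose and validate a maintenance constraint:

* **Flux prediction** by parsimonious flux balance analysis (pFBA):
  maximize the biomass objective subject to `S v = 0` and measured
  exchange-rate bounds, then minimize `Σ|v|` at the fixed optimum. The LP
  core is a bounded-variable two-phase simplex written for determinism and
  cross-checked against brute-force vertex enumeration.
* **¹³C flux reconciliation**: signed many-to-one mapping of GSMM fluxes
  onto the coarse reaction namespaces of ¹³C metabolic flux analysis
  (compartment merges, lumped-step net fluxes, multi-reaction sums), with
  relative errors `|v_p − v_e| / |v_e|` after filtering fluxes below 1 % of
  the dataset maximum.
* **Computational mATP estimation**: a grid search (0–40 mmol gDW⁻¹ h⁻¹,
  step 0.25) fixing the ATP-hydrolysis maintenance reaction and picking the
  value minimizing the median relative flux error, per dataset and jointly.
* **Uptake objective functions**: minimizing the uptake of a nonessential
  nutrient (glucose, glutamine, ...) instead of maximizing growth, with
  essential amino-acid uptakes reconciled against the minimum required for
  the measured growth rate.
* **Chemostat energetics**: steady-state rate computation from raw
  continuous-culture series (`D = F/V`, `μ = D·Nt/Nv`,
  `q = (Cout − Cin)·D/X`) with standard-deviation propagation, slope-based
  stability checks and carbon-recovery accounting; then ATP-hydrolysis
  maximization per steady state and the Pirt-style linear fit

  ```
  ATP_total(μ) = mATP + (1000 / Y_ATP^max) · μ
  ```

  whose intercept is the maintenance demand and reciprocal slope the
  maximal biomass yield per ATP (g mol⁻¹).
* **Synthetic ground truth**: a compartmentalized central-carbon toy model
  (glycolysis, PPP, TCA, glutaminolysis, amino-acid catabolism, a
  proton-explicit respiratory chain whose P/O ratio is an emergent,
  tunable property, two biomass variants at 56 % / 70 % protein) plus
  generators for ¹³C datasets and chemostat runs with known mATP, so every
  stage of the pipeline is testable against an exact answer.

## Worked example

```r
library(maintflux)

model <- build_toy_model()          # deterministic reference model
measure_po_ratio(model)
#> [1] 2.5                           # ATP per NADH, emergent from the ETC

# synthetic 13C dataset with known maintenance (6 mmol/gDW/h), no noise
sim <- simulate_c13_dataset(model, synthetic_truth(6, noise_cv = 0, seed = 11))
est <- estimate_matp(model, sim$c13, sim$mapping)
est
#> <maintenance_estimate> synth1: mATP = 6 mmol/gDW/h (median RE 8.42e-13,
#>   33/161 grid points feasible)

# chemostat route: simulate 11 dilution rates, fit ATP production vs growth
recs <- simulate_chemostat(model, synthetic_truth(4.3, 0, seed = 5),
                           seq(0.016, 0.035, length.out = 11))
pts <- lapply(recs, function(r)
  atp_curve_point(model, rates_to_exchange_dataset(steady_state_rates(r))))
fit_maintenance(pts)
#> <maintenance_fit> mATP = 4.3 +/- 5.4e-14 mmol/gDW/h,
#>   Y_ATP^max = 5.71 +/- 6.4e-14 g/mol (R^2 1, n = 11)
```

The noiseless closed loops recover the generating truth exactly; with 10 %
multiplicative measurement noise the estimates land within the grid
resolution of the truth and the 95 % confidence interval of the chemostat
fit covers it (see `tests/testthat/test-acceptance.R`).

## Analysis workflow

The `analysis/` directory holds the full study as numbered drivers that
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1   # model + synthetic datasets
Rscript analysis/02_estimate_matp.R       # grid search, error profiles,
                                          # subsystem accuracy, effect test
Rscript analysis/03_uof.R                 # uptake-objective comparison
Rscript analysis/04_chemostat.R --seed 1  # rates table, ATP curve, fit,
                                          # P/O sweep
```

On the bundled synthetic study (seed 1) stage 2 reports the overall median
relative error dropping from 0.44 to 0.09 with the estimated maintenance
and the experimental-vs-predicted slope moving from 0.73 to 1.02
(interaction p ≈ 3e-10); stage 4 fits mATP 4.16 ± 0.71 mmol gDW⁻¹ h⁻¹
against a generating truth of 4.3 at 5 % noise, with carbon recoveries of
0.98–1.07 across dilution rates.

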