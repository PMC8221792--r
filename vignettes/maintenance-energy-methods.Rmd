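---
title: "Methods: maintenance-energy estimation in constraint-based CHO models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maintenance-energy estimation in constraint-based CHO models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maintflux)
```

## The problem and the model

Flux balance analysis (FBA) treats metabolism at steady state as a linear
program: find fluxes `v` with `S v = 0`, `lb ≤ v ≤ ub`, optimizing an
objective — conventionally the biomass reaction for growing cells.
Parsimonious FBA (pFBA) resolves the degeneracy of the optimal face by
fixing the objective at its optimum, splitting every reaction into two
irreversible directions and minimizing the total flux `Σ|v|`, on the
premise that cells minimize the resources devoted to any flux state.

For CHO cells such models predict growth well but underestimate central
carbon fluxes, because the energy demand they encode — growth-associated
maintenance (GAM) inside the biomass reaction plus product synthesis — is
incomplete: it omits the non-growth-associated maintenance (mATP), the ATP
hydrolysed for macromolecule turnover and ion homeostasis regardless of
growth. `maintflux` adds that demand as a flux constraint on an explicit
ATP-hydrolysis reaction (`atp + h2o -> adp + pi + h`, id `DM_atp_c`) and
provides two independent ways of quantifying it.

**Computational route.** For a dataset of measured exchange rates and ¹³C
intracellular fluxes, the maintenance flux is fixed at each value of a grid
(0–40 mmol gDW⁻¹ h⁻¹ by steps of 0.25), growth is maximized by pFBA, the
predicted fluxes are mapped onto the ¹³C reaction namespace and scored by
the median relative error `median |v_p − v_e| / |v_e|`. Experimental fluxes
below 1 % of the dataset's maximum absolute flux are removed first: their
relative errors are enormous while their absolute deviations are
negligible, and they obscure the error minimum. The feasible grid values
form an interval (feasibility of a fixed flux value is an interval property
of a linear program), so the range is bracketed by minimizing and
maximizing the maintenance flux before scanning. Ties in the minimal median
error break toward the smaller, more parsimonious demand. The joint
estimate across datasets sums per-dataset median errors over the feasible
datasets at each grid value and divides by their number, since fewer
datasets remain feasible as the demand grows.

**Experimental route.** In a chemostat at steady state the dilution rate
`D = F/V` sets the growth rate `μ = D·Nt/Nv` (dead cells wash out too, so
`μ ≥ D` with equality at 100 % viability), and exchange rates follow from
the concentration balance `q = (Cout − Cin)·D/X` with uptake negative.
With all measured rates and growth imposed as `value ± SD` interval
constraints, maximizing ATP hydrolysis by pFBA yields the cell's total
energy budget at that growth rate; summing all net nucleoside-triphosphate
production (netting NTP transport within a reaction and excluding
NDP-kinase/adenylate-kinase interconversions, which would double-count
transferred phosphate) and regressing it on `μ` gives the Pirt line whose
intercept is mATP and whose reciprocal slope, scaled to g mol⁻¹, is the
maximal biomass yield per ATP, `Y_ATP^max = 1000/slope`.

## The solver

No linear-programming backend is assumed: the package carries a
bounded-variable two-phase primal simplex (`solve_lp`), with Dantzig
pricing, a largest-pivot tie-break in the ratio test, a Bland fallback
against cycling, periodic refactorization, and tolerances of 1e-9 on
reduced costs and feasibility. All bounds must be finite (models use
±1000). Determinism matters more than speed here: the grid search and the
recovery tests rely on bit-reproducible solutions, and the problem sizes
(≤ ~150 variables after the pFBA split) keep dense tableau iterations
cheap. The solver is validated in the test suite against brute-force
vertex enumeration on random small models and against an independent
simplex implementation. Alternate optima within the minimal-total-flux set
remain solver-determined, so tests and analyses assert on objective
values, total flux and mapped aggregate fluxes, never on individual fluxes
of degenerate reactions.

## The toy model

`build_toy_model()` constructs a deterministic, fully element- and
charge-balanced central-carbon network (~72 reactions, ~65 metabolites;
compartments: extracellular, cytosol, mitochondrial matrix, intermembrane
space) sized so that exact oracles remain tractable: lumped glycolysis,
an oxidative PPP branch producing NADPH and ribose with a non-oxidative
return (6 P5 → 5 P6), lactate dehydrogenase, pyruvate and TCA lumps,
glutaminolysis, synthesis and catabolism for the nonessential amino acids,
uptake-only metabolism for the essential ones (histidine, lysine,
threonine, plus tryptophan handled by its own fallback rule), and two
biomass variants differing in protein content (56 % vs 70 %).

Respiration is proton-explicit: the NADH branch pumps `4·(P/O)` protons
into the intermembrane space per NADH (plus one matrix proton consumed
chemically), the FADH₂ branch 60 % of that, and the ATP synthase uses 4
intermembrane protons per ATP (one consumed in the chemistry; the
phosphate carrier returns one proton per Pi). The P/O ratio is therefore
an emergent network property — `measure_po_ratio()` recovers it by FBA
with an NADH-regenerating probe flux as sole energy source — and
`set_po_ratio()` rescales only the pumping stoichiometry. The default 2.5
for NADH (1.5 for FADH₂) is the standard mammalian value. A proton leak
and a reversible synthase provide the physiological dissipation routes, so
surplus energy never renders a constraint set infeasible by bookkeeping
alone. The maximal ATP yield of complete glucose oxidation is exactly 32
at P/O 2.5 (10 NADH·2.5 + 2 FADH₂·1.5 + 2 GTP + 2 substrate-level ATP),
which the test suite asserts.

Two parameters carry the energy calibration. The growth-associated demand
embedded in both biomass reactions defaults to `gam = 173` mmol ATP
gDW⁻¹: together with the ~2 mmol gDW⁻¹ of precursor-synthesis ATP this
makes the model's total growth cost ≈ 175 mmol gDW⁻¹, i.e. a maximal
yield near the 5.7 g mol⁻¹ reported for CHO — the slope of the ATP-vs-μ
line is then on the experimentally observed scale. The biomass amino-acid
demand uses a mean residue mass of 110 g mol⁻¹ distributed over nine
amino acids, with tryptophan the least abundant (1 %), which is what makes
the smallest-measured-uptake fallback for unmeasured tryptophan a sensible
approximation.

The product-synthesis reaction built by `add_product_synthesis_reaction()`
spends, per mole of polymerized amino acid, 2 GTP → 2 GDP + 2 Pi
(translation) and 1.306 ATP → 1 AMP + PPi + 0.306 ADP + 0.306 Pi
(charging plus auxiliary steps). The phosphate/water bookkeeping that
accompanies these hydrolyses is not uniquely determined by the net
nucleotide balance; the package closes the reaction explicitly with Pi,
PPi, water and protons so that the energetic species balance elementally
up to exactly one water per peptide bond (credited to the polymer), and
adds a pyrophosphatase so the charging by-product is recyclable. This
closure is a design choice of the package, asserted by an elemental-balance
test.

## The synthetic-data generators

The generators define the study conditions under which every pipeline
stage is validated; their defaults are fixed, not tuning knobs.

`simulate_c13_dataset()` emulates a literature ¹³C dataset: it fixes the
maintenance reaction at the true value, samples a nutrient environment —
scarce glucose (uptake bound 0.12–0.20 mmol gDW⁻¹ h⁻¹), moderate
glutamine (0.06–0.10) and generous essential amino acids — runs pFBA
maximizing growth, and treats the resulting fluxes as truth. The scarce
glucose matters: growth must be energy-limited at the true mATP (surplus
amino acids catabolized), because only then do the predicted fluxes
respond to the maintenance constraint on both sides of the truth and the
median-relative-error profile show a V with its minimum at the generating
value; environments failing an explicit responsiveness probe are
resampled. Observed fluxes and exchange rates are perturbed
multiplicatively with `Normal(1, cv)` truncated at ±3σ (default CV 10 %,
roughly the proportional uncertainty of literature ¹³C fluxes), and
confidence intervals are set to ±1.96·cv·|value|. Ammonium, CO₂ and
oxygen are left unmeasured, as in the emulated datasets; this also keeps
the nitrogen balance from pinning the growth rate when noisy uptakes are
point-fixed. Tryptophan is measured by default, with `trp_measured =
FALSE` available to exercise the fallback rule.

`simulate_chemostat()` emulates a continuous culture at 270 mL working
volume, viability 95 %, 5.5·10⁶ viable cells mL⁻¹ and 264 pg dry mass per
cell (the literature average used for unit conversion throughout): for
each dilution rate it fixes `μ = D/viability` and the true maintenance,
bounds uptakes by feed availability `Cin·D/X`, minimizes glucose uptake by
pFBA, and back-computes bioreactor concentrations from the mass balance.
Off-gas CO₂ is included among the recorded rates so the carbon balance of
the (elementally closed) model makes carbon recovery exactly 1 in the
noiseless case — the recovery statistic then isolates measurement error,
not model incompleteness. Feed-mass series imply the exact dilution rate;
sampling noise is multiplicative as above, with a five-fold smaller CV on
viability (a counting ratio) and ten-fold smaller on balance masses.

What the generators do not emulate: inter-laboratory differences in ¹³C
model structure and labelling strategy, non-stationary labelling,
correlated measurement errors, steady-state multiplicity, and any kinetic
or thermodynamic limits on uptake — feasibility in the chemostat
simulation scales with `D`, so "washout" manifests at low dilution (the
fixed maintenance cannot be paid from availability that scales with `D`)
rather than at high dilution as in a real reactor. Passing the recovery
tests therefore shows the pipeline is correct and well-calibrated on its
own terms, not that real datasets will behave this gently.

## Numerical and statistical choices

* Constraint policies: computational estimation point-fixes exchange rates
  (both bounds at the value); the chemostat energy analysis uses
  `value ± SD` intervals. Oxygen is never constrained. The maintenance
  value on the grid is an equality, matching "constrained to" semantics.
* Infeasible interval-constrained steady states are repaired by relaxing
  the lower bounds of secretion rates in 5 % steps to a 40 % cap — a
  generalization of the ad-hoc 25–40 % case-by-case relaxations such data
  require — with every relaxation logged; upper bounds are never loosened.
* Essential amino-acid uptakes that cannot sustain the measured growth are
  replaced by the minimal requirement computed with growth fixed and all
  other uptakes free; this cannot distort the energy balance because these
  amino acids only feed biomass in the model.
* Weighted flux-comparison fits use `1/(CI width)` weights; zero widths are
  capped at the largest finite weight and missing widths get the median
  weight, so no point acquires infinite leverage. The maintenance-line fit
  is unweighted ordinary least squares.
* The effect of the maintenance constraint is tested by stacking both
  prediction sets, adding the constraint as a 0/1 predictor with an
  interaction term (`vp ~ ve * g`), and reading the interaction p-value,
  plus a likelihood-ratio χ² (df 2) between the nested models. Two-sided,
  α = 0.05, no multiple-testing correction.
* Error propagation uses the standard first-order forms: relative
  variances add for products and quotients (`σ_C = |C|·√((σ_A/A)² +
  (σ_B/B)²)`), absolute variances add for sums and differences. A
  million-draw Monte-Carlo oracle in the tests confirms both within 2 % in
  the moderate-relative-error regime they are built for.
* Steady-state stability: ordinary least squares of each monitored series
  against time, stable iff the 95 % CI of the slope contains zero; fewer
  than three points is flagged as insufficient rather than silently
  stable, and a statistically significant slope whose fitted total change
  is below a configured instrument error raises a within-measurement-error
  override flag. Instrument-error thresholds are configuration with no
  universal default.
* The NTP-production sum nets per-reaction stoichiometries of the same NTP
  across compartments (transporters produce nothing) and excludes a
  configurable interconversion list (NDP kinases, adenylate kinase);
  whether such exclusions are applied is underdetermined in the field's
  descriptions, and counting transfers would double-count energy.

## Problem sizes

The validation suite uses 20 seeded noisy ¹³C datasets for parameter
recovery, 100 seeded chemostat replicates (8 dilution rates each) for
confidence-interval coverage, 50 random ≤8-reaction models for the
LP-vertex oracle, 500 null simulations for the size of the interaction
test, and 10⁶ Monte-Carlo draws for the error-propagation oracle. The
bundled analysis workflow simulates six noisy datasets plus a noiseless
control and an 11-dilution-rate chemostat, mirroring the reference
experiment's design at a scale where the whole study re-runs in minutes.

## Known limitations

* The simplex is dense and single-threaded; genome-scale models in the
  thousands of reactions would need a sparse revised implementation or an
  external solver behind the same `solve_lp` interface.
* pFBA alternate optima are tie-broken by pivoting order; mapped aggregate
  fluxes are stable but individual degenerate fluxes are not identifiable.
* The toy model's lumped stoichiometry reproduces yields and energetics,
  not pathway-level redundancy; questions that hinge on alternative
  NADPH sources (malic enzyme, NADP-dependent isocitrate dehydrogenase)
  or on compartment-specific cofactor pools are outside its resolution.
* SBML support covers the Level 3 + FBC subset the package writes; it is
  an interchange format for these models, not a general SBML parser.
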