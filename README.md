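# hogadapt

Kinetic modelling and analysis of the budding-yeast response to
hyperosmotic stress.

When *Saccharomyces cerevisiae* is hit with a salt step, turgor pressure
collapses, water leaves the cell, and the HOG MAP-kinase pathway
activates Hog1, which rewires gene expression (GPD1, STL1), metabolism
(Pfk26/27 → F26DP → Pfk1) and membrane transport (closure of the
aquaglyceroporin Fps1) to accumulate glycerol as a compatible solute —
at the cost of growth. `hogadapt` implements an integrated ODE model of
this process for systems biologists who want to simulate it, take it
apart, and fit it: volume/turgor biophysics, two-reaction Hog1
signalling, a stress-responsive expression layer, lumped fermentative
glycolysis with glycerol/trehalose/ethanol/acetate branches,
density-corrected transport, and biomass growth with full carbon
bookkeeping.

## The model in brief

One shared parameter set drives a 29-variable state. The biophysical
core is

```
dVos/dt = Lp_A (Pi_i − Pi_e − Pi_t),      Pi_t = clip(Pi_t0 (Vos − V_lp)/(Vos0 − V_lp), 0, Pi_t0)
```

with the Hog1 input signal `u = max(0, (Pi_t0 − Pi_t)/Pi_t0)` and just
two signalling reactions, `k_ph·u·Hog1u` and `k_dp·Hog1PP`. Growth is
gated by volume and by active Hog1,

```
mu = mu0 · clip((Vos − V_gmin)/(Vos0 − V_gmin), 0, 1) · (1 − theta_H·Hog1PP/(K_gH + Hog1PP)),
```

and every per-cell amount carries growth dilution while external pools
accumulate with cell density. Mutant strains (`hog1Δ`, `gpd1Δ`,
`pfk26/27Δ`, `HOG1-att`, `FPS1-Δ1`, `stl1Δ`, …) are single parameter
edits of the wild-type set (`apply_strain()`). ASCII names (`"hog1d"`,
`"fps1-d1"`) are accepted everywhere.

On top of simulation the package provides:

- **time-dependent scaled response coefficients**
  `R(t) = (q/x(t)) ∂x(t)/∂q` via forward sensitivity equations, with an
  independent finite-difference oracle (`compute_sensitivities()`,
  `scale_rc()`, `fd_oracle_rc()`);
- **glycerol flux decomposition** into Fps1-reliant, Gpd1-reliant and
  other contributions with ternary coordinates
  (`decompose_glycerol_flux()`, `ternary_coordinates()`,
  `plot_ternary()`);
- **growth and carbon trade-off analysis** (`doubling_time()`,
  `flux_shares()`, `carbon_conservation_drift()`);
- **multi-strain weighted least-squares estimation** with analytic
  scaling factors for relative (blot/transcript) data and seeded
  Latin-hypercube multistarts refined by Levenberg-Marquardt
  (`fit_problem()`, `hog_fit()`, `optimal_scaling()`);
- a **synthetic time-course generator** emulating the study's
  measurement campaign — 14 observed variables, per-variable schedules,
  replicate structure, lognormal noise — in a model-based and a
  phenomenological mode (`generate_model_based()`,
  `generate_phenomenological()`, `trehalose_template()`);
- tidy CSV I/O and SBML Level 3 export (`read_timecourse_csv()`,
  `export_sbml()`).

## Worked example

```r
library(hogadapt)
params <- hog_params()
sim <- hog_simulate(params, strain = "WT", protocol = stress_protocol())
#> <hog_sim> strain WT, 181 time points (0..180 min), NaCl step 0.4 M at t = 0

gly <- sim$obs[, "cGlyi"]
cat("basal glycerol:", round(gly[1], 1), "mM; peak:", round(max(gly), 1),
    "mM at", sim$times[which.max(gly)], "min\n")
#> basal glycerol: 6.1 mM; peak: 979.1 mM at 59 min

dec <- decompose_glycerol_flux(sim)
dec$time_min[which(dec$r_Gpd1 > dec$r_Fps1 & dec$r_Gpd1 > dec$r_Others)[1]]
#> [1] 4
```

Intracellular glycerol climbs from a basal ~6 mM to nearly 1 M,
peaking at 59 min once Fps1 reopens and efflux overtakes production.
The decomposition says *why*: in the first minutes the net glycerol
gain is dominated by the volume-concentration effect and the closing
channel, and from 4 min on Gpd1-dependent production takes the lead.
Growth pays for it:

```r
pre <- hog_simulate(params, "WT",
                    stress_protocol(t_end = 90, t_grid = seq(-60, 90, 1)))
doubling_time(pre, c(-60, 0)); doubling_time(pre, c(0, 90))
#> [1] 120    # min, before the step
#> [1] 163    # min, after
flux_shares(sim, 20)[, c("biomass_share", "glycerol_share")]
#> biomass_share 0.052, glycerol_share 0.141
```

— at 20 min the cell routes nearly three times more glucose carbon to
glycerol than to biomass, the trade-off the growth-rate drop buys.
`autoplot(sim)`, `plot_ternary(dec)` and `plot_rc()` plot the
trajectories, the ternary contributions and response coefficients.

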