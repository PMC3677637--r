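---
title: "Modelling yeast osmoadaptation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling yeast osmoadaptation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hogadapt)
```

## The model

`hogadapt` implements an integrated kinetic model of the budding-yeast
response to a hyperosmotic salt step. Five layers share one 29-entry
state vector and one parameter set:

1. **Biophysics.** The cell is a basal solid volume `Vb` plus an
   osmotically active volume `Vos`. Water follows the pressure balance
   `dVos/dt = Lp_A (Pi_i - Pi_e - Pi_t)`, with internal osmolarity
   `Pi_i` from a background osmolyte amount `n0` plus the ten metabolite
   pools, external osmolarity `Pi_e` from the medium background, the van
   't Hoff-weighted NaCl step (`i_vh = 2` by default, dissociation of
   NaCl) and the external carbon pools, and turgor `Pi_t` a
   piecewise-linear function of `Vos` clipped to `[0, Pi_t0]` that
   vanishes at the volume `V_lp`.
2. **Signalling.** Hog1 is a two-form pool with exactly two reactions:
   phosphorylation `k_ph * u * Hog1u` driven by the relative turgor loss
   `u = max(0, (Pi_t0 - Pi_t)/Pi_t0)`, and dephosphorylation
   `k_dp * Hog1PP`.
3. **Expression.** GPD1 transcription has a basal, a Hog1-dependent and
   a small Hog1-independent osmotic term (`k_b1 + k_h1 Hog1PP + k_o1 u`);
   Gpd1 monomers dimerize and only the dimer is catalytically active, so
   the measurable signal is `Gpd1tot = Gpd1m + 2 Gpd1d`. Gpd2 is a
   protein pool with a small osmotic induction. STL1 is
   glucose-repressed and Hog1-induced; Pfk26/27 is activated by Hog1 and
   produces F26DP, which raises the Vmax of the lumped Pfk1 step.
4. **Metabolism and transport.** A lumped fermentative glycolysis from
   glucose uptake through hexose phosphates, FBP and triose phosphates
   to glycerol (via G3P), trehalose, ethanol and acetate, with
   Michaelis-Menten kinetics for enzymatic steps, mass action for
   aldolase and trehalose mobilization, and linear gradient-driven
   passive transport. Glycerol crosses the membrane through Fps1
   (gated: closure on turgor loss and by active Hog1, reopening at rate
   `k_open`) and is imported irreversibly by Stl1. Transport rates are
   corrected for cell density (`CD * 1e-12` cells per fL of culture) so
   external pools accumulate as the culture grows.
5. **Growth.** The specific growth rate is
   `mu0 * clip((Vos - V_gmin)/(Vos0 - V_gmin), 0, 1) *
   (1 - theta_H Hog1PP/(K_gH + Hog1PP))` — a volume gate and a
   Hog1-dependent cell-cycle arrest. Growth drains hexose phosphate at
   `gamma_bm mu` glucose-equivalents per cell (substrate-limited through
   `K_bm`) and dilutes every per-cell amount.

Units: amol/cell for intracellular amounts (so amount / `Vos` in fL is
mM), mM for external concentrations, Osm for pressures, minutes for
time. This makes the culture-density correction a single
`cells*fL -> mL` factor of `1e-12`.

### Carbon bookkeeping

Every metabolic reaction is carbon-closed: decarboxylations (PDC, ALD6)
release one CO2 carbon, the biomass drain counts 6 carbons per
glucose-equivalent, and trehalose counts 12. `check_carbon_closure()`
verifies the stoichiometric matrix symbolically and
`carbon_conservation_drift()` audits an integrated trajectory including
the CO2 and biomass accumulators; at the shipped tolerances the drift is
at rounding level (~1e-13 relative over 180 min).

### The Hog1 moiety under growth

Per-cell amounts dilute at rate `mu`. A protein pool without synthesis
would therefore decay even before stress, which contradicts a pre-stress
fixed point. Hog1 synthesis is modelled as homeostatic, `+mu * Hog1tot`
into the unphosphorylated form, so `Hog1u + Hog1PP = Hog1tot` is an
exact invariant under balanced growth, and with `mu0 = 0` the moiety is
conserved to machine precision. All other proteins and mRNAs have
explicit synthesis terms, so their fixed points exist with dilution
included.

## The reference parameterization

The shipped `hog_params()` set was hand-tuned in three stages, not
fitted to any external dataset:

1. **Pre-stress steady state.** Fluxes and pool sizes were chosen at
   textbook magnitudes for fermenting yeast (glucose uptake ~3000
   amol/min/cell, ~19% of carbon to biomass at a 120-min doubling time,
   millimolar glycolytic intermediates, basal glycerol a few mM,
   `Vos0 = 35` fL, turgor 0.6 Osm, internal osmolarity just under 1
   Osm), and the Vmax/Km pairs back-solved from those targets. The
   background osmolyte amount `n0` was then calibrated so the
   equilibrated cell rests at the nominal volume with zero turgor-loss
   signal; `prestress_equilibrate()` (settling integration plus damped
   Newton polish) reaches residuals below 1e-8.
2. **Signalling and gating.** `k_ph`, `k_dp` set the phospho-pulse
   (peak within minutes, decay over tens of minutes); Fps1 closure was
   made predominantly Hog1-driven (`k_cH >> k_cT`), which is what
   separates the strains: without Hog1 the channel stays leaky, and
   without Gpd1 (but with Hog1) glycerol is retained.
3. **Flux response.** GPD1 induction, dimerization and `VmGPP` were
   scaled so wild-type glycerol rises to several hundred mM and peaks
   after the channel reopens (~1 h); the lower-glycolysis step operates
   near but not at saturation (`KLG = 2` mM) so rerouting, not
   saturation, buffers the pyruvate flux during adaptation.

Two calibration choices deserve a note. The Hog1-independent osmotic
GPD1 term `k_o1` is kept small (a few percent of the Hog1-dependent
response) so that the anchored-kinase strain shows essentially no
GPD1 induction while the deletion strains still accumulate glycerol
through Gpd2; and the pre-stress culture density (4e6 cells/mL) is
low enough that external-pool accumulation perturbs the unstressed
cell by well under a percent over three hours, which is what makes the
pre-stress state quasi-steady in the first place.

## Simulation

`hog_simulate()` integrates with `deSolve::lsoda` at `rtol = 1e-8`,
`atol = 1e-10` (defaults), using a compiled right-hand side; the salt
step is an event handled by stopping and restarting the integrator with
no smoothing. A pure-R `evaluate_rhs()` built from the explicit
stoichiometric matrix is the reference implementation; a property test
pins the compiled code to it on randomized states. The default
reporting horizon is 180 min (the window in which the model layers are
all active); the synthetic-data generator extends to 240 min.

Halving the solver tolerances moves intracellular glycerol by less than
0.1% in sup-norm; grid-refinement stability is part of the test suite.

## Response coefficients

`compute_sensitivities()` solves the forward sensitivity system
`dS/dt = J S + df/dq` with the Jacobian from central finite differences
of the right-hand side (relative step 1e-6). Initial sensitivities are
obtained by re-equilibration differencing, because the pre-stress state
itself depends on the parameters; zero initialization is available as
an option. Scaled response coefficients `R = (q/x) S` are masked (not
clipped) where `|x|` falls below `x_floor` (default 1e-9 in the
variable's own unit) to avoid spurious spikes from vanishing
denominators. `fd_oracle_rc()` provides the independent check — central
differences of two complete simulations at `q(1 ± delta)` — and the two
routes agree to well under 1% wherever `|R| > 0.05`. A parameter whose
value is zero in a strain variant is treated as structurally absent
(sensitivities identically zero), matching the scaled-coefficient limit
`q -> 0`.

## Glycerol flux decomposition

`decompose_glycerol_flux()` splits `d(cGlyi)/dt` into a Gpd1-attributed
production term (the phosphatase flux, attributed by the upstream
Gpd1-dimer vs Gpd2 shares), the signed Fps1 exchange, and "Others":
Gpd2-attributed production, Stl1 uptake, growth dilution and the
concentration effect of volume change. The three terms sum to the
derivative identically (to 1e-9 against the independent right-hand-side
evaluation). Relative contributions use absolute magnitudes
`|J_i| / sum |J|`, so efflux and influx phases both render on the
ternary simplex; instants where all three vanish map to the flagged
centroid. Signed normalization was the alternative; absolute was chosen
because it keeps the trajectory on the simplex through sign changes of
the net flux.

## Estimation

`fit_objective()` is a weighted least-squares over all strains and
variables, with the analytic scaling factor
`s = sum(y_m y_d / sigma^2) / sum(y_m^2 / sigma^2)` (clamped at 0)
absorbing the arbitrary units of immunoblot and transcript data.
Weights are `sigma_rel |y|` with a per-dataset floor (2% of the dataset
mean) and an absolute detection-limit floor (1e-6 in the variable's
unit) so that structurally-zero signals in deletion strains do not
produce dust-scaled weights. The fitting window is 0–180 min; later
samples are excluded. Failures inside the objective are penalized
(1e10 plus the residual count), never thrown.

`hog_fit()` is a seeded multistart: Latin-hypercube starts in a log10
box (±2 decades around the reference), Levenberg-Marquardt refinement
on the residual vector for every start, a deeper pass for the most
promising starts and a final polish. One numerical point matters more
than any other here: the LM finite-difference step (`epsfcn = 1e-6`,
i.e. relative steps ~1e-3) must sit well above the integrator noise
floor, otherwise the Jacobian is dominated by solver jitter and the
refinement stalls far from any optimum.

The recovery experiment exercised in the test suite designates ten
parameters spanning signalling (`k_ph`, `k_dp`), the glycerol system
(`kcatGpd1`, `k_fps`, `k_open`, `k_cH`), uptake and fermentation
(`kHXT`, `VmPDC`), growth (`mu0`) and storage (`kTPSh`). These have
distinct signatures in the measured variables across the wild-type and
deletion strains; parameters whose data signal at the study conditions
is below the noise floor (e.g. Km values of near-saturated steps) are
deliberately not designated.

## The synthetic-data generator

`generate_model_based()` emulates the study's measurement campaign: the
14 observed variables (four in arbitrary units, the rest absolute),
per-variable schedules over 0–240 min (denser early sampling for
phospho/protein signals), replicates, and multiplicative lognormal
noise parameterized so the mean factor is exactly 1 and the CV exactly
`sigma_rel` (default 0.15, three replicates — a typical spread for
blot and enzymatic time-course data). Lognormal noise preserves
positivity, which Gaussian noise would not.

`generate_phenomenological()` produces the same table from closed-form
templates instead of the model: strictly decreasing external glucose,
increasing fermentation products and cell density (with a stress
slowdown), an early Hog1 pulse, a 30–60-min glycerol transient, and a
double-peaked trehalose course whose noise-free maxima sit exactly at
45 and 180 min (`trehalose_template()`, two Gaussian bumps whose
cross-talk at 135-min separation is numerically negligible). The
two-peak trehalose shape is a *generator* feature only: the mechanistic
model is required to accumulate trehalose under stress, not to
reproduce the second peak, whose cause lies outside the modelled
network.

What passing tests on synthetic data do **not** show: real blots have
gel-to-gel scale drift beyond a single factor, real metabolite panels
have correlated errors from shared extractions, and real cultures leave
balanced growth at high density. None of these are emulated.

## Known limitations

- No NAD(H)/ATP dynamics: redox is implicit in the lumped kinetics, so
  redox-mediated couplings (e.g. between Gpd2 and fermentation) are
  invisible.
- The upstream Sln1/Sho1 branches are condensed into one turgor signal;
  questions about branch-specific signalling are out of reach.
- The constitutively-open-channel strain underestimates total glycerol
  production: with the shared parameter set the model shows the
  sustained-production flux state but not the full measured amplitude,
  and no strain-specific rescue is attempted.
- Doubling times are computed from simulated cell density; the package
  makes no claim about absolute agreement with plate-reader growth
  curves.
- Beyond ~120 min, processes outside the model (late stress responses,
  nutrient shifts) would interfere in reality; simulated horizons to
  240 min are for data-structure emulation, not for biology.

## Reproducibility notes

Every stochastic step (noise draws, multistart locations) is governed
by a single integer seed. Problem sizes used by the shipped checks:
1-min output grids over 0–180 min; sensitivity systems on 2-min grids
over 0–60/90 min; the recovery experiment uses three strains, ten free
parameters, three replicates at 15% noise and twenty multistarts.
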