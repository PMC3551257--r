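---
title: "A multi-scale model of acetaminophen hepatotoxicity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale model of acetaminophen hepatotoxicity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hepasim couples three scales of description of acetaminophen (APAP)
toxicokinetics: a kinetic model of one hepatocyte, a spatially resolved
liver lobule fed by dispersive sinusoidal blood flow, and a flow-limited
whole-body PBPK model with oral absorption. This vignette is the
package's account of the science: the model equations and their
assumptions, the parameters that matter and where their defaults come
from, the numerical machinery, and the design decisions that were
genuinely open.

## The hepatocyte model

The cell state is a vector of 12 intracellular and 5 extracellular
concentrations evolving as

$$\frac{dc}{dt} = N\,v(c, p),$$

with $N$ the integer stoichiometric matrix (17 species x 26 reactions,
`build_network()`) and $v$ the reaction-rate vector. The chemistry is
the canonical APAP pathway: phase II conjugation to the glucuronide
(UGT) and sulfate (SULT); CYP-mediated oxidation to the reactive
quinone imine NAPQI by CYP3A4, CYP2E1 and a lumped minor pool
(CYP2A6/1A2/2D6); NQO1 back-reduction; GST-catalysed conjugation of
NAPQI with glutathione; and non-specific binding pools for APAP, APAPS
and NAPQI. Protein-bound NAPQI (`NAPQI_P`) stands for the mitochondrial
membrane adducts that disturb respiration: it drives superoxide
production at rate $k_\mathrm{ros}\,[\mathrm{NAPQI\_P}]$ without being
consumed, and is slowly repaired (first-order `koff_napqi`,
half-life about 70 min, the time scale of adducted-protein turnover).
The oxidative-stress branch is SOD dismutation of superoxide to
H~2~O~2~, GPX reduction of H~2~O~2~ at the cost of 2 GSH, GSR
regeneration of GSH from GSSG, and a basal first-order H~2~O~2~
clearance (catalase, lumped). Glutathione is synthesised at a constant
lumped flux (GSS; its amino-acid precursors are outside the model) and
degraded by GGT, giving a basal steady state
$\mathrm{GSH}_0 = K_{m,\mathrm{GGT}}\,v_\mathrm{GSS} /
(V_\mathrm{GGT} - v_\mathrm{GSS}) = 6.5\ \mathrm{mM}$, a typical
hepatocyte value.

Rate-law forms: all enzymatic steps are irreversible Michaelis-Menten
(GST and GPX bi-substrate with multiplicative saturation terms),
membrane transport is a saturable basolateral carrier plus linear
passive diffusion for APAP and NAPQI, conjugate export is MRP2
(apical; the bile stream leaves the modeled system) and MRP3/4
(basolateral, returning to the sinusoidal bulk), and binding is
reversible mass action. These are the minimal forms consistent with
the pathway; every constant lives in the configuration
(`enzyme_profile()`, `default_config()`).

### Where the kinetic constants come from

The two measured anchors are the CYP3A4 and CYP2E1 activities of the
reference individual (0.95 and 1.0 umol/L_cell/min; the variant
individuals use 1.9 and 5.0). `convert_specific_activity()` maps
recombinant-enzyme activities to these cell-volume units using 30 g
total protein per litre of cells and a microsomal-to-total protein
ratio of 0.22.

The remaining constants are package calibration choices at
literature-typical magnitudes, frozen after a one-time calibration and
not claims about measured values:

* **Phase II capacity** (`vmax_ugt` 60, `km_ugt` 6000 uM; `vmax_sult`
  15, `km_sult` 300 uM): glucuronidation is low-affinity/high-capacity,
  sulfation high-affinity and the first to saturate, as in human APAP
  disposition.
* **CYP Km = 750 uM** for all three oxidative routes (APAP oxidation is
  a low-affinity, sub-mM to mM reaction). Within the defensible
  0.5-3 mM range this constant controls how in-vitro exposure
  translates to in-vivo dose, because the in-vivo liver operates near
  this Km while the 4000 uM in-vitro anchor is deep in saturation. It
  was calibrated (once, then frozen) so that the emergent in-vivo
  critical dose falls in the clinically reported 300-340 mg/kg window
  while 310 mg/kg remains free of mortality.
* **Adduct repair `koff_napqi` = 0.01/min**: with much slower repair,
  damage integrates over arbitrary exposure durations and any dose
  above ~250 mg/kg becomes uniformly lethal at long horizons; with a
  ~70 min repair half-life, injury tracks the concentration peak, which
  is what produces a sharp dose threshold at all.
* **Glutathione and ROS handling** (GSS 26 uM/min, GGT 30/1000, GPX
  600/100/1000, GSR 150/100, SOD 2000/500, basal H~2~O~2~ clearance
  0.05/min): sized so that GPX+GSR buffer H~2~O~2~ while GSH lasts,
  GSSG recycling saturates under sustained oxidative load (the
  bifurcation that makes the death criterion switch-like), and GSH
  recovers within hours after a sub-critical exposure.

`k_ros` is not hand-set at all: it is fixed by `calibrate_injury()`
(below).

## The injury model

A cell dies by necrosis when two conditions hold simultaneously:
intracellular H~2~O~2~ above a critical concentration, and glutathione
depleted below 10% of its basal level. While the criterion holds the
cell dies with per-minute hazard `hazard_scale * w(x)`, where the
positional weight $w(x) = \min(1, s/(1-x+\epsilon))$ is anchored to 1
at the central vein and falls toward the portal inlet
(`sensitivity_floor` = 0.05): pericentral cells are hypoxic and more
sensitive. An executed death draws a uniform 0-1 min onset delay, then
freezes the cell ($dc/dt = 0$ thereafter). The hazard formulation is
the minimal normalizable reading of "death probability inversely
proportional to distance to the central vein"; with `hazard_scale` = 5
/min a cell that stays above the criterion dies within a few minutes,
so the stochasticity mainly scatters death times and the identity of
marginal cells, not the dose threshold itself. The engine accumulates
each cell's cumulative hazard against a pre-drawn exponential survival
threshold, which is mathematically identical to the per-step Bernoulli
`death_check()` (both are provided; the test suite checks the per-step
form against its closed-form death fraction).

### Calibration from the in-vitro LC50

The critical H~2~O~2~ concentration is not a free parameter: following
the in-vitro anchoring strategy, `calibrate_injury(4000)` simulates the
nominal cell at the reported LC50 exposure (4000 uM APAP) for the assay
duration and defines the criterion as the peak H~2~O~2~ reached;
`k_ros` is rescaled (log-bisection, since the peak is a steep function
of the gain near the GSH-crash bifurcation) so that this peak equals
the reported round value of 4000 uM. The in-vitro assay duration
defaults to 12 h, a standard acute cytotoxicity window; with a 24 h
sustained exposure the anchor sits so low that no dose window can
reproduce both the 4000 uM LC50 and a ~300 mg/kg in-vivo threshold
under these kinetics.

### The in-vitro population

`simulate_in_vitro()` exposes `n_cells` = 200 cultured cells to
constant APAP. Population variability is one median-1 lognormal
multiplier (CV 0.2) on the cell's oxidative (CYP) capacity — the axis
along which the study varies individuals — sampled by stratified
quantiles so a finite assay represents the population without binomial
distortion of the 50% point. Because the calibrated nominal cell is
exactly the population median, viability at the calibration exposure is
0.5 by construction and `estimate_lc50()` (log-linear interpolation at
viability 0.5) recovers the anchor; the acceptance suite verifies the
round trip within +-10%. Defence-side variability (GPX, GSR, GST, GSH
turnover) is deliberately excluded from the default population: adding
it widens the viability curve but biases its median away from the
calibrated cell, breaking the anchoring identity that the calibration
procedure assumes.

## Sinusoidal transport

A sinusoid is a rigid tube of radius 5 um lined by 16 sections of 4
hepatocytes (23 um each). Bulk transport is advection-dispersion at the
near-wall suspension velocity $U_x$ = 0.05 mm/s (the Fahraeus-corrected
value; the red-cell velocity of 0.1 mm/s is recorded in the geometry
table but the suspension carries the solute). The dispersion
coefficient is Stokes-Einstein,
$D = k_B T / (6 \pi \eta R_g) = 2.22\times 10^{-10}\ \mathrm{m^2/s}$
for APAP's 2.99 A radius of gyration in blood of viscosity 3 mPa s.
The relation as used omits temperature; $T = 273$ K reproduces the
published coefficient from the published viscosity and radius (310 K
would give $2.53\times10^{-10}$), so 273 K is the default and the
temperature is exposed in the configuration.

The single-pulse solution is the Gaussian plume
(`plume_concentration()`). The simulator propagates bulk material in
discrete steps: each sub-step lasts one section transit
($l_h/U_x$ = 0.46 s), in which advection is an exact one-section shift
and dispersion is the matrix exponential of the zero-flux discrete
Laplacian, evaluated analytically in its cosine eigenbasis
(`dispersion_kernel()`). This propagator was chosen over an
erf-binned Green's-function kernel deliberately: binned kernels add a
projection diffusion of order $\Delta x^2/12$ per step and therefore
cannot satisfy the semigroup identity (n small steps = one n-fold
step), whereas the matrix-exponential kernel satisfies it to machine
precision, conserves mass exactly, converges to the Gaussian plume
under grid refinement (verified in the tests at 2%) and degenerates to
pure plug flow as $D \to 0$. The outlet end absorbs (blood leaves to
the central vein); the inlet end is zero-flux for dispersion.

Cell-bulk exchange happens inside each sub-step: passive exchange is
an exact exponential relaxation of the section's bulk concentration
toward the cell interior (with the cell state frozen across the
sub-step), the saturable carrier takes an explicit sub-step, and every
amount moved is credited to the receiving side, so species mass
balance holds to rounding. After the sub-cycle, each section's live
cells are integrated over the macro step with the exchanged amounts as
constant sources; basolateral conjugate export accumulates in
quadrature states and is returned to the section bulk. The eliminated
amount $E_k$ of sinusoid $k$ is the cumulative net APAP the cells
removed from the bulk — the only mass-consistent reading of the
clearance bookkeeping, since it is what the liver compartment loses.

## The lobule and zonation

Six identical sinusoids form a mean lobule (384 cells). Zonation
multiplies the CYP3A4 Vmax by 1.0/1.0/1.3 over three equal thirds of
the sinusoid length (the pericentral zone is 1.3x more active; zone
boundaries are not reported, equal thirds is the symmetric default and
both boundaries and multipliers are configurable). Only CYP3A4 is
zonated, as stated for the reference individual; whether CYP2E1 should
be as well is left to the configuration.

Because the six sinusoids see the same inlet and are deterministic
between death events, the engine integrates one representative
sinusoid and expands it into six independent copies only when the
first stochastic death executes; the four cells of a section likewise
share one state, with dead cells frozen as snapshots. Both collapses
are exact, not approximations, and `lobule_step()` remains a pure
aggregator: with deaths disabled, one sinusoid and the lobule mean are
identical (tested).

## The whole-body model

Adipose, well-perfused (WPT) and poorly perfused (PPT) tissues are
flow-limited compartments, $V_i\,dC_i/dt = F_i (C_b - C_i/PC_i)$, with
the flows, volumes and partition coefficients of a 73 kg adult. Oral
dosing places $F_\mathrm{ring} \cdot \mathrm{weight} \cdot
\mathrm{dose}$ (90% of the ingested amount) in the gut, which empties
into the liver at $k_\mathrm{gut}$ = 0.025/min. The liver compartment
receives arterial blood and the gut stream and loses APAP at
$\xi \sum_k E_k / n_s$, with $\xi$ = 0.75 (the parenchymal share
adjustment) and the lobule elimination scaled to the organ by
(0.8 x liver volume) / (volume of one lobule's hepatocytes) — the only
way a single lobule's umol/min can act on a 1.82 L organ. Urinary
clearance of 0.016 L/min acts on blood. Two closures are not printed
anywhere and are package decisions: the blood compartment balances the
venous returns of the four tissues against total tissue flow (the
printed per-tissue flows sum to 6.99 L/min, not the 6.4 L/min blood
row; the closure uses the tissue sum, and no separate plasma state is
carried since blood and plasma share a partition coefficient), and the
gut term enters the liver as $k_\mathrm{gut} Q_\mathrm{gut}$ in mg/min
(the dimensionally consistent reading). The global balance — gut +
tissues + blood + urine + metabolised = absorbed dose — is tracked at
every step and enforced to 0.1%.

`simulate()` co-simulates the two scales with a macro step of 65
transport sub-steps (29.9 s; chosen so the advective shift is exactly
one hepatocyte per sub-step, and indistinguishable from 0.5 min at PK
time scales): the lobule advances with the unbound portal inlet
$f_u (C_b + k_\mathrm{gut} Q_\mathrm{gut} / F_\mathrm{liv})$, its
elimination rate feeds back into the liver ODEs (classical RK4,
sub-stepped) for the same interval. Cell deaths reduce the working
parenchyma, so clearance falls and the plasma curve flattens — the
feedback loop that makes supra-threshold dosing self-amplifying.

## Numerical choices

The cell ODEs are integrated with an embedded Cash-Karp 4/5
Runge-Kutta with adaptive step control (`rtol` 1e-6, `atol` 1e-4 uM).
The kinetic constants were chosen with first-order rate scales below
about 10/min, so the system is at most mildly stiff and the adaptive
explicit integrator resolves the GSH-crash transition without step
failures; the test suite cross-checks trajectories against
`deSolve::lsoda` at tight tolerances. Michaelis-Menten terms clamp
negative arguments to zero, which keeps the right-hand side Lipschitz
under solver overshoot; non-negativity is enforced only to solver
tolerance (no hard clipping, which would break the mass-balance
audits). Death execution is bookkept at macro-step boundaries (exact
trigger and execution times are logged); with a 0.5 min step and a 0-1
min delay this displaces an execution by less than one macro step.

Problem sizes: the acceptance-level experiments run the full study —
16 doses x 3 seeds x 2000 min for the threshold scan, 200 cells x 7
concentrations x 12 h for the in-vitro assay — by exploiting the exact
symmetry collapses above; a sub-threshold whole-body run integrates 16
distinct cell states, a post-necrosis run at most 96.

## What the synthetic conditions do and do not show

All inputs are synthetic by construction: the study conditions are the
published physiology (geometry, flows, volumes, partition
coefficients, absorption and excretion constants) around a
reconstructed cell model whose rate laws and constants are design
choices. The verification reference (`reference_pk()`) is likewise
self-generated — the same PBPK body around a well-stirred liver whose
intrinsic clearance is matched to the structured lobule's low-dose
limit — so the chi-square comparison is a regression surface for the
transport coupling, not agreement with clinical data. Passing tests
therefore show internal consistency (conservation, limits,
monotonicity, calibration round trips) and that the assembled system
reproduces the reported emergent behaviours (LC50, dose threshold,
pericentral-first necrosis, CYP-activity risk ordering); they do not
validate the kinetic constants against measured microsomal data, nor
the plasma curves against clinical PK beyond their qualitative shape.

## Known limitations

* Elimination at toxic doses is slow (blood APAP declines with a
  half-life of roughly a day at 310 mg/kg), because the lobule-to-organ
  scaling bottlenecks hepatic clearance at the scaled sinusoidal
  perfusion; urinary excretion dominates. The dose threshold and
  viability endpoints are insensitive to this, but absolute plasma
  time courses at high dose should be read qualitatively.
* The dose-viability curve descends zone by zone (all of zone 3 dies
  before zone 2 is touched), a consequence of piecewise-constant
  zonation with no inter-cell variability in vivo; real lobules grade
  more smoothly.
* No enterohepatic recirculation, no RNS/nitration chemistry (lumped
  into the ROS/H~2~O~2~ pathway), no regeneration after injury, no 3D
  lobule geometry, no inter-individual physiological variability.
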