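# hepasim

Multi-scale simulation of acetaminophen (APAP) pharmacokinetics and
hepatotoxicity in R.

Acetaminophen overdose is the leading cause of acute liver failure in
many countries, and the injury it causes is spatially structured: the
toxic oxidation product NAPQI is generated by zonated CYP enzymes,
detoxified by glutathione, and kills hepatocytes preferentially around
the central vein once glutathione collapses and peroxide accumulates.
Whether a given oral dose injures a given individual therefore depends
on cellular kinetics, lobule microanatomy and whole-body disposition at
once. hepasim is for modellers and toxicologists who want those three
scales in one mechanistic, individually parameterisable simulator: it
predicts plasma time courses, spatial metabolite distributions,
per-cell necrosis and dose thresholds from enzyme activities.

## The model

Three nested layers:

* **Hepatocyte** — a kinetic network `dc/dt = N v(c, p)` over 17
  species and 26 reactions: phase II conjugation (UGT, SULT),
  CYP-mediated NAPQI formation (CYP3A4, CYP2E1, lumped minor CYPs),
  NQO1 back-reduction, GST conjugation of NAPQI with GSH, non-specific
  binding pools, MRP2/MRP3-4 conjugate export, glutathione turnover
  (GSS/GGT), and the oxidative-stress branch
  NAPQI-protein → ROS →(SOD) H₂O₂ →(GPX, 2 GSH) GSSG →(GSR) GSH.
  Enzymatic steps are Michaelis–Menten; all constants are per cell
  volume (μmol/L_cell/min).
* **Lobule** — six parallel sinusoids (16 sections × 4 hepatocytes,
  23 μm cells, 5 μm tube radius) with advection–dispersion transport at
  the suspension velocity U_x = 0.05 mm/s and the Stokes–Einstein
  dispersion coefficient D = k_B T / (6π η R_g) ≈ 2.22×10⁻¹⁰ m²/s;
  CYP3A4 activity is 1.3× higher in the pericentral third. A cell dies
  (stochastically, with a hazard that increases toward the central
  vein and a 0–1 min onset delay) when intracellular H₂O₂ exceeds a
  critical concentration while GSH is below 10% of basal; dead cells
  freeze (`dc/dt = 0`).
* **Whole body** — flow-limited PBPK compartments (adipose, liver,
  well- and poorly-perfused tissue, blood) for a 73 kg adult, oral
  absorption `dQ_gut/dt = −k_gut Q_gut` with 90% of the dose entering
  the gut, urinary clearance 0.016 L/min, and the liver compartment
  losing APAP at `ξ Σ E_k / n_s`, the lobule's mean elimination scaled
  to the parenchyma (ξ = 0.75).

The necrosis threshold is not a free parameter: `calibrate_injury()`
anchors it to the in-vitro LC₅₀ of ~4000 μM by simulating the nominal
cell at that exposure and rescaling the ROS gain so the peak H₂O₂
equals 4000 μM. See the vignette
(`vignettes/multiscale-hepatotoxicity.Rmd`) for the full model account
and design rationale.

## Worked example

Calibrate the injury model, then simulate a toxic 450 mg/kg oral dose
in the reference individual (CYP3A4 0.95, CYP2E1 1.0 μmol/L_cell/min):

```r
library(hepasim)

cal <- calibrate_injury(4000)      # anchor necrosis to the in-vitro LC50
cal$injury
#> injury parameters: H2O2_crit = 3999.679 uM; GSH depleted below 0.1 x basal; delay U[ 0 , 1 ] min

res <- simulate(dose_regimen(450),
                list(profile = cal$profile, injury = cal$injury),
                duration = 2000, seed = 1)
res
#> whole-body simulation: 2000.31 min; dose 450 mg/kg; final viability 0.6875 ( 120 death events ); Cmax blood 656.3 mg/L

head(res$events[order(res$events$time_exec),
                c("sinusoid", "section", "x_frac", "time_exec")], 3)
#>    sinusoid section  x_frac time_exec
#> 4         1      16 0.96875  466.4983
#> 19        5      16 0.96875  466.5634
#> 9         3      16 0.96875  466.6394
```

Blood APAP peaks at 656 mg/L about 155 min after dosing. From about
466 min the pericentral cells (normalised position x ≈ 0.97, section
16 of several sinusoids) begin to die; by 2000 min the whole
pericentral zone is necrotic and lobule viability has fallen to 0.69
(120 of 384 cells dead). At 310 mg/kg the same individual shows no
mortality at all, and a 10 mg/kg-resolution scan places the smallest
injurious dose at ~330 mg/kg (`dose_scan()`).

Study harnesses: `simulate_in_vitro()` / `estimate_lc50()` (population
viability curves), `dose_scan()`, `cyp_scan()` (e.g. CYP2E1 5.0 for
chronic alcohol exposure), and `reference_pk()` (well-stirred liver
comparator). A command-line front end ships in `inst/cli/hepasim`:

```sh
inst/cli/hepasim simulate --dose 393 --weight 73 --seed 1 --out out/
inst/cli/hepasim dose-scan --seed 1 --out scan/
```

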