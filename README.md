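# decorakin

Quantitative biophysics of bacteriophage capsid decoration, for structural
biologists and biosensor/NMR/SAXS practitioners who want the full analysis
chain of a decoration-protein study as tested, reusable R code. The package
covers five measurement modalities around one system — a small two-domain
decoration protein binding the 120 hexamer centres of an icosahedral phage
capsid — plus a seeded synthetic-data generator so everything runs and is
testable without instrument files.

## What it computes

**SPR kinetics with mass-transport limitation.** Sensorgrams follow the
two-compartment 1:1 model

    dR/dt = [k_on C (R_max − R) − k_off R] / [1 + k_on (R_max − R) / k_t]

with `C = 0` during dissociation; `k_t → ∞` recovers the ideal Langmuir
model. Finite `k_t` slows both apparent association and apparent
dissociation (rebinding), which is why a binder with k_off = 2×10⁻⁴ s⁻¹
can lose far less than the ideal 1 − e^(−k_off·t) during a 700 s
dissociation. The package simulates (`simulate_sensorgram`), double
references, corrects capture drift, fits k_off from dissociation phases,
and globally fits (k_on, R_max, k_t) across concentrations with k_off
fixed or free (`fit_global`), reporting K_D = k_off/k_on.

**Model-free ¹⁵N relaxation.** Backbone R1, R2 and {¹H-¹⁵N} NOE are
predicted from the Lipari–Szabo spectral density

    J(ω) = (2/5) [ S²τ_m / (1+(ωτ_m)²) + (1−S²)τ / (1+(ωτ)²) ],
    1/τ = 1/τ_m + 1/τ_e

through the standard dipolar + CSA expressions; `fit_residue` selects among
models M1–M5 (S², τ_e, Rex, two-timescale) by AICc, `mc_errors` gives
Monte-Carlo intervals, `estimate_tm_from_ratio` inverts trimmed R2/R1
ratios into per-domain tumbling times, and `flag_exchange` makes the
exchange census.

**SAXS forward scoring.** `debye_curve` evaluates
I(q) = Σᵢⱼ wᵢwⱼ sin(q dᵢⱼ)/(q dᵢⱼ); `pr_from_beads` gives P(r), Rg and
Dmax; `chi_score` is χ = sqrt( (1/N) Σ_q ((I_exp − I_calc)/σ)² ) with an
optional fitted scale; `guinier_rg` cross-checks Rg from the low-q slope.

**DNA-release thermal analysis.** `extract_tex` reads the genome-exit
temperature T_ex as the peak of the smoothed fluorescence derivative above
30 °C, and `compare_tex` tabulates condition-wise ΔT_ex between phages
with propagated replicate errors.

**Cooperative lattice decoration.** A Metropolis sampler
(`simulate_population`) exchanges ligands between a finite shared pool and
the sites of many 120-site capsids with energy ΔG_bind per bound ligand and
ε_coop per occupied neighbour pair, reproducing the all-or-none population
behaviour seen on native gels: at sub-stoichiometric ligand most capsids
stay bare while a minority saturates, with almost no intermediates.

## Worked example

```r
library(decorakin)

kin <- kinetic_params(k_on = 1.8e8, k_off = 2e-4, r_max = 1000, k_t = 6e9)
sgs <- gen_sensorgram_series(kin, noise = noise_spec(sd = 0.5, seed = 101))
fit_global(sgs, koff_fixed = 2e-4, n_starts = 5, seed = 1)
```

```
Global 1:1 transport-limited fit
  k_on  = 1.805e+08 +/- 1.8e+05 /M/s
  k_off = 0.0002 /s (fixed)
  R_max = 1000 RU
  k_t   = 5.999e+09 RU/M/s
  K_D   = 1.108e-12 M  (no error: k_off forced)
  residual sd = 0.497 RU over 5607 points
```

The seven simulated curves (0.312–20 nM) are fitted jointly; the on-rate
comes back within 0.3 % of the generating value, the residual sd equals the
injected noise, and the picomolar K_D follows from the fixed off-rate. No
K_D error is reported when k_off is forced.

The numbered scripts under `analysis/` run the whole study end to end
(`01_simulate_inputs.R` … `06_coop_lattice.R`), writing tables under
`results/`: the variant K_D table, model-free fits with the
16-residue exchange census, P(r) with Rg ≈ 30 Å and Dmax ≈ 112 Å, the
ΔT_ex panel (≈ +6.3 °C at acetate pH 5, 300 mM NaCl), and decoration
occupancy histograms at ligand:site ratios 0.4 and 1.2.

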