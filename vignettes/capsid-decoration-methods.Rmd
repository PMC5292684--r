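---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decorakin)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters with their defaults
and why, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open. Every
number quoted here is computed by the package's tests, the analysis
scripts or `scripts/acceptance.R`; nothing is asserted that the code does
not itself produce.

## The system

A small two-domain decoration protein binds the outer surface of a mature
icosahedral phage capsid, one monomer at the centre of each of the 120
hexamers. Only the expanded capsid presents binding sites. The package
analyses five measurement modalities of such a system: surface plasmon
resonance (SPR) binding kinetics, ¹⁵N backbone relaxation, small-angle
X-ray scattering (SAXS), thermal DNA-release fluorimetry, and native-gel
decoration patterns rationalised by a lattice model.

## SPR: the two-compartment transport-limited 1:1 model

The observed response R (resonance units, RU, proportional to bound mass)
obeys

$$\frac{dR}{dt} \;=\; \frac{k_{on} C (R_{max} - R) \;-\; k_{off} R}
{1 + k_{on}(R_{max}-R)/k_t},$$

with analyte concentration $C$ during injection and $C=0$ afterwards. The
denominator is the steady-state mass-transport correction: when delivery
of analyte to the surface (coefficient $k_t$, RU M⁻¹ s⁻¹) is slow
compared with intrinsic binding, association is delivery-limited and
dissociated ligand rebinds before escaping, slowing the apparent
dissociation. As $k_t \to \infty$ the ideal Langmuir model is recovered;
the simulator then uses the closed-form solution, while every finite
$k_t$ is integrated with a stiff-capable adaptive integrator (`lsoda`,
rtol $10^{-8}$, atol $10^{-6}$ RU, compiled right-hand side). Equilibrium
is unaffected by $k_t$: the long-time response is
$R_{max} C/(C + K_D)$ in both regimes (a property test verifies this).

Assumptions: a homogeneous 1:1 interaction, no bivalent or heterogeneous
ligand, no bulk refractive-index term beyond what double referencing
removes, and a capture surface whose own slow release is either negligible
or corrected by `correct_capture_drift` (division of the dissociation
phase by $e^{-k_{off,capture}t}$).

### Fitting protocol

Very slow dissociation (here $k_{off} \approx 2\times10^{-4}$ s⁻¹, i.e.
14% ideal loss over 700 s and less with rebinding) cannot be determined
accurately from one cycle, so the protocol is: estimate $k_{off}$ by
single-exponential fits of (corrected) dissociation phases averaged over
curves, fix it, then globally fit one shared $(k_{on}, R_{max}, k_t)$
across all concentrations by unweighted least squares
(Levenberg–Marquardt on log-scale parameters, seeded multi-start, default
10 starts). Per-point instrument errors are unreported in this kind of
data, hence unweighted. $K_D = k_{off}/k_{on}$ holds exactly in every
fit object; no $K_D$ error is reported when $k_{off}$ is fixed. When the
fitted $k_t$ exceeds $10^3 \times k_{on}R_{max}$ the data carry no
transport signature and $k_t$ is reported as unbounded above rather than
as a spurious number.

### Generator conditions

The synthetic design mirrors the study conditions: seven concentrations
0.312–20 nM, 200 s association, 600 s dissociation, 1 s sampling.
Unreported quantities were fixed once: additive i.i.d. Gaussian noise of
sd 0.5 RU; $R_{max} = 1000$ RU (the capture level of large particles on an
antibody surface, 800–1200 RU); and $k_t = 6\times10^9$ RU M⁻¹ s⁻¹,
chosen by a back-of-envelope rebinding argument so that a 700 s
dissociation from saturation loses about 7% instead of the ideal 13% —
the acceptance script computes 6.7% vs 13.1%. The 7% figure is treated as
qualitative throughout: only the direction (finite $k_t$ loses strictly
less) is asserted.

## Model-free ¹⁵N relaxation

R1, R2 and the {¹H-¹⁵N} NOE are computed from the Lipari–Szabo spectral
density (given in the README) through the standard ¹⁵N dipolar + CSA
expressions at the five canonical frequencies. Physical constants are the
conventional model-free defaults — N–H bond length 1.02 Å, ¹⁵N CSA
−160 ppm — configurable via `options(decorakin.r_nh=, decorakin.csa_n=)`.
Tumbling is isotropic per domain: the two domains of the protein tumble
semi-independently (distinct mean T1/T2), and no diffusion-tensor
anisotropy is modelled. Rex is quoted at a reference field (600 MHz) and
scaled by $B^2$ across fields.

Per-residue fitting tries M1 (S²), M2 (S², τe), M3 (S², Rex), M4 (S², τe,
Rex) and M5 (Sf², S², τs) and selects by AICc
($\chi^2 + 2k + 2k(k+1)/(n-k-1)$), skipping models without positive
residual degrees of freedom; a `selection = "chi2"` ladder is available.
AICc replaces the historical stepwise F-test protocol because it is
simpler and reproducible. Two deliberate conventions:

* **Zero measurement errors fall back to unit weights.** The fit is then
  well-defined but the AICc penalty comparison becomes unit-dependent, so
  "noise-free" model-selection properties are exercised in the
  vanishing-noise limit (exact observables with a tiny stated precision).
* Records whose stated errors span the observable's physical range are
  flagged `"uninformative"`; a winning model that still fails a
  $p < 10^{-3}$ goodness-of-fit cut is flagged `"unmodelled"`. Flags are
  never silent.

Monte-Carlo errors resample observables within their stated sds and refit
the selected model (percentile intervals, default 68%). Per-domain
tumbling estimation excludes residues with NOE < 0.6 (the conventional
rigidity cut) and trims the most extreme 10% of R2/R1 ratios from each
tail before inverting the rigid-limit ratio; the generator calibrates its
domain tumbling times numerically (`calibrate_tm_to_ratio`) so the
noise-free dataset reproduces configured domain averages (12.0 and 17.2)
exactly, internal motion and exchange included.

The synthetic protein (40 + 45 residues, S² ≈ 0.85 ± 0.04, τe 10–80 ps,
16 exchange residues with Rex 2–6 s⁻¹ clustered at block ends, duplicate
measurements at 600 and 700 MHz with 2% relative rate noise and 0.02 NOE
noise) emulates the statistical structure of a well-behaved two-domain
dataset. It does not emulate: overlapped or missing resonances, anisotropic
tumbling, field-dependent CSA variation, or correlated replicate errors.
Recovery numbers on it (median |ΔS²| ≈ 0.005–0.007, median |ΔRex| ≈
0.1–0.2 s⁻¹) therefore bound what the estimator does under clean
conditions, not what real spectra give.

## SAXS forward model

Beads are point scatterers of unit weight: no atomic form factors, no
hydration layer. This is intentional — the forward direction suffices for
the geometric observables (I(q) shape, P(r), Rg, Dmax) and for χ scoring
between curves on equal footing. Consequences: χ against a real
experimental curve computed with full-atom tools is *not* comparable and
is out of scope.

`pr_from_beads` bins pairwise distances (default 1 Å); Dmax is the exact
maximum pairwise distance with no smoothing or extrapolation. The discrete
Rg uses $R_g^2 = \sum_{i<j} w_i w_j d_{ij}^2 / W^2$ — the exact identity
with the coordinate definition (the continuous
$\int r^2 P \, dr / (2\int P\, dr)$ is its large-N limit). χ fits a single
multiplicative scale by default, mirroring standard practice.

The default two-lobe generator (75 + 75 beads: a 14 Å sphere and a
48×8×8 Å prolate ellipsoid 50 Å apart with a 6-bead straight linker) is
calibrated so P(r) gives Rg = 30 ± 1 Å and Dmax = 110 ± 5 Å. To keep those
windows stable at only 75 beads per lobe, each uniform interior sample is
recentred and isotropically rescaled to its solid's analytic Rg and the
outer axial extreme beads are snapped onto the lobe tips (pinning
Dmax = separation + 14 + 48 = 112 Å). Guinier analysis at the
conventional $qR_g < 1.3$ cut underestimates Rg by ~7% for this elongated
shape (expected behaviour); the cross-checks use the conservative 1.0 cut,
where agreement with P(r) is within 5%.

## Thermal DNA release

The generator models the dye fluorescence as
$B(T)\,(1-L(T)) + A\,L(T)$: a linearly declining probe baseline
($B_0 = 400$ a.u., slope 0.005/°C — the dye's own response decreases with
temperature) weighted by the closed fraction, plus the released fraction
$L$ (a logistic centred at the true exit temperature, scale 2 °C) times
the free-DNA amplitude ($A = 1000$ a.u.), on a 4–99 °C grid in 0.5 °C
steps. The analytic maximum of the release derivative sits exactly at the
configured midpoint.

`extract_tex` reports the temperature of the global maximum of
$+dF/dT$ above 30 °C (the low-temperature region is dye equilibration,
not release). The release transition is a fluorescence *increase*, so the
$+$ derivative is used; a `sign = "-"` option serves instruments that plot
the opposite derivative of a globally decreasing signal — both conventions
exist in practice and neither is asserted as canonical. Peak finding is
two-stage: localisation on a wider smoothed derivative (15 points), apex
interpolation by a local quadratic (±4 °C) on the declared 7-point
Savitzky–Golay derivative. The single-stage argmax has outlier-driven
errors of ~1 °C at 2% noise; the two-stage estimator achieves an
extraction sd below 0.3 °C, within the 0.5 °C target the recovery
property demands. A peak only counts as release if its
baseline-subtracted rise exceeds 5% of the total signal range (only the
positive excess counts, so a purely declining curve reports "no release
detected").

Noise levels: the 100-curve recovery study uses sd 20 a.u. (2% of
amplitude); the paired wild-type vs decoration-less panel uses sd 10
a.u., consistent with instrument replicate sds below 0.3 °C on T_ex in
quadruplicate — a level the generator reproduces. ΔT_ex is reported as
reference minus mutant with propagated standard errors
($sd/\sqrt{n}$ per group).

## Cooperative decoration on the 120-site lattice

The equilibrium model is a lattice gas: energy
$E = \Delta G_{bind} N_{bound} + \epsilon_{coop} N_{pairs}$ in kT, with
$\epsilon_{coop} < 0$ favouring occupied neighbours. Ligand is exchanged
between one finite pool and the sites of all capsids; the configuration
weight $e^{-E} \, v^F/F!$ (free count $F$, activity volume $v$, default:
the total site count) makes Metropolis exchange moves satisfy detailed
balance and yields the closed-form independent-site isotherm at
$\epsilon = 0$ — `dg_for_occupancy` inverts that isotherm and is the
oracle against which the sampler's binomial limit is chi-square tested.
Ligand conservation is exact at every sweep.

Adjacency: a real T=13 lattice is non-uniform near its pentamers; the
package offers a deterministic 6-coordinated wrapped triangular net
("icosa-net") and a seeded random 6-regular graph for sensitivity checks.
Burn-in is the first half of the sweeps; equilibration is diagnosed by
comparing third- vs fourth-quarter mean occupancy (2% tolerance,
flag + warning on failure). The demonstration scenarios
($\Delta G = +4$, $\epsilon = -2$, i.e. binding unfavourable alone but
strongly stabilised by neighbours) need ~4000 sweeps of 300 capsids to
pass that diagnostic — nucleation is the slow step. With these energetics
the population is all-or-none: at ligand:site ratio 0.4 most capsids stay
bare while a minority saturates (partial-band fraction ≈ 0, bimodality
score 1), and at ratio 1.2 over 90% saturate. Only equilibrium populations
are modelled — no kinetic conformational spreading — and the
nearest-neighbour pairwise coupling is this package's declared embodiment
of the cooperativity, not a mechanistic claim.

## Problem sizes and determinism

Default problem sizes were chosen so the whole suite and the acceptance
script each run in minutes on one CPU: 50 seeded kinetic experiments for
the on-rate recovery study, 85 residues × 2 fields for the relaxation
dataset, 156 beads, 100 melt curves, 300–400 capsids × 400–4000 sweeps
for the lattice. Every stochastic function takes an explicit seed, uses an
isolated RNG stream and restores the caller's RNG state, so identical
seeds give bit-identical outputs everywhere.

## Known limitations

* The transport-limited regime makes the apparent dissociation-phase
  $k_{off}$ an underestimate of the intrinsic rate (rebinding); the
  fixed-$k_{off}$ protocol assumes an independent consensus value.
* Flow-rate dependence of $k_t$ and surface-regeneration effects are not
  modelled.
* Relaxation fitting assumes isotropic per-domain tumbling; anisotropic
  diffusion, ¹³C relaxation and dispersion experiments are out of scope.
* The SAXS module never inverts experimental I(q) to P(r)
  (no regularised indirect transform) and χ values are only comparable
  between curves produced on the same footing.
* Band classification in the gel model is by occupancy thresholds
  (<10%, >90%); no electrophoretic mobility physics.
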