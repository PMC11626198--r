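---
title: "Models and methods behind idrbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind idrbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrbind)
```

# The scientific problem

idrbind analyzes the interaction between a small, highly charged,
intrinsically disordered protein (a SERF-family polycation, +12 at neutral
pH) and a folded RNA hairpin (the 29-nt HIV-1 TAR stem-loop, or the
unstructured homopolymer (rU)~29/30~ as a control). The pair forms a *fuzzy*
1:1 complex — bound, but without a single fixed interface — and, at high
concentrations, undergoes charge-driven complex coacervation. The package
provides the computational side of that characterization: sequence charge
analytics, equilibrium binding models for anisotropy titrations, a
coarse-grained two-molecule simulator, back-calculation of ensemble
observables (PRE, distance maps, scattering, shift-based secondary
structure, CSP), and turbidity/phase analysis, together with seeded
synthetic-data generators so every stage is testable without external
downloads.

# Sequence charge bookkeeping

Charges follow the integer convention at pH 7.5: Arg/Lys +1, Asp/Glu −1,
His 0, uncharged termini; RNA counts −1 per nucleotide. This reproduces the
published whole-molecule values (+12 for the 68-residue protein, −29/−30 for
the RNAs) without invoking terminal or fractional charges. A pH hook exists
(`charge_table(ph = )`) that protonates His below pH 6; it is deliberately
minimal. NCPR profiles average per-residue charges over an odd window
(default 5) and *shrink* the window at the termini so the profile always has
one value per residue.

The charge-matched stoichiometry `|z_RNA| / z_protein` (≈ 2.42 for +12 vs
−29) is the molar ratio at which coacervation is expected to be maximal;
the turbidity analysis compares its recovered peak against this prediction.

**The packaged protein sequence is a labelled synthetic stand-in.** The
study protein's letters are published only in a figure; what the text states
is its composition: 68 residues, net +12, one proline, nine arginines (three
N-terminal), five Asn/Gln in the first ~20 residues, an ERDK-rich
composition and a C-terminal helical region. `inst/extdata/serf_synthetic.fasta`
is a designed sequence satisfying every one of those constraints; all
bookkeeping checks run on it, and nothing downstream depends on the residue
order beyond composition and charge placement. The TAR sequence is the
exact printed 29-mer.

# Binding models

The 1:1 model treats ligand depletion exactly: the complex concentration is
the stable root of

$$ C^2 - C\,(P_t + R_t + K_D) + P_t R_t = 0, $$

and the anisotropy is $r = r_\mathrm{free} + (r_\mathrm{bound} -
r_\mathrm{free})\,C/R_t$. The quadratic costs nothing and is correct at any
probe concentration, so no excess-titrant approximation is made. The 2:1
alternative is parameterized as two sequential macroscopic dissociation
constants (P+R ⇌ PR, P+PR ⇌ P₂R) solved by numeric mass balance, with one
shared bound-state endpoint by default (`shared_endpoint = FALSE` frees the
PR and P₂R endpoints — required to make the 2:1 hypothesis distinguishable
when its signal really is biphasic).

Fitting is weighted Levenberg–Marquardt least squares with dissociation
constants on the log scale. Per-point SDs estimated from three replicates
are themselves very noisy; raw inverse-variance weights make the linearized
confidence intervals overconfident (we measured ~75% coverage at nominal
95%). The package therefore shrinks each SD toward the median SD with equal
weight before forming weights, which restores calibrated intervals (~91–94%
coverage in the packaged recovery study) while still down-weighting
genuinely noisier points. Model comparison uses AICc with a tie flag at
|ΔAICc| < 2. Starting values: endpoints from the first/last points, K_D from
the mid-transition concentration — robust for sigmoid-in-log data.

# The coarse-grained simulator

One bead per amino acid or nucleotide; flexible chains carry harmonic bonds
(k = 8033 kJ mol⁻¹ nm⁻², r₀ = 0.381 nm protein / 0.5 nm RNA); the
interaction between beads is a Wang–Frenkel short-range term (depth ε, size
σ, shape μ, ν; identically zero beyond its cutoff 3σ) plus Debye–Hückel
screened electrostatics

$$ U_\mathrm{el}(r) = \frac{k_C\,q_i q_j}{\varepsilon_r\, r}
   e^{-r/\lambda_D}, $$

shifted to be continuous at the global 3 nm cutoff, with λ_D computed from
ionic strength, temperature and dielectric (0.79 nm at 150 mM, 300 K, ε_r
80).

**Parameter provenance.** The bead table
(`inst/extdata/cg_forcefield.tsv`, version 1) is an *approximate*
transcription in the style of residue-resolution IDP/RNA force fields of the
Mpipi class: σ from residue van der Waals sizes, ε from a
hydrophobicity/stickiness scale with aromatic and arginine enrichment, RNA
bead charge −0.75 e (the force-field convention, deliberately different
from the −1/nt bookkeeping of the sequence module — the two serve different
purposes). The published pair-specific tables were not available to this
project; consequences: *relative* and directional quantities (which RNA
binds tighter; compaction on binding) are meaningful, absolute K_D values
are not calibrated and come out weaker than experiment. The table is
versioned and user-replaceable (`load_forcefield(path)`).

**Dynamics.** BAOAB Langevin integration at 10 fs in a periodic cubic box;
a rigid RNA conformer moves as one rigid body (center-of-mass Langevin
translation plus isotropic-inertia rotation, an adequate approximation for
a compact hairpin). Multi-conformer rigid RNAs are simulated one conformer
per run and pooled (`pooling = "separate_runs"`); a conformer-swap
Monte-Carlo mode was considered and rejected for version 1 because pooled
separate runs make the per-conformer statistics (contact-map SD across
conformers) explicit. All randomness flows through R's RNG from the config
seed, so trajectories are bitwise reproducible.

The default friction is 0.01 ps⁻¹: weak coupling maximizes configurational
diffusion, which is what binding/unbinding statistics need. The price is
slow kinetic-energy relaxation (τ ≈ 1/2γ = 50 ps), so *temperature
averages* over short runs of small systems fluctuate by several percent;
thermostat checks in the test suite therefore use friction 1 ps⁻¹, where
1e5 steps give a tight average. Both are legitimate settings of the same
thermostat.

**Initialization.** Flexible chains start on a compact overlap-free spiral,
rigid bodies at a random orientation, and the two molecules at a seeded
random separation between "touching" and roughly half the box — so both
association and dissociation are observable within a run. Equilibration
(first 10% of steps) is discarded.

**Bound-state definition.** A frame is bound when at least one interchain
bead pair (configurable) is within 1.2× the mean σ of the touching pair.
With one molecule of each partner in volume V, mass action gives

$$ K_{D,\mathrm{app}} = \frac{(1 - f_b)^2}{f_b\, V\, N_A}, $$

and the relative affinity of two RNAs in equal boxes is the K_D ratio,
which cancels the volume.

**Study conditions at package scale.** The reference simulations use a
15 nm box, 300 K, 150 mM ionic strength — conditions chosen once so that
both binding and unbinding occur for both RNA partners. The acceptance
simulations run 5 hairpin conformers × 60 000 steps versus 3 pooled
homopolymer runs × 100 000 steps, plus one 300 000-step high-occupancy run
(12 nm box) for bound/unbound Rg partitioning; these problem sizes are the
package's own choice of a scale at which the directional results
(structured hairpin binds tighter than the homopolymer; the protein
compacts when bound) are statistically resolvable on a single CPU within
minutes. The K_D *ratio* at this scale lands in the published factor-of-two
band; absolute K_D values do not (see parameter provenance above).

# Ensemble observables

Coordinates are Angstrom in this module (nm in the simulator; converters at
the boundary, units recorded in every file).

* **Rg distributions** are per-frame, about the unweighted site centroid,
  with a Scott's-rule KDE normalized to integrate to 1 (deterministic given
  the data).
* **Distance maps** are per-frame pairwise means. The null model for
  normalization is the analytical Flory random coil: Gaussian inter-residue
  vectors with RMS step b = 6.2 Å, i.e. mean separations
  $\langle r_{ij}\rangle = \sqrt{8/3\pi}\, b\, |i-j|^{1/2}$ and
  $R_g = b\sqrt{(N^2-1)/6N}$. The prefactor is the literature value for
  Flory-random-coil simulations of polypeptides (Rg ≈ 2.5 Å · N^½); for
  N = 68 the model predicts 20.9 Å, matching the published null-model value
  of 20.8 Å without being fit to it.
* **PRE** uses $\Gamma_2(i) = K \tau_c \langle r_i^{-6}\rangle$ with the
  ensemble average over $r^{-6}$ (correct for this observable; averaging
  $\langle r\rangle^{-6}$ would misweight rare close approaches), and
  intensity ratio $R_2 e^{-\Gamma_2 t_d}/(R_2+\Gamma_2)$. Defaults
  K = 1.23×10¹⁶ Å⁶ s⁻², τ_c = 4 ns, R₂ = 10 s⁻¹, t_d = 10 ms; all four are
  exposed because the experimental values vary by field strength and label.
* **Helicity** is computed from dihedrals (α basin φ ∈ [−100°, −30°],
  ψ ∈ [−80°, −5°], run length ≥ 3) as a *substitute* for chemical-shift
  back-calculation, which would require an external shift predictor; the
  two are not equivalent and the documentation says so.
* **Secondary-structure propensity** is the windowed (ΔδCα − ΔδCβ) scaled
  by a single full-helix reference of 2.8 ppm for both signs. A dual-scale
  convention (different helix and strand references) exists in the
  literature but breaks the antisymmetry of the statistic under sign flips
  of the secondary shifts, which we keep as an invariant.
* **CSP** combines weighted shift differences as the root mean square over
  nuclei (default weights ¹H 1.0, ¹⁵N 0.154, ¹³C 0.25), with a max-carbon
  variant for RNA, where both sugar and base carbons are accepted.
* **Scattering** is the uniform-point-form-factor Debye sum — no atomic
  form factors, hydration layer or excluded-volume corrections, so computed
  curves are comparable to each other and to closed forms, not to absolute
  beamline intensities. Guinier fitting iterates the q-window until
  q_max·Rg ≤ 1.3; the dimensionless Kratky transform has its analytic
  maximum at (√3, 3/e) for Guinier-ideal curves, which the tests use as an
  oracle.

# Phase analysis

Turbidity is treated as an arbitrary-units order parameter: no scattering
physics is attached to A₃₄₀. Features are extracted from a 3-point moving
average: peak location, plateau flag (last three smoothed points within
noise of the maximum — the published curves can saturate rather than turn
over, so both are reported), and onset (baseline + 3 SD). Salt series are
checked for monotone decrease and the half-maximum crossing is linearly
interpolated. Phase diagrams are threshold calls (default baseline + 5·SD)
on a concentration grid with row/column threshold crossings reported as the
boundary.

# Synthetic-data generators

Every generator is a pure function of (parameters, seed) and emits a
TruthRecord JSON with everything needed to regenerate the data. The chain
generator defaults to a freely jointed chain (closed-form expectations for
tests); a Gaussian-step mode generates ensembles with *exactly* the AFRC
reference statistics at every separation, which is what the
normalized-distance-map identity test requires (an FJC differs from the
Gaussian chain at small separations by up to ~8%). Helical segments are
ideal Cα helices (rise 1.5 Å, radius 2.3 Å, 100°/residue) inserted in a
stated fraction of frames with dihedrals emitted to match. The toy hairpin
generator builds A-form-like stems (rise 2.8 Å, radius 9 Å, twist
32.7°/step) joined at a jittered interhelical bend; the realized bend is
measured by a cylinder-axis fit (minimizing the variance of point-to-axis
distances, exact for ideal helices — principal-axis fits are badly biased
for stems this short). The titration and turbidity generators reuse the
package's own forward models plus Gaussian noise, with defaults matching
the published measurement design (16 points, 10 nM probe, σ_r = 0.002,
three replicates; 25-point turbidity grids at 2% noise).

What the generators *do not* emulate: excluded volume, sequence-specific
intrachain interactions, real RNA thermodynamics, instrument drift.
Passing the closure tests (fit recovers the generating K_D, the helicity
profile recovers the helical fraction, the peak detector recovers the peak
ratio) therefore demonstrates correctness of the estimators under their own
assumptions, not agreement with any laboratory measurement.

# Numerical choices and degenerate inputs

* Seeds: one master seed per run; child streams are derived
  deterministically and kept below 2³¹. Generators save and restore the
  caller's RNG state.
* Unidentifiable titrations (range below ~4× noise) raise a diagnostic
  error rather than returning a meaningless fit; saturated simulations
  (f_b ∈ {0, 1}) warn and return 0/Inf rather than an estimate.
* Single-site frames give Rg = 0 with a warning; the PRE label site is
  reported as ratio 0 by convention; distance-map diagonals are masked NA.
* Flat turbidity curves set a no-transition flag instead of erroring —
  buffer controls are expected inputs, not failures.
* The 2:1 mass balance root is bracketed on [0, P_t] and solved with an
  absolute tolerance floor so that optimizer excursions to extreme K values
  cannot produce invalid tolerances.

# Configuration and interfaces

Run configuration files are YAML (a TOML layer was considered; no TOML
parser is part of the package's dependency set, and YAML covers the same
needs). The CLI (`inst/cli/idrbind`) is a thin Rscript over exported
functions with subcommands `synth`, `simulate`, `fit-binding`,
`observables`, `phase`, `report`; each stage writes its outputs plus a log
carrying seed and package version. Trajectories are stored as an RDS array
with a JSON sidecar recording units, stride, seed and the full config echo.

# Known limitations

* Absolute coarse-grained affinities are uncalibrated (approximate ε/σ
  table); use ratios and directions.
* The rigid-body rotational thermostat uses an isotropic inertia scalar;
  rotational kinetics of elongated conformers are approximate (their
  equilibrium sampling is not affected by this choice at the level used
  here).
* The AFRC implementation is length-based, not sequence-aware.
* PRE back-calculation ignores the spectral-density field dependence beyond
  the single constant K.
* The Guinier and Kratky machinery is validated on model curves and rigid
  bodies; reproducing beamline-scale experimental values requires the
  original scattering data, which the package does not ship.
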