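# idrbind

Charge-driven binding and ensemble analysis for disordered protein–RNA
complexes.

Many RNA-binding proteins engage RNA through intrinsically disordered
regions rather than folded domains. idrbind is built around the smallest
useful model of that situation: one small polycationic disordered protein
(a 68-residue SERF-family protein, net charge +12) and one folded RNA
hairpin (the 29-nt HIV-1 TAR stem-loop, net −29), which form a dynamic
"fuzzy" 1:1 complex in dilute solution and undergo complex coacervation —
charge-driven associative phase separation — at high concentration. The
package implements the computational workflow for characterizing such a
system end to end:

* **Sequence charge analytics** — net charge (Arg/Lys +1, Asp/Glu −1, His
  neutral; −1 per nucleotide), windowed NCPR profiles, composition counts,
  and the charge-matched stoichiometry |z_RNA|/z_protein that predicts the
  coacervation optimum.
* **Binding isotherms** — fluorescence anisotropy models with exact ligand
  depletion: 1:1 via the mass-balance quadratic

      C² − C (P + R + K_D) + P·R = 0,   r = r_free + (r_bound − r_free)·C/R

  and a sequential 2:1 alternative; weighted Levenberg–Marquardt fitting
  with calibrated confidence intervals and AICc model comparison.
* **Coarse-grained simulation** — one bead per residue/nucleotide,
  Wang–Frenkel short-range plus Debye–Hückel electrostatics, BAOAB Langevin
  dynamics in a periodic box (C++ core), rigid multi-conformer RNA, bound
  state classification, apparent K_D from the bound fraction
  (K_D = (1−f_b)²/(f_b·V·N_A)), contact maps, and bound/unbound Rg.
* **Ensemble observables** — Rg distributions with KDE, distance maps
  normalized by an analytical Flory-random-coil null model, PRE intensity
  ratios (Γ₂ = K·τ_c·⟨r⁻⁶⟩), Debye scattering with Guinier and
  dimensionless Kratky analysis, chemical-shift secondary-structure
  propensity, and chemical shift perturbations.
* **Phase analysis** — turbidity titration features (peak/plateau/onset),
  salt dependence, and two-component phase diagrams.
* **Synthetic data** — seeded generators for every input type, each
  emitting a TruthRecord for exact regeneration.

The packaged protein FASTA is a *labelled synthetic stand-in* whose
composition matches the published description of the study protein (68
residues, +12, one proline, nine arginines); see the methods vignette.

## Worked example

```r
library(idrbind)

serf <- example_sequence("serf_synthetic")
tar  <- example_sequence("tar")
net_charge(serf)                    # 12
net_charge(tar)                     # -29
charge_matched_ratio(serf, tar)     # 2.417  (protein:RNA at charge match)

# synthetic anisotropy titration at K_D = 0.67 uM, fit back
gen <- gen_titration(kd = 0.67e-6, r_free = 0.05, r_bound = 0.20,
                     noise_sd = 0.002, replicates = 3, seed = 1)
fit <- fit_isotherm(gen$series, "one_to_one")
fit
#> <binding_fit> one_to_one model, n = 16 points
#>   K_D,app: 6.758e-07 M
#>   r_free = 0.0505, r_bound = 0.2002, RSS = 1.46e-05, AICc = -210.88
```

The recovered K_D,app of 0.676 µM sits within 1% of the generating truth,
and the 95% CI (0.647–0.705 µM) covers it. The random-coil null model for
the protein's chain length:

```r
afrc_reference(68)$rg
#> 20.87005        # Angstrom; ensemble Rg of a 68-residue ideal coil
```

A turbidity titration peaking near the charge-matched ratio:

```r
gt <- gen_turbidity(peak_ratio = 2.5, noise_sd = 0.02, seed = 7)
titration_features(gt$curve)
#> $transition TRUE  $peak_x 2.4  $max_a340 0.932  $onset_x 1.6  $plateau FALSE
```

The recovered peak (2.4) is within one grid step of the generating ratio
2.5, which in turn brackets the charge-matched prediction 29/12 ≈ 2.42.

A two-molecule coarse-grained run and its apparent affinity:

```r
top <- build_topology(serf, example_sequence("rU", 29))
cfg <- sim_config(box_edge = 15, n_steps = 1e5, seed = 11)
traj <- run_simulation(top, cfg)
st <- classify_bound(traj)
apparent_kd(st, cfg)        # molar K_D,app from the bound fraction
```

A command-line front end (`inst/cli/idrbind`) exposes the stages as
subcommands (`synth`, `simulate`, `fit-binding`, `observables`, `phase`,
`report`).

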