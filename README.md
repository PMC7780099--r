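# loopdimer

Structural and biophysical analysis of interface loops in homodimeric
enzymes, written for studies of cold-active alkaline phosphatases — dimers
in which a large surface loop of one monomer (residues ~324–354 in the
*Vibrio* enzyme) reaches over the partner monomer's active site and anchors
an intersubunit hydrogen-bond network around an arginine (Arg336).  The
package is for structural biologists who want to quantify, from coordinate
files and simple CSV assay tables:

* **monomer asymmetry** — least-squares (Kabsch) superposition of
  residue-matched chains with per-residue Cα deviation traces
  (`superpose_chains()`, `compare_structures()`),
* **flexibility** — per-residue B-factor profiles, max-normalization,
  differential-region calls and percentile-mapped worm radii
  (`residue_bfactor_profile()`, `compare_flexibility()`, `worm_scores()`),
* **interface networks** — distance-classed hydrogen bonds (< 3.0 Å strong,
  3.0–5.0 Å weak), salt bridges (minimum charged-group distance ≤ 5.0 Å),
  water-mediated bridges, and a loop bond census split into intramolecular
  and intersubunit contacts (`detect_hbonds()`, `detect_salt_bridges()`,
  `loop_interaction_summary()`, `active_site_separation()`),
* **thermal stability and kinetics** — Arrhenius fits of inactivation rate
  constants with the derived T50% = (Ea·1000)/(R·(lnA − ln k)) at
  k = ln 2/1800 s⁻¹, two-state melt fits (Tm at F_U = 0.5), and direct
  Michaelis–Menten fits (`fit_arrhenius()`, `t50_from_fit()`,
  `fit_two_state_melt()`, `fit_michaelis_menten()`).

A synthetic dimer generator (`make_toy_dimer()`, `vap_dimer_spec()`) builds
two-fold symmetric models with *planted* displacements, B-factor profiles,
polar contacts at exact distances, metal sites and waters — and audits its
own output — so the entire pipeline is testable offline with known ground
truth.  PDB/mmCIF input and PDB output go through
[bio3d](https://CRAN.R-project.org/package=bio3d).

## Worked example

```r
library(loopdimer)

gen <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 1))
gen$model
#> StructureModel 'synthetic-vap-wildtype': 2550 atoms, chains [A, B]
#>   polymer    2538 atoms,   620 residues
#>   metal         6 atoms,     6 residues
#>   water         6 atoms,     6 residues

sup <- superpose_chains(gen$model, "A", "B")   # monomer A vs monomer B
sup$trace
#> DeviationTrace: 310 residues, mean 0.304 A, rms 0.452 A (fit atom set: mainchain)

loop_interaction_summary(gen$model, "A", c(324, 354))
#> InteractionNetwork around A:324-354
#>   edges: 78
#>   intramolecular within loop: 12 strong H-bonds (6 mainchain-mainchain), 43 weak, 0 salt
#>   intersubunit: 11 bonds (10 strong, 0 weak, 1 salt; 1 water bridges)
#>   thresholds: strong < 3.00, weak <= 5.00, floor 2.20, salt <= 5.00, water leg <= 3.40 A

detect_salt_bridges(gen$model)$distance
#> [1] 4.9 4.9                                   # Arg336-Asp59' across both interfaces

fit <- fit_arrhenius(simulate_inactivation(280, 104.79, noise_sd = 0.05, seed = 1))
fit
#> ArrheniusFit: Ea 281.72 kJ/mol, lnA 105.504, R^2 0.9997 (n = 8)
t50_from_fit(fit)$t50_C
#> [1] 25.74349
```

Read as a study: the dimer's two monomers superpose to a mean main-chain
deviation of 0.30 Å (near-perfect two-fold symmetry with localized
asymmetry), the large loop carries 12 internal hydrogen bonds (6 between
main-chain atoms) and makes 11 bonds to the partner subunit including a
4.9 Å long-range salt bridge, and an Arrhenius fit of simulated
inactivation data recovers a half-inactivation temperature of ~25.7 °C over
a 30-minute incubation.

A command-line entry point mirrors the same stages:

```sh
exec/loopdimer simulate  --variant wildtype --seed 1 --outdir out
exec/loopdimer compare   --structure out/synthetic_wildtype.pdb --outdir out
exec/loopdimer network   --structure out/synthetic_wildtype.pdb \
                         --loop-start 324 --loop-end 354 --outdir out
exec/loopdimer stability --csv out/inactivation.csv --outdir out
```

## Documentation

The methods vignette (`vignettes/interface-loop-analysis.Rmd`) describes the
models and conventions: superposition and trace summaries, B-factor
normalization, the distance criteria behind each interaction class, the
stability fits, the synthetic generator's design (balanced displacement
fields, planted-contact placement, strict geometry audit) and what the
emulation does and does not capture about real crystal structures.
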