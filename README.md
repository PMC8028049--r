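# reaxkit

Reactive force-field toolkit for aqueous iron–sulfur cluster chemistry, in R.

Iron–sulfur clusters (FeS, Fe₂S₂, Fe₄S₄, …) are the active sites of
ferredoxins and other electron-transfer proteins, form structural motifs of
pyrite and mackinawite, and figure prominently in origin-of-life chemistry.
Studying their behaviour *in water* — waters binding and leaving the Fe
sites, hydrogen-bond networks, cluster breathing — needs a potential that
lets bonds break and form. `reaxkit` implements such a bond-order reactive
potential (ReaxFF-style, standard dialect) for H/O/Fe/S, together with the
full workflow around it:

- **Potential**: total energy as the sum of tapered terms
  `E = E_bond + E_lp + E_over + E_under + E_val + E_pen + E_coa + E_tors +
  E_conj + E_Hbond + E_vdW + E_Coul + E_charge`, with
  electronegativity-equalization (EEM) charges re-solved at every
  evaluation and analytic forces (validated against central differences to
  < 10⁻⁴ kcal mol⁻¹ Å⁻¹). Isolated and orthorhombic-periodic systems.
- **I/O**: the community fixed-format `ffield` parameter file (strict
  round-trip), (extended) XYZ structures, tab-separated training sets,
  multi-frame extended-XYZ trajectories.
- **Dynamics**: L-BFGS geometry optimization to an RMSG criterion;
  velocity-Verlet NVT with a Berendsen thermostat (seeded, reproducible).
- **Training**: internal-coordinate scan generators (bonds, angles,
  torsions, cluster–water distances); weighted least-squares cost
  `C = Σ w_m (y_m^FF − y_m^ref)²`; particle-swarm optimization with
  Gaussian-mutation respawn and Nelder–Mead polishing; train/validation
  partitions.
- **Analysis**: permutation-inversion RMSD (Hungarian + Kabsch),
  hydrogen-bond counting (3.7 Å / 20° donor–acceptor criteria), trajectory
  statistics over analysis windows, symmetry-unique geometry-deviation
  reports, correlation and partial-charge reports, Fe coordination states.
- **Fixtures**: a deterministic synthetic H/O/Fe/S toy force field,
  solvated-box builder and synthetic training sets, so everything is
  testable offline.

## Worked example

```r
library(reaxkit)

ff <- make_toy_forcefield(c("H", "O"))   # synthetic, physically plausible
w  <- water_molecule()                   # O-H 0.9572 A, H-O-H 104.52 deg

compute_energy(w, ff)
#> <reax_energy> total: -250.230770 kcal/mol
#>   E_bond       -259.577285
#>   E_lp           -0.000000
#>   E_over         -9.033725
#>   E_under        -0.495938
#>   E_val           1.236900
#>   ...
#>   E_vdW          51.628366
#>   E_Coul        -81.279025
#>   E_charge       47.289937

equilibrate_charges(w, ff)
#> [1] -0.6173077  0.3086538  0.3086538
```

The EEM charges (O ≈ −0.62 e, H ≈ +0.31 e) and the term balance — large
negative bond energy against positive vdW/self-energy contributions — are
typical of this class of potential. Relaxing the monomer:

```r
wmin <- minimize_structure(w, ff, rmsg_tol = 1e-4)
measure_coordinate(wmin, c(1, 2))    # O-H bond length
#> [1] 0.9388409
measure_coordinate(wmin, c(2, 1, 3)) # H-O-H angle
#> [1] 97.52948
```

Parameter training closes the loop: references generated by a known force
field are recovered by the swarm trainer.

```r
ts <- make_synthetic_trainset(
  ff, list(water = w),
  list(water = list(scan_spec("bond", c(1, 2), 0.1, c(-0.3, 0.5)),
                    scan_spec("angle", c(2, 1, 3), 10, c(-30, 30))))
)
mask <- parameter_mask(tibble::tibble(
  section = "bonds", key = "H-O", param = c("De_s", "p_bo2"),
  lower = c(100, 3), upper = c(220, 6)), ff)
fit <- train_swarm(ff, mask, ts, swarm_config(n_agents = 20, seed = 11))
tidy(fit)$estimate   # generating values were 160 and 4.279
#> [1] 160.000 4.279
```

Solvation analysis of a short NVT run (Fe₂S₂ in a periodic water box):

```r
ff4  <- make_toy_forcefield()          # all four elements
box  <- build_solvated_box(box_spec(c(10, 10, 10), 33,
                                    solute = fe2s2_cluster(0), seed = 1))
traj <- run_md(box, ff4,
               md_config(timestep = 0.2, temperature = 300,
                         berendsen_tau = 25, n_steps = 600, seed = 1))
trajectory_statistics(traj, window = c(60, 120),
  distances = list(d_FeS = list(c(1,3), c(1,4), c(2,3), c(2,4))),
  dihedrals = list(theta = c(1, 3, 2, 4)),
  hbonds    = list(cluster = 1:4))
```

which reports the mean ± SD Fe–S distance, the folded Fe–S–Fe–S ring
dihedral and the cluster–water hydrogen-bond count over the analysis
window.

A thin command-line front-end lives at `inst/scripts/reaxkit`
(`reaxkit energy`, `minimize`, `md`, `scan`, `analyze`, `fixtures`,
`validate-ffield`, `convert`).

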