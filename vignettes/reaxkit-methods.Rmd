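---
title: "Methods: the reaxkit reactive potential, trainer and analysis tools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the reaxkit reactive potential, trainer and analysis tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`reaxkit` implements a bond-order reactive force field for H/O/Fe/S
chemistry together with everything needed to train, run and analyse it:
fixed-format parameter-file I/O, electronegativity-equalization (EEM)
charges, analytic forces, geometry optimization, Berendsen-NVT molecular
dynamics, scan-based training-set construction, a particle-swarm parameter
trainer, and solvation/quality analysis. This vignette records the model,
the numerical choices, and the design decisions a maintainer would want to
know.

## The potential

The total energy is a sum of tapered contributions

$$E = E_\mathrm{bond} + E_\mathrm{lp} + E_\mathrm{over} + E_\mathrm{under}
    + E_\mathrm{val} + E_\mathrm{pen} + E_\mathrm{coa} + E_\mathrm{tors}
    + E_\mathrm{conj} + E_\mathrm{Hbond} + E_\mathrm{vdW} + E_\mathrm{Coul}
    + E_\mathrm{charge},$$

where every bonded term depends on interatomic distances only through
continuous bond orders, so bonds may break and form during dynamics. The
functional forms follow the standard ReaxFF dialect (the 2008-era
formulation with lone-pair and overcoordination corrections) that mainstream
MD codes consume:

* **Bond orders.** Uncorrected sigma/pi/pi-pi bond orders are
  three-exponential functions of distance,
  $BO'_{ij} = \exp[p_{bo1}(r/r_\sigma)^{p_{bo2}}] + \ldots$, corrected by
  the standard overcoordination factors $f_1(\Delta'_i,\Delta'_j)$ and
  $f_4 f_5$ (1/3-bond corrections). Per-atom overcoordinations
  $\Delta = \sum_j BO_{ij} - \mathrm{Val}$ drive the lone-pair,
  over/under-coordination and valence-angle machinery.
* **Valence angles** use the $f_7 f_8$-damped harmonic-in-Gaussian form
  with the SBO/`theta_0` expansion, plus the double-bond penalty and
  three-body conjugation terms. **Torsions** use the standard
  $f_{10}\sin\Theta_1\sin\Theta_2$ three-term cosine series with the
  pi-bond-order Gaussian in the $V_2$ channel, plus four-body conjugation.
* **Hydrogen bonds** are evaluated for donor-H covalent pairs with bond
  order above 0.01 (configurable) and acceptors within 7.5 A:
  $E_{hb} = p_{hb1}(1 - e^{-p_{hb2} BO_{XH}})
  e^{-p_{hb3}(r_0/r + r/r_0 - 2)}\sin^4(\Theta_{XHZ}/2)$.
* **Nonbonded terms** (shielded Morse vdW and shielded Coulomb) are
  evaluated for *all* pairs, bonded included, and multiplied by a 7th-order
  taper that brings the value and its first three derivatives to zero at
  the cutoff radius (the `swb` general parameter, 10 A by default).
  Periodic systems enumerate explicit lattice images within the cutoff
  sphere instead of using minimum image, which stays correct for cells
  shorter than twice the cutoff - the regime of the solvated-cluster boxes
  this package targets. No Ewald summation is used, consistent with the
  tapered-Coulomb convention.
* **Charges** are re-equilibrated at every evaluation by solving the EEM
  linear system: minimize
  $\sum_i (\chi_i q_i + \eta_i q_i^2) + \sum_{i<j} K_{ij} q_i q_j$ subject
  to $\sum q_i = Q$, with the shielded, tapered kernel
  $K_{ij} = 332.0637\,\mathrm{Tap}(r)\,(r^3 + \gamma_{ij}^{-3})^{-1/3}$.

Omitted on purpose: the triple-bond stabilisation, C2 correction and
inner-core repulsion terms (not part of the energy decomposition above),
ACKS2-style charge models, and non-orthorhombic cells.

### Analytic forces

Forces are assembled by reverse-mode (adjoint) accumulation: each term
deposits derivatives with respect to corrected bond-order components,
per-atom bond-order sums, lone-pair counts and geometric coordinates; a
resolution pass propagates these through the correction factors down to raw
bond orders and distances. Two points matter:

1. **Charges are frozen during differentiation, and that is exact.** The
   EEM objective being minimized is *identical* to the
   $E_\mathrm{Coul} + E_\mathrm{charge}$ contribution to the total energy,
   so by the Hellmann-Feynman/envelope argument the $\partial q/\partial x$
   term vanishes at the EEM solution. The central-difference numerical mode
   (which differentiates straight through the charge solve) is used as the
   oracle in the tests and agrees to better than $10^{-4}$
   kcal mol$^{-1}$ A$^{-1}$.
2. **The bond-order cutoff is made $C^1$.** Raw bond orders below the
   cutoff $c$ (general parameter `bo_cutoff_x100` x 0.01) drop the pair
   from the bonded list. The sigma component is passed through the switch
   $(b-c)^2/b$, which vanishes *with zero slope* at $c$, so both the energy
   and the forces of every bonded term go to zero continuously as a pair
   crosses the cutoff. A plain threshold (or a constant shift) leaves a
   force discontinuity of order $D_e \cdot c$ that demonstrably stalls
   gradient-based minimization before tight RMSG criteria are reached.
   Residual non-smoothness remains at the hydrogen-bond donor threshold and
   the lone-pair integer boundaries; both are inherent to the standard
   forms and small enough not to obstruct the $10^{-4}$ RMSG criterion in
   practice.

Angle and torsion terms are enumerated for every pair in the bonded list
(no secondary bond-order threshold) precisely so that their $f_7$/$f_{10}$
prefactors switch the terms on continuously from zero.

## Geometry optimization and dynamics

`minimize_structure()` wraps L-BFGS-B with the analytic gradient and
iterates until the root-mean-square gradient over all $3N$ Cartesian
components reaches the requested tolerance (defaults: $10^{-3}$
kcal mol$^{-1}$ A$^{-1}$; the quality analyses use $10^{-4}$). On
non-convergence it raises a condition carrying the best-so-far structure.

`run_md()` integrates velocity Verlet with a Berendsen weak-coupling
thermostat, $\lambda = \sqrt{1 + (\Delta t/\tau)(T_0/T - 1)}$, applied
after the second half-kick; $\tau = \infty$ gives NVE. Initial velocities
are Maxwell-Boltzmann at the target temperature with the center-of-mass
motion removed and an exact rescale to the target (seeded; trajectories are
bit-reproducible for a fixed seed). Instantaneous temperature uses $3N - 3$
degrees of freedom for isolated systems and $3N$ for periodic ones. The
reference NVT protocol this mirrors is a 0.1 fs time step with
$\tau = 25$ fs in the 200-500 K range; energy-conservation tests run the
integrator at $\Delta t = 0.05$ fs and verify second-order convergence of
the drift.

## Training

`generate_scan()` displaces a rigid fragment along one internal coordinate
(bond, valence angle, torsion, or cluster-water distance, where the intact
water translates along the cluster-atom to oxygen axis) in fixed
increments - the typical choices are 0.1-0.4 A for distances and 10 degrees
for angles. The moving fragment defaults to the connected component on the
far side of the scanned coordinate, computed from a covalent-radius
connectivity heuristic; scans of cyclic coordinates need an explicit
`moving_set`.

`evaluate_cost()` implements the weighted least-squares objective
$C = \sum_m w_m (y_m^\mathrm{FF} - y_m^\mathrm{ref})^2$ over
training-partition entries. `w_m` multiplies the squared residual by
default; `weight_convention = "divide"` selects the reciprocal convention
$(\mathrm{res}/w_m)^2$ common in existing training sets. Energy entries are
differences between a distorted structure and its equilibrium reference;
charge entries are EEM charges of single atoms; validation-partition
entries never enter the cost. Training is staged: charge-related parameters
can be fitted first (`stage = "charges_only"`) before all parameters are
released, mirroring standard practice. Geometry-item entries are parsed and
stored but do not enter the cost (the objective is defined for energy and
charge data).

`train_swarm()` minimizes the cost with inertia-weighted global-best
particle-swarm optimization: cognitive/social coefficients $c_1 = c_2 =
2.0$, inertia decaying linearly from 0.9 to 0.4 over the run, velocity
clamped at half the bound range, Gaussian-mutation respawn of the
worst-performing fraction (default 0.2) of agents around the global best
with per-dimension sigma $\gamma(\mathrm{upper}-\mathrm{lower})$,
$\gamma = 0.1$, and periodic Nelder-Mead polishing of every agent (default
every 20 iterations - polishing at every iteration is too expensive to be
worthwhile). Respawned agents never replace the global best, so the
best-cost history is non-increasing by construction. With respawn and
polish disabled the implementation reduces to canonical gbest PSO, which is
regression-tested on a sphere function. The "transformed cost function"
variant described for flocking-style ReaxFF trainers is not implemented.

## Analysis

* `aligned_rmsd()` computes the minimum RMSD over translation, proper
  rotation, permutations within element classes and overall inversion, by
  alternating optimal assignment (an $O(n^3)$ Hungarian solver on squared
  distances within each element class) with Kabsch rotation until a fixed
  point, from 30 deterministic initial orientations and both parities. An
  exhaustive-permutation oracle validates it on 6-atom systems.
* `count_hbonds()` applies donor-acceptor criteria of 3.7 A and 20 degrees.
  The angular criterion is interpreted as the deviation from linearity of
  D-H...A measured between the D->H and D->A directions (<= 20 degrees
  means near-linear); a configuration switch selects the H-vertex
  convention (D-H-A angle >= 160 degrees) instead. Covalent D-H assignment
  uses a nearest-donor distance heuristic (1.3 A cutoff). With a cluster
  selection, only bonds with exactly one partner in the cluster count -
  the cluster-water hydrogen bonds of the solvation analyses.
* `trajectory_statistics()` averages named distances (pooling
  symmetry-equivalent pairs per frame, e.g. the four Fe-S distances of a
  Fe2S2 rhombus), folded-absolute dihedrals in [0, 180] degrees (the sign
  convention of the ring dihedral is not meaningful), and hydrogen-bond
  counts over a time window, reporting means and population standard
  deviations. The solvation protocol this supports discards an initial
  equilibration span and analyses the remainder.
* `geometry_deviation_report()` measures absolute deviations of bond
  lengths, valence angles and torsions over *symmetry-unique* internal
  coordinates: coordinates equivalent under automorphisms of the
  element-coloured bonded-topology graph (computed with igraph) are counted
  once.
* `coordination_states()` classifies Fe sites by the number of water
  oxygens within a 2.8 A cutoff (3 = trigonal, 4 = tetrahedral,
  5 = bipyramidal); the cutoff is configurable since no universal value
  exists.

## Synthetic fixtures and what they do (not) show

`make_toy_forcefield()` returns a complete, hand-designed H/O/Fe/S
parameter set. Its magnitudes are physically plausible (water minimizes to
an O-H bond of about 0.94 A and an H-O-H angle near 98 degrees; the Fe2S2
rhombus is planar with Fe-S around 2.2 A; water binds Fe at about 2.3-2.4 A
with a binding energy near 8 kcal/mol), but it is *synthetic*: it was
designed once, by hand, and is not fitted to any quantum-mechanical
reference. `build_solvated_box()` re-implements deterministic solvation:
jittered-lattice placement of rigid water monomers (0.9572 A / 104.52
degrees) with seeded random orientations and a 2.0 A heavy-atom minimum
separation; the reference box (13.0 x 16.4 x 15.24 A, one Fe2S2, 78 waters)
reproduces a density of 0.99 g/mL. `make_synthetic_trainset()` closes the
loop for trainer validation: references generated *by* a known force field
must be recoverable by the trainer (noise-free recovery to well under 1%).

Passing tests against these fixtures demonstrate the correctness of the
machinery - evaluator, gradients, integrator, trainer, analyses - not the
chemical accuracy of the toy parameter set. Conclusions about real aqueous
iron-sulfur chemistry require a force field fitted to quantum-mechanical
reference data, which is exactly the workflow (scans, staged training,
validation partition, deviation/correlation/charge reports) the package
automates.

## Problem sizes used in the shipped checks

The test suite and the reproduction script deliberately use scaled-down
problem sizes chosen to probe each property with comfortable margin: force
consistency on 5-6-atom random structures, NVE conservation on a water
dimer (0.05 fs, 10^4 steps, plus a halved-step run for the order check),
trainer recovery with two free bond parameters over diatomic/triatomic
scans (20 agents, 40 iterations), hydrogen-bond and RMSD oracles on
20-water frames and 6-atom clusters, and a 10 A box with 33 waters
(about 1 g/mL) for the short NVT solvation demonstration.

## Known limitations

* Pure-R evaluator: practical for hundreds of atoms and short trajectories,
  not for the 10^4-10^6-atom regimes of production MD engines.
* EEM transfers fractional charge between distant fragments (a known
  artifact of global charge equilibration); dissociation limits of charged
  species inherit it.
* No Nose-Hoover or Langevin thermostats, no barostats, no constraints;
  Berendsen does not sample a strict canonical ensemble.
* Lone-pair counts use the standard truncation form, whose derivative is
  discontinuous at integer electron-pair boundaries; minimizers can in
  principle stall exactly there.
* Torsion records support leading/trailing wildcards (`X-j-k-X`) only.
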