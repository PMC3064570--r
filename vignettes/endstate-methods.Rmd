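---
title: "Methods: end-state free energies and rotamer kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: end-state free energies and rotamer kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endstate)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real trajectories.

## The end-state free energy model

The package analyses the non-covalent association R + L ⇌ C from snapshot
ensembles of molecular dynamics trajectories. The binding free energy is
split into an enthalpic ensemble average and a solute entropy term,

$$\Delta G = \Delta H - T\Delta S, \qquad
  \Delta H = \Delta E_{MM} + \Delta G_{solv},$$

where each Δ is mean(complex) − mean(receptor) − mean(ligand). The
molecular-mechanics part is the standard fixed-charge force-field sum:
harmonic bonds and angles and periodic cosine torsions (the *internal*
term), plus pairwise 12-6 Lennard-Jones (Lorentz–Berthelot combination,
σ as the zero-crossing) and Coulomb energies evaluated with the constant
332.0636 kcal·Å·mol⁻¹·e⁻² and *no cutoff* — end-state analysis evaluates
interaction energies exactly rather than reproducing the truncation
scheme of the dynamics engine. Default 1-4 scalings are 1/2.0 (vdW) and
1/1.2 (Coulomb), the ff03-family convention, exposed as arguments.

Solvation is implicit and two-part. The polar term is a Still-form
generalized Born sum over all atom pairs (self terms included),

$$\Delta G_{polar} = -\tfrac{332.0636}{2}
  \Bigl(\tfrac{1}{\varepsilon_{in}} - \tfrac{1}{\varepsilon_{out}}\Bigr)
  \sum_{ij} \frac{q_i q_j}{f_{GB}(r_{ij}, B_i, B_j)},\qquad
  f_{GB} = \sqrt{r^2 + B_iB_j e^{-r^2/4B_iB_j}},$$

with effective Born radii from the pairwise analytic (HCT) descreening
integral followed by the OBC tanh rescaling (α = 1.0, β = 0.8, γ = 4.85,
radius offset 0.09 Å, neighbour scaling 0.8 — the standard published
constants of that model family; all configurable). Dielectrics default to
ε_in = 4 and ε_out = 80, the protein-in-water convention for charged
interfaces. A finite-difference Poisson–Boltzmann solver is deliberately
out of scope: the framework is solver-agnostic, and the report layer
accepts externally computed polar columns so PB values can be slotted in;
polar columns are always labelled with their backend. The one-ion limit of
the GB expression is the exact Born formula, which the tests exploit as a
closed-form oracle.

The nonpolar term is the linear surface model γ·SASA + β, with SASA from
Shrake–Rupley sphere sampling (default 960 deterministic golden-spiral
points per atom, probe 1.4 Å). Two published parameter sets are carried:
(γ, β) = (0.00542, 0.92) for PB-flavoured runs and (0.005, 0.0) for
GB-flavoured runs.

Standard errors default to the naive SEM over snapshots — the convention
of the classic end-state tools — combined across species as
√(SE²_C + SE²_R + SE²_L); block averaging (any block size) is available
because snapshot series are autocorrelated and the naive SEM is then an
underestimate, which the convergence report makes visible. Under the
single-trajectory protocol the receptor and ligand snapshots are slices of
the complex trajectory, so the internal terms cancel; the assembly
verifies the cancellation (tolerance 1e-6) and then sets ΔE_int to exactly
zero rather than carrying numerical noise.

All derived sums (ΔE_gas, ΔG_solv, ΔH, ΔG_polar+ΔE_ele) are computed once
on full precision and satisfy their identities exactly; reports round to
two decimals (comma or dot decimal separator configurable) only at the
formatting stage. The packaged reference tables for the four
JMJD2A-tudor–histone complexes reproduce every derivable printed cell
within half-ulp stacking of the two-decimal inputs (0.015 kcal/mol); one
printed entropy total (H3K4me3) disagrees with the sum of its own printed
components by exactly 0.01 kcal/mol and is treated as a rounding artifact
of the source table.

## Solute entropy

Translational entropy is Sackur–Tetrode at a 1 atm standard state (the
standard state and temperature, 310 K, are explicit arguments — absolute
translational entropies are meaningless without them). Rotational entropy
is the classical rigid rotor from the principal moments of inertia, with
the symmetry number exposed, the two-moment form for linear molecules and
a flagged zero for a single atom. Vibrational entropy is the quantum
harmonic oscillator summed over normal modes; frequencies come from
diagonalising the mass-weighted Hessian, dropping the six smallest-|λ|
rigid-body modes for a nonlinear molecule (count configurable; imaginary
modes are excluded with a warning and counted, never silently zeroed).

Full force-field normal-mode analysis of a solvated protein is not
desk-scale; the package therefore computes vibrational entropy from a
user-supplied Hessian or from a harmonic elastic-network Hessian built on
a single structure (uniform springs within a cutoff). The elastic network
has exactly six zero modes by construction, which doubles as an invariant
test. Consequently the packaged reference entropy values are anchors for
the Δ-assembly identity (−TΔS_tot is the exact sum of its three terms),
not absolute reproductions.

## Rotamer kinetics and barriers

A methyl torsion time series (IUPAC-signed dihedrals on (−180°, 180°]) is
mapped to rotamer states by a scheme that must partition the circle; the
default is symmetric 120° sectors centred on the canonical wells:
g+ = (0°, 120°], t = (120°, 180°] ∪ (−180°, −120°], g− = (−120°, 0°].
Boundaries are half-open (lo, hi], matching the angle wrapping, so every
angle has exactly one state and 120° itself is still g+.

Transition rates are counts over dwell time, k(i→j) = N(i→j)/T_i in ns⁻¹.
Runs shorter than `min_dwell` frames (default 2) are treated as boundary
recrossing chatter and removed before counting — appropriate for noisy
continuous dynamics. For trajectories from the package's own Markov
generator the emission jitter (sd 10°, six sigma from any boundary)
produces no chatter, while the filter *would* swallow genuine fast
two-step excursions and bias rate ratios; closed-loop Markov tests
therefore estimate with `min_dwell = 1`. A state never visited has its
outgoing rates flagged undefined (NA), which is different from an observed
rate of zero (visited, never left): the latter maps to an infinite
barrier.

Barriers invert the Arrhenius relation, E_a = −RT ln k + c. The prefactor
is unobservable from a single trajectory, so barriers are reported
relative to a datum: `min_zero` (smallest barrier pinned at 0, default) or
a fixed constant. Barrier *differences* are datum-independent and satisfy
E_a(i→j) − E_a(k→l) = RT ln(k(k→l)/k(i→j)) exactly; at 310 K a rate ratio
of 20 corresponds to 1.845 kcal/mol. Torsional energy profiles use
Boltzmann inversion, E(θ) = −RT ln p̂(θ), shifted so the minimum is zero —
which removes the temperature-dependent additive constant inherent to the
inversion; empty histogram bins are NA, never zero energy.

## Interactions

A hydrogen bond is a donor heavy atom (N/O) with a covalently attached
hydrogen (nearest heavy atom within 1.25 Å) and an acceptor (N/O) with
donor–acceptor distance ≤ 3.5 Å and donor–H–acceptor angle ≥ 120°; a salt
bridge pairs Asp/Glu carboxylate oxygens (and terminal OXT) with
Arg/Lys/His — and methylated-lysine — nitrogens within 4.0 Å, boundary
closed. These cutoffs are the conventional ones; the source analyses in
this domain rarely state theirs, so published occupancy percentages are
treated as qualitative anchors and never as test targets, while the
package's own bookkeeping (occupancy = 100 × present/total frames,
episodes as maximal runs of consecutive present frames) is tested exactly
against planted ground truth. Occupancy is tracked per donor–acceptor atom
pair, with a residue-level roll-up (max over atom pairs) attached because
published interaction tables are residue-level.

## Geometric observables

Radius of gyration is mass-weighted about the centre of mass. RMSD uses
Kabsch superposition via SVD with the determinant sign correction (the
rotation is always proper, never a reflection; weights supported). RMSF
first superposes every frame onto frame 1 and then iterates superposition
onto the running mean structure until the mean moves < 1e-6 Å RMSD (max
10 iterations) — the initial canonical orientation makes the fixed point
invariant under rigid motions applied to input frames. The dominant period
of a distance series is the highest non-zero-frequency peak of the FFT
periodogram after mean removal, accepted only when its power exceeds 3×
the median non-zero-frequency power (otherwise "aperiodic"); the reported
confidence span is the ±1 frequency-bin interval, the natural resolution
limit of a length-N record.

## What the generators emulate — and what they do not

The synthetic module generates every input class with known truth and a
receipt (seed + exact parameters), all from a local RNG that never
disturbs the global stream:

- **Dihedral trajectories.** `markov` draws a continuous-time jump process
  between the three wells (rates either Arrhenius-derived from the
  potential spec or supplied directly) and emits well-centre + Gaussian
  jitter; `langevin` integrates overdamped Euler–Maruyama dynamics on a
  smooth periodic potential interpolating the spec's well depths and
  barrier tops (order-4 trigonometric fit constrained to zero slope at the
  well centres), refusing time steps beyond the explicit-Euler stability
  bound γ/max|E″|. Long Langevin runs sample the Boltzmann density of
  that potential, so profile recovery is a genuine parameter-recovery
  test.
- **Energy tables.** Stationary Gaussian AR(1) per component with
  requested means, sds and lag-1 correlation: enough to validate the
  assembly arithmetic, SEM propagation and the block-averaging response to
  autocorrelation — but *not* the heavy-tailed, cross-correlated
  component fluctuations of real force-field snapshots.
- **Toy complexes.** Contacts planted with exact present-frame subsets
  (round(f·N) frames, seeded), geometries satisfying or violating the
  criteria with wide margin. Real trajectories live near the cutoffs;
  passing these tests shows the bookkeeping is exact, not that 3.5 Å/120°
  are the right criteria for a given system.
- **Breathing trajectories.** Two rigid lobes with sinusoidal tip
  separation plus optional coordinate noise — a single-mode caricature of
  inter-domain motion with none of the drift or mode-mixing of real
  dynamics.

Passing the closed-loop suite therefore demonstrates correctness of the
estimators under their stated models, with controlled statistical
tolerances; it does not certify force-field or sampling adequacy for any
real system.

## Problem sizes and tolerances

The test and acceptance runs use sizes chosen to keep statistical
tolerances honest at interactive scale: 10⁶-step Markov trajectories for
rate-ratio recovery (barrier differences within 0.1 kcal/mol of
RT ln 20); 2×10⁶-step Langevin runs at dt = 0.02 ps over wells of
0–0.8 kcal/mol depth and 2.2–2.6 kcal/mol barriers — barrier heights in
the range reported for methyl rotamer transitions in methylated-lysine
readers, and low enough that inter-well transitions are plentiful — for
well-depth recovery within 0.15 kcal/mol and minima within one 5° bin;
400-frame toy complexes for exact occupancy fractions; 1200-frame
breathing records (10 ps/frame) for period recovery within one frequency
bin at SNR 5 over 20 seeds.

## Known limitations

- No Poisson–Boltzmann solver; the polar column is GB unless an external
  column is supplied.
- No quasi-harmonic (covariance-based) entropy; vibrational entropy
  quality is bounded by the supplied Hessian, and the elastic-network
  default is a topology-level approximation.
- Per-residue decomposition splits pair energies half-and-half, the
  convention of the classic decomposition tools; other attributions
  (e.g. surface-weighted) are not implemented.
- The Markov dihedral generator emits unimodal jitter per well, so it
  cannot exercise schemes with overlapping state densities.
- Binary trajectory formats (DCD/NetCDF) are not read; multi-model PDB
  plus a TSV topology sidecar is the interchange, since force-field
  charges and radii cannot be recovered from PDB columns anyway.
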