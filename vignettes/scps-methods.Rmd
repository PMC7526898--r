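---
title: "Ratchet-and-pawl dynamics and self-consistent path sampling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratchet-and-pawl dynamics and self-consistent path sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scps)
```

## The procedure

`scps` samples rare transitions between a reactant and a target state in
three repeated steps.

**Step 1 — ratchet-and-pawl dynamics (rMD).** Langevin dynamics is augmented
with a history-dependent force on a collective variable (CV) z(X),

$$F_i = -k_R \, \nabla_i z \,(z - z_m)\,\theta(z - z_m),$$

where $z_m$ is the running minimum of z. When the system progresses
($z \le z_m$) the force is exactly zero and the dynamics is plain MD; the
bias only opposes backtracking. We take $\theta(0)=0$, so on the boundary
$z = z_m$ the bias is off — this makes the latent-bias invariant (zero bias
work on latent frames) exact rather than approximate. The memory is
initialized from the first frame (the running minimum "up to time t" at t=0
is the initial value) and is updated *after* each force evaluation, so the
force at a step always uses the memory of the previous step; this makes
single-step behavior well defined.

The initial CV is the squared contact-map difference to the target,
$z(X)=\sum_{ij}[C_{ij}(X)-C_{ij}(X_{\mathrm{ref}})]^2$ with
$C_{ij}=[1-(r_{ij}/r_0)^6]/[1-(r_{ij}/r_0)^{10}]$, $r_0 = 7.5$ Å, and a hard
cutoff $r_c = 12$ Å beyond which entries are exactly zero. The removable
singularity at $r=r_0$ is evaluated by its limit 3/5 (series branch inside a
guard band of $10^{-7} r_0$); the jump at $r_c$ is accepted as an efficiency
device, applied identically to instantaneous and reference maps. At Cα
resolution the exclusion of trivially bonded contacts is a residue-separation
rule, $|i-j| \ge$ `min_separation` (default 3).

**Step 2 — mean path.** Successful trajectories (see below) are averaged
frame-wise (iso-time mean) in contact-map space and downsampled to
$N_C = 10$ maps equally spaced in z, endpoints always kept, ties resolved to
the earlier frame (determinism).

**Step 3 — double ratchet on path CVs.** The mean path defines a progress
coordinate $s_\lambda$ and a proximity coordinate $w_\lambda$
(log-sum-exp over the squared map distances $d_k$ to the $N_C$ maps). The
next iteration ratchets independently on $s_\lambda$ (force constant $k_s$)
and on the off-path distance $d=-w_\lambda$ (force constant $k_w$), each with
its own running-minimum memory. Iterations repeat until the mean squared
distance between corresponding maps of successive downsampled paths falls
below a tolerance (default $10^{-3}$ in squared-norm units) — a quantitative
surrogate for visual convergence of landscape plots. With ensembles of ~20
trajectories the iso-time mean carries sampling noise of order $10^{-2}$, so
on the toy systems the procedure typically reports the convergence trace
rather than triggering the threshold; the trace is the meaningful output.

**Success criterion.** A trajectory reaches the target if some frame has
RMSD below `rmsd_th` (default 3 Å) *and* the root-mean-square of the
over-threshold excursions across all later frames stays below `e_th`
(default 0.3 Å). The excursion statistic is an RMS — the square root of the
mean of $\theta(\mathrm{RMSD}-\mathrm{th})(\mathrm{RMSD}-\mathrm{th})^2$ —
so that it carries the same units (Å) as the tolerance it is compared to.

## Conventions resolved during implementation

Three printed conventions are ambiguous or mutually inconsistent, and the
package resolves them as follows (each choice is testable):

* **$s_\lambda$ normalization.** Indexing the mean-path maps $k=0,\dots,
  N_C-1$ and defining $s = 1 - \langle k\rangle/(N_C-1)$ satisfies the
  endpoint contract exactly ($s=1$ at the first map, $s=0$ at the last, in
  the large-$\lambda$ limit); the literal 1-based form divided by $N_C$
  yields $s \approx 1 - 1/N_C$ at the first map instead.
* **$w_\lambda$ index factor.** $w_\lambda = \lambda^{-1}\ln\sum_k
  e^{-\lambda d_k}$, without an index factor inside the sum, matching the
  "shortest distance" reading: $-w_\lambda \to \min_k d_k$ at large
  $\lambda$. The index-weighted variant is available
  (`w_indexed = TRUE`).
* **$\lambda$.** Setting $\lambda$ "equal to the average distance between
  neighboring maps" is dimensionally inconsistent with
  $e^{-\lambda\|\cdot\|^2}$; the default is the reciprocal of the mean
  squared-norm neighbor distance (`set_lambda(mode = "reciprocal")`), the
  literal reading is selectable. Degenerate paths (zero neighbor distance)
  floor the mean at $10^{-12}$ with a warning.
* **Ratchet direction for the w channel.** The ratchet acts on
  $d \equiv -w_\lambda$ with a running-minimum memory, so the bias opposes
  excursions away from the path beyond the closest approach attained.

## The engine

The integrator is BAOAB Langevin (velocity Verlet in the zero-friction,
zero-noise limit) or Euler–Maruyama overdamped dynamics, in reduced units
($k_B = 1$, unit masses). Positional restraints (harmonic anchors) play the
role of heavy-atom restraints; at Cα resolution only Cα restraints exist, so
the restrained-subunit contract is expressed as an RMSD bound on the
restrained beads rather than a faithful heavy-atom equivalent. All
randomness flows through R's RNG, so a seed makes whole trajectories
bit-reproducible; with bias constants set to zero the biased code path is
bit-identical to plain dynamics under the same seed (the branch adds exactly
zero force and consumes no extra random numbers).

Forces, contact maps, CV gradients and Kabsch RMSD are implemented in C++
(RcppArmadillo); all analytic gradients are validated against central finite
differences at relative error below $10^{-5}$ in the test suite.

## Toy systems and what they emulate

The paper-scale application of this method family is explicit-solvent
all-atom MD; here the force field is replaced by desk-scale models, because
the algorithm — not the force field — is the object under test.

* **Mueller–Brown surface** and a **two-channel double well** (quartic wells
  with a Gaussian bump splitting the barrier into two channels; the bump is
  offset so one channel dominates, keeping the transition mechanism stable
  across iterations). For 2-D systems the "contact map" degenerates to the
  coordinates themselves and z to the squared distance to the product
  minimum; the full SCPS machinery operates unchanged. The converged mean
  path is validated against a string-method (zero-temperature minimum-energy
  path) computation with equal-arc-length reparametrization — an independent
  oracle.
* **Cα Gō models** built from a reference structure: harmonic bonds and
  angles and cosine dihedrals at native values, 12-10 Lennard-Jones wells at
  native contact distances (contacts: Cα–Cα ≤ 7.5 Å, $|i-j| \ge 3$), WCA
  repulsion elsewhere. Because every non-native eligible pair is farther
  than the contact cutoff in the native state and the WCA cutoff is 4 Å,
  the total force at the reference structure is exactly zero — the "native
  state is a force-free minimum" invariant is exact, not approximate. A
  16-bead β-hairpin serves as the folding system; it folds spontaneously at
  reduced temperature ≈ 0.45, which provides the unbiased reference
  ensemble for pathway validation.
* **Toy fibril**: a two-rung β-solenoid with a rectangular rung
  cross-section (aspect 1.6), 4.8 Å stacking rise, template subunits exact
  translated copies, one converting monomer at the growing end. The
  rectangular cross-section is deliberate: with a square cross-section a
  register-rotated docking of the monomer is nearly degenerate in
  contact-map space and traps the dynamics in a misregistered intermediate.
  Initial conditions come from restrained thermal denaturation at five times
  the model's folding temperature (the all-atom recipe of a fixed
  temperature is force-field-specific), harvesting frames with monomer
  Q < 0.1, optionally filtered to template-proximal configurations.

**Templated conversion requires an intrinsically unstable monomer.** In a
plain pairwise Gō model the converting monomer's native fold is stable in
isolation, and biased trajectories then fold the monomer internally first
and dock it as a rigid body last — the opposite of templated growth. The
fibril model therefore scales the well depth per contact class
(`fibril_go_model(eps_scale = ...)`): intra-monomer rung-stacking contacts
are strongly weakened while the monomer–fibril stacking interface is
strengthened. This emulates the defining feature of amyloid conversion — the
free monomer is disordered and acquires structure only on the fibril
surface — within a pairwise model that cannot otherwise express the
three-body cooperativity of templating.

**Incorporation metric.** Secondary-structure assignment is undefined at Cα
Gō resolution, so the per-residue incorporation event is native-contact
based. The default is saturation of all of a residue's native contacts
(≥ 70%, > 5 consecutive frames). For solenoid rungs a local surrogate of a
β-strand call is used instead (`rung_stack_pairs()`): a rung residue is
structured through its intra-rung contacts plus its contacts to the rung it
stacks on — for the anchored rung the template surface, for the distal rung
the anchored rung — mirroring a backbone secondary-structure call in which a
strand is formed when paired with the strand beneath it.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `r0` | 7.5 | Å | contact-function reference distance (C = 3/5 there) |
| `rc` | 12 | Å | hard contact cutoff (entries exactly 0 beyond) |
| `min_separation` | 3 | residues | excludes trivially bonded contacts |
| `rmsd_th` / `e_th` | 3 / 0.3 | Å | success criterion (surfaces: 0.3 / 0.1 in surface units) |
| `n_c` | 10 | maps | downsampled mean-path length |
| `k_r`, `k_s`, `k_w` | system-specific | energy per CV² | ratchet force constants |
| `dt`, `friction`, `temperature` | system-specific | reduced | engine parameters |

The ratchet constants are scaled to the reduced-unit CV magnitudes of each
toy system (`demo_system()`); the constants appropriate to all-atom,
kJ/mol-scale applications are preserved for reference in
`allatom_reference_settings()`. On the toy systems the s-channel constant
must overcome the underlying landscape forces (e.g. $k_s \sim 10^3$–$10^4$
for CVs of order 1), while the w-channel constant is kept much smaller for
bead systems: at desk scale an individual trajectory's instantaneous contact
map lies far from every map of a 10-point iso-time mean (the fluctuation
distance exceeds the neighbor spacing), so a successful transition must
transiently *increase* the off-path distance, and a stiff w-ratchet
suppresses the transition instead of guiding it. This scale separation
disappears at all-atom scale, where the printed constants put the two
channels within a factor of two of each other.

## Numerical choices and degenerate inputs

* Log-sum-exp evaluation of $s_\lambda$ and $w_\lambda$ (shift by the
  minimum map distance) — no underflow for any $\lambda$.
* Coincident beads ($r = 0$) score contact 1 (the limit) with a warning.
* Downsampling with non-monotone z: nearest-target selection remains
  defined; duplicate selections are collapsed (the path may then carry fewer
  than $N_C$ maps).
* Empty ensembles, zero native contacts, restrained converting monomers,
  and trajectories shorter than the persistence window raise explicit
  errors or warnings rather than propagating NaNs.
* Non-finite coordinates truncate the trajectory with an error flag in the
  metadata.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run: Mueller–Brown ensembles of
20 trajectories × 40 000 steps; double-well ensembles of 20 × 20 000 steps;
hairpin (16 beads) ensembles of 6–10 × 20 000–100 000 steps; fibril (36
beads) ensembles of 12 trajectories × 150 000 steps from each of two
denaturation-derived initial conditions (400 000-step denaturation runs) —
sizes chosen so the full suite completes on a single CPU core in minutes
while leaving every statistic well resolved.

## What passing tests do and do not show

The toy systems exercise every algorithmic component — the ratchet
mechanics, the CV algebra and gradients, the mean-path construction, the
success classification, and all validation statistics — under conditions
where independent oracles exist (closed forms, brute-force enumeration,
finite differences, the string method, spontaneous folding at elevated
temperature). They do not probe explicit-solvent energetics, secondary
structure in the backbone-dihedral sense, or system sizes where neighbor
lists and force-field accuracy dominate; conclusions about real proteins
require the all-atom setting this package deliberately replaces.

## Known limitations

* The iso-time mean path is computed over trajectories from one initial
  condition (pooling across conditions is not the default), matching the
  per-condition construction of the method.
* The w-channel ratchet direction is a design decision (see above); other
  readings of the printed definition exist.
* Convergence at 20 trajectories/iteration is noise-limited (see Step 3);
  the convergence flag is conservative.
* The fibril's contact-class energy scaling is a deliberate model of
  monomer instability, not a measured quantity.
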