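---
title: "Pocket-shape collective variables, metadynamics setup and ensemble selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket-shape collective variables, metadynamics setup and ensemble selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitedyn)
```

## The problem

Many enzymes bind their ligands in a cleft between quasi-rigid domains
and close over them through hinge-like motions; the unbound (apo)
crystal structure can then differ from the bound (holo) one by several
Angstrom over the binding site. Docking against the apo structure alone
fails for such targets. The strategy implemented here biases a
molecular-dynamics simulation of the apo protein along a small set of
*binding-site shape* collective variables (CVs), so that the sampling
visits compact, holo-like pocket geometries without using any knowledge
of the ligand, and then distills the trajectory into a maximally
diverse ensemble of receptor conformations for ensemble docking.

`sitedyn` covers every desk-side stage of that workflow: site
definition, CV construction, metadynamics input generation, CV-space
clustering of trajectories, holo-likeness evaluation and docking-pose
post-processing. Running the MD and docking engines themselves is out
of scope.

## The collective variables

Given a binding site $S$ (a residue list, either a 3.5 Å heavy-atom
shell around a ligand in a reference complex or a merged
pocket-prediction consensus), four shape CVs are built from the apo
structure:

* **RoG\_BS** — the mass-weighted radius of gyration
  $\sqrt{\sum_i w_i\,|r_i-r_c|^2 / \sum_i w_i}$ of the site's backbone
  atoms (N, CA, C, O). It measures pocket compactness and is the axis
  along which closure proceeds.
* **CIP\_1–3** — contacts across the three *inertia planes*: the
  planes orthogonal to the principal inertia axes of the site's heavy
  atoms, each passing through the site's geometric center. Each plane
  splits the site residues into two groups (by the sign of the
  projection of their heavy-atom geometric centers; a residue exactly
  on the plane goes to the first group) and the CV is the
  switching-function contact count between the groups,
  $\sum_{i\in A}\sum_{j\in B} s(r_{ij})$ with the rational switch
  $s(r) = \frac{1-x^n}{1-x^m},\; x=(r-d_0)/r_0$. These
  shape-adaptive contacts drive the two halves of the pocket toward or
  away from each other regardless of its orientation.
* **cRD** — contacts between quasi-rigid domains. For every mobile
  domain, the site residues at its interface with the core (selected
  on both sides by an 8 Å minimum heavy-atom distance rule) define one
  coordination CV, mobile side versus core side. Two validity
  conditions are enforced as hard errors, since the interface cutoff
  is only meaningful when they hold: no site residue may belong to two
  interfaces, and each domain side must contribute at least four
  residues.
* **Charged split** — when more than 25% of the site residues are
  charged (ASP/GLU/LYS/ARG by default; histidine is deliberately
  excluded as ambiguous at neutral pH), each cRD CV is split into a
  charged-residue and an other-residue variant, provided every
  resulting group on both sides keeps at least two residues that are
  not sequence-adjacent. "Non-adjacent" is read as sequence numbers
  differing by at least two within a chain. The decision, either way,
  is recorded in the bundle's audit log.

The inertia frame is computed once from the apo structure and frozen:
biasing requires fixed atom groups, so the planes are a property of
the setup, not of each frame. Axis signs follow a deterministic
convention (largest-magnitude component positive, third axis completed
right-handed), so repeated setups are byte-identical.

## Metadynamics parameters and the restraint schedule

The emitted input deck uses bias-exchange well-tempered metadynamics
defaults of hill height 0.6 kcal/mol, bias factor 10, deposition every
2.5 ps and bias exchange every 50 ps. Hill widths are not guessable
a priori: they are set to the per-CV sample standard deviation over a
short (about 200 ps) unbiased run, with a configurable scale factor
(default 1). A constant CV in that run is an error — a zero width is
unusable — rather than a silently substituted default.

Pocket contraction is steered by a four-phase schedule on RoG\_BS:

1. 10 ns unrestrained;
2. 40 ns with an upper wall at the apo value, force constant ramping
   linearly 10 → 25 kcal mol⁻¹ Å⁻²;
3. 400 ns in which the wall center is lowered stepwise (every 1 ns,
   linear envelope) to 85% of the apo value;
4. 150 ns hold at the target.

The defaults sum to 600 ns although the protocol they are taken from
reports 550 ns of cumulative time per replica; the two figures cannot
both be right if the phases are strictly sequential, and the likeliest
reading is that the 400 ns phase was counted as elapsed time from the
start of the run. We do not silently pick one interpretation: the
durations are taken verbatim, the discrepancy is printed in the audit
log, and all four durations are configurable.

A pace that is not an integer number of MD steps (e.g. 2.5 ps at a
3 fs timestep) is an error at emission time, not a rounding. The deck
is deterministic — identical inputs give byte-identical text — and
`parse_metadynamics_input()` recovers every parameter, so
emit–parse–emit is an identity.

## Two-stage ensemble clustering

Frames are clustered in CV space, not coordinate space. The RoG\_BS
axis is cut into 30 equal-width slices (half-open on the right, the
last closed). Slice $i$ with $N_i$ of $N_{tot}$ frames receives
$x_i = \mathrm{round}\!\left(\frac{N_i}{N_{tot}} N_c\right)$ clusters,
with $N_c = 100$ by default; if any populated slice would receive
fewer than two, $N_c$ is raised by 10 and the allocation recomputed
until every populated slice holds at least two clusters. Within each
slice, complete-linkage agglomerative clustering seeds the partition;
a deterministic Lloyd k-means (at most 10,000 iterations, empty
clusters repaired by re-seeding with the farthest frame so the count
is preserved) refines it globally. The representative of each cluster
is its member frame nearest the centroid, earliest frame on ties.

Choices the procedure's description leaves open, fixed here:

* **Standardization.** CV columns are standardized to zero mean and
  unit variance over the whole series before any distance is computed.
  The CVs mix Angstrom and dimensionless contact counts spanning two
  orders of magnitude; unstandardized Euclidean distance would let
  whichever contact CV is largest dominate arbitrarily.
* **Rounding.** $x_i$ uses round-half-away-from-zero, then is clipped
  to the slice size. Banker's rounding would make the documented
  inflation behavior (e.g. slice sizes (980, 10, 10) terminating at
  $N_c = 150$ with allocation (147, 2, 2)) irreproducible.
* **Exemption.** A slice with fewer than two frames can never hold two
  clusters, so it is exempt from the rule (it keeps one cluster per
  frame) and a message is emitted; without the exemption the inflation
  loop cannot terminate.
* **Linkage.** Complete, the common default of the hierarchical
  routine the procedure is built on.

There is no randomized initialization anywhere, so the pipeline is
deterministic given the input series.

## Evaluation metrics

Holo-likeness is always measured after superposing the *site*
selection (Kabsch least-squares fit with reflection correction), never
the whole protein: `binding_site_rmsd()` on CA or heavy atoms,
`per_residue_holo_flags()` for per-residue heavy-atom RMSD under a
single whole-site alignment (default threshold 2.0 Å per residue,
overridable per residue — the published per-residue criteria table is
not available, so a uniform default consistent with the 2/2.5 Å
structure-level bands is used), `rmsd_distribution()` for 0.2 Å-binned,
cubic-spline-smoothed densities on a 0.05 Å grid (negative spline
overshoot is clipped to zero and the curve renormalized to unit area),
and `ensemble_summary()` for percentage-below-threshold tables.

For docking poses, `native_contact_set()` collects all ligand–protein
heavy-atom pairs within 5 Å in the reference complex, and
`fraction_native_contacts()` reports the fraction of those pairs
preserved in a model — an atom-pair (not residue-pair) definition,
the stricter CAPRI-style reading. Pose clustering uses the
size-adaptive cutoff $d_c = 0.067 \cdot N_{nh}$ Å (reported to one
decimal, used unrounded internally) with average-linkage agglomerative
clustering of no-fit RMSDs computed in the common site-aligned frame.
"Distance RMSD" could also mean internal-distance-matrix RMSD, but
that would make the site-alignment step pointless — the poses are
aligned precisely so that ligand displacement is meaningful — so the
no-fit coordinate reading is used.

## The synthetic test world

`make_hinged_toy_protein()` builds a minimal three-domain system: a
core (a 10-residue floor plus two 4-residue walls) and two 10-residue
arms hinged at pivots beyond the floor ends, standing in for the
LID/NMP-like mobile domains. Each toy residue carries N, CA, C, O and
one CB pseudo-side-chain atom, the smallest atom set that
distinguishes every selection rule (backbone, CA-only, heavy). The
32-residue site spans both arm–core interfaces, with 11 charged
residues (about 34%, matching the charged-site regime that triggers
the split rule) placed so that every charge group on every interface
side keeps two non-adjacent members. Closing the hinges from 15° to
75° off vertical folds the arms over the core, which by construction:

* shrinks the site backbone radius of gyration by more than 20%
  (measured: about 35%, from 17.3 Å to 11.3 Å),
* raises both inter-domain contact CVs,
* changes all three inertia-plane contact CVs.

The generators are pure functions of their spec and a mandatory seed
(the caller's RNG stream is saved and restored), so fixtures are
byte-reproducible. What the toy does *not* model: real side-chain
chemistry and rotamers, sterics, solvent, force-field energetics, and
the conformational heterogeneity of a real trajectory. A green test on
the toy therefore establishes that the *rules* (selection cutoffs,
partitions, schedules, clustering arithmetic) are implemented
correctly, not that the protocol finds holo-like states of any real
protein — that claim requires the actual enhanced-sampling
simulations, which are out of scope.

## Numerical choices and limitations

* Switching defaults $r_0 = 4.5$ Å, $d_0 = 0$, $n = 6$, $m = 12$: the
  published per-CV values live in supplementary material not available
  here, so the conventional exponents of the coordination routine and
  a standard heavy-atom contact radius are used; everything is
  overridable per CV. The removable singularity at $x = 1$ is filled
  with $n/m$.
* Inter-residue distances are minima over heavy-atom pairs — the
  least biased convention when none is stated.
* Alternate-location conformers resolve to the highest occupancy;
  insertion codes are carried but never renumbered.
* Whether the gyration CV is mass-weighted in the reference
  implementation is unstated; mass weighting is the default here and a
  flag (`mass_weighted_rog`) exposes the alternative.
* Structures with missing atoms are not repaired and protonation is
  not assigned; hydrogen handling is limited to flagging, since every
  selection rule is defined on heavy atoms.
* Trajectories are read as multi-model PDB; binary formats (XTC/DCD)
  would need readers not available to this package's dependency set.
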