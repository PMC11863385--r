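# sitedyn

Generate holo-like receptor ensembles from a single apo protein
structure — without knowing the ligand.

Proteins that bind their ligands between quasi-rigid domains (kinases,
transferases, adenylate-kinase-like enzymes) close over them through
hinge motions, so the apo crystal structure can be several Angstrom
away from any bound conformation and single-structure docking fails.
`sitedyn` implements the desk-side stages of a protocol that biases
molecular dynamics of the apo protein along *binding-site shape*
collective variables (CVs), then distills the trajectory into a
maximally diverse conformational ensemble for ensemble docking:

* **Site definition** — a 3.5 Å heavy-atom shell around a ligand in a
  reference complex, or a merged pocket-prediction consensus
  (predictions below a 0.01 confidence floor are discarded).
* **CV construction** — the site backbone radius of gyration RoG_BS;
  three contacts-across-inertia-plane CVs (CIP_1–3), one per principal
  inertia axis of the site, each counting switching-function contacts
  `s(r) = (1 - x^n)/(1 - x^m)`, `x = (r - d0)/r0` between the residue
  groups on either side of the plane; and one contacts CV per
  mobile-domain/core interface (cRD), selected by an 8 Å rule and
  split into charged/other variants when the site is more than 25%
  charged.
* **Metadynamics setup** — hill widths from the fluctuations of a
  ~200 ps unbiased run; a complete bias-exchange well-tempered
  metadynamics deck (height 0.6 kcal/mol, bias factor 10, deposition
  2.5 ps, exchange 50 ps) with a four-phase restraint schedule that
  contracts the pocket to 85% of its apo gyration radius.
* **Ensemble clustering** — 30 equal-width RoG_BS slices, proportional
  cluster allocation `x_i = (N_i/N_tot)·N_c` with inflation until every
  populated slice holds at least two clusters, hierarchical seeding,
  deterministic k-means refinement, and centroid-nearest
  representatives.
* **Evaluation** — binding-site RMSD after site superposition,
  per-residue holo-like flags, spline-smoothed RMSD distributions,
  ensemble summary tables, and the fraction of native contacts
  (5 Å shell) for docking poses.
* **Pose post-processing** — site-aligned pose clustering with the
  size-adaptive cutoff `d_c = 0.067 · N_nh` Å and ranking by best
  score.

Running MD/docking engines, force-field setup and free-energy
reconstruction are out of scope; the package emits the inputs and
analyzes the outputs.

## Worked example

Everything is testable without downloads through the built-in hinged
toy protein (three domains, a 32-residue site spanning both arm–core
interfaces, 11 charged residues):

```r
library(sitedyn)

toy <- make_hinged_toy_protein()
bundle <- build_protocol(toy$structure, toy$site, toy$domains)
print(bundle)
#> Protocol bundle: 8 CVs
#>  - cip_1: normal=(0.991,-0.017,-0.131) groups 16/16 residues
#>  - cip_2: normal=(0.017,1.000,-0.002) groups 18/14 residues
#>  - cip_3: normal=(0.131,-0.000,0.991) groups 16/16 residues
#>  - crd_nmp: 5 NMP + 4 CORE residues
#>  - crd_lid: 5 LID + 4 CORE residues
#>  - site charged fraction: 11/32 (34%)
#>  - crd_nmp: split into c/o (charged fraction 34% > 25%)
#>  - crd_lid: split into c/o (charged fraction 34% > 25%)
#>  - schedule phases 10+40+400+150 ns (total 600 ns)
```

The audit log is the setup's contract: the inertia-plane partitions,
the interface sizes, why each inter-domain CV was (or was not) split
by charge, and the restraint schedule. With widths estimated from an
unbiased series, `emit_metadynamics_input(bundle)` serializes this to
a PLUMED-dialect deck.

Cluster a (synthetic) open-to-closed trajectory and extract
representatives:

```r
traj <- make_open_close_trajectory(n_frames = 120, sigma = 0.1, seed = 7)
series <- evaluate_cv_series(traj, bundle$cvs)
res <- cluster_cv_series(series, n_slices = 10, base = 20)
reps <- extract_representatives(res, series, traj)
nrow(res$centroids)            # 31 clusters (>= the base 20)
range(reps$manifest$rog_bs)    # 11.34 .. 17.24 A: the full closure range
```

The representatives span the whole pocket-size range by construction
of the slice rule — that diversity is the point of the protocol. The
closed toy is far from the open one over the site
(`binding_site_rmsd()` gives 16.0 Å heavy-atom RMSD), mirroring the
apo/holo divergence that motivates ensemble generation. For docking
post-processing, `adaptive_cutoff(23)` returns `1.5` — the merging
radius in Å for a 23-heavy-atom ligand such as AMP.

A thin command-line front end over the same functions lives at
`inst/scripts/sitedyn.R` with subcommands `setup`, `cluster`,
`evaluate`, `cluster-poses` and `fixtures`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the size-adaptive pose-clustering cutoffs for the four
adenylate kinase ligands (AP5, AMP, ADP, GCP) from their heavy-atom
counts via `adaptive_cutoff()` and writes them as JSON.
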