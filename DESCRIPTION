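Package: sitedyn
Title: Binding-Site Shape Collective Variables, Metadynamics Setup, and
    Ensemble-Docking Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for generating maximally diverse, holo-like receptor
    ensembles from a single apo protein structure. Builds binding-site
    shape collective variables (pocket radius of gyration, contacts
    across inertia planes, inter-domain contacts with an automated
    charged-residue split), emits complete bias-exchange well-tempered
    metadynamics input decks with a pocket-contraction restraint
    schedule, clusters trajectories in collective-variable space with a
    two-stage (hierarchical seeding plus k-means refinement) scheme
    stratified over pocket-size slices, and post-processes ensemble
    docking runs (size-adaptive pose clustering, fraction of native
    contacts, binding-site RMSD summaries).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
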