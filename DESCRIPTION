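Package: contactdyn
Title: Time-Resolved Interresidue Contact Map Analysis of Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds time-resolved interresidue contact maps from molecular
    dynamics trajectories and derives statistics from them: clamped
    minimum-distance maps with sparse live-pair storage, hysteretic
    (dual-cutoff) contact states, aggregate and fluctuation maps,
    first/last-encounter (rupture-time) maps, Pearson correlation of
    contacts with time or external observables, contact-count
    cross-correlation between residues, inter-frame contact RMSD with
    hierarchical clustering and medoid extraction, and principal component
    analysis of contact maps. A single keyword-driven input file runs the
    whole pipeline, writing plain-text matrices and optional images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
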