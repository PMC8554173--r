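Package: rigiditygraph
Title: Rigidity Graphs of Protein Mechanical Couplings from Elastic
    Network Fluctuation Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns backbone/side-chain elastic network model (bsENM) spring
    constants from molecular-dynamics trajectories by self-consistent
    fluctuation matching, and analyses the resulting inter-residue rigidity
    graphs. Provides atomic-to-coarse-grained mapping of structures and
    trajectories, Hessian-based normal mode analysis of the learned network,
    signless Laplacian spectral statistics over trajectory windows
    (mean-modes, mode contents, prominent modes, mechanical hotspots),
    per-residue backbone and side-chain rigidity scores, and heavy-tailed
    (Lomax, power-law) fits to coupling-strength distributions. A synthetic
    reference-network generator supports end-to-end validation by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
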