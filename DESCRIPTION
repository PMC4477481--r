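Package: pepdyn
Title: Structural Stability Analysis of Peptide Conformational Ensembles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of replica molecular-ensemble data for intrinsically
    flexible protein domains, built around the signal-receiving domain of
    an ankyrin-repeat NF-kB inhibitor. Provides consensus secondary-structure
    annotation from multiple three-state predictors, Kabsch superposition with
    per-residue root-mean-square fluctuations, a Kabsch-Sander (DSSP-style)
    eight-state secondary-structure assignment with helix-formation
    probabilities and timelines, geometric hydrogen-bond and salt-bridge
    detection with replica-occupancy persistence filtering, Shrake-Rupley
    solvent-accessible surface areas with Gly-X-Gly relative accessibility and
    buried/exposed classification, a synthetic ensemble generator with
    controlled helix occupancy and interface-contact schedules, and a pipeline
    driver comparing bound and free states. Trajectories are exchanged as
    multi-model PDB files; all reports are plain TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    bio3d,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
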