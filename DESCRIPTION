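Package: bindsight
Title: Structural and Pharmacological Analysis of Transporter-Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis of inhibitor binding to neurotransmitter
    transporters from atomic coordinates, molecular-dynamics trajectories and
    dose-response assays. Provides rigid-body (Kabsch) superposition with RMSD,
    transmembrane helix displacement and reorientation metrics, binding-site
    distance measurements, metal/ion coordination-shell detection and geometry
    validation, trajectory interaction statistics (per-residue contact
    probabilities with a stable-contact rule, ring pi-stacking occupancy,
    hydrogen-bond occupancy, per-moiety RMSF, solvent radial distribution
    functions), and nonlinear fitting of Michaelis-Menten uptake, single-site
    binding and Hill inhibition models. A seeded synthetic-data module builds
    structures, trajectories and assay datasets with known ground truth so
    every analysis stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
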