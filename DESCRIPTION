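Package: xpftriage
Title: Virtual Screening Triage and Cisplatin-Enhancement Hit Calling for
    ERCC1-XPF Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Repro", "Pipelines", email = "repro@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a structure-based virtual screening
    triage workflow for inhibitors of the ERCC1-XPF DNA-repair endonuclease.
    Provides a native 2D cheminformatics core (SMILES graphs, physicochemical
    descriptors, Morgan fingerprints, Tanimoto similarity, Murcko scaffolds,
    substructure-based PAINS flagging), a docking-score triage cascade with
    scaffold clustering and t-SNE chemical-space maps, geometric protein-ligand
    interaction profiling on PDB structures (pocket definition, Kabsch
    superposition, buried surface area, typed contacts), and a cell-based
    decision cascade that promotes compounds to cisplatin enhancers from
    viability plates, including 4PL dose-response fitting and relative
    gene-expression ranking. Synthetic-data generators stand in for the
    commercial docking engine and the wet-lab plates so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
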