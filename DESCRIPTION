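Package: adafa
Title: Adaptive Firefly Optimization with Application to C-alpha Backbone
    Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Swarm-intelligence global optimization with the firefly
    algorithm and an adaptive variant (AdaFa) that tunes the light
    absorption coefficient from inter-firefly distances, modulates the
    randomization step through gray relational analysis, and selects among
    heterogeneous position-update rules with six decay schedules for the
    randomization parameter.  Ships the classic twelve-function benchmark
    suite, nonparametric comparison tests (Friedman, aligned Friedman,
    Quade), and a structural-bioinformatics application: rebuilding a
    protein C-alpha trace from virtual bond lengths, bond angles and
    dihedrals by per-atom constraint-energy minimization, scored by RMSD,
    TM-score and GDT.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
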