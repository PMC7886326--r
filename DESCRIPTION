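Package: fpatools
Title: Arrest-Peptide Force-Profile Analysis of Cotranslational Membrane-Protein Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for force-profile analysis (FPA) of cotranslational
    membrane-protein integration with translational arrest peptides: turning
    SDS-PAGE band intensities or 1-D lane traces into fraction-full-length
    (f_FL) values with replicate statistics, assembling f_FL-versus-N force
    profiles, calling peaks (N_start, N_max, N_end) and relating them to the
    ribosomal peptidyl-transferase center, computing hydropathy profiles, and
    comparing profiles across arrest-peptide variants and mutants. Includes a
    coarse-grained overdamped-Langevin simulator of nascent-chain integration
    through the SecYEG translocon (three-residue beads, implicit bilayer,
    switching lateral gate, membrane potential) that produces simulated force
    profiles, a relative-contact-order calculator for atomic structures, and
    generators of synthetic profiles, lane traces and topologies for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
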