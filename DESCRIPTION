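Package: ectodimer
Title: Chimeric ErbB Ectodomain Dimer Modeling and Interface Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds chimeric models of epidermal growth factor receptor (ErbB)
    family ectodomain dimers by anchored rigid-body superposition (subunit
    replacement, segmented placement of bent monomers, ligand grafting), and
    computes the geometric and interface observables used to characterise
    their dimerization: the domain-II bend angle defined by three C-alpha
    anchors, Shrake-Rupley solvent-accessible surface area, domain-restricted
    buried interface area, inter-subunit contact series (hydrogen bond, salt
    bridge, cation-pi), dimerization-arm drift, and sliding-window averages
    over trajectory frames. Includes cross-receptor residue equivalence maps
    from pairwise global sequence alignment, side-chain chi-angle
    manipulation with grid-search clash resolution, and a synthetic-structure
    generator (tunable bend angle, interface gap, pseudo-trajectories) so the
    full pipeline is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
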