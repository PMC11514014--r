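Package: coevodyn
Title: Linking Coevolving Residue Sectors to Correlated Protein Motions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical coupling analysis (SCA) of protein multiple sequence
    alignments, independent-component extraction of coevolving residue groups
    (sectors), dynamic cross-correlation (DCC) matrices from molecular dynamics
    trajectories, and the rank-based comparison of correlated motions across
    sector categories. Includes alignment preprocessing and sequence weighting,
    trajectory superposition and structural observables (hinge distances,
    side-chain dihedrals, contact masks), Pro-Pro motif co-occurrence counting,
    and synthetic-data generators with planted coevolution and planted
    correlated-motion blocks for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
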