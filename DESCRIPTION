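Package: sitemotif
Title: Active-Site Motif Templates and Distance-Constraint Matching for
    Enzyme Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Build orientation-independent motif templates for enzyme
    catalytic sites from protein structures, search query structures for
    residue constellations that satisfy the template's inter-atom distance
    constraints, and score hits by Levenshtein distance and superposition
    RMSD (all-atom, C-alpha, and C-alpha plus C-beta). Includes a
    synthetic-structure generator that plants idealized catalytic sites
    (for example a Ser-His-Asp triad) among decoy residues so the whole
    pipeline can be exercised without downloading structures, a brute-force
    search oracle for verification, batch search over motif libraries with
    CSV output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
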