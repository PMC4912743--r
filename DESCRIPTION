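Package: prefscan
Title: Biophysical Constraints on Site-Specific Amino Acid Preferences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and maps the biophysical and biochemical constraints that
    shape site-specific amino acid preferences measured in saturated
    mutational libraries (deep mutational scanning) or derived from protein
    sequence alignments. Each site's 20 amino acid preferences are regressed
    against a catalog of amino-acid descriptor scales (volume, hydrophobicity,
    secondary-structure propensities, metabolic cost, ...) with Bonferroni
    family-wise error control and F-test based selection of the best
    descriptor per site. Includes conversion of gapped alignments to
    statistical free-energy tables, an entropy-based tolerance-to-substitution
    metric, site classification and summary tables, structure-mapping outputs
    (PyMOL/VMD selections, B-factor annotated PDB), and synthetic-data
    generators with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
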