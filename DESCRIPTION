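Package: dichokey
Title: Dichotomous Identification Keys from Phenotypic Character Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with single-access (dichotomous) identification
    keys and the taxon-by-character state matrices that back them, built around
    the phenotypic taxonomy of the ascomycetous yeast genus Wickerhamomyces.
    Provides a character-state algebra for growth and assimilation test
    outcomes (positive, negative, weak, latent, slow, strain-variable,
    no-data, and alternations thereof), readers and writers for character
    matrices and structured key files, uncertainty-aware key traversal and
    specimen identification, key-versus-matrix consistency checking, greedy
    information-gain key construction, occurrence-table diversity summaries,
    and seeded synthetic-data generators for end-to-end testing. Ships the
    genus-wide character matrix (38 species by 22 characters), the printed
    species key (37 couplets), and the global distribution table (36 species)
    as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
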