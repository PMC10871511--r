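Package: eifrag
Title: Combinatorial Electron-Ionization Fragment Prediction for Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts electron-ionization (EI) mass-spectral fragments of
    unfunctionalized amino acids and short peptides by combinatorially
    applying literature-derived fragmentation mechanisms: Type A/B/C backbone
    cleavage, C-terminal carboxyl degradations, and residue-specific
    side-chain events (relative neutral or radical losses and non-relative
    charged side-chain ions). Produces exhaustive monoisotopic m/z
    fingerprints with mechanism-path bookkeeping, reads plain-text peak
    lists, matches observed peaks to predictions within an instrumental
    tolerance with contaminant masking, and computes threshold-based
    spectrum fitness scores. Includes a seeded synthetic-spectrum generator
    and a plain-text mechanism-definition dialect so the mechanism catalogue
    can be extended without code changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
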