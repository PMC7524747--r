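Package: quadpipe
Title: Protein Stability Trajectories from AHA Pulse-Chase Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for QUAD (Quantification of Azidohomoalanine
    Degradation) pulse-chase experiments. Reads peptide-level heavy/light
    isotope ratio tables, applies quality and parsimony (protein-group)
    filters, aggregates peptide ratios to protein medians per chase time
    point, builds natural-log protein stability trajectories (PSTs), fits
    per-protein degradation slopes, rate constants and half-lives by
    least squares, clusters trajectories with Ward linkage on Euclidean
    distances, enforces a biological-replicate concordance filter,
    classifies proteins as stable or unstable, and provides the
    comparative layers used in tissue degradation studies (heavy
    identification fractions, tissue and age contrasts, protein-complex
    co-stability, replicate and property correlations). Includes a
    synthetic pulse-chase data generator with known ground-truth
    degradation constants so every stage is testable without raw mass
    spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
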