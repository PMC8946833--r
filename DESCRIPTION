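Package: gammahq
Title: Quantification of Gamma-H2AX Immunofluorescence and Co-Stress
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for gamma-H2AX DNA-damage positivity in
    two-channel fluorescence micrographs of cultured keratinocytes under
    sequential osmotic and genotoxic (UV or hydrogen peroxide) stress.
    Segments nuclei from the DAPI channel, scores each cell by its
    brightest background-corrected gamma-H2AX pixel, derives a positivity
    threshold from each experiment's untreated control, and computes
    percent-positive cells, treated-versus-untreated fold changes,
    Grubbs outlier exclusion and paired t-tests across replicate
    experiments. Also includes relative quantification of TaqMan qPCR
    data by the 2^-ddCt method with reference-gene normalisation, and a
    synthetic-field generator with exact ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
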