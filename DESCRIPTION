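Package: slipscan
Title: Detection and Quantification of Transcriptional Slippage at
    Homopolymeric Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcriptional slippage (reiterative
    transcription) at poly-A tracts in bacterial coding sequences: scanning
    coding sequences for homopolymeric A/T runs adjacent to premature
    in-frame stop codons, predicting the protein length variants produced
    by net insertion or deletion of untemplated adenosines, predicting
    average masses of RT-PCR amplicon ladders for ESI/MS peak assignment,
    and estimating frameshift frequencies from western-blot band
    intensities and three-construct GFP reporter measurements. Includes a
    synthetic-data generator that designs slippery-site genes and simulates
    the stochastic slippage process with noisy readouts, so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    tibble,
    stats,
    utils,
    withr
Suggests:
    seqinr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
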