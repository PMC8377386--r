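Package: trimertax
Title: Taxonomic Classification of Short Reads from Codon-Trimer Usage Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composition-based taxonomic classification of short metagenomic
    DNA reads. Scores 3-codon DNA 9-mers that encode amino-acid trimers of
    protein secondary structures against genus-specific usage-bias databases,
    distinguishes coding from non-coding sequence over all six reading frames,
    and reports genus and taxon-group predictions together with a signed
    rank-sum P-value score computed from the exact dice-sum distribution.
    Includes a synthetic benchmark generator with genus-specific codon-usage
    profiles for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
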