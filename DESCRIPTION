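Package: pathomine
Title: Pathogen Mention Identification and Characterisation in Literature Citations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding and characterising mentions of pathogens
    (organisms, PrPSc prions and toxins) in MEDLINE/PubMed citation records.
    Builds a matching lexicon from an NCBI-style OBO taxonomy with subspecies
    expansion and a term normalization cascade; recognizes mentions by
    longest-match dictionary lookup, toxin regular expressions and prion/species
    co-occurrence; derives weakly supervised relevance labels from MeSH index
    terms with entity masking; trains a confidence-thresholded linear classifier
    (modified Huber loss, stochastic gradient descent) to filter mentions that
    are not experimentally studied; and evaluates per-pathogen precision, recall
    and F1 with micro and macro averaging. Includes a deterministic synthetic
    fixture generator and a mock record-service backend so the whole pipeline
    runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
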