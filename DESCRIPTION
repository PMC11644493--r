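Package: mirsel
Title: Selection Analysis of MicroRNA Target Sites in Rice Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dissects natural and artificial selection on plant microRNA
    binding sites from phased population alignments. Implements an empirical
    plant miRNA target complementarity filter, per-population nucleotide
    diversity and divergence statistics with sliding windows, outgroup
    polarization of the site frequency spectrum, a dinucleotide-preserving
    shuffle null for window diversity, a neutral coalescent simulator,
    Fay and Wu's H test with a fixed-S coalescent null, a maximum-likelihood
    multilocus HKA test, miRNA:target duplex energy scoring with
    length-normalization, and a synthetic-data generator emulating
    resequenced cultivated and wild rice panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
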