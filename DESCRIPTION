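Package: amirkit
Title: Design and Small RNA-Seq Evaluation of Minimal MIR390-Based
    Artificial MicroRNA Precursors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for engineering plant artificial microRNA (amiRNA)
    precursors on MIR390-derived backbones, from the full-length 521-nt
    pri-AtMIR390a down to an 89-nt shortened chimeric ('shc') precursor,
    including star-strand design, per-construct compensation of backbone
    nucleotides, annealed-oligonucleotide design for BsaI ('B/c') cloning
    vectors with an in-silico ligation check, and layout-based hairpin
    validation with a base-pair-maximization cross-check. Implements the
    companion small RNA-seq computations used to evaluate precursor
    processing: read collapsing, exact ungapped mapping with per-position
    counts and reads-per-million, processing-accuracy and strand-polarity
    statistics, and 21-register phasing tables, together with a seedable
    read simulator so every metric is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
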