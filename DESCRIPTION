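Package: gdtcr
Title: Paired Single-Cell Gamma-Delta TCR Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Tools for paired single-cell and bulk gamma-delta T-cell receptor
    (TCR) repertoire analysis in the developing human thymus. Reads AIRR
    Rearrangement tables, 10x contig annotations and germline segment FASTA;
    decomposes CDR3 junctions into germline-templated parts, palindromic (P)
    nucleotides and non-templated (N) additions; computes cross-repertoire
    clonotype publicity, Vg9Vd2 pairing, public-CDR3 tagging, public
    gamma/delta pairing preferences, and subject-level group contrasts
    (paired Wilcoxon, ANOVA with Tukey or Holm-Sidak post hoc, Spearman age
    trends). Includes a paired-repertoire simulator with age-dependent
    TdT-driven N additions and a full ground-truth ledger so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
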