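Package: intclone
Title: Transgene Integration-Site Calling and Clonality Verification from
    Split-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies vector-genome integration sites from SAM alignments of
    targeted sequence-capture reads mapped against a host genome with the
    linearized transfection vector appended as an extra scaffold. Split
    (chimeric) reads carrying SA tags are parsed, junction coordinates are
    derived from CIGAR arithmetic, candidate junctions are filtered on mapping
    quality, edit distance and unique read-pair support, and called sites are
    compared across multiplexed samples to group cell lines into clonal
    lineages. Includes capture enrichment statistics and a deterministic
    alignment-level simulator that plants integration junctions for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
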