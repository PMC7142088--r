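Package: punchcard
Title: Topological DNA Data Storage via Enzymatic Nicking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for storing digital data in the backbone topology of
    native double-stranded DNA. Registers (fixed genomic fragments, default
    450 bp) carry information as single-strand nicks placed at designed sites
    by a DNA-guided nicking enzyme. The package designs guide sequences and
    nick sites under composition and distance constraints, encodes byte
    payloads as binary or sense/antisense ternary nick patterns, simulates
    the physical channel (nicking, denaturation into single-stranded
    fragments, toehold release, paired-end sequencing), and decodes payloads
    exactly by reference alignment, insert-size gating and coverage-breakpoint
    analysis. Adder-channel (Lindstrom-type detecting matrices) and
    group-testing codecs support pooled recording on copies of the same
    register.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
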