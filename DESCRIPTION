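Package: tcrclonality
Title: T-Cell Receptor Clonality Assessment from Bulk RNA-Seq Clonotype Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment of T-cell receptor (TCR) clonality and repertoire
    structure from clonotype tables extracted from bulk RNA-seq. Implements
    three-step decontamination filtering of CDR3 clonotype tables (alignment
    based read filtering, genomic-match clone filtering, recurrent public-clone
    filtering), per-chain transcript quantification in reads per million (RPM)
    with expression-adequacy thresholds, binomial sampling-error machinery for
    clone-fraction thresholds, a rule-based monoclonality and biallelic
    classifier (dominant-fraction and top2-to-third ratio rules, V-gene usage
    fallback, CDR3 precedence), cohort-level statistics (top-10 clonotype
    profiles, V-usage tables, Fisher and Welch tests, EBV positivity), and a
    fully synthetic repertoire generator with V(D)J junction simulation for
    end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
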