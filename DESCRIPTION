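Package: txcombine
Title: Evidence-Based Combination of Gene Prediction Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Combines transcript predictions from multiple gene-annotation
    runs (e.g. RNA-seq-supported and protein-supported BRAKER outputs) into a
    single higher-specificity gene set. Every transcript is scored by how well
    extrinsic evidence hints (intron intervals, start/stop codon positions,
    each with a source label and multiplicity) support its structure; pairs of
    transcripts with overlapping in-frame coding regions are compared by an
    ordered threshold rule and the weaker transcript is marked for removal;
    survivors are clustered into genes by single linkage over coding overlap.
    Includes exact-match annotation accuracy metrics (sensitivity,
    specificity, F1) at CDS, transcript and gene level, a deterministic
    synthetic-fixture generator, and a brute-force reference selector for
    equivalence testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
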