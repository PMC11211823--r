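Package: motifsyntax
Title: Discover Cis-Acting mRNA Motifs and Their Combinatorial Syntax by
    Interpreting Sequence-to-Function Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains hybrid convolutional-recurrent neural networks that map
    mRNA sequence to scalar measures of translation efficiency (mean ribosome
    load) or stability (half-life), and interprets the trained networks to
    recover the cis-regulatory code they learned. Convolutional neurons are
    decoded into position probability matrices by maximal-activation seqlet
    extraction with cluster-based decoupling of multifaceted neurons; motifs
    are annotated against a user-supplied library with permutation-based
    similarity q-values; each motif's direction of effect is assessed by
    comparing labels between activating and non-activating sequences; and
    epistasis between co-occurring motif pairs is quantified by combinatorial
    in-silico mutagenesis with paired Wilcoxon signed-rank testing and
    classified as synergistic, antagonistic, additive, or sign epistasis.
    A synthetic-data module plants known motif effects and interactions in
    random-background sequences and scores end-to-end recovery, including the
    contrast between uniformly random and designed training sequences and the
    upstream-AUG shortcut in random 5'UTR libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
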