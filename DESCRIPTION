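Package: embalign
Title: Local and Global Protein Alignment from Language-Model Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects local and global similarity between protein sequences by
    directly comparing per-residue embeddings from a protein language model.
    A context-dependent substitution matrix is built from pairwise cosine
    similarities of normalized residue embeddings and fed to a gap-free
    variant of the Smith-Waterman recurrence; candidate alignment paths are
    traced back from every sequence boundary and scanned with a moving
    average against a sigma threshold to extract local alignments, or aligned
    end-to-end with a zero-gap Needleman-Wunsch for global mode. Includes an
    indexed binary embedding archive, a windowed-cosine database prefilter,
    per-residue precision/sensitivity metrics against reference alignments,
    a deterministic synthetic-embedding generator with planted homologous
    segments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    optparse,
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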