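Package: nmlseq
Title: Normalized Maximum Likelihood Compression Bounds for Symbol Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sequence-specific lossless-compression bounds for symbol
    sequences over finite alphabets. Parses a sequence under candidate
    dictionaries (fixed-length words with phase, codon translation into
    amino acids, LZ78 incremental phrases), computes exact and asymptotic
    normalized-maximum-likelihood (NML) code lengths, Bayesian-predictive
    (Dirichlet-mixture, Krichevsky-Trofimov) code lengths and BIC-style
    two-part code lengths, and uses compression rates against the raw bit
    length, together with permutation randomization, for randomness testing
    and minimum-description-length model selection such as reading-frame
    discovery in protein-coding DNA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
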