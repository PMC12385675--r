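# Synthetic sources used across tests.

# A protein-coding-like DNA sequence: amino acids drawn from a skewed
# usage, each encoded by a preferred codon, so the phase-0 codon parsing
# carries a strong compression signal (as in a real ORF).
makeCodingDNA <- function(nCodons = 969L, seed = 101L) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  stops <- names(gc)[gc == "*"]
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    # skewed codon usage: few codons dominate
    w <- rexp(length(sense))^2
    body <- sample(sense, nCodons - 2L, replace = TRUE, prob = w / sum(w))
    codons <- c("ATG", body, sample(stops, 1L))
    SymbolSequence(paste(codons, collapse = ""), alphabet = "DNA")
  })
}

# Brute-force Shtarkov sum by enumerating all m^n sequences: the
# independent oracle for the dynamic-programming normalizer.
shtarkovBruteForce <- function(n, m) {
  grid <- expand.grid(rep(list(seq_len(m)), n))
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    x <- as.integer(grid[i, ])
    nk <- tabulate(x, nbins = m)
    p <- nk[nk > 0] / n
    tot <- tot + prod(p^(nk[nk > 0]))
  }
  log2(tot)
}

# Random word counts: a composition of n into m positive parts.
randomCounts <- function(n, m) {
  stopifnot(n >= m)
  cuts <- sort(sample(seq_len(n - 1L), m - 1L))
  diff(c(0L, cuts, n))
}
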