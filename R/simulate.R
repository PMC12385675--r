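# Seeded synthetic sources: i.i.d. categorical strings and the
# pseudo-random-sequence benchmark table they feed.

#' Simulate an i.i.d. symbol string
#'
#' Draws S independent symbols from the given alphabet with probabilities
#' `p` using R's seeded generator. With the default fair probabilities and
#' the binary alphabet this is the Bernoulli(0.5) pseudo-random source used
#' throughout the randomness benchmarks.
#'
#' @param alphabet preset name (`"DNA"`, `"binary"`) or character vector of
#'   symbols.
#' @param p probability vector over the alphabet (default uniform); must be
#'   non-negative and sum to 1.
#' @param S string length.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return a [SymbolSequence-class]; deterministic given the seed.
#' @examples
#' iidString("binary", S = 10, seed = 42)
#' @export
iidString <- function(alphabet, p = NULL, S, seed = NULL) {
  if (length(alphabet) == 1L && alphabet %in% names(ALPHABETS))
    alphabet <- ALPHABETS[[alphabet]]
  if (is.null(p)) p <- rep(1 / length(alphabet), length(alphabet))
  if (length(p) != length(alphabet) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("'p' must be a probability vector over the alphabet")
  if (S < 0) stop("S must be >= 0")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  draws <- if (S > 0) sample(alphabet, S, replace = TRUE, prob = p)
           else character(0)
  SymbolSequence(paste(draws, collapse = ""), alphabet = alphabet)
}

#' Compression-rate benchmark of a pseudo-random binary string
#'
#' Simulates one Bernoulli(0.5) binary string of length S, parses it at
#' phase 0 into words of each requested length, and reports the three
#' bounds as rates against the raw bit length of the encoded symbols: the
#' plug-in entropy bound \eqn{nH(\hat\theta)}, the two-part/BIC bound
#' \eqn{nH(\hat\theta) + (d/2)\log_2 n}, and the NML bound. On a truly
#' random string the entropy bound drifts below 1 as the dictionary grows
#' (it underestimates), the BIC bound overshoots, and the NML bound stays
#' just above 1 until the dictionary size approaches the word number and
#' the asymptotic expansion degrades.
#'
#' @param seed integer seed for the simulated string.
#' @param S string length (default 3000).
#' @param wordLengths word lengths to scan (default 1:9).
#' @return a data.frame with columns `word_length, n, m, rate_entropy,
#'   rate_bic, rate_nml`.
#' @export
replicateTable1 <- function(seed = NULL, S = 3000L, wordLengths = 1:9) {
  seq <- iidString("binary", S = S, seed = seed)
  rows <- lapply(wordLengths, function(k) {
    ws <- parseFixedLength(seq, k = k, phase = 0L)
    wc <- countWords(ws)
    raw <- rawBits(ws@encodedSymbols, 2L)
    H <- empiricalEntropy(wc)
    d <- wc@m - 1
    data.frame(word_length = k, n = wc@n, m = wc@m,
               rate_entropy = compressionRate(wc@n * H, raw),
               rate_bic = compressionRate(wc@n * H + d / 2 * log2(wc@n), raw),
               rate_nml = compressionRate(totalBits(nmlCodelengthMultinomial(wc)),
                                          raw))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic sequence as a FASTA fixture
#'
#' @param seq a [SymbolSequence-class].
#' @param path output file.
#' @param id record identifier (default `"synthetic"`).
#' @param width line width.
#' @return `path`, invisibly.
#' @export
writeSyntheticFasta <- function(seq, path, id = "synthetic", width = 70L) {
  stopifnot(is(seq, "SymbolSequence"))
  s <- seq@symbols
  n <- nchar(s)
  starts <- seq.int(1L, max(1L, n), by = width)
  lines <- c(paste0(">", id),
             if (n > 0) substring(s, starts, pmin(starts + width - 1L, n))
             else character(0))
  writeLines(lines, path)
  invisible(path)
}
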