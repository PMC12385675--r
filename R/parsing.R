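#' Fixed-length parsing of a symbol sequence
#'
#' Cuts the sequence into consecutive non-overlapping words of `k` symbols
#' starting at offset `phase` (0-based). The leading `phase` symbols and any
#' trailing fragment shorter than `k` are dropped, so the number of words is
#' `floor((S - phase) / k)`. Different phases of the same word length are
#' distinct parsing models (e.g. the three reading frames of a codon model).
#'
#' @param seq a [SymbolSequence-class].
#' @param k word length (positive integer).
#' @param phase offset in `[0, k-1]` at which the first word starts.
#' @return a [WordSequence-class].
#' @examples
#' parseFixedLength(SymbolSequence("ACGTACG", "DNA"), k = 3, phase = 1)
#' @export
parseFixedLength <- function(seq, k, phase = 0L) {
  stopifnot(is(seq, "SymbolSequence"))
  k <- as.integer(k); phase <- as.integer(phase)
  if (k < 1L) stop("word length k must be >= 1")
  if (phase < 0L || phase >= k) stop("phase must lie in [0, k-1]")
  S <- nchar(seq@symbols)
  nw <- max(0L, (S - phase) %/% k)
  if (nw == 0L)
    return(new("WordSequence", words = character(0), encodedSymbols = 0L))
  starts <- phase + 1L + k * (seq_len(nw) - 1L)
  words <- substring(seq@symbols, starts, starts + k - 1L)
  new("WordSequence", words = words, encodedSymbols = k * nw)
}

#' Translate DNA triplets into an amino-acid word sequence
#'
#' Splits the sequence into codons from offset `phase` and maps each complete
#' codon to its one-letter amino-acid code under the standard genetic code.
#' Stop codons map to the word `"*"` and are kept as ordinary dictionary
#' words. Each amino-acid word covers 3 nucleotides, so `encodedSymbols` is
#' 3 times the number of codons.
#'
#' @param seq a [SymbolSequence-class] over the DNA alphabet A/C/G/T.
#' @param phase reading-frame offset, 0, 1 or 2.
#' @return a [WordSequence-class] of amino-acid words.
#' @examples
#' words(translateCodons(SymbolSequence("ATGAAATAA", "DNA")))  # M K *
#' @export
translateCodons <- function(seq, phase = 0L) {
  stopifnot(is(seq, "SymbolSequence"))
  if (!setequal(seq@alphabet, ALPHABETS$DNA))
    stop("codon translation requires the DNA alphabet A,C,G,T")
  codons <- parseFixedLength(seq, k = 3L, phase = phase)
  if (length(codons@words) == 0L)
    return(new("WordSequence", words = character(0), encodedSymbols = 0L))
  aa <- unname(Biostrings::GENETIC_CODE[codons@words])
  new("WordSequence", words = aa, encodedSymbols = codons@encodedSymbols)
}

#' LZ78 incremental phrase parsing
#'
#' Standard LZ78 parsing: each phrase is the shortest prefix of the remaining
#' input that is not yet in the phrase dictionary, i.e. the longest
#' previously seen phrase extended by one symbol. A final incomplete phrase
#' at the end of the input (which duplicates an earlier phrase) is counted
#' as one phrase. Each phrase can be coded by the address of its prefix
#' phrase plus one symbol, which is what [lz78Codelength()] charges for.
#'
#' @param seq a [SymbolSequence-class].
#' @return character vector of phrases in parsing order.
#' @examples
#' lz78Phrases(SymbolSequence("1011010100010", "binary"))
#' @export
lz78Phrases <- function(seq) {
  stopifnot(is(seq, "SymbolSequence"))
  chars <- strsplit(seq@symbols, "", fixed = TRUE)[[1L]]
  dict <- new.env(parent = emptyenv(), size = 1024L)
  phrases <- character(0)
  cur <- ""
  for (ch in chars) {
    cand <- paste0(cur, ch)
    if (exists(cand, envir = dict, inherits = FALSE)) {
      cur <- cand
    } else {
      assign(cand, TRUE, envir = dict)
      phrases <- c(phrases, cand)
      cur <- ""
    }
  }
  if (nzchar(cur)) phrases <- c(phrases, cur)
  phrases
}

#' Count word frequencies
#'
#' Tabulates the words of a [WordSequence-class] into a [WordCounts-class]:
#' counts over observed words only (the dictionary is the set of distinct
#' observed words, not all \eqn{\alpha^k} possibilities), total word number
#' `n`, dictionary size `m`, model dimension `d = m - 1`. Words are stored
#' in lexicographic (byte) order for deterministic reporting.
#'
#' @param ws a [WordSequence-class], or a character vector of words.
#' @return a [WordCounts-class]. An empty word sequence yields n = m = 0
#'   with a warning; code-length operations reject such counts.
#' @examples
#' countWords(c("ACG", "TAC", "ACG"))
#' @export
countWords <- function(ws) {
  w <- if (is(ws, "WordSequence")) ws@words else as.character(ws)
  if (length(w) == 0L) {
    warning("empty word sequence: n = 0, m = 0")
    return(new("WordCounts", counts = integer(0), n = 0L, m = 0L))
  }
  tab <- table(w)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  ord <- order(names(counts), method = "radix")
  counts <- counts[ord]
  new("WordCounts", counts = counts, n = length(w), m = length(counts))
}

# Direct construction from a count vector (e.g. simulated or published
# counts); names are optional and generated when absent.
#' Build WordCounts from a vector of counts
#'
#' @param counts positive integer vector of word counts, optionally named.
#' @return a [WordCounts-class].
#' @export
wordCountsFromVector <- function(counts) {
  counts <- setNames(as.integer(counts), names(counts))
  if (is.null(names(counts)))
    names(counts) <- sprintf("w%03d", seq_along(counts))
  counts <- counts[order(names(counts), method = "radix")]
  new("WordCounts", counts = counts, n = sum(counts), m = length(counts))
}

# Parse a sequence under a ParsingModel; used by the scanning layer.
parseModel <- function(seq, model) {
  switch(model@kind,
    fixed     = parseFixedLength(seq, model@wordLength, model@phase),
    translate = translateCodons(seq, model@phase),
    lz78      = {
      ph <- lz78Phrases(seq)
      new("WordSequence", words = ph, encodedSymbols = nchar(seq@symbols))
    })
}
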