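# Accessors and show methods for the core classes.

#' @describeIn SymbolSequence-class the raw string.
#' @param x,object a SymbolSequence.
#' @export
setGeneric("symbols", function(x) standardGeneric("symbols"))

#' @rdname SymbolSequence-class
#' @export
setMethod("symbols", "SymbolSequence", function(x) x@symbols)

#' @describeIn SymbolSequence-class the declared alphabet.
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname SymbolSequence-class
#' @export
setMethod("alphabet", "SymbolSequence", function(x) x@alphabet)

#' @describeIn SymbolSequence-class alphabet size \eqn{\alpha}.
#' @export
setGeneric("alphabetSize", function(x) standardGeneric("alphabetSize"))

#' @rdname SymbolSequence-class
#' @export
setMethod("alphabetSize", "SymbolSequence", function(x) length(x@alphabet))

#' @rdname SymbolSequence-class
#' @export
setMethod("length", "SymbolSequence", function(x) nchar(x@symbols))

setMethod("show", "SymbolSequence", function(object) {
  s <- object@symbols
  preview <- if (nchar(s) > 60L) paste0(substr(s, 1L, 57L), "...") else s
  cat(sprintf("SymbolSequence of %d symbols over {%s}\n  %s\n",
              nchar(s), paste(object@alphabet, collapse = ","), preview))
})

setMethod("show", "ParsingModel", function(object) {
  cat(sprintf("ParsingModel '%s': kind=%s, k=%d, phase=%d\n",
              object@label, object@kind, object@wordLength, object@phase))
})

#' @describeIn WordSequence-class the words, in order.
#' @param x,object a WordSequence.
#' @export
setGeneric("words", function(x) standardGeneric("words"))

#' @rdname WordSequence-class
#' @export
setMethod("words", "WordSequence", function(x) x@words)

#' @describeIn WordSequence-class raw symbols covered by the words.
#' @export
setGeneric("encodedSymbols", function(x) standardGeneric("encodedSymbols"))

#' @rdname WordSequence-class
#' @export
setMethod("encodedSymbols", "WordSequence", function(x) x@encodedSymbols)

#' @rdname WordSequence-class
#' @export
setMethod("length", "WordSequence", function(x) length(x@words))

setMethod("show", "WordSequence", function(object) {
  w <- object@words
  preview <- paste(utils::head(w, 8L), collapse = " ")
  if (length(w) > 8L) preview <- paste(preview, "...")
  cat(sprintf("WordSequence of %d words covering %d symbols\n  %s\n",
              length(w), object@encodedSymbols, preview))
})

#' @describeIn WordCounts-class named count vector (lexicographic order).
#' @param x,object a WordCounts.
#' @export
setGeneric("wordCounts", function(x) standardGeneric("wordCounts"))

#' @rdname WordCounts-class
#' @export
setMethod("wordCounts", "WordCounts", function(x) x@counts)

#' @describeIn WordCounts-class total word number n.
#' @export
setGeneric("nWords", function(x) standardGeneric("nWords"))

#' @rdname WordCounts-class
#' @export
setMethod("nWords", "WordCounts", function(x) x@n)

#' @describeIn WordCounts-class dictionary size m (distinct observed words).
#' @export
setGeneric("dictionarySize", function(x) standardGeneric("dictionarySize"))

#' @rdname WordCounts-class
#' @export
setMethod("dictionarySize", "WordCounts", function(x) x@m)

#' @describeIn WordCounts-class model dimension d = m - 1.
#' @export
setGeneric("modelDimension", function(x) standardGeneric("modelDimension"))

#' @rdname WordCounts-class
#' @export
setMethod("modelDimension", "WordCounts", function(x) x@m - 1L)

setMethod("show", "WordCounts", function(object) {
  cat(sprintf("WordCounts: n=%d words, m=%d distinct (d=%d)\n",
              object@n, object@m, object@m - 1L))
  if (object@m > 0L) print(utils::head(object@counts, 10L))
})

#' @describeIn CodeLengthBreakdown-class entropy term \eqn{nH(\hat\theta)} in bits.
#' @param x,object a CodeLengthBreakdown.
#' @export
setGeneric("entropyBits", function(x) standardGeneric("entropyBits"))

#' @rdname CodeLengthBreakdown-class
#' @export
setMethod("entropyBits", "CodeLengthBreakdown", function(x) x@entropyBits)

#' @describeIn CodeLengthBreakdown-class parametric-complexity terms in bits.
#' @export
setGeneric("complexityBits", function(x) standardGeneric("complexityBits"))

#' @rdname CodeLengthBreakdown-class
#' @export
setMethod("complexityBits", "CodeLengthBreakdown", function(x) x@complexityBits)

#' @describeIn CodeLengthBreakdown-class total code length in bits.
#' @export
setGeneric("totalBits", function(x) standardGeneric("totalBits"))

#' @rdname CodeLengthBreakdown-class
#' @export
setMethod("totalBits", "CodeLengthBreakdown", function(x) x@totalBits)

setMethod("show", "CodeLengthBreakdown", function(object) {
  cat(sprintf("CodeLengthBreakdown [%s]: %.4f bits = %.4f (entropy) + %.4f (complexity)\n",
              object@method, object@totalBits, object@entropyBits,
              object@complexityBits))
})

#' @describeIn DirichletPrior-class the concentration vector.
#' @param x,object a DirichletPrior.
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname DirichletPrior-class
#' @export
setMethod("concentrations", "DirichletPrior", function(x) x@concentrations)

setMethod("show", "DirichletPrior", function(object) {
  a <- object@concentrations
  cat(sprintf("DirichletPrior over %d categories, total concentration %.3f\n",
              length(a), sum(a)))
})

setMethod("show", "PermutationSummary", function(object) {
  cat(sprintf("PermutationSummary: %d permutations (seed %s)\n",
              object@replicates,
              if (is.na(object@seed)) "unset" else format(object@seed)))
  print(object@summary, digits = 4)
})
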