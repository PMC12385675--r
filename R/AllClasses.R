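#' @import methods
NULL

ALPHABETS <- list(
  DNA    = c("A", "C", "G", "T"),
  binary = c("0", "1")
)

#' SymbolSequence: a validated string over a declared finite alphabet
#'
#' The elementary input of the package: an ordered string of symbols together
#' with the finite alphabet it is written in. The alphabet size \eqn{\alpha}
#' sets the raw bit length \eqn{S \log_2 \alpha} against which all compressed
#' code lengths are compared.
#'
#' @slot symbols single character string holding the sequence.
#' @slot alphabet character vector of allowed single-character symbols
#'   (size at least 2).
#'
#' @seealso [SymbolSequence()] for the user constructor.
#' @export
setClass("SymbolSequence",
  slots = c(symbols = "character", alphabet = "character"))

setValidity("SymbolSequence", function(object) {
  if (length(object@symbols) != 1L || is.na(object@symbols))
    return("'symbols' must be a single non-NA string")
  ab <- object@alphabet
  if (length(ab) < 2L)
    return("alphabet must contain at least 2 symbols")
  if (any(nchar(ab) != 1L) || anyDuplicated(ab))
    return("alphabet symbols must be distinct single characters")
  chars <- strsplit(object@symbols, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% ab))
  if (length(bad))
    return(sprintf("symbol '%s' at position %d is not in the declared alphabet",
                   chars[bad[1L]], bad[1L]))
  TRUE
})

#' Construct a SymbolSequence
#'
#' @param symbols a single string (or character vector of single symbols,
#'   which is pasted together).
#' @param alphabet either a preset name (`"DNA"` for A/C/G/T, `"binary"` for
#'   0/1), a character vector of single-character symbols, or `NULL` to use
#'   the sorted distinct symbols observed in `symbols`.
#'
#' Letters are normalised to upper case before validation, so lower-case
#' FASTA sequence is accepted. Symbols outside the declared alphabet (for
#' DNA this includes ambiguity codes such as N) are a hard error reporting
#' the first offending position.
#'
#' @return a [SymbolSequence-class] object.
#' @examples
#' SymbolSequence("ACGTACG", "DNA")
#' SymbolSequence("010011", "binary")
#' @export
SymbolSequence <- function(symbols, alphabet = NULL) {
  if (length(symbols) > 1L) symbols <- paste(symbols, collapse = "")
  symbols <- toupper(symbols)
  if (is.null(alphabet)) {
    alphabet <- sort(unique(strsplit(symbols, "", fixed = TRUE)[[1L]]),
                     method = "radix")
  } else if (length(alphabet) == 1L && alphabet %in% names(ALPHABETS)) {
    alphabet <- ALPHABETS[[alphabet]]
  } else {
    alphabet <- toupper(alphabet)
  }
  new("SymbolSequence", symbols = symbols, alphabet = alphabet)
}

#' ParsingModel: how a sequence is cut into words
#'
#' A parsing model turns a [SymbolSequence-class] into a word sequence. Three
#' kinds are supported: `fixed` (consecutive non-overlapping words of `k`
#' symbols starting at offset `phase`), `translate` (DNA triplets mapped to
#' amino acids, `k` forced to 3), and `lz78` (incremental variable-length
#' phrase parsing). Labels follow the `"k.phase"` convention, e.g. `"2.0"`,
#' `"3.1"`; `"a.a."` denotes translation.
#'
#' @slot kind one of `"fixed"`, `"translate"`, `"lz78"`.
#' @slot wordLength word length `k` (fixed/translate; 3 for translate).
#' @slot phase integer offset in `[0, k-1]` at which parsing starts.
#' @slot label display label used in reports.
#' @export
setClass("ParsingModel",
  slots = c(kind = "character", wordLength = "integer",
            phase = "integer", label = "character"))

setValidity("ParsingModel", function(object) {
  if (!object@kind %in% c("fixed", "translate", "lz78"))
    return("kind must be one of 'fixed', 'translate', 'lz78'")
  if (object@kind != "lz78") {
    if (object@wordLength < 1L) return("word length must be >= 1")
    if (object@phase < 0L || object@phase >= object@wordLength)
      return("phase must lie in [0, word length - 1]")
    if (object@kind == "translate" && object@wordLength != 3L)
      return("translation requires word length 3")
  }
  TRUE
})

#' Construct a ParsingModel from a label or explicit fields
#'
#' @param label a model label: `"k"` or `"k.phase"` for fixed-length parsing
#'   (`"1"`, `"2.0"`, `"3.1"`, ...), `"aa"`/`"a.a."` for codon translation,
#'   `"lz78"` for Lempel–Ziv phrase parsing. Ignored when `kind` is given.
#' @param kind,k,phase explicit specification, overriding `label`.
#' @return a [ParsingModel-class] object.
#' @examples
#' parsingModel("3.1")
#' parsingModel("aa")
#' parsingModel(kind = "fixed", k = 4, phase = 2)
#' @export
parsingModel <- function(label = NULL, kind = NULL, k = NULL, phase = NULL) {
  if (is.null(kind)) {
    stopifnot(is.character(label), length(label) == 1L)
    lab <- tolower(gsub("[[:space:]]", "", label))
    if (lab %in% c("aa", "a.a.", "a.a"))
      return(new("ParsingModel", kind = "translate", wordLength = 3L,
                 phase = 0L, label = "a.a."))
    if (lab == "lz78")
      return(new("ParsingModel", kind = "lz78", wordLength = 1L,
                 phase = 0L, label = "lz78"))
    parts <- strsplit(lab, ".", fixed = TRUE)[[1L]]
    k <- suppressWarnings(as.integer(parts[1L]))
    phase <- if (length(parts) >= 2L)
      suppressWarnings(as.integer(parts[2L])) else 0L
    if (is.na(k) || is.na(phase))
      stop("cannot parse model label '", label, "'")
    kind <- "fixed"
  } else {
    if (is.null(k)) k <- if (kind == "translate") 3L else 1L
    if (is.null(phase)) phase <- 0L
  }
  if (is.null(label))
    label <- if (k == 1L && phase == 0L) "1" else sprintf("%d.%d", k, phase)
  new("ParsingModel", kind = kind, wordLength = as.integer(k),
      phase = as.integer(phase), label = label)
}

#' WordSequence: the ordered words produced by a parsing
#'
#' @slot words character vector of words in sequence order.
#' @slot encodedSymbols number of raw symbols covered by the words (for
#'   fixed-length parsing, word length times the number of words; for
#'   translation, 3 nucleotides per amino-acid word). Incomplete leading or
#'   trailing fragments are dropped, so `encodedSymbols` can be smaller than
#'   the sequence length.
#' @export
setClass("WordSequence",
  slots = c(words = "character", encodedSymbols = "integer"))

setValidity("WordSequence", function(object) {
  if (object@encodedSymbols < 0L) return("encodedSymbols must be >= 0")
  TRUE
})

#' WordCounts: word frequencies under a dictionary of observed words
#'
#' Holds the sufficient statistics of the multinomial fit: counts of each
#' distinct observed word, the total word number `n`, and the dictionary
#' size `m` (distinct observed words). The model dimension is `d = m - 1`,
#' the number of free parameters on the probability simplex.
#'
#' @slot counts named integer vector (names are words, lexicographic order);
#'   only observed words are stored, so all counts are positive.
#' @slot n total number of words.
#' @slot m number of distinct words.
#' @export
setClass("WordCounts",
  slots = c(counts = "integer", n = "integer", m = "integer"))

setValidity("WordCounts", function(object) {
  if (object@n != sum(object@counts)) return("counts must sum to n")
  if (object@m != length(object@counts)) return("m must equal length(counts)")
  if (object@n > 0L && any(object@counts < 1L))
    return("only observed words are stored: all counts must be >= 1")
  if (object@m > 0L && is.null(names(object@counts)))
    return("counts must be named by word")
  TRUE
})

#' CodeLengthBreakdown: a code length split into entropy and complexity
#'
#' Total description length in bits, decomposed as
#' \eqn{n H(\hat\theta)} (the plug-in empirical-entropy term) plus the
#' parametric-complexity terms (everything else). Base-2 logarithms
#' throughout, so all quantities are in bits.
#'
#' @slot entropyBits \eqn{n H(\hat\theta)} in bits.
#' @slot complexityBits remaining terms in bits.
#' @slot totalBits their sum.
#' @slot method one of `"nml_asym"`, `"nml_exact"`, `"mixture"`, `"bic"`,
#'   `"entropy_only"`, `"lz78"`.
#' @export
setClass("CodeLengthBreakdown",
  slots = c(entropyBits = "numeric", complexityBits = "numeric",
            totalBits = "numeric", method = "character"))

setValidity("CodeLengthBreakdown", function(object) {
  if (abs(object@totalBits - (object@entropyBits + object@complexityBits)) > 1e-9)
    return("totalBits must equal entropyBits + complexityBits")
  if (object@entropyBits < 0) return("entropyBits must be >= 0")
  if (!object@method %in% c("nml_asym", "nml_exact", "mixture", "bic",
                            "entropy_only", "lz78"))
    return("unknown method")
  TRUE
})

codeLengthBreakdown <- function(entropyBits, complexityBits, method) {
  new("CodeLengthBreakdown", entropyBits = entropyBits,
      complexityBits = complexityBits,
      totalBits = entropyBits + complexityBits, method = method)
}

#' DirichletPrior: concentrations of a Dirichlet prior on word frequencies
#'
#' The conjugate prior of the multinomial. Concentrations all equal to 1/2
#' give the Jeffreys prior (the Krichevsky–Trofimov assignment).
#'
#' @slot concentrations positive numeric vector, optionally named by word
#'   (names are required for sequential predictive coding so that each word
#'   can be matched to its concentration).
#' @seealso [jeffreysPrior()]
#' @export
setClass("DirichletPrior", slots = c(concentrations = "numeric"))

setValidity("DirichletPrior", function(object) {
  if (length(object@concentrations) < 1L) return("empty prior")
  if (any(!is.finite(object@concentrations)) || any(object@concentrations <= 0))
    return("all concentrations must be positive and finite")
  TRUE
})

#' @param concentrations positive numeric vector, optionally named by word.
#' @rdname DirichletPrior-class
#' @export
dirichletPrior <- function(concentrations) {
  new("DirichletPrior", concentrations = concentrations)
}

#' Jeffreys (Krichevsky–Trofimov) prior for an m-word dictionary
#'
#' Dirichlet(1/2, ..., 1/2) over `m` categories.
#'
#' @param m number of categories, or a [WordCounts-class] object whose
#'   dictionary defines (and names) the categories.
#' @return a [DirichletPrior-class].
#' @export
jeffreysPrior <- function(m) {
  if (is(m, "WordCounts")) {
    conc <- rep(0.5, m@m)
    names(conc) <- names(m@counts)
  } else {
    conc <- rep(0.5, m)
  }
  dirichletPrior(conc)
}

setClassUnion("functionOrNULL", c("function", "NULL"))

#' ExponentialFamilySpec: ingredients of the code-length expansion
#'
#' Everything the asymptotic NML / Bayesian-predictive expansions need about
#' a d-dimensional exponential family: the entropy at the maximum-likelihood
#' estimate, the (log of the) integrated root Fisher determinant over the
#' parameter space, the root Fisher determinant at a point, and optionally a
#' prior density. All logarithms base 2.
#'
#' @slot dimension model dimension d (at least 1).
#' @slot entropyAtMLE function mapping a [WordCounts-class] (or a counts
#'   vector) to \eqn{H(\hat\theta)} in bits per word.
#' @slot log2FisherSqrtIntegral \eqn{\log_2 \int_\Theta |I(\theta)|^{1/2} d\theta};
#'   must be finite (restrict the parameter space to a compact subset when
#'   the integral diverges).
#' @slot log2FisherSqrtAt function mapping the MLE \eqn{\hat\theta} to
#'   \eqn{\log_2 |I(\hat\theta)|^{1/2}}.
#' @slot log2PriorAt optional function mapping \eqn{\hat\theta} to
#'   \eqn{\log_2 w(\hat\theta)}.
#' @seealso [multinomialSpec()], [gaussianMeanIntervalSpec()]
#' @export
setClass("ExponentialFamilySpec",
  slots = c(dimension = "numeric", entropyAtMLE = "function",
            log2FisherSqrtIntegral = "numeric",
            log2FisherSqrtAt = "function",
            log2PriorAt = "functionOrNULL"))

setValidity("ExponentialFamilySpec", function(object) {
  if (object@dimension < 1) return("dimension must be >= 1")
  if (!is.finite(object@log2FisherSqrtIntegral))
    return("the integrated root Fisher determinant must be finite; restrict the parameter space")
  TRUE
})

#' PermutationSummary: permutation-reference statistics of compression rates
#'
#' @slot summary data.frame with one row per (model, method): mean rate, SD,
#'   empirical 1% and 99% quantiles over permuted sequences.
#' @slot replicates number of permutations.
#' @slot seed the RNG seed used (NA if none was set).
#' @export
setClass("PermutationSummary",
  slots = c(summary = "data.frame", replicates = "integer", seed = "numeric"))

setValidity("PermutationSummary", function(object) {
  s <- object@summary
  if (nrow(s) &&
      (any(s$q01 > s$mean + 1e-12) || any(s$mean > s$q99 + 1e-12)))
    return("quantile ordering violated: need q01 <= mean <= q99")
  TRUE
})
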