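# Compression rates, model scanning, permutation randomization, verdict.

#' Raw (uncompressed) bit length
#'
#' The theoretical bit length of the encoded stretch of the raw sequence:
#' symbols actually covered by the parsing times \eqn{\log_2 \alpha}.
#' Phased models drop one to three symbols, and the denominator follows the
#' symbols the model actually encodes.
#'
#' @param encodedSymbols number of raw symbols covered by the words.
#' @param alpha alphabet size of the raw sequence.
#' @return bits.
#' @examples
#' rawBits(2907, 4)  # 5814
#' @export
rawBits <- function(encodedSymbols, alpha) {
  stopifnot(alpha >= 2)
  encodedSymbols * log2(alpha)
}

#' Compression rate
#'
#' Total code length divided by the raw bit length. Rates at or above 1
#' under every dictionary tried mark the sequence as incompressible, i.e.
#' consistent with randomness; a rate clearly below 1 exposes structure.
#'
#' @param totalBits code length in bits.
#' @param raw raw bit length (positive).
#' @return the plain quotient (tables display it to 4 decimals).
#' @export
compressionRate <- function(totalBits, raw) {
  if (raw <= 0) stop("raw bit length must be positive")
  totalBits / raw
}

defaultMethods <- c("nml", "bic", "entropy", "mixture")

breakdownFor <- function(wc, method, prior = NULL) {
  switch(method,
    nml     = nmlCodelengthMultinomial(wc),
    bic     = bicCodelength(wc),
    entropy = codeLengthBreakdown(wc@n * empiricalEntropy(wc), 0, "entropy_only"),
    mixture = if (is.null(prior)) mixtureCodelengthDirichlet(wc)
              else mixtureCodelengthDirichlet(wc, prior),
    stop("unknown code-length method '", method, "'"))
}

#' Scan a sequence under a list of parsing models
#'
#' Runs parse, count and code length for each model, and reports per
#' model the word number n, dictionary size m, entropy per word, the
#' entropy and complexity terms, total bits, raw bits and the compression
#' rate. The minimum-rate model is flagged: by the MDL principle it is the
#' selected description of the sequence (for coding DNA, the in-frame
#' codon model).
#'
#' @param seq a [SymbolSequence-class].
#' @param models list of [ParsingModel-class] objects or character labels
#'   (see [parsingModel()]); defaults to the standard DNA scan of word
#'   lengths 1-4 over all phases plus amino-acid translation.
#' @param method code-length method: `"nml"` (default), `"bic"`,
#'   `"entropy"`, or `"mixture"`. Models of kind `lz78` always use the
#'   LZ78 code length.
#' @param prior optional [DirichletPrior-class] for `method = "mixture"`
#'   (default Jeffreys over each model's observed dictionary).
#' @return a data.frame with one row per applicable model, sorted by label,
#'   columns `model, n, m, entropy, entropy_bits, complexity_bits,
#'   total_bits, raw_bits, rate, is_min`. Models inapplicable to the
#'   sequence's alphabet are skipped with a warning.
#' @examples
#' seq <- iidString("DNA", S = 600, seed = 1)
#' modelScan(seq, models = c("1", "2.0", "3.0"))
#' @export
modelScan <- function(seq, models = dnaScanModels(), method = "nml",
                      prior = NULL) {
  stopifnot(is(seq, "SymbolSequence"))
  method <- match.arg(method, defaultMethods)
  if (length(models) == 0L) stop("need at least one parsing model")
  models <- lapply(models, function(mdl)
    if (is(mdl, "ParsingModel")) mdl else parsingModel(mdl))
  alpha <- length(seq@alphabet)
  rows <- lapply(models, function(mdl) {
    if (mdl@kind == "translate" && !setequal(seq@alphabet, ALPHABETS$DNA)) {
      warning("model '", mdl@label, "' skipped: requires DNA alphabet")
      return(NULL)
    }
    ws <- parseModel(seq, mdl)
    if (length(ws@words) == 0L) {
      warning("model '", mdl@label, "' skipped: no complete words")
      return(NULL)
    }
    if (mdl@kind == "lz78") {
      wc <- countWords(ws)
      bd <- lz78Codelength(length(ws@words), alpha)
      ent <- NA_real_
    } else {
      wc <- countWords(ws)
      bd <- breakdownFor(wc, method, prior)
      ent <- empiricalEntropy(wc)
    }
    raw <- rawBits(ws@encodedSymbols, alpha)
    data.frame(model = mdl@label, n = wc@n, m = wc@m, entropy = ent,
               entropy_bits = bd@entropyBits, complexity_bits = bd@complexityBits,
               total_bits = bd@totalBits, raw_bits = raw,
               rate = compressionRate(bd@totalBits, raw),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no applicable model in the scan list")
  out <- do.call(rbind, rows)
  out <- out[order(out$model, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out$is_min <- seq_len(nrow(out)) == which.min(out$rate)
  out
}

#' Standard DNA model scan list
#'
#' Word lengths 1 to 4 at every phase, plus amino-acid translation:
#' the labels `1, 2.0, 2.1, 3.0, 3.1, 3.2, 4.0, 4.1, 4.2, 4.3, a.a.`.
#'
#' @param translated include the amino-acid translation model.
#' @return character vector of model labels.
#' @export
dnaScanModels <- function(translated = TRUE) {
  labs <- c("1",
            paste0("2.", 0:1),
            paste0("3.", 0:2),
            paste0("4.", 0:3))
  if (translated) labs <- c(labs, "a.a.")
  labs
}

#' Permutation randomization of compression rates
#'
#' Permutes the symbols of the sequence (uniformly, without replacement, so
#' the base composition is preserved exactly) `R` times and recomputes the
#' compression rate of every model under each requested code-length method.
#' The resulting reference distribution calibrates the rates of the
#' original sequence: for a permuted (hence structureless) sequence every
#' multi-symbol NML rate should sit above 1, while single-symbol (k = 1)
#' counts are permutation-invariant and have zero spread.
#'
#' @param seq a [SymbolSequence-class].
#' @param models models to scan (as in [modelScan()]); translation is
#'   excluded from the default here, matching its exclusion from the
#'   randomness verdict.
#' @param R number of permutations (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param methods code-length methods to evaluate (default the NML, plain
#'   entropy and BIC bounds).
#' @return a [PermutationSummary-class]: per (model, method) the mean, SD
#'   and empirical 1%/99% quantiles (type-1 order statistics) of the rate
#'   over the R permutations.
#' @export
permutationTest <- function(seq, models = dnaScanModels(translated = FALSE),
                            R = 1000L, seed = NULL,
                            methods = c("nml", "entropy", "bic")) {
  stopifnot(is(seq, "SymbolSequence"), R >= 1L)
  methods <- match.arg(methods, defaultMethods, several.ok = TRUE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  chars <- strsplit(seq@symbols, "", fixed = TRUE)[[1L]]
  labels <- vapply(lapply(models, function(m)
    if (is(m, "ParsingModel")) m else parsingModel(m)),
    function(m) m@label, character(1))
  rates <- array(NA_real_,
                 dim = c(R, length(labels), length(methods)),
                 dimnames = list(NULL, labels, methods))
  for (r in seq_len(R)) {
    perm <- SymbolSequence(paste(sample(chars), collapse = ""),
                           alphabet = seq@alphabet)
    for (me in methods) {
      sc <- modelScan(perm, models = models, method = me)
      rates[r, sc$model, me] <- sc$rate
    }
  }
  summ <- do.call(rbind, lapply(methods, function(me) {
    do.call(rbind, lapply(labels, function(lb) {
      x <- rates[, lb, me]
      data.frame(model = lb, method = me, mean = mean(x), sd = stats::sd(x),
                 q01 = stats::quantile(x, 0.01, type = 1, names = FALSE),
                 q99 = stats::quantile(x, 0.99, type = 1, names = FALSE),
                 R = R, stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  if (R == 1L) summ$sd <- 0
  new("PermutationSummary", summary = summ, replicates = as.integer(R),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Randomness verdict from a model scan
#'
#' A sequence is consistent with randomness when its compression rate is at
#' least 1 under every dictionary tried (incompressibility); the minimum is
#' taken over the scanned models, strictly on the computed real values.
#' The amino-acid translation model is excluded by default: it is not a
#' lossless description of the underlying DNA, so a low translated rate
#' does not witness compressibility of the nucleotide sequence.
#'
#' @param reports a scan data.frame from [modelScan()].
#' @param includeTranslated keep the `a.a.` row in the minimum.
#' @return a list with `min_rate`, `model` (the argmin label), and
#'   `verdict` (`"consistent-with-random"` or `"not-random"`).
#' @export
randomnessVerdict <- function(reports, includeTranslated = FALSE) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1L)
  if (!includeTranslated)
    reports <- reports[reports$model != "a.a.", , drop = FALSE]
  if (nrow(reports) == 0L) stop("no reports left after exclusions")
  i <- which.min(reports$rate)
  list(min_rate = reports$rate[i],
       model = reports$model[i],
       verdict = if (reports$rate[i] >= 1) "consistent-with-random"
                 else "not-random")
}
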