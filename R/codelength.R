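# Code-length mathematics. All logarithms are base 2; the unit is the bit.
# Gamma functions are always evaluated through lgamma to avoid overflow.

log2e <- 1 / log(2)
log2gamma <- function(x) lgamma(x) * log2e

asWordCounts <- function(wc) {
  if (is(wc, "WordCounts")) wc else wordCountsFromVector(wc)
}

#' Empirical entropy of word frequencies
#'
#' The plug-in entropy \eqn{H(\hat\theta) = -\sum_k \hat p_k \log_2 \hat p_k}
#' with \eqn{\hat p_k = n_k/n} the observed word frequencies. This is the
#' per-word first term of every code-length bound, and on its own an
#' underestimate of the attainable compression.
#'
#' @param wc a [WordCounts-class] (or bare counts vector).
#' @return entropy in bits per word, in `[0, log2(m)]`.
#' @examples
#' empiricalEntropy(c(1, 1, 1, 1))  # 2 bits
#' empiricalEntropy(c(3, 1))
#' @export
empiricalEntropy <- function(wc) {
  wc <- asWordCounts(wc)
  if (wc@n < 1L) stop("empirical entropy needs at least one word (n >= 1)")
  p <- wc@counts / wc@n
  -sum(p * log2(p))
}

#' Parametric-complexity terms of the multinomial NML code length
#'
#' The terms of the multinomial stochastic complexity other than the
#' entropy term, from the word number and dictionary size alone:
#' \deqn{(d/2)\log_2 n - d/2 - \log_2\Gamma((d+1)/2) + (1/2)\log_2\pi,}
#' with \eqn{d = m - 1}.
#'
#' @param n total word number.
#' @param m dictionary size (distinct observed words).
#' @return complexity in bits; 0 exactly when d = 0 (with a warning — a
#'   single-word dictionary has no free parameter and the expansion is
#'   meaningless there).
#' @examples
#' nmlComplexityBits(2907, 4)   # 16.58 bits
#' nmlComplexityBits(969, 58)   # 157.11 bits
#' @export
nmlComplexityBits <- function(n, m) {
  if (n < 1) stop("need n >= 1")
  d <- m - 1
  if (d == 0) {
    warning("single-word dictionary (d = 0): complexity is 0 and the asymptotic expansion is degenerate")
    return(0)
  }
  d / 2 * log2(n) - d / 2 - log2gamma((d + 1) / 2) + 0.5 * log2(pi)
}

#' Multinomial NML (stochastic-complexity) code length
#'
#' The asymptotic normalized-maximum-likelihood code length of the word
#' sequence under the multinomial model of its dictionary:
#' \deqn{L = nH(\hat\theta) + (d/2)\log_2 n - d/2 - \log_2\Gamma((d+1)/2) + (1/2)\log_2 \pi.}
#' This is the Jeffreys-prior instance of the generic exponential-family
#' expansion (see [nmlParametricExpansion()]), and the objective function of
#' MDL dictionary selection.
#'
#' @param wc a [WordCounts-class] (or bare counts vector).
#' @return a [CodeLengthBreakdown-class] with method `"nml_asym"`.
#' @examples
#' wc <- countWords(strsplit(strrep("ACGT", 25), "")[[1]])
#' nmlCodelengthMultinomial(wc)
#' @export
nmlCodelengthMultinomial <- function(wc) {
  wc <- asWordCounts(wc)
  if (wc@n < 1L) stop("need n >= 1")
  H <- empiricalEntropy(wc)
  codeLengthBreakdown(wc@n * H, nmlComplexityBits(wc@n, wc@m), "nml_asym")
}

#' BIC-style two-part code length
#'
#' Entropy term plus the classical \eqn{(d/2)\log_2 n} model-cost term,
#' without the Fisher-information correction. Always at least as long as
#' the NML code length once \eqn{n > 2\pi}; kept as a comparison bound.
#'
#' @inheritParams nmlCodelengthMultinomial
#' @return a [CodeLengthBreakdown-class] with method `"bic"`.
#' @export
bicCodelength <- function(wc) {
  wc <- asWordCounts(wc)
  if (wc@n < 1L) stop("need n >= 1")
  d <- wc@m - 1
  H <- empiricalEntropy(wc)
  codeLengthBreakdown(wc@n * H, d / 2 * log2(wc@n), "bic")
}

#' Fisher information determinant of the multinomial
#'
#' For the discrete distribution with probabilities \eqn{(p_1,...,p_m)} and
#' free parameters \eqn{p_1,...,p_{m-1}},
#' \eqn{|I(p)| = 1/\prod_{k=1}^{m} p_k}.
#'
#' @param p probability vector (all positive, summing to 1).
#' @return the determinant (plain number, not a logarithm).
#' @examples
#' fisherDetMultinomial(c(.5, .25, .25))  # 32
#' @export
fisherDetMultinomial <- function(p) {
  if (any(p <= 0)) stop("all probabilities must be positive")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  1 / prod(p)
}

#' Integrated root Fisher determinant of the multinomial (Jeffreys integral)
#'
#' \eqn{\log_2 \int_\Theta |I(\theta)|^{1/2} d\theta} over the d-dimensional
#' probability simplex, which by the Dirichlet(1/2,...,1/2) normalizer
#' identity equals \eqn{\log_2 ( \pi^{(d+1)/2} / \Gamma((d+1)/2) )}.
#' Plugging this into the generic expansion recovers the closed-form
#' multinomial NML complexity exactly.
#'
#' @param d model dimension (m - 1, at least 1).
#' @return \eqn{\log_2} of the integral, in bits.
#' @export
jeffreysLogIntegralMultinomial <- function(d) {
  if (d < 1) stop("need d >= 1")
  (d + 1) / 2 * log2(pi) - log2gamma((d + 1) / 2)
}

#' Exponential-family spec for the multinomial model
#'
#' @param m dictionary size (categories); dimension is m - 1.
#' @return an [ExponentialFamilySpec-class] whose Fisher ingredients are the
#'   multinomial ones and whose default prior is Jeffreys.
#' @export
multinomialSpec <- function(m) {
  d <- m - 1
  new("ExponentialFamilySpec",
      dimension = d,
      entropyAtMLE = function(wc) empiricalEntropy(wc),
      log2FisherSqrtIntegral = jeffreysLogIntegralMultinomial(d),
      log2FisherSqrtAt = function(p) 0.5 * log2(fisherDetMultinomial(p)),
      log2PriorAt = function(p) {
        # Jeffreys density on the simplex
        log2gamma((d + 1) / 2) - (d + 1) / 2 * log2(pi) - 0.5 * sum(log2(p))
      })
}

#' Exponential-family spec for a Gaussian mean on a bounded interval
#'
#' Mean parameter restricted to \eqn{[-a, a]} with known standard deviation
#' \eqn{\sigma}: \eqn{|I(\mu)| = 1/\sigma^2}, so the integrated root Fisher
#' determinant is \eqn{2a/\sigma}. A second, continuous-data instance of the
#' expansion (description length rather than code length); the entropy at
#' the MLE is the differential entropy \eqn{\frac12\log_2(2\pi e \sigma^2)}.
#'
#' @param a half-width of the mean interval.
#' @param sigma known standard deviation.
#' @return an [ExponentialFamilySpec-class] of dimension 1.
#' @export
gaussianMeanIntervalSpec <- function(a, sigma = 1) {
  stopifnot(a > 0, sigma > 0)
  new("ExponentialFamilySpec",
      dimension = 1,
      entropyAtMLE = function(wc) 0.5 * log2(2 * pi * exp(1) * sigma^2),
      log2FisherSqrtIntegral = log2(2 * a / sigma),
      log2FisherSqrtAt = function(theta) -log2(sigma),
      log2PriorAt = function(theta) -log2(2 * a))
}

#' Generic asymptotic NML expansion for an exponential family
#'
#' \deqn{L_{NML} = nH(\hat\theta) + (d/2)\log_2(n/2\pi) +
#'   \log_2 \int_\Theta |I(\theta)|^{1/2} d\theta + o(1).}
#' With the multinomial spec this reproduces
#' [nmlCodelengthMultinomial()] exactly (algebraic identity); with other
#' specs it extends the bound to arbitrary exponential families whose
#' Jeffreys integral is finite.
#'
#' @param spec an [ExponentialFamilySpec-class].
#' @param wc a [WordCounts-class] (or counts vector); only `n` and the
#'   entropy functional are used.
#' @return a [CodeLengthBreakdown-class] with method `"nml_asym"`.
#' @export
nmlParametricExpansion <- function(spec, wc) {
  stopifnot(is(spec, "ExponentialFamilySpec"))
  wc <- asWordCounts(wc)
  if (wc@n < 1L) stop("need n >= 1")
  if (!is.finite(spec@log2FisherSqrtIntegral))
    stop("integral term is not finite; restrict the parameter space to a compact subset")
  H <- spec@entropyAtMLE(wc)
  comp <- spec@dimension / 2 * log2(wc@n / (2 * pi)) + spec@log2FisherSqrtIntegral
  codeLengthBreakdown(wc@n * H, comp, "nml_asym")
}

# Align a Dirichlet prior with observed word counts. Named priors may
# declare a super-dictionary (words never observed get count 0); unnamed
# priors must match the dictionary size and are taken in lexicographic
# word order.
alignPrior <- function(wc, prior) {
  stopifnot(is(prior, "DirichletPrior"))
  a <- prior@concentrations
  if (!is.null(names(a))) {
    missing <- setdiff(names(wc@counts), names(a))
    if (length(missing))
      stop("observed word(s) outside the prior support: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    nk <- rep(0L, length(a))
    names(nk) <- names(a)
    nk[names(wc@counts)] <- wc@counts
  } else {
    if (length(a) != wc@m)
      stop("unnamed prior must have one concentration per distinct word")
    nk <- unname(wc@counts)
    a <- unname(a)
  }
  list(alpha = a, nk = nk)
}

#' Dirichlet-mixture (Bayesian marginal) code length
#'
#' The exact code length of the word sequence under the Dirichlet-multinomial
#' marginal likelihood,
#' \deqn{L = -\log_2\left[\frac{\Gamma(A)}{\Gamma(n+A)}
#'   \prod_k \frac{\Gamma(n_k+\alpha_k)}{\Gamma(\alpha_k)}\right],
#'   \quad A = \sum_k \alpha_k,}
#' which is order-independent (exchangeable) and identical to the total of
#' the sequential Bayesian predictive code
#' ([predictiveCodelengthSequential()]). With the Jeffreys prior
#' \eqn{\alpha_k = 1/2} this is the Krichevsky–Trofimov code.
#'
#' @param wc a [WordCounts-class] (or counts vector).
#' @param prior a [DirichletPrior-class]; named concentrations may declare a
#'   super-dictionary containing all observed words.
#' @return a [CodeLengthBreakdown-class] with method `"mixture"`; the
#'   breakdown reports the entropy term \eqn{nH(\hat\theta)} and the
#'   complexity as total minus entropy.
#' @examples
#' mixtureCodelengthDirichlet(c(`0` = 1, `1` = 1), jeffreysPrior(2))
#' @export
mixtureCodelengthDirichlet <- function(wc, prior = jeffreysPrior(asWordCounts(wc))) {
  wc <- asWordCounts(wc)
  if (wc@n < 1L) stop("need n >= 1")
  al <- alignPrior(wc, prior)
  A <- sum(al$alpha)
  total <- -(log2gamma(A) - log2gamma(wc@n + A) +
             sum(log2gamma(al$nk + al$alpha) - log2gamma(al$alpha)))
  H <- empiricalEntropy(wc)
  codeLengthBreakdown(wc@n * H, total - wc@n * H, "mixture")
}

#' Sequential Bayesian predictive code length
#'
#' One-pass predictive coding: the k-th word is coded with the current
#' posterior-predictive probability
#' \eqn{q_k(x_k) = (\alpha_{x_k} + c_{x_k}) / (A + k - 1)}, where
#' \eqn{c_{x_k}} counts earlier occurrences of the word, and the posterior
#' is updated after each word. The total equals the closed-form mixture
#' code length of the same counts (to floating-point accuracy), so one pass
#' over the data attains the two-pass bound.
#'
#' @param ws a [WordSequence-class] or character vector of words, in order.
#' @param prior a [DirichletPrior-class] with concentrations named by word,
#'   covering every word that occurs.
#' @return total code length in bits.
#' @export
predictiveCodelengthSequential <- function(ws, prior) {
  w <- if (is(ws, "WordSequence")) ws@words else as.character(ws)
  if (length(w) == 0L) stop("need at least one word")
  stopifnot(is(prior, "DirichletPrior"))
  a <- prior@concentrations
  if (is.null(names(a)))
    stop("sequential coding needs a prior with concentrations named by word")
  outside <- setdiff(unique(w), names(a))
  if (length(outside))
    stop("word(s) outside the prior support: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  A <- sum(a)
  idx <- match(w, names(a))
  seen <- integer(length(a))
  bits <- 0
  for (i in seq_along(idx)) {
    j <- idx[i]
    bits <- bits - log2((a[[j]] + seen[j]) / (A + i - 1))
    seen[j] <- seen[j] + 1L
  }
  bits
}

#' Asymptotic expansion of the Bayesian predictive (mixture) code length
#'
#' \deqn{L = nH(\hat\theta) + (d/2)\log_2(n/2\pi) +
#'   \log_2 |I(\hat\theta)|^{1/2} - \log_2 w(\hat\theta) + o(1).}
#' With the Jeffreys prior the prior and Fisher terms collapse to the
#' integrated root Fisher determinant and the expansion coincides with
#' [nmlParametricExpansion()]. Requires an interior MLE: every category of
#' the declared dictionary must be observed, otherwise the expansion point
#' sits on the simplex boundary and the method refuses.
#'
#' @param spec an [ExponentialFamilySpec-class] (its dimension declares the
#'   dictionary; for the multinomial use [multinomialSpec()] with the full
#'   dictionary size).
#' @param wc a [WordCounts-class] (or counts vector).
#' @param log2PriorAt optional override of the spec's prior density
#'   (function of \eqn{\hat\theta} returning \eqn{\log_2 w(\hat\theta)}).
#' @return a [CodeLengthBreakdown-class] with method `"mixture"`.
#' @export
bayesExpansion <- function(spec, wc, log2PriorAt = NULL) {
  stopifnot(is(spec, "ExponentialFamilySpec"))
  wc <- asWordCounts(wc)
  if (wc@n < 1L) stop("need n >= 1")
  if (spec@dimension != wc@m - 1)
    stop("boundary MLE: the declared dictionary has unobserved words ",
         "(spec dimension ", spec@dimension, " vs observed d = ", wc@m - 1, ")")
  if (is.null(log2PriorAt)) log2PriorAt <- spec@log2PriorAt
  if (is.null(log2PriorAt))
    stop("no prior density available: supply 'log2PriorAt'")
  theta <- wc@counts / wc@n
  H <- spec@entropyAtMLE(wc)
  comp <- spec@dimension / 2 * log2(wc@n / (2 * pi)) +
    spec@log2FisherSqrtAt(theta) - log2PriorAt(theta)
  codeLengthBreakdown(wc@n * H, comp, "mixture")
}

#' Exact Shtarkov normalizer of the multinomial NML distribution
#'
#' Computes \eqn{\log_2 C(n,m)} where
#' \deqn{C(n,m) = \sum_{n_1+\cdots+n_m=n} \binom{n}{n_1,\ldots,n_m}
#'   \prod_k (n_k/n)^{n_k}}
#' is the sum of maximized likelihoods over all length-n sequences on m
#' categories. The exact NML code length of counts \eqn{(n_k)} is then
#' \eqn{nH(\hat\theta) + \log_2 C(n,m)}; the asymptotic expansion converges
#' to it as n grows. Evaluated by an m-fold log-space convolution of
#' \eqn{a_t = t^t/t!} (never by enumerating sequences), but guarded to
#' small problems: this is an oracle for validation, not a production code
#' length.
#'
#' @param n number of words.
#' @param m number of categories.
#' @return \eqn{\log_2 C(n,m)}.
#' @examples
#' shtarkovNormalizerExact(1, 2)  # log2(2) = 1
#' shtarkovNormalizerExact(3, 2)  # log2(26/9)
#' @export
shtarkovNormalizerExact <- function(n, m) {
  stopifnot(n >= 1, m >= 1)
  if (choose(n + m - 1, m - 1) > 1e6)
    stop("exact Shtarkov sum refused: more than 1e6 compositions of n into m parts")
  if (m == 1) return(0)
  t <- 0:n
  # log of a_t = t^t / t!   (a_0 = 1)
  la <- ifelse(t == 0, 0, t * log(t)) - lgamma(t + 1)
  lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  acc <- la
  for (j in seq_len(m - 1L)) {
    acc <- vapply(t, function(tt)
      lse(acc[seq_len(tt + 1L)] + la[tt + 1L - seq_len(tt + 1L) + 1L]),
      numeric(1))
  }
  (lgamma(n + 1) - n * log(n) + acc[n + 1L]) * log2e
}

#' Exact multinomial NML code length
#'
#' \eqn{nH(\hat\theta) + \log_2 C(n,m)} with the exact Shtarkov normalizer;
#' subject to the same small-problem guard as [shtarkovNormalizerExact()].
#'
#' @inheritParams nmlCodelengthMultinomial
#' @param m number of categories of the model (defaults to the observed
#'   dictionary size; pass a larger value to model a super-dictionary).
#' @return a [CodeLengthBreakdown-class] with method `"nml_exact"`.
#' @export
nmlCodelengthExact <- function(wc, m = NULL) {
  wc <- asWordCounts(wc)
  if (wc@n < 1L) stop("need n >= 1")
  if (is.null(m)) m <- wc@m
  H <- empiricalEntropy(wc)
  codeLengthBreakdown(wc@n * H, shtarkovNormalizerExact(wc@n, m), "nml_exact")
}

#' LZ78 code length
#'
#' For `c` phrases over an alphabet of size \eqn{\alpha}, each phrase is
#' stored as the address of its prefix phrase plus one literal symbol:
#' \deqn{L = c\log_2 c + c\log_2 \alpha} bits (address book plus literals).
#'
#' @param c number of LZ78 phrases.
#' @param alpha alphabet size.
#' @return a [CodeLengthBreakdown-class] with method `"lz78"`: the literal
#'   bits \eqn{c\log_2\alpha} are reported as the entropy part and the
#'   address bits \eqn{c\log_2 c} as the complexity part.
#' @examples
#' totalBits(lz78Codelength(635, 4))  # 5912 + 1270 bits
#' @export
lz78Codelength <- function(c, alpha) {
  stopifnot(c >= 0, alpha >= 2)
  address <- if (c > 1) c * log2(c) else 0
  literal <- if (c > 0) c * log2(alpha) else 0
  codeLengthBreakdown(literal, address, "lz78")
}
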