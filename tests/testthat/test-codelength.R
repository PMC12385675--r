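test_that("empirical entropy matches direct evaluation and its bounds", {
  expect_equal(empiricalEntropy(c(1, 1, 1, 1)), 2.0)
  expect_equal(empiricalEntropy(c(4)), 0.0)
  expect_equal(empiricalEntropy(c(3, 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    m <- sample(2:10, 1)
    counts <- randomCounts(sample(m:60, 1), m)
    H <- empiricalEntropy(counts)
    expect_gte(H, 0)
    expect_lte(H, log2(m) + 1e-12)
  }
})

test_that("multinomial NML complexity reproduces closed-form values", {
  # independent recomputation of each term, straight from the formula
  ref <- function(n, d) d / 2 * log2(n) - d / 2 - lgamma((d + 1) / 2) / log(2) +
    0.5 * log2(pi)
  for (nm in list(c(100, 4), c(2907, 4), c(969, 58), c(50, 2))) {
    expect_equal(nmlComplexityBits(nm[1], nm[2]), ref(nm[1], nm[2] - 1),
                 tolerance = 1e-12)
  }
  # no overflow at large dictionaries: log-gamma path stays finite
  expect_true(is.finite(nmlComplexityBits(1e5, 1e4)))
  expect_warning(z <- nmlComplexityBits(10, 1), "single-word")
  expect_identical(z, 0)
})

test_that("code-length breakdowns are internally consistent", {
  wc <- countWords(parseFixedLength(iidString("DNA", S = 600, seed = 3), 2))
  for (bd in list(nmlCodelengthMultinomial(wc), bicCodelength(wc),
                  mixtureCodelengthDirichlet(wc))) {
    expect_equal(totalBits(bd), entropyBits(bd) + complexityBits(bd),
                 tolerance = 1e-9)
    expect_gte(entropyBits(bd), 0)
  }
  expect_equal(entropyBits(nmlCodelengthMultinomial(wc)),
               nWords(wc) * empiricalEntropy(wc))
})

test_that("BIC complexity is (d/2) log2 n", {
  wc <- wordCountsFromVector(randomCounts(3000, 2))
  expect_equal(complexityBits(bicCodelength(wc)), 0.5 * log2(3000))
  expect_equal(complexityBits(bicCodelength(wordCountsFromVector(c(5)))), 0)
})

test_that("multinomial Fisher determinant is the reciprocal product", {
  expect_equal(fisherDetMultinomial(c(.5, .5)), 4)
  expect_equal(fisherDetMultinomial(rep(.25, 4)), 256)
  expect_equal(fisherDetMultinomial(c(.5, .25, .25)), 32)
  expect_error(fisherDetMultinomial(c(1, 0)), "positive")
})

test_that("Jeffreys integral identity makes the generic expansion exact", {
  expect_equal(jeffreysLogIntegralMultinomial(1), log2(pi))
  expect_equal(jeffreysLogIntegralMultinomial(3), 2 * log2(pi))
  set.seed(11)
  for (i in 1:20) {
    m <- sample(2:40, 1)
    n <- sample((m + 1):3000, 1)
    wc <- wordCountsFromVector(randomCounts(n, m))
    a <- totalBits(nmlCodelengthMultinomial(wc))
    b <- totalBits(nmlParametricExpansion(multinomialSpec(m), wc))
    expect_lt(abs(a - b), 1e-9)
  }
})

test_that("Gaussian-mean spec gives the closed-form expansion terms", {
  spec <- gaussianMeanIntervalSpec(a = 1, sigma = 1)
  wc <- wordCountsFromVector(randomCounts(100, 2))  # only n is used
  expect_equal(complexityBits(nmlParametricExpansion(spec, wc)),
               0.5 * log2(100 / (2 * pi)) + 1, tolerance = 1e-12)
  # quadrupling n adds exactly one bit for d = 1
  wc4 <- wordCountsFromVector(randomCounts(400, 2))
  d1 <- complexityBits(nmlParametricExpansion(multinomialSpec(2), wc4)) -
    complexityBits(nmlParametricExpansion(multinomialSpec(2), wc))
  expect_equal(d1, 1, tolerance = 1e-12)
})

test_that("Dirichlet-mixture code length matches hand-computed marginals", {
  p <- dirichletPrior(c(`0` = .5, `1` = .5))
  expect_equal(totalBits(mixtureCodelengthDirichlet(
    wordCountsFromVector(c(`0` = 1)), p)), 1.0)
  expect_equal(totalBits(mixtureCodelengthDirichlet(
    wordCountsFromVector(c(`0` = 1, `1` = 1)), p)), 3.0)
  expect_equal(totalBits(mixtureCodelengthDirichlet(
    wordCountsFromVector(c(`0` = 2)), p)), log2(8 / 3), tolerance = 1e-12)
  expect_error(dirichletPrior(c(0.5, 0)), "positive")
})

test_that("sequential predictive code equals the mixture closed form", {
  expect_equal(predictiveCodelengthSequential(
    c("0", "1"), dirichletPrior(c(`0` = .5, `1` = .5))), 3.0)
  set.seed(19)
  for (i in 1:15) {
    m <- sample(2:6, 1)
    ab <- LETTERS[seq_len(m)]
    n <- sample(5:60, 1)
    w <- sample(ab, n, replace = TRUE)
    prior <- dirichletPrior(setNames(runif(m, 0.1, 3), ab))
    lseq <- predictiveCodelengthSequential(w, prior)
    lmix <- totalBits(mixtureCodelengthDirichlet(countWords(w), prior))
    expect_lt(abs(lseq - lmix), 1e-9)
    # exchangeability: permuted word order gives the identical total
    expect_equal(predictiveCodelengthSequential(sample(w), prior), lseq,
                 tolerance = 1e-9)
  }
  # single word: -log2 of its prior predictive probability
  pr <- dirichletPrior(c(A = 2, B = 1))
  expect_equal(predictiveCodelengthSequential("A", pr), -log2(2 / 3))
  expect_error(predictiveCodelengthSequential(c("A", "Z"), pr), "support")
})

test_that("Bayesian-predictive expansion matches NML under Jeffreys and refuses boundaries", {
  set.seed(23)
  for (i in 1:10) {
    m <- sample(2:8, 1)
    wc <- wordCountsFromVector(randomCounts(sample(50:500, 1), m))
    spec <- multinomialSpec(m)
    expect_equal(totalBits(bayesExpansion(spec, wc)),
                 totalBits(nmlParametricExpansion(spec, wc)),
                 tolerance = 1e-9)
  }
  # declared dictionary larger than observed: boundary MLE is refused
  expect_error(bayesExpansion(multinomialSpec(4),
                              wordCountsFromVector(c(10, 20))), "boundary")
})

test_that("uniform-prior expansion assembles from the Fisher determinant", {
  wc <- wordCountsFromVector(c(`0` = 600, `1` = 400))
  # uniform prior on [0,1]: w = 1, so log2 w = 0
  bd <- bayesExpansion(multinomialSpec(2), wc, log2PriorAt = function(p) 0)
  want <- 0.5 * log2(1000 / (2 * pi)) +
    0.5 * log2(fisherDetMultinomial(c(0.6, 0.4)))
  expect_equal(complexityBits(bd), want, tolerance = 1e-12)
})

test_that("expansion converges to the exact mixture as n grows at fixed composition", {
  gaps <- sapply(c(50, 500, 5000), function(n) {
    wc <- wordCountsFromVector(c(`0` = 0.6 * n, `1` = 0.4 * n))
    prior <- dirichletPrior(c(`0` = 1, `1` = 1))
    exact <- totalBits(mixtureCodelengthDirichlet(wc, prior))
    asym <- totalBits(bayesExpansion(multinomialSpec(2), wc,
                                     log2PriorAt = function(p) 0))
    abs(exact - asym)
  })
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.01)
})

test_that("exact Shtarkov normalizer agrees with brute-force enumeration", {
  expect_equal(shtarkovNormalizerExact(1, 2), 1.0)
  expect_equal(shtarkovNormalizerExact(2, 2), log2(2.5), tolerance = 1e-10)
  expect_equal(shtarkovNormalizerExact(3, 2), log2(26 / 9), tolerance = 1e-10)
  for (m in 2:3) for (n in 2:6) {
    expect_equal(shtarkovNormalizerExact(n, m), shtarkovBruteForce(n, m),
                 tolerance = 1e-9)
  }
  expect_error(shtarkovNormalizerExact(1e6, 50), "refused")
})

test_that("exact NML code lengths define a probability distribution (Kraft equality)", {
  for (m in 2:3) for (n in c(3, 5, 6)) {
    grid <- expand.grid(rep(list(seq_len(m)), n))
    total <- 0
    for (i in seq_len(nrow(grid))) {
      nk <- tabulate(as.integer(grid[i, ]), nbins = m)
      wc <- wordCountsFromVector(setNames(nk[nk > 0],
                                          LETTERS[seq_len(m)][nk > 0]))
      L <- nWords(wc) * empiricalEntropy(wc) + shtarkovNormalizerExact(n, m)
      total <- total + 2^(-L)
    }
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("NML complexity grows with n and with dictionary size", {
  for (d in c(1, 3, 10)) {
    comp <- sapply(c(5, 10, 100, 1000), function(n) nmlComplexityBits(n, d + 1))
    expect_true(all(diff(comp) > 0))
  }
  for (n in c(10, 100, 2907)) {
    comp <- sapply(2:min(n, 30), function(m) nmlComplexityBits(n, m))
    expect_true(all(diff(comp) > 0))
  }
})

test_that("plug-in entropy underestimates the source entropy on average", {
  set.seed(31)
  p0 <- c(.4, .3, .2, .1)
  H0 <- -sum(p0 * log2(p0))
  n <- 150
  gaps <- replicate(60, {
    x <- sample(4, n, replace = TRUE, prob = p0)
    n * H0 - n * empiricalEntropy(tabulate(x, 4)[tabulate(x, 4) > 0])
  })
  expect_gt(mean(gaps), 0)
})

test_that("LZ78 code length charges addresses plus literals", {
  bd <- lz78Codelength(635, 4)
  expect_equal(complexityBits(bd), 635 * log2(635), tolerance = 1e-9)
  expect_equal(entropyBits(bd), 1270)
  expect_equal(totalBits(lz78Codelength(1, 2)), 1)
  expect_equal(totalBits(lz78Codelength(0, 2)), 0)
})
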