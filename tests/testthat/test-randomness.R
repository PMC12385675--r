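test_that("raw bits and compression rate follow the definitions", {
  expect_equal(rawBits(3000, 2), 3000)
  expect_equal(rawBits(2907, 4), 5814)
  expect_equal(compressionRate(5277.51, 5814), 0.9077, tolerance = 1e-4)
  expect_equal(compressionRate(42, 42), 1.0)
  expect_error(compressionRate(10, 0), "positive")
})

test_that("model scan reports one sorted row per applicable model with the minimum flagged", {
  s <- makeCodingDNA(400L, seed = 77)
  sc <- modelScan(s, models = dnaScanModels())
  expect_identical(nrow(sc), 11L)
  expect_identical(sc$model, sort(sc$model, method = "radix"))
  expect_identical(sum(sc$is_min), 1L)
  expect_equal(sc$rate, sc$total_bits / sc$raw_bits, tolerance = 1e-12)
  expect_equal(sc$raw_bits, 2 * (sc$n * c(1, 2, 2, 3, 3, 3, 4, 4, 4, 4, 3)),
               tolerance = 1e-12)
  # phased models drop symbols: denominator follows the encoded stretch
  expect_lt(sc$raw_bits[sc$model == "3.1"], sc$raw_bits[sc$model == "3.0"])
  # a degenerate sequence is maximally compressible under every model
  # single-word dictionaries (d = 0) legitimately warn about degeneracy
  flat <- suppressWarnings(modelScan(SymbolSequence(strrep("A", 300), "DNA"),
                                     models = c("1", "2.0", "3.0")))
  expect_true(all(flat$rate < 0.5))
})

test_that("translation is skipped with a warning outside the DNA alphabet", {
  s <- iidString("binary", S = 200, seed = 1)
  expect_warning(sc <- modelScan(s, models = c("1", "2.0", "a.a.")), "skipped")
  expect_identical(nrow(sc), 2L)
})

test_that("BIC totals exceed NML totals at table-like sizes", {
  s <- iidString("DNA", S = 1200, seed = 9)
  nml <- modelScan(s, models = c("1", "2.0", "3.0"), method = "nml")
  bic <- modelScan(s, models = c("1", "2.0", "3.0"), method = "bic")
  expect_true(all(bic$total_bits >= nml$total_bits))
})

test_that("LZ78 model rows use the phrase-based code length", {
  s <- iidString("DNA", S = 500, seed = 12)
  sc <- modelScan(s, models = list("1", "lz78"))
  row <- sc[sc$model == "lz78", ]
  c0 <- length(lz78Phrases(s))
  expect_identical(row$n, c0)
  expect_equal(row$total_bits, c0 * log2(c0) + c0 * 2, tolerance = 1e-9)
})

test_that("permutations leave single-symbol counts invariant and are reproducible", {
  s <- iidString("DNA", S = 900, seed = 21)
  ps <- permutationTest(s, models = c("1", "2.0", "3.0"), R = 20, seed = 5)
  su <- ps@summary
  expect_true(all(su$sd[su$model == "1"] == 0))
  expect_true(all(su$sd[su$model != "1" & su$method == "nml"] > 0))
  expect_true(all(su$q01 <= su$mean + 1e-12 & su$mean <= su$q99 + 1e-12))
  ps2 <- permutationTest(s, models = c("1", "2.0", "3.0"), R = 20, seed = 5)
  expect_identical(ps@summary, ps2@summary)
  ps3 <- permutationTest(s, models = c("1", "2.0", "3.0"), R = 20, seed = 6)
  expect_false(identical(ps@summary$mean, ps3@summary$mean))
})

test_that("permuted multi-symbol NML rates sit above 1", {
  s <- makeCodingDNA(500L, seed = 33)  # structured input, destroyed by permuting
  ps <- permutationTest(s, models = c("2.0", "3.0", "4.0"), R = 15, seed = 8)
  su <- ps@summary
  expect_true(all(su$mean[su$method == "nml"] > 1))
  expect_true(all(su$mean[su$method == "bic"] > 1))
  expect_true(all(su$mean[su$method == "entropy"] < 1))
})

test_that("single-replicate summaries collapse to the observed rate", {
  s <- iidString("DNA", S = 400, seed = 2)
  ps <- permutationTest(s, models = c("2.0",  "3.0"), R = 1, seed = 4)
  su <- ps@summary
  expect_equal(su$q01, su$mean)
  expect_equal(su$q99, su$mean)
  expect_true(all(su$sd == 0))
})

test_that("randomness verdict takes the strict minimum, excluding translation by default", {
  s <- makeCodingDNA(700L, seed = 55)
  sc <- modelScan(s, models = dnaScanModels())
  v <- randomnessVerdict(sc)
  expect_identical(v$verdict, "not-random")
  expect_identical(v$model, "3.0")  # in-frame codon model exposes the structure
  expect_false(v$model == "a.a.")
  vaa <- randomnessVerdict(sc, includeTranslated = TRUE)
  expect_identical(vaa$model, "a.a.")
  # boundary: rate exactly 1 is still consistent with randomness
  one <- data.frame(model = "1", rate = 1.0)
  expect_identical(randomnessVerdict(one)$verdict, "consistent-with-random")
})

test_that("uniform random sequences are incompressible across word lengths", {
  s <- iidString("binary", S = 3000, seed = 88)
  rows <- lapply(1:6, function(k) {
    wc <- countWords(parseFixedLength(s, k))
    compressionRate(totalBits(nmlCodelengthMultinomial(wc)),
                    rawBits(encodedSymbols(parseFixedLength(s, k)), 2))
  })
  expect_true(all(unlist(rows) > 1 - 3 * 0.006))
})
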