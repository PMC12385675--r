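---
title: "Compression bounds for individual sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression bounds for individual sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmlseq)
```

# The problem

Given one concrete symbol sequence — a gene, a binary stream — how many
bits does a lossless description of it need? Kolmogorov complexity answers
in principle but is uncomputable; Shannon's `nH` needs an oracle source
distribution the data do not come with. `nmlseq` takes the practical
middle road: fit the sequence, under a chosen *parsing* into words, with a
multinomial model of the observed word frequencies, and charge the
normalized-maximum-likelihood (NML) code length — the maximized likelihood
plus the log of the Shtarkov normalizer, the minimax-optimal price for not
knowing the parameters. Two uses follow:

* **Randomness testing.** An incompressible sequence has compression rate
  at least 1 under *every* dictionary tried. Rates are calibrated against
  symbol permutations of the same sequence.
* **Model (dictionary) selection.** Among parsings, the one with the
  smallest total code length is the MDL choice; for protein-coding DNA
  this is the in-frame codon parsing, so the scan rediscovers the reading
  frame.

# Code lengths computed

All logarithms are base 2; every Gamma factor goes through `lgamma`, so
dictionaries of thousands of words cause no overflow. For counts
`n_1..n_m` with `n = Σ n_k`, `d = m − 1`:

* **Plug-in entropy**: `n·H(θ̂)`, `H(θ̂) = −Σ (n_k/n) log(n_k/n)`. Alone it
  *under*-estimates the bound (its rate drifts below 1 on fair-coin data
  as the dictionary grows — the test suite demonstrates this on simulated
  strings).
* **Asymptotic multinomial NML** (`nmlCodelengthMultinomial`):
  `n·H(θ̂) + (d/2)log n − d/2 − log Γ((d+1)/2) + ½ log π`. This is the
  generic exponential-family expansion
  `n·H(θ̂) + (d/2)log(n/2π) + log ∫|I(θ)|^½ dθ` with the multinomial
  Jeffreys integral `π^{(d+1)/2}/Γ((d+1)/2)` substituted; the package
  carries both forms and the tests hold them equal to 1e-9 bits.
* **Exact NML** (`nmlCodelengthExact`): `n·H(θ̂) + log C(n,m)` with the
  Shtarkov sum `C(n,m)` computed exactly (below). The oracle the
  expansion's `o(1)` term converges to.
* **Dirichlet-mixture / Bayesian predictive**
  (`mixtureCodelengthDirichlet`, `predictiveCodelengthSequential`): the
  closed-form Dirichlet-multinomial marginal and its one-pass sequential
  equivalent; with concentrations ½ this is the Krichevsky–Trofimov code.
  Their totals agree to 1e-9 bits by exchangeability, which the tests
  exercise over random priors — one pass over the data already attains the
  two-pass bound.
* **BIC two-part code** (`bicCodelength`): `n·H(θ̂) + (d/2)log n`. Kept as
  the comparison bound; it overestimates the model cost (no Fisher
  correction), visibly so at large dictionaries.
* **LZ78** (`lz78Phrases`, `lz78Codelength`): incremental parsing; `c`
  phrases cost `c·log c` address bits plus `c·log α` literal bits.

## Dimension convention

`d` is the number of **distinct observed words minus one**. The
dictionary is the observed dictionary, not all `α^k` possibilities: a
2907-nt sequence parsed into codons can show 58 distinct codons out of
64, and `d = 57`. This convention is what reproduces the published
complexity values the acceptance checks pin down (e.g. 157.11 bits at
`n = 969, m = 58`); treating `d` as the full `α^k` dictionary size does
not.

## Exact Shtarkov normalizer

`C(n,m) = Σ multinomial(n; n_1..n_m) Π (n_k/n)^{n_k}` over all
compositions. It is evaluated as an `m`-fold log-space convolution of
`a_t = t^t/t!` (with `Σ` via log-sum-exp and the global factor
`n!/n^n`), which costs `O(m n²)` instead of enumerating compositions.
The implementation still refuses problems with more than 1e6
compositions: the quantity is an oracle for validating the expansion,
not a production code length. Tests verify the convolution against full
enumeration of all `m^n` sequences at `n ≤ 6`, that the implied NML
probabilities sum to exactly 1 (Kraft equality), and that the expansion's
gap to the exact value shrinks monotonically to under 0.1 bit by
`n = 500` at `m ∈ {2,3}`.

# Parsing rules

* **Fixed length** (`parseFixedLength`): non-overlapping `k`-mers from
  offset `phase` (0-based); the leading `phase` symbols and any trailing
  fragment are **dropped, not padded** — word numbers are
  `floor((S − phase)/k)`, and the rate denominator counts only the
  symbols actually encoded (`encodedSymbols · log α`), so a phased model
  of a 2907-nt sequence is compared against 5812 raw bits, not 5814.
* **Translation** (`translateCodons`): codons to one-letter amino-acid
  words under the standard genetic code (Biostrings' table); stop codons
  are an ordinary 21st word `"*"`. Translation is lossy for the DNA
  (synonymous codons collapse), so the `a.a.` model participates in scans
  — its rate measures the genetic code's redundancy — but is excluded
  from the randomness verdict by default.
* **LZ78** (`lz78Phrases`): each phrase is the shortest prefix not yet in
  the dictionary; a final incomplete phrase counts as one phrase.
* Sequences are validated against a declared alphabet; ambiguity codes
  (N) are rejected with their position rather than silently handled —
  there is no principled word count for an ambiguous symbol, and a hard
  error keeps the bounds honest. Strands are never reverse-complemented.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `models` in `modelScan` | word lengths 1–4, all phases, plus `a.a.` | the dictionary subset scanned; "min over all dictionaries" is operationalized as the minimum over this list |
| `method` | `"nml"` | code-length family used for scanning |
| Dirichlet concentrations | ½ (Jeffreys/KT) | prior of the mixture code |
| `R` in `permutationTest` | 1000 | permutation replicates; quantiles are type-1 order statistics |
| `seed` | unset | every stochastic entry point takes one and restores the caller's RNG state |
| `S`, `p` in `iidString` | — / uniform | synthetic source length and symbol law |

Permutations are true permutations (sampling without replacement), so
every replicate preserves the base composition exactly; single-symbol
counts are therefore permutation-invariant and their rate has zero spread
— a built-in sanity check the tests assert.

# The synthetic generator, and what passing tests show

`iidString` draws i.i.d. symbols from a declared law with R's seeded
generator; `replicateTable1` wraps the fair-coin binary benchmark
(S = 3000, word lengths 1–9) that the acceptance script replays. The
reference values for that benchmark come from an independently simulated
string of the same law, so they are matched **in distribution**, within
Monte-Carlo tolerance, never bit-for-bit. Test sequences emulating coding
DNA draw codons i.i.d. from a skewed usage; real genes add codon
autocorrelation, GC skew, and repeats that i.i.d. draws do not have.
Passing tests therefore certify the mathematics and the pipeline
(parsing → counting → code length → rate → verdict), and that the codon
signal is detected when present; they do not certify the published rates
of any particular organism's gene, which require that gene's sequence as
input. Given such a FASTA file, `modelScan(readFastaSequence(path),
dnaScanModels())` is the entire pipeline.

# Numerical and degenerate-input choices

* `0·log 0 = 0` in the entropy; totals are reals (no integer rounding —
  the generalized Kraft view drops the integer constraint).
* `d = 0` (a single-word dictionary): entropy 0, complexity 0, returned
  with a warning; the asymptotic expansion is meaningless there.
  Similarly, at word length 9 on a 3000-symbol string the dictionary size
  approaches the word number and the NML rate may legitimately fall below
  1 — an expansion-breakdown regime, not a randomness failure.
* The Bayesian-predictive expansion needs an interior MLE; if the
  declared dictionary contains unobserved words the implementation
  refuses (boundary flag) rather than extrapolates.
* The generic expansion requires a finite `∫|I|^½`; an infinite integral
  is an error instructing the caller to restrict the parameter space to a
  compact subset (the Gaussian-mean-on-interval spec shows the pattern).
* Scan rows are sorted by model label (radix order) and dictionaries
  lexicographically, so reports are deterministic; display rounds to 4
  decimals but verdicts and JSON companions use full precision.

# Problem sizes

The test suite runs at desk scale by design: exact-NML enumerations at
`n ≤ 6, m ≤ 3`, Shtarkov convolutions to `n = 500`, scans of
2907-symbol sequences, permutation summaries at `R = 15–25`, and 24
seeds for the stochastic benchmark (the full suite completes in well
under a minute). `R = 1000` remains the recommended production setting
for permutation quantiles; the 1% quantile of 25 replicates is only the
sample minimum.

# Limitations

* Only code *lengths* are computed; no bitstream encoder (arithmetic or
  Huffman) is included, and no decoder round-trip is possible.
* The i.i.d. multinomial fit captures local dependence only through
  longer words; no Markov or context-tree models.
* No p-values: permutation output is mean/SD/quantiles, read as a
  reference distribution.
* The redundancy/law-of-iterated-logarithm refinements of the expansion
  are out of scope; only the convergence direction of the `o(1)` term is
  checked empirically.
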