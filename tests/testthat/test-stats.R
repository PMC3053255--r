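test_that("fractionBetter counts strictly-lower values", {
  s <- new("FitnessSample", values = c(2, 3, 5, 5, 9), model = 1L,
           fitnessKind = "MS")
  expect_equal(fractionBetter(s, 1), 0)
  expect_equal(fractionBetter(s, 100), 1)
  expect_equal(fractionBetter(s, 5), 0.4)     # ties are not better
  expect_error(fractionBetter(numeric(0), 1), "empty")

  set.seed(50)
  v <- runif(1000)
  ref <- 0.37
  count <- 0L
  for (x in v) if (x < ref) count <- count + 1L
  expect_equal(fractionBetter(v, ref), count / 1000)
})

test_that("p.d.m. anchors at 0% and 100% and is affine-invariant", {
  expect_equal(pdmValue(pdm(10, 10, 3)), 0)
  expect_equal(pdmValue(pdm(10, 3, 3)), 100)
  expect_error(pdm(3, 5, 10), "deltaMean")

  set.seed(51)
  for (k in 1:50) {
    dl <- runif(1); dm <- dl + runif(1) + 0.1; dc <- runif(1, dl, dm)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pdmValue(pdm(a * dm + b, a * dc + b, a * dl + b)),
                 pdmValue(pdm(dm, dc, dl)), tolerance = 1e-9)
  }
})

test_that("random model-1 codes are on average far worse than canonical", {
  s <- sampleRandomCodes(10000, model = 1, seed = 52)
  v <- sampleValues(s)
  expect_true(all(v >= 0))
  expect_gt(mean(v), ms(canonicalCode()))
  expect_lt(sd(v) / sqrt(length(v)), 0.01 * mean(v))   # SE < 1% of mean
  s1 <- sampleRandomCodes(1, model = 2, seed = 53)
  expect_length(sampleValues(s1), 1L)
  expect_gte(sampleValues(s1), 0)
})

test_that("histograms conserve counts and match brute-force binning", {
  s <- sampleRandomCodes(2000, model = 1, seed = 54)
  h <- fitnessHistogram(s, bins = 30, reference = ms(canonicalCode()))
  expect_equal(sum(h$count), 2000L)
  expect_equal(h$count, oracle_histogram(sampleValues(s), 30))
  expect_equal(h$lower[1], min(sampleValues(s)))
  expect_equal(h$upper[30], max(sampleValues(s)))

  # consistency with fractionBetter: cumulative counts below/at the
  # reference bin bracket the strict count
  rb <- attr(h, "referenceBin")
  nbelow <- fractionBetter(s, ms(canonicalCode())) * 2000
  expect_lte(sum(h$count[seq_len(max(rb - 1, 0))]), nbelow)
  expect_gte(sum(h$count[seq_len(min(max(rb, 0), nrow(h)))]), nbelow)

  single <- fitnessHistogram(rep(4.2, 10), bins = 5)
  expect_equal(sum(single$count), 10L)
  expect_equal(sum(single$count > 0), 1L)
  expect_error(fitnessHistogram(s, bins = 0), "bins")
})

test_that("pattern proxies behave and agree with nested-loop oracle", {
  flat <- propertyScale(setNames(rep(2, 20),
                                 names(propertyValues(polarRequirement()))))
  expect_equal(unname(patternScores(canonicalCode(), flat)), c(0, 0))

  ps <- patternScores(canonicalCode())
  expect_lt(ps[["pattern1"]], 0)   # first-position "column" similarity
  expect_gt(ps[["pattern2"]], 0)   # second-base purine/pyrimidine split

  set.seed(55)
  for (code in list(canonicalCode(), randomPermutationCode(),
                    randomReassignmentCode())) {
    expect_equal(patternScores(code), oracle_patterns(code, polarRequirement()),
                 tolerance = 1e-9)
  }
})

test_that("optimalityAnalysis assembles a coherent arm", {
  res <- optimalityAnalysis(model = 1, fitnessKind = "MS", nRandom = 2000,
                            config = evolutionConfig(model = 1,
                                                     populationSize = 150,
                                                     replicates = 2,
                                                     seed = 56))
  expect_equal(res$deltaCode, ms(canonicalCode()))
  expect_equal(res$deltaMean, mean(sampleValues(res$sample)))
  expect_equal(res$deltaLow, min(bestValues(res$trace)))
  expect_gt(res$deltaMean, res$deltaCode)
  expect_gt(res$deltaCode, res$deltaLow)
  expect_equal(pdmValue(res$pdm),
               100 * (res$deltaMean - res$deltaCode) /
                 (res$deltaMean - res$deltaLow))
})
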