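test_that("evolutionConfig validates its fields", {
  expect_error(evolutionConfig(model = 3), "model")
  expect_error(evolutionConfig(fitnessKind = "XYZ"))
  expect_error(evolutionConfig(populationSize = 1), "populationSize")
  expect_error(evolutionConfig(tournamentFraction = 0), "tournamentFraction")
  expect_error(evolutionConfig(operatorProbability = 2),
               "operatorProbability")
  # default tournament window: 3% of 1000 = 30
  expect_equal(CodeOptimality:::.tournament_window(evolutionConfig()), 30L)
  expect_equal(CodeOptimality:::.tournament_window(
    evolutionConfig(populationSize = 10, tournamentFraction = 0.03)), 1L)
})

test_that("swap operator is an involution that only touches two blocks", {
  set.seed(20)
  code <- randomPermutationCode()
  expect_identical(codeString(swapOperator(code, 4, 4)), codeString(code))
  for (k in 1:20) {
    ij <- sample.int(20, 2)
    once <- swapOperator(code, ij[1], ij[2])
    expect_true(isPermutationCode(once))
    expect_identical(codeString(swapOperator(once, ij[1], ij[2])),
                     codeString(code))
    blocks <- blockStructure()
    changed <- vapply(seq_len(20), function(b) {
      cods <- blocks[[b]]
      !identical(codonAssignments(once)[cods], codonAssignments(code)[cods])
    }, logical(1))
    expect_true(all(which(changed) %in% ij))
  }
  expect_error(swapOperator(code, 0, 5), "1..20")
  expect_error(swapOperator(code, 1, 21), "1..20")
})

test_that("tournament selection picks the fittest draw, ties to low index", {
  fit <- c(0.9, 0.3, 0.3, 0.7, 0.1, 0.5)
  for (s in 1:50) {
    set.seed(s)
    draws <- sample.int(length(fit), 4, replace = TRUE)
    expected <- min(draws[fit[draws] == min(fit[draws])])
    set.seed(s)
    expect_identical(tournamentSelect(fit, 4), expected)
  }
  expect_error(tournamentSelect(numeric(0), 1), "empty")
  expect_error(tournamentSelect(fit, 7), "window")
})

test_that("window-1 tournaments select uniformly (chi-square)", {
  fit <- runif(10)
  set.seed(21)
  picks <- vapply(1:10000, function(i) tournamentSelect(fit, 1), integer(1))
  p <- chisq.test(table(factor(picks, levels = 1:10)),
                  p = rep(0.1, 10))$p.value
  expect_gt(p, 0.01)
})

test_that("the reassignment operator honors its full contract", {
  # crafted code in which 19 amino acids are sole instances: without the
  # sole-instance guard most applications would lose an amino acid
  base <- codonAssignments(canonicalCode())
  crafted <- base
  crafted[crafted != "*"] <- "A"
  singles <- setdiff(unique(base[base != "*"]), "A")
  spots <- names(base)[match(singles, base)]      # one canonical codon each
  crafted[spots] <- singles
  crafted_code <- geneticCode(crafted)
  expect_true(validObject(crafted_code))

  check_contract <- function(code0, seed) {
    set.seed(seed)
    code1 <- reassignmentOperator(code0)
    expect_true(validObject(code1))               # 20 amino acids, 3 stops
    a0 <- codonAssignments(code0)
    a1 <- codonAssignments(code1)
    changed <- names(a0)[a0 != a1]
    expect_lte(length(changed), 1L)
    if (length(changed) == 1L) {
      t <- changed
      expect_false(a1[[t]] == "*")
      # donated label sits on a one-base neighbor of the target
      donors <- codonNeighbors(t)$codon
      expect_true(any(a0[donors] == a1[[t]]))
      # recipient label was not a sole instance; counts shift by one
      expect_gte(sum(a0 == a0[[t]]), 2L)
      expect_equal(sum(a1 == a1[[t]]), sum(a0 == a1[[t]]) + 1L)
      expect_equal(sum(a1 == a0[[t]]), sum(a0 == a0[[t]]) - 1L)
      expect_equal(sum(a1 != "*"), 61L)
    }
    invisible(length(changed) == 0L)
  }

  unchanged <- 0L
  for (s in 1:300) unchanged <- unchanged + check_contract(crafted_code, s)
  expect_gt(unchanged, 0L)                        # the guard does fire
  set.seed(22)
  for (s in 301:340) check_contract(randomReassignmentCode(), s)
})

test_that("evolution is deterministic, elitist, and invariant-preserving", {
  cfg <- evolutionConfig(model = 1, populationSize = 60, generations = 30,
                         replicates = 3, seed = 5)
  tr1 <- evolveCodes(cfg)
  tr2 <- evolveCodes(cfg)
  expect_identical(tr1@best, tr2@best)
  expect_identical(tr1@meanFit, tr2@meanFit)
  expect_identical(lapply(bestCodes(tr1), codeString),
                   lapply(bestCodes(tr2), codeString))

  cfg2 <- evolutionConfig(model = 2, populationSize = 60, generations = 40,
                          replicates = 3, seed = 5, fitnessKind = "tMS")
  for (tr in list(tr1, evolveCodes(cfg2))) {
    for (r in seq_along(tr@best)) {
      expect_true(all(diff(tr@best[[r]]) <= 1e-12))  # elitism
      code <- bestCodes(tr)[[r]]
      expect_true(validObject(code))
      expect_identical(stopCodons(code), c("UAA", "UAG", "UGA"))
      if (traceConfig(tr)@model == 1L) expect_true(isPermutationCode(code))
    }
    expect_equal(bestValues(tr),
                 vapply(tr@best, function(v) v[length(v)], numeric(1)))
  }

  sm <- traceSummary(tr1)
  expect_equal(nrow(sm), max(lengths(tr1@best)))
  expect_true(all(diff(sm$best) <= 1e-12))
})

test_that("codon-reassignment evolution reaches lower error than swaps", {
  # paired seeded replicates, sign test: model 2 contains the model-1 space
  # and should find better codes in expectation
  n <- 20
  b1 <- bestValues(evolveCodes(evolutionConfig(
    model = 1, populationSize = 150, replicates = n, seed = 31)))
  b2 <- bestValues(evolveCodes(evolutionConfig(
    model = 2, populationSize = 150, replicates = n, seed = 31)))
  wins <- sum(b2 < b1)
  expect_lt(binom.test(wins, n, alternative = "greater")$p.value, 0.05)
})
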