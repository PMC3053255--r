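test_that("the canonical code has the standard structure", {
  cc <- canonicalCode()
  expect_true(validObject(cc))
  expect_identical(stopCodons(cc), c("UAA", "UAG", "UGA"))
  deg <- degeneracy(cc)
  expect_equal(deg[["L"]], 6L)
  expect_equal(deg[["S"]], 6L)
  expect_equal(deg[["R"]], 6L)
  expect_equal(deg[["M"]], 1L)
  expect_equal(deg[["W"]], 1L)
  expect_equal(sum(deg), 61L)
  # spot-check assignments
  a <- codonAssignments(cc)
  expect_equal(unname(a[c("AUG", "UGG", "UUU", "GGG")]),
               c("M", "W", "F", "G"))
})

test_that("the canonical code matches the reference translation table", {
  skip_if_not_installed("Biostrings")
  ref <- Biostrings::GENETIC_CODE
  names(ref) <- chartr("T", "U", names(ref))
  a <- codonAssignments(canonicalCode())
  expect_identical(unname(a[names(ref)]), as.vector(ref))
})

test_that("codon neighbors are the 9 single-base variants", {
  for (cd in c("AAA", "UGG", "CGC", "GUA")) {
    nb <- codonNeighbors(cd)
    expect_equal(nrow(nb), 9L)
    expect_setequal(nb$codon, oracle_neighbors(cd))
    expect_equal(sum(nb$class == "transition"), 3L)
    expect_equal(sum(nb$class == "transversion"), 6L)
    # each neighbor differs in exactly the annotated position
    for (k in seq_len(9)) {
      diff_pos <- which(strsplit(cd, "")[[1]] !=
                          strsplit(nb$codon[k], "")[[1]])
      expect_equal(diff_pos, nb$position[k])
    }
  }
  expect_error(codonNeighbors("AXA"), "valid codon")
})

test_that("the neighbor relation is symmetric", {
  cc <- canonicalCode()
  all_codons <- names(codonAssignments(cc))
  for (cd in all_codons) {
    for (nb in codonNeighbors(cd)$codon) {
      expect_true(cd %in% codonNeighbors(nb)$codon)
    }
  }
})

test_that("transitions are within-purine or within-pyrimidine changes", {
  expect_true(isTransition("A", "G"))
  expect_true(isTransition("U", "C"))
  expect_true(isTransition("T", "C"))   # T accepted as U
  expect_false(isTransition("A", "C"))
  expect_false(isTransition("G", "U"))
  expect_error(isTransition("A", "A"), "distinct")
  expect_error(isTransition("A", "X"), "U, C, A, G")
})

test_that("model-1 random codes are uniform bijections over the blocks", {
  set.seed(42)
  canon_deg <- sort(unname(degeneracy(canonicalCode())))
  first_block_aa <- character(1000)
  for (k in 1:1000) {
    code <- randomPermutationCode()
    expect_true(validObject(code))
    expect_identical(stopCodons(code), c("UAA", "UAG", "UGA"))
    expect_identical(sort(unname(degeneracy(code))), canon_deg)
    expect_true(isPermutationCode(code))
    first_block_aa[k] <- codonAssignments(code)[["GCU"]]  # canonical Ala block
  }
  expect_equal(length(unique(first_block_aa)), 20L)
})

test_that("block-1 occupancy of model-1 codes is uniform (chi-square)", {
  # which amino acid lands on the canonical Ala block across 10,000 draws
  set.seed(7)
  occ <- vapply(1:10000,
                function(i) codonAssignments(randomPermutationCode())[["GCU"]],
                character(1))
  p <- chisq.test(table(occ), p = rep(1 / 20, 20))$p.value
  expect_gt(p, 0.01)
})

test_that("model-2 random codes satisfy the code invariants", {
  set.seed(43)
  sizes <- integer(0)
  for (k in 1:1000) {
    code <- randomReassignmentCode()
    expect_true(validObject(code))  # 3 stops, all 20 amino acids present
    expect_identical(stopCodons(code), c("UAA", "UAG", "UGA"))
    if (k <= 50) sizes <- c(sizes, max(degeneracy(code)))
  }
  # pigeonhole: 61 codons over 20 amino acids forces multi-codon families
  expect_true(all(sizes >= 2))
})

test_that("a model-1 code lies inside the model-2 space", {
  set.seed(44)
  code <- randomPermutationCode()
  # same invariants enforced on model-2 codes hold, and the reassignment
  # operator accepts it
  expect_true(validObject(code))
  expect_s4_class(reassignmentOperator(code), "GeneticCode")
})

test_that("the code-space count for model 1 is 20!", {
  expect_identical(codeSpaceSize(1), factorial(20))
  expect_equal(signif(codeSpaceSize(1), 3), 2.43e18)
  # model-2 space (surjections of 61 sense codons onto 20 amino acids)
  # strictly contains the 20! permutation codes
  expect_gt(codeSpaceSize(2), codeSpaceSize(1))
})
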