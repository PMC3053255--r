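# code model: constructors, the canonical code, codon arithmetic, and the
# random-code generators for the two models of hypothetical codes.

#' Construct a GeneticCode
#'
#' @param x one of: a single 64-character string of amino-acid one-letter
#'   codes with `"*"` for stop, in the package codon order (first base
#'   slowest, base order U, C, A, G); an unnamed character vector of length
#'   64 in that order; or a character vector named by codons (T accepted as
#'   a synonym of U in names).
#' @return a validated [GeneticCode][GeneticCode-class].
#' @examples
#' identical(geneticCode(codeString(canonicalCode())), canonicalCode())
#' @export
geneticCode <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (nchar(x) != 64L)
      stop("code string must have exactly 64 characters, got ", nchar(x))
    x <- strsplit(x, "")[[1]]
  }
  if (!is.character(x) || length(x) != 64L)
    stop("a genetic code needs one label for each of the 64 codons")
  if (is.null(names(x))) {
    names(x) <- .CODONS
  } else {
    names(x) <- chartr("Tt", "Uu", toupper(names(x)))
    if (!setequal(names(x), .CODONS))
      stop("codon names must be the 64 RNA codons")
    x <- x[.CODONS]
  }
  new("GeneticCode", assignment = x)
}

#' The canonical (standard) genetic code
#'
#' @return the standard genetic code as a [GeneticCode][GeneticCode-class]:
#'   stop on UAA, UAG and UGA, the usual degeneracy pattern (e.g. 6 codons
#'   for Leu, 1 for Met and Trp).
#' @examples
#' stopCodons(canonicalCode())
#' @export
canonicalCode <- function() geneticCode(.CANONICAL_STRING)

#' @name accessors
#' @title Accessors for code-model objects
#' @description `codeString` returns the 64-character serialization of a
#'   code; `stopCodons` its stop codons; `codonAssignments` the full named
#'   codon-to-label vector; `degeneracy` the number of codons per amino acid;
#'   `propertyValues` the named value vector of a scale; `weightMatrix` the
#'   3 x 2 weight matrix.
#' @param x the object.
#' @return see description.
NULL

setMethod("codeString", "GeneticCode",
          function(x) paste(x@assignment, collapse = ""))
setMethod("stopCodons", "GeneticCode",
          function(x) names(x@assignment)[x@assignment == .STOP_CHAR])
setMethod("codonAssignments", "GeneticCode", function(x) x@assignment)
setMethod("degeneracy", "GeneticCode", function(x) {
  a <- x@assignment
  vapply(.AA_LETTERS, function(aa) sum(a == aa), integer(1))
})
setMethod("propertyValues", "PropertyScale", function(x) x@values)
setMethod("weightMatrix", "MistranslationWeights", function(x) x@weights)

#' Is a base change a transition?
#'
#' A transition swaps the two purines (A, G) or the two pyrimidines (U, C);
#' every other change is a transversion.
#'
#' @param a,b distinct nucleotides from U, C, A, G (T accepted as U).
#' @return logical.
#' @examples
#' isTransition("A", "G")  # TRUE
#' isTransition("A", "C")  # FALSE
#' @export
isTransition <- function(a, b) {
  ai <- match(chartr("T", "U", toupper(a)), .BASES)
  bi <- match(chartr("T", "U", toupper(b)), .BASES)
  if (anyNA(ai) || anyNA(bi))
    stop("bases must be one of U, C, A, G")
  if (any(ai == bi))
    stop("a mutation requires two distinct bases")
  .is_purine_idx(ai) == .is_purine_idx(bi)
}

#' Single-base neighbors of a codon
#'
#' @param codon a 3-letter RNA codon (T accepted as U).
#' @return a data.frame with 9 rows (3 positions x 3 alternative bases):
#'   `codon` (the neighbor), `position` (mutated position, 1-3) and `class`
#'   (`"transition"` or `"transversion"`).
#' @examples
#' codonNeighbors("AAA")
#' @export
codonNeighbors <- function(codon) {
  i <- match(chartr("Tt", "Uu", toupper(codon)), .CODONS)
  if (is.na(i))
    stop("not a valid codon: ", codon)
  k <- which(.NB$i == i)
  data.frame(codon = .CODONS[.NB$j[k]],
             position = .NB$pos[k],
             class = c("transition", "transversion")[.NB$class[k]],
             stringsAsFactors = FALSE)
}

#' The canonical synonym-block structure
#'
#' The 64 codons partitioned into the 21 canonical sets: for each amino acid
#' the set of all codons encoding it in the standard code, plus the stop set.
#' Model-1 hypothetical codes keep this partition fixed and only permute
#' which amino acid sits on which of the 20 sense blocks.
#'
#' @return a named list of 21 character vectors of codons; the first 20
#'   elements are named by amino acid (alphabetical one-letter order) and
#'   the last, `"*"`, is the stop set.
#' @export
blockStructure <- function() {
  out <- lapply(.BLOCK_CODONS, function(ix) .CODONS[ix])
  names(out) <- .AA_LETTERS
  c(out, list("*" = .CANONICAL_STOPS))
}

# build a GeneticCode from a model-1 permutation (block k -> aa perm[k])
.code_from_perm <- function(perm) {
  idx <- rep(.STOP_IDX, 64L)
  for (k in seq_len(20L)) idx[.BLOCK_CODONS[[k]]] <- perm[k]
  geneticCode(.LABELS[idx])
}

# recover the permutation of a model-1 code (error if blocks are not uniform)
.perm_of_code <- function(code) {
  a <- code@assignment
  perm <- integer(20L)
  for (k in seq_len(20L)) {
    lab <- unique(a[.BLOCK_CODONS[[k]]])
    if (length(lab) != 1L || lab == .STOP_CHAR)
      stop("not a model-1 code: canonical block ", .AA_LETTERS[k],
           " does not carry a single amino acid")
    perm[k] <- match(lab, .AA_LETTERS)
  }
  if (!identical(stopCodons(code), .CANONICAL_STOPS))
    stop("not a model-1 code: stop codons are not at canonical positions")
  perm
}

#' Is a code a model-1 (permutation) code?
#'
#' Model-1 codes keep the canonical block structure and stop positions and
#' assign one amino acid per block (a bijection onto the 20 sense blocks).
#'
#' @param code a [GeneticCode][GeneticCode-class].
#' @return logical.
#' @export
isPermutationCode <- function(code) {
  !inherits(try(.perm_of_code(code), silent = TRUE), "try-error")
}

#' Random hypothetical codes, model 1 (amino-acid permutations)
#'
#' Draws a code uniformly from the 20! permutation codes: the canonical
#' synonym-block structure and stop codons are kept and the 20 amino acids
#' are assigned to the 20 sense blocks by a uniformly random bijection.
#' Uses the current R random number generator state (call `set.seed()` for
#' reproducibility).
#'
#' @return a [GeneticCode][GeneticCode-class].
#' @examples
#' set.seed(1)
#' degeneracy(randomPermutationCode())  # same multiset of sizes as canonical
#' @export
randomPermutationCode <- function() .code_from_perm(sample.int(20L))

#' Random hypothetical codes, model 2 (unconstrained sense assignments)
#'
#' Draws a code uniformly from all assignments of the 61 sense codons to the
#' 20 amino acids that use every amino acid at least once (rejection
#' sampling); the 3 stop codons stay at their canonical positions.  This is
#' the space explored by the codon-reassignment model; it contains every
#' model-1 code.
#'
#' @param stopCodons the 3 codons reserved for stop (default canonical:
#'   UAA, UAG, UGA).
#' @return a [GeneticCode][GeneticCode-class].
#' @export
randomReassignmentCode <- function(stopCodons = .CANONICAL_STOPS) {
  st <- .stop_set(stopCodons)
  repeat {
    draw <- sample.int(20L, 61L, replace = TRUE)
    if (length(unique(draw)) == 20L) break
  }
  idx <- rep(.STOP_IDX, 64L)
  idx[setdiff(seq_len(64L), match(st, .CODONS))] <- draw
  geneticCode(.LABELS[idx])
}

.stop_set <- function(stopCodons) {
  st <- chartr("Tt", "Uu", toupper(stopCodons))
  if (length(st) != 3L || anyNA(match(st, .CODONS)) || anyDuplicated(st))
    stop("stopCodons must be 3 distinct valid codons")
  st
}

#' Number of distinct hypothetical codes
#'
#' For model 1 the code space is the 20! (about 2.43e18) bijections of the
#' amino acids onto the canonical sense blocks.  For model 2 it is the number
#' of surjections of the 61 sense codons onto the 20 amino acids
#' (inclusion-exclusion).
#'
#' @param model 1 or 2.
#' @return a numeric count (exact for model 1, where 20! is exactly
#'   representable as a double).
#' @examples
#' codeSpaceSize(1)  # 20! = 2.43e18
#' @export
codeSpaceSize <- function(model = 1) {
  model <- as.integer(model)
  if (model == 1L) return(factorial(20))
  if (model == 2L) {
    k <- 0:20
    return(sum((-1)^k * choose(20, k) * (20 - k)^61))
  }
  stop("model must be 1 or 2")
}
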