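# fitness: the MS and tMS error statistics, plus the vectorized population
# fitness engine shared by the genetic algorithm and the random-code sampler.

#' Construct a PropertyScale
#'
#' @param values named numeric of length 20, names = amino-acid one-letter
#'   codes.
#' @return a validated [PropertyScale][PropertyScale-class].
#' @export
propertyScale <- function(values) {
  v <- as.numeric(values)
  names(v) <- names(values)
  v <- v[.AA_LETTERS]
  names(v) <- .AA_LETTERS
  new("PropertyScale", values = v)
}

#' The embedded Woese polar requirement scale
#'
#' Polar requirement is a hydrophobicity-related property of amino acids
#' derived from their partitioning in a water/pyrimidine system; it is the
#' property scale classically used to score genetic-code error minimization.
#'
#' @return a [PropertyScale][PropertyScale-class].
#' @export
polarRequirement <- function() propertyScale(.POLAR_REQUIREMENT)

#' Construct MistranslationWeights
#'
#' @param transitions,transversions numeric length-3 vectors of weights for
#'   codon positions 1-3.  Defaults are the empirical mistranslation
#'   quantification: transitions (1, 0.5, 1), transversions (0.5, 0.1, 1).
#' @return a validated
#'   [MistranslationWeights][MistranslationWeights-class].
#' @export
mistranslationWeights <- function(transitions = c(1, 0.5, 1),
                                  transversions = c(0.5, 0.1, 1)) {
  w <- matrix(as.numeric(c(transitions, transversions)), nrow = 3L,
              dimnames = dimnames(.DEFAULT_WEIGHTS))
  new("MistranslationWeights", weights = w)
}

# amino-acid index (1..20, 21 = stop) of each codon of a code
.aa_idx <- function(code) match(code@assignment, .LABELS)

setMethod("substitutionEvents", "GeneticCode", function(code) {
  idx <- .aa_idx(code)
  keep <- idx[.NB$i] != .STOP_IDX & idx[.NB$j] != .STOP_IDX
  data.frame(from = .LABELS[idx[.NB$i[keep]]],
             to = .LABELS[idx[.NB$j[keep]]],
             position = .NB$pos[keep],
             class = c("transition", "transversion")[.NB$class[keep]],
             stringsAsFactors = FALSE)
})

# shared core: weighted mean of squared property differences over all
# ordered sense-sense neighbor pairs of `code`
.delta2 <- function(code, scale, wmat = NULL) {
  idx <- .aa_idx(code)
  x <- propertyValues(scale)[.AA_LETTERS]
  keep <- which(idx[.NB$i] != .STOP_IDX & idx[.NB$j] != .STOP_IDX)
  if (!length(keep))
    stop("degenerate code: no substitution events between sense codons")
  d2 <- (x[idx[.NB$i[keep]]] - x[idx[.NB$j[keep]]])^2
  if (is.null(wmat))
    return(sum(d2) / length(d2))
  w <- wmat[cbind(.NB$pos[keep], .NB$class[keep])]
  tw <- sum(w)
  if (tw == 0)
    stop("all event weights are zero: weighted mean undefined")
  sum(w * d2) / tw
}

setMethod("ms", "GeneticCode", function(code, scale = polarRequirement(), ...)
  .delta2(code, scale))

setMethod("tms", "GeneticCode",
          function(code, scale = polarRequirement(),
                   weights = mistranslationWeights(), ...)
  .delta2(code, scale, weightMatrix(weights)))

# ---- vectorized population fitness -----------------------------------------
#
# Model-1 individuals are 20-long permutations (block -> amino-acid index);
# fitness reduces to a quadratic form over block pairs, aggregated once per
# run.  Model-2 individuals are 61-long amino-acid index vectors over the
# sense codons; fitness sums over the fixed sense-sense pair list of the
# stop-codon layout.

# per-pair weight vector for a sense structure under MS (all ones) or tMS
.pair_weights <- function(ss, wmat = NULL) {
  if (is.null(wmat)) rep(1, length(ss$pair_i))
  else wmat[cbind(ss$pair_pos, ss$pair_class)]
}

# aggregate canonical sense pairs to block pairs: list(bi, bj, w, total)
.block_agg <- function(wmat = NULL) {
  ss <- .CANONICAL_SENSE
  w <- .pair_weights(ss, wmat)
  bi <- .BLOCK_OF_CODON[ss$sense[ss$pair_i]]
  bj <- .BLOCK_OF_CODON[ss$sense[ss$pair_j]]
  key <- (bi - 1L) * 20L + bj
  agg <- rowsum(w, key)
  keys <- as.integer(rownames(agg))
  list(bi = (keys - 1L) %/% 20L + 1L, bj = (keys - 1L) %% 20L + 1L,
       w = as.numeric(agg), total = sum(w))
}

# fitness of a 20 x n matrix of model-1 permutations
.fitness_perm <- function(perm, x, agg) {
  n <- ncol(perm)
  xp <- matrix(x[perm], nrow = 20L, ncol = n)
  d2 <- (xp[agg$bi, , drop = FALSE] - xp[agg$bj, , drop = FALSE])^2
  as.numeric(colSums(d2 * agg$w)) / agg$total
}

# fitness of a 61 x n matrix of model-2 sense assignments
.fitness_sense <- function(assign, x, ss, w, total) {
  n <- ncol(assign)
  xm <- matrix(x[assign], nrow = nrow(assign), ncol = n)
  d2 <- (xm[ss$pair_i, , drop = FALSE] - xm[ss$pair_j, , drop = FALSE])^2
  as.numeric(colSums(d2 * w)) / total
}
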