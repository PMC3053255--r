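# evolution: variation operators, tournament selection, and the genetic
# algorithm that searches for better-adapted codes.

#' Construct an EvolutionConfig
#'
#' @param model 1 (amino-acid permutations over the canonical blocks, varied
#'   by the swap operator) or 2 (codon-reassignment codes, varied by the
#'   reassignment operator).
#' @param fitnessKind `"MS"` or `"tMS"`.
#' @param populationSize population size (default 1000).
#' @param tournamentFraction tournament window as a fraction of the
#'   population (default 0.03, i.e. a window of 30 at the default size).
#' @param generations maximum generations per run; defaults to 100 for
#'   model 1 and 300 for model 2 (model-2 search needs more generations).
#' @param plateau end a run early after this many generations without
#'   improvement of the best fitness (default 25).
#' @param replicates number of independent runs (default 50).
#' @param seed base seed; replicate `r` uses a seed derived from it, so
#'   replicates are independent and individually reproducible.
#' @param operatorProbability probability of applying the variation operator
#'   to each non-elite offspring (default 1: every offspring is varied once).
#' @param scale,weights fitness ingredients; defaults are the polar
#'   requirement scale and the embedded mistranslation weights.
#' @return a validated [EvolutionConfig][EvolutionConfig-class].
#' @export
evolutionConfig <- function(model = 1, fitnessKind = c("MS", "tMS"),
                            populationSize = 1000,
                            tournamentFraction = 0.03,
                            generations = NULL, plateau = 25,
                            replicates = 50, seed = 1,
                            operatorProbability = 1,
                            scale = polarRequirement(),
                            weights = mistranslationWeights()) {
  fitnessKind <- match.arg(fitnessKind)
  model <- as.integer(model)
  if (is.null(generations))
    generations <- if (identical(model, 2L)) 300L else 100L
  new("EvolutionConfig", model = model, fitnessKind = fitnessKind,
      populationSize = as.integer(populationSize),
      tournamentFraction = as.numeric(tournamentFraction),
      generations = as.integer(generations), plateau = as.integer(plateau),
      replicates = as.integer(replicates), seed = as.integer(seed),
      operatorProbability = as.numeric(operatorProbability),
      scale = scale, weights = weights)
}

.tournament_window <- function(config)
  max(1L, as.integer(round(config@tournamentFraction *
                             config@populationSize)))

.derive_seed <- function(seed, r) {
  s <- (as.numeric(seed) %% 2147483647) * 1000003 + as.numeric(r) * 7919
  as.integer(s %% 2147483647) + 1L
}

#' Swap operator (model 1)
#'
#' Exchanges the amino acids carried by two canonical synonym blocks of a
#' model-1 code; all other blocks are unchanged.  The operator is an
#' involution (`swap(swap(c, i, j), i, j) == c`) and `swap(c, i, i) == c`.
#'
#' @param code a model-1 [GeneticCode][GeneticCode-class].
#' @param i,j block indices in 1..20 (blocks ordered by the canonical amino
#'   acid in alphabetical one-letter order, as in [blockStructure()]).
#' @return a new [GeneticCode][GeneticCode-class]; the input is unmodified.
#' @export
swapOperator <- function(code, i, j) {
  i <- as.integer(i); j <- as.integer(j)
  if (is.na(i) || is.na(j) || i < 1L || i > 20L || j < 1L || j > 20L)
    stop("block indices must lie in 1..20")
  perm <- .perm_of_code(code)
  perm[c(i, j)] <- perm[c(j, i)]
  .code_from_perm(perm)
}

#' Reassignment operator (model 2)
#'
#' Models natural codon reassignments: a random sense codon is chosen and
#' its amino acid is copied onto a randomly chosen sense codon differing in
#' exactly one base.  If the amino acid about to be overwritten is the only
#' instance of that amino acid in the code, the operator is not applied and
#' the code is returned unchanged (this guard keeps all 20 amino acids in
#' the code).  Stop codons are never sources or targets.  Uses the current
#' R random number generator state.
#'
#' @param code a [GeneticCode][GeneticCode-class].
#' @return a [GeneticCode][GeneticCode-class] differing from the input at a
#'   single codon, or the input code itself when the guard fires.
#' @export
reassignmentOperator <- function(code) {
  a <- code@assignment
  sense <- which(a != .STOP_CHAR)
  s <- sense[sample.int(length(sense), 1L)]
  nb <- .NB$j[.NB$i == s]
  nb <- nb[a[nb] != .STOP_CHAR]
  if (!length(nb)) return(code)
  t <- nb[sample.int(length(nb), 1L)]
  if (sum(a == a[t]) == 1L) return(code)
  a[t] <- a[s]
  geneticCode(a)
}

#' Tournament selection
#'
#' Draws `window` individuals uniformly with replacement and returns the
#' index of the fittest (minimum fitness); ties are broken toward the lowest
#' population index among the tied draws.  Uses the current R random number
#' generator state.
#'
#' @param fitnesses numeric vector of fitness values (lower is better).
#' @param window tournament size, between 1 and `length(fitnesses)`.
#' @return the selected index.
#' @export
tournamentSelect <- function(fitnesses, window) {
  n <- length(fitnesses)
  if (n < 1L) stop("empty population")
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window > n)
    stop("window must lie in 1..length(fitnesses)")
  draws <- sample.int(n, window, replace = TRUE)
  f <- fitnesses[draws]
  min(draws[f == min(f)])
}

# ---- vectorized operators on population matrices ---------------------------

.op_swap_pop <- function(off, cols) {
  n <- length(cols)
  if (!n) return(off)
  i <- sample.int(20L, n, replace = TRUE)
  j <- sample.int(19L, n, replace = TRUE)
  j <- j + (j >= i)                      # distinct pair, uniform
  li <- (cols - 1L) * 20L + i
  lj <- (cols - 1L) * 20L + j
  tmp <- off[li]
  off[li] <- off[lj]
  off[lj] <- tmp
  off
}

.op_reassign_pop <- function(off, cols, ss) {
  n <- length(cols)
  if (!n) return(off)
  ns <- nrow(off)
  s <- sample.int(ns, n, replace = TRUE)
  u <- floor(stats::runif(n) * ss$nb_deg[s]) + 1L
  t <- ss$nb_mat[cbind(u, s)]
  ls <- (cols - 1L) * ns + s
  lt <- (cols - 1L) * ns + t
  ta <- off[lt]
  # occurrence count of each target amino acid within its own individual
  cnt <- colSums(off[, cols, drop = FALSE] ==
                   matrix(ta, nrow = ns, ncol = n, byrow = TRUE))
  ok <- cnt > 1L                         # sole-instance guard
  off[lt[ok]] <- off[ls[ok]]
  off
}

.init_pop_perm <- function(p) replicate(p, sample.int(20L))

.init_pop_sense <- function(p, nsense = 61L) {
  pop <- matrix(sample.int(20L, nsense * p, replace = TRUE), nsense, p)
  repeat {
    present <- Reduce(`&`, lapply(seq_len(20L),
                                  function(k) colSums(pop == k) > 0L))
    bad <- which(!present)
    if (!length(bad)) break
    pop[, bad] <- sample.int(20L, nsense * length(bad), replace = TRUE)
  }
  pop
}

# GeneticCode from a 61-long sense assignment under a sense structure
.code_from_sense <- function(assign, ss) {
  idx <- rep(.STOP_IDX, 64L)
  idx[ss$sense] <- assign
  geneticCode(.LABELS[idx])
}

#' Evolve genetic codes toward lower error
#'
#' Runs the genetic algorithm described by `config`: each replicate starts
#' from a random population of the chosen model, and every generation the
#' single best individual is carried over unchanged (elitism) while the rest
#' of the next generation is produced by tournament selection followed by
#' one application of the model's variation operator (swap for model 1,
#' codon reassignment for model 2) with probability
#' `operatorProbability`.  A run ends at `generations` or when the best
#' fitness has not improved for `plateau` consecutive generations.
#'
#' @param config an [EvolutionConfig][EvolutionConfig-class].
#' @param verbose log best/mean fitness per generation via [message()].
#' @return an [EvolutionTrace][EvolutionTrace-class] with per-generation
#'   best/mean fitness for each replicate, the final best fitness values,
#'   and the final best codes.
#' @examples
#' tr <- evolveCodes(evolutionConfig(model = 1, populationSize = 50,
#'                                   generations = 20, replicates = 2,
#'                                   seed = 7))
#' bestValues(tr)
#' @export
evolveCodes <- function(config, verbose = FALSE) {
  stopifnot(is(config, "EvolutionConfig"))
  validObject(config)
  x <- propertyValues(config@scale)[.AA_LETTERS]
  wmat <- if (config@fitnessKind == "tMS") weightMatrix(config@weights)
          else NULL
  p <- config@populationSize
  win <- .tournament_window(config)
  ss <- .CANONICAL_SENSE
  if (config@model == 1L) {
    agg <- .block_agg(wmat)
    evalpop <- function(pop) .fitness_perm(pop, x, agg)
    init <- function() .init_pop_perm(p)
    vary <- function(off, cols) .op_swap_pop(off, cols)
    tocode <- function(ind) .code_from_perm(ind)
  } else {
    w <- .pair_weights(ss, wmat)
    tw <- sum(w)
    evalpop <- function(pop) .fitness_sense(pop, x, ss, w, tw)
    init <- function() .init_pop_sense(p)
    vary <- function(off, cols) .op_reassign_pop(off, cols, ss)
    tocode <- function(ind) .code_from_sense(ind, ss)
  }

  nr <- config@replicates
  best_l <- mean_l <- codes <- vector("list", nr)
  bvals <- numeric(nr)
  for (r in seq_len(nr)) {
    set.seed(.derive_seed(config@seed, r))
    pop <- init()
    fit <- evalpop(pop)
    gmax <- config@generations
    btr <- mtr <- numeric(gmax + 1L)
    best_so_far <- Inf
    stale <- 0L
    gen <- 0L
    repeat {
      eb <- which.min(fit)
      btr[gen + 1L] <- fit[eb]
      mtr[gen + 1L] <- mean(fit)
      if (verbose)
        message(sprintf("replicate %d generation %d: best %.4f mean %.4f",
                        r, gen, fit[eb], mtr[gen + 1L]))
      if (fit[eb] < best_so_far) {
        best_so_far <- fit[eb]
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (gen >= gmax || stale >= config@plateau) break
      gen <- gen + 1L

      m <- p - 1L
      draws <- matrix(sample.int(p, win * m, replace = TRUE), nrow = win)
      fd <- matrix(fit[draws], nrow = win)
      low <- fd[1L, ]
      if (win > 1L)
        for (k in 2:win) low <- pmin(low, fd[k, ])
      winner <- rep(Inf, m)
      for (k in seq_len(win))
        winner <- pmin(winner, ifelse(fd[k, ] <= low, draws[k, ], Inf))
      winner <- as.integer(winner)

      off <- pop[, winner, drop = FALSE]
      cols <- if (config@operatorProbability < 1)
        which(stats::runif(m) < config@operatorProbability)
      else seq_len(m)
      off <- vary(off, cols)
      pop <- cbind(pop[, eb, drop = FALSE], off)
      fit <- c(fit[eb], evalpop(off))
    }
    best_l[[r]] <- btr[seq_len(gen + 1L)]
    mean_l[[r]] <- mtr[seq_len(gen + 1L)]
    fb <- which.min(fit)
    bvals[r] <- fit[fb]
    codes[[r]] <- tocode(pop[, fb])
  }
  new("EvolutionTrace", best = best_l, meanFit = mean_l,
      bestValues = bvals, bestCodes = codes, config = config)
}

#' @name trace-accessors
#' @title Accessors for EvolutionTrace objects
#' @description `bestValues` returns the final best fitness of each
#'   replicate; `bestCodes` the final best code of each replicate;
#'   `bestCode` the single best code over all replicates; `traceSummary` a
#'   data.frame of per-generation best and mean fitness averaged over
#'   replicates (runs that plateaued early are carried forward at their
#'   final values, which elitism makes exact for the best-fitness curve).
#' @param x an [EvolutionTrace][EvolutionTrace-class].
#' @return see description.
NULL

setMethod("bestValues", "EvolutionTrace", function(x) x@bestValues)
setMethod("bestCodes", "EvolutionTrace", function(x) x@bestCodes)
setMethod("bestCode", "EvolutionTrace",
          function(x) x@bestCodes[[which.min(x@bestValues)]])
setMethod("traceSummary", "EvolutionTrace", function(x) {
  gmax <- max(lengths(x@best))
  pad <- function(v) c(v, rep(v[length(v)], gmax - length(v)))
  bm <- rowMeans(vapply(x@best, pad, numeric(gmax)))
  mm <- rowMeans(vapply(x@meanFit, pad, numeric(gmax)))
  data.frame(generation = seq_len(gmax) - 1L, best = bm, mean = mm)
})

#' @rdname trace-accessors
#' @export
traceConfig <- function(x) x@config
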