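#' @import methods
NULL

#' GeneticCode: an assignment of the 64 codons to amino acids and stop
#'
#' A `GeneticCode` maps each of the 64 RNA codons to one of the 20 standard
#' amino acids (one-letter code) or to the stop signal (`"*"`).  Every valid
#' code carries exactly 3 stop codons and uses all 20 amino acids at least
#' once, mirroring the constraints under which hypothetical alternative codes
#' are generated and evolved.
#'
#' @slot assignment named character vector of length 64; names are the codons
#'   in the package's fixed enumeration order (first base slowest, base order
#'   U, C, A, G), values are amino-acid one-letter codes or `"*"`.
#'
#' @seealso [canonicalCode()], [randomPermutationCode()],
#'   [randomReassignmentCode()], [parseCodeTable()]
#' @export
setClass("GeneticCode", representation(assignment = "character"))

setValidity("GeneticCode", function(object) {
  a <- object@assignment
  if (length(a) != 64L)
    return("assignment must cover exactly 64 codons")
  if (!identical(names(a), .CODONS))
    return("assignment names must be the 64 codons in U/C/A/G base1-major order")
  bad <- setdiff(unique(a), .LABELS)
  if (length(bad))
    return(paste0("illegal label(s): ", paste(bad, collapse = ", ")))
  if (sum(a == .STOP_CHAR) != 3L)
    return("a code must have exactly 3 stop codons")
  missing_aa <- setdiff(.AA_LETTERS, a)
  if (length(missing_aa))
    return(paste0("amino acid(s) absent from code: ",
                  paste(missing_aa, collapse = ", ")))
  TRUE
})

#' PropertyScale: an amino-acid property scale
#'
#' Maps each of the 20 standard amino acids to a real property value.  The
#' package's embedded default is the Woese polar requirement scale
#' (dimensionless, derived from water/pyrimidine partitioning), the property
#' used by the load-minimization literature.
#'
#' @slot values named numeric of length 20 (names are one-letter amino-acid
#'   codes), all finite.
#' @seealso [polarRequirement()], [propertyScale()]
#' @export
setClass("PropertyScale", representation(values = "numeric"))

setValidity("PropertyScale", function(object) {
  v <- object@values
  if (length(v) != 20L || !setequal(names(v), .AA_LETTERS))
    return("scale must assign a value to each of the 20 standard amino acids")
  if (!all(is.finite(v)))
    return("all property values must be finite")
  TRUE
})

#' MistranslationWeights: per-position, per-class substitution weights
#'
#' Weights the contribution of a single-base substitution to the tMS error
#' by codon position (1-3) and mutation class (transition or transversion),
#' modeling the empirical mistranslation biases of the three codon bases.
#' The defaults are transitions (1, 0.5, 1) and transversions (0.5, 0.1, 1)
#' for positions 1, 2, 3.
#'
#' @slot weights 3 x 2 numeric matrix, rows = codon positions 1-3, columns =
#'   `transition`, `transversion`; all entries nonnegative and finite, not
#'   all zero.
#' @seealso [mistranslationWeights()], [tms()]
#' @export
setClass("MistranslationWeights", representation(weights = "matrix"))

setValidity("MistranslationWeights", function(object) {
  w <- object@weights
  if (!is.numeric(w) || !identical(dim(w), c(3L, 2L)))
    return("weights must be a 3 x 2 numeric matrix (positions x classes)")
  if (!all(is.finite(w)) || any(w < 0))
    return("weights must be finite and nonnegative")
  if (all(w == 0))
    return("weights must not be all zero (weighted mean undefined)")
  TRUE
})

#' EvolutionConfig: parameters of a code-evolution experiment
#'
#' @slot model integer, 1 (amino-acid permutations over the canonical block
#'   structure) or 2 (codon-reassignment codes).
#' @slot fitnessKind `"MS"` or `"tMS"`.
#' @slot populationSize positive integer (default 1000).
#' @slot tournamentFraction fraction of the population drawn into each
#'   tournament window, in (0, 1] (default 0.03; window =
#'   `max(1, round(fraction * populationSize))`).
#' @slot generations maximum generations per run.
#' @slot plateau stop a run early after this many generations without
#'   improvement of the best fitness (default 25).
#' @slot replicates number of independent runs (default 50).
#' @slot seed base seed; replicate r runs on a derived stream seed.
#' @slot operatorProbability probability that a non-elite offspring receives
#'   one application of the model's variation operator (default 1).
#' @slot scale the [PropertyScale][PropertyScale-class] used by the fitness.
#' @slot weights the [MistranslationWeights][MistranslationWeights-class]
#'   used when `fitnessKind == "tMS"`.
#' @seealso [evolutionConfig()], [evolveCodes()]
#' @export
setClass("EvolutionConfig",
         representation(model = "integer", fitnessKind = "character",
                        populationSize = "integer",
                        tournamentFraction = "numeric",
                        generations = "integer", plateau = "integer",
                        replicates = "integer", seed = "integer",
                        operatorProbability = "numeric",
                        scale = "PropertyScale",
                        weights = "MistranslationWeights"))

setValidity("EvolutionConfig", function(object) {
  if (!object@model %in% c(1L, 2L)) return("model must be 1 or 2")
  if (!object@fitnessKind %in% c("MS", "tMS"))
    return("fitnessKind must be 'MS' or 'tMS'")
  if (object@populationSize < 2L) return("populationSize must be >= 2")
  if (object@tournamentFraction <= 0 || object@tournamentFraction > 1)
    return("tournamentFraction must be in (0, 1]")
  if (object@generations < 1L) return("generations must be >= 1")
  if (object@plateau < 1L) return("plateau must be >= 1")
  if (object@replicates < 1L) return("replicates must be >= 1")
  if (object@operatorProbability < 0 || object@operatorProbability > 1)
    return("operatorProbability must be in [0, 1]")
  TRUE
})

#' EvolutionTrace: the record of a code-evolution experiment
#'
#' @slot best list (one numeric vector per replicate) of best fitness per
#'   generation; generation 0 is the initial population.  With elitism each
#'   vector is non-increasing.
#' @slot meanFit list of mean population fitness per generation, same shape.
#' @slot bestValues numeric, the final best fitness of each replicate.
#' @slot bestCodes list of [GeneticCode][GeneticCode-class], the final best
#'   code of each replicate.
#' @slot config the [EvolutionConfig][EvolutionConfig-class] that produced
#'   the trace.
#' @seealso [evolveCodes()], [traceSummary()], [bestValues()]
#' @export
setClass("EvolutionTrace",
         representation(best = "list", meanFit = "list",
                        bestValues = "numeric", bestCodes = "list",
                        config = "EvolutionConfig"))

#' FitnessSample: error values of a sample of random codes
#'
#' @slot values numeric vector of MS/tMS values, all nonnegative.
#' @slot model integer model of the generating process (1 or 2).
#' @slot fitnessKind `"MS"` or `"tMS"`.
#' @seealso [sampleRandomCodes()], [fractionBetter()], [fitnessHistogram()]
#' @export
setClass("FitnessSample",
         representation(values = "numeric", model = "integer",
                        fitnessKind = "character"))

setValidity("FitnessSample", function(object) {
  if (any(object@values < 0)) return("error values must be nonnegative")
  TRUE
})

#' PdmResult: percentage distance minimization of a code
#'
#' p.d.m. = 100 * (delta_mean - delta_code) / (delta_mean - delta_low) places
#' a code on a linear scale between the mean of random codes (0%) and the
#' best code found (100%).
#'
#' @slot deltaMean average error of random codes.
#' @slot deltaCode error of the code under study (usually the canonical code).
#' @slot deltaLow best (lowest) error found, e.g. by the genetic algorithm.
#' @seealso [pdm()]
#' @export
setClass("PdmResult",
         representation(deltaMean = "numeric", deltaCode = "numeric",
                        deltaLow = "numeric"))

setValidity("PdmResult", function(object) {
  if (object@deltaMean <= object@deltaLow)
    return("deltaMean must exceed deltaLow (p.d.m. scale undefined otherwise)")
  TRUE
})

setMethod("show", "GeneticCode", function(object) {
  a <- object@assignment
  cat("GeneticCode (64 codons; ", sum(a == .STOP_CHAR), " stops: ",
      paste(names(a)[a == .STOP_CHAR], collapse = " "), ")\n", sep = "")
  cat(" ", .CANONICAL_STRING_HEADER, "\n", sep = "")
  cat(" ", paste(a, collapse = ""), "\n", sep = "")
})

# shown above the 64-character string so a reader can line codons up
.CANONICAL_STRING_HEADER <- "codon order: UUU UUC UUA UUG UCU ... GGG (base1-major, U C A G)"

setMethod("show", "PropertyScale", function(object) {
  cat("PropertyScale over the 20 standard amino acids\n")
  print(round(object@values, 3))
})

setMethod("show", "MistranslationWeights", function(object) {
  cat("MistranslationWeights (codon position x mutation class)\n")
  print(object@weights)
})

setMethod("show", "EvolutionConfig", function(object) {
  cat("EvolutionConfig: model ", object@model, ", fitness ",
      object@fitnessKind, "\n", sep = "")
  cat("  population ", object@populationSize, ", tournament ",
      format(100 * object@tournamentFraction), "% (window ",
      .tournament_window(object), "), elitism, operator p = ",
      format(object@operatorProbability), "\n", sep = "")
  cat("  up to ", object@generations, " generations (plateau ",
      object@plateau, "), ", object@replicates, " replicate(s), seed ",
      object@seed, "\n", sep = "")
})

setMethod("show", "EvolutionTrace", function(object) {
  cat("EvolutionTrace: ", length(object@best), " replicate(s), model ",
      object@config@model, ", fitness ", object@config@fitnessKind,
      "\n", sep = "")
  cat("  best-of-run: mean ", format(mean(object@bestValues), digits = 5),
      ", sd ", format(stats::sd(object@bestValues), digits = 3),
      ", min ", format(min(object@bestValues), digits = 5), "\n", sep = "")
  cat("  generations per run: ",
      paste(range(lengths(object@best) - 1L), collapse = "-"), "\n", sep = "")
})

setMethod("show", "FitnessSample", function(object) {
  cat("FitnessSample: ", length(object@values), " model-", object@model,
      " codes, ", object@fitnessKind, "\n", sep = "")
  print(summary(object@values))
})

setMethod("show", "PdmResult", function(object) {
  cat("p.d.m. = ", format(pdmValue(object), digits = 4), "%  (delta_mean = ",
      format(object@deltaMean, digits = 5), ", delta_code = ",
      format(object@deltaCode, digits = 5), ", delta_low = ",
      format(object@deltaLow, digits = 5), ")\n", sep = "")
})
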