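# stats: random-code sampling (statistical approach), histograms, the
# percentage-distance-minimization statistic (engineering approach), and
# quantitative proxies for the two regularity patterns of optimized codes.

#' Sample random hypothetical codes and score them
#'
#' Draws `n` independent codes from the chosen model's random generator and
#' scores each with MS or tMS.  This is the "many randomly generated
#' alternative codes" ingredient of both optimality measures: the fraction
#' of random codes beating the canonical code (statistical approach) and
#' the random-code mean entering the p.d.m. (engineering approach).
#'
#' @param n number of codes.
#' @param model 1 or 2.
#' @param fitnessKind `"MS"` or `"tMS"`.
#' @param scale,weights fitness ingredients (defaults: polar requirement and
#'   the embedded mistranslation weights).
#' @param seed optional seed set before sampling.
#' @return a [FitnessSample][FitnessSample-class].
#' @examples
#' s <- sampleRandomCodes(500, model = 1, seed = 1)
#' fractionBetter(s, ms(canonicalCode()))
#' @export
sampleRandomCodes <- function(n, model = 1, fitnessKind = c("MS", "tMS"),
                              scale = polarRequirement(),
                              weights = mistranslationWeights(),
                              seed = NULL) {
  fitnessKind <- match.arg(fitnessKind)
  model <- as.integer(model)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (!model %in% c(1L, 2L)) stop("model must be 1 or 2")
  if (!is.null(seed)) set.seed(seed)
  x <- propertyValues(scale)[.AA_LETTERS]
  wmat <- if (fitnessKind == "tMS") weightMatrix(weights) else NULL
  if (model == 1L) {
    vals <- .fitness_perm(.init_pop_perm(n), x, .block_agg(wmat))
  } else {
    ss <- .CANONICAL_SENSE
    w <- .pair_weights(ss, wmat)
    vals <- .fitness_sense(.init_pop_sense(n), x, ss, w, sum(w))
  }
  new("FitnessSample", values = vals, model = model,
      fitnessKind = fitnessKind)
}

#' @name sample-accessors
#' @title Accessor for FitnessSample objects
#' @description `sampleValues` returns the numeric vector of error values.
#' @param x a [FitnessSample][FitnessSample-class].
#' @return numeric vector.
NULL

setMethod("sampleValues", "FitnessSample", function(x) x@values)

#' Fraction of sampled codes better than a reference
#'
#' @param sample a [FitnessSample][FitnessSample-class] (or numeric vector).
#' @param reference a reference error value, typically the canonical code's
#'   MS or tMS.
#' @return the proportion of values strictly below `reference` (ties count
#'   as not better), in \[0, 1\].
#' @export
fractionBetter <- function(sample, reference) {
  v <- if (is(sample, "FitnessSample")) sample@values else as.numeric(sample)
  if (!length(v)) stop("empty sample")
  mean(v < reference)
}

#' Percentage distance minimization (p.d.m.)
#'
#' Places a code on a linear optimality scale between the average random
#' code (0%) and the best code found (100%):
#' `pdm = 100 * (delta_mean - delta_code) / (delta_mean - delta_low)`.
#'
#' @param deltaMean average error of random codes.
#' @param deltaCode error of the code under study.
#' @param deltaLow best (lowest) error found, e.g. the minimum over genetic
#'   algorithm replicates.
#' @return a [PdmResult][PdmResult-class]; extract the percentage with
#'   [pdmValue()].
#' @examples
#' pdmValue(pdm(10, 5.19, 3.5))
#' @export
pdm <- function(deltaMean, deltaCode, deltaLow) {
  new("PdmResult", deltaMean = as.numeric(deltaMean),
      deltaCode = as.numeric(deltaCode), deltaLow = as.numeric(deltaLow))
}

#' @rdname pdm
#' @param x a [PdmResult][PdmResult-class].
#' @export
setMethod("pdmValue", "PdmResult", function(x)
  100 * (x@deltaMean - x@deltaCode) / (x@deltaMean - x@deltaLow))

#' Histogram of a fitness sample
#'
#' Bins a sample of code error values into `bins` equal-width bins spanning
#' the sample range; optionally reports the bin containing a reference value
#' (the vertical canonical-code marker of the classic histogram figures).
#'
#' @param sample a [FitnessSample][FitnessSample-class] (or numeric vector).
#' @param bins number of bins (default 30).
#' @param reference optional reference error value.
#' @return a data.frame with columns `lower`, `upper`, `count` (the last bin
#'   is closed on the right, all others half-open).  If `reference` is
#'   given, the attribute `referenceBin` holds its bin index (0 below the
#'   range, `bins + 1` above).
#' @export
fitnessHistogram <- function(sample, bins = 30, reference = NULL) {
  v <- if (is(sample, "FitnessSample")) sample@values else as.numeric(sample)
  if (!length(v)) stop("empty sample")
  bins <- as.integer(bins)
  if (bins < 1L) stop("bins must be >= 1")
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    breaks <- seq(lo - 0.5, hi + 0.5, length.out = bins + 1L)
  } else {
    breaks <- seq(lo, hi, length.out = bins + 1L)
  }
  bin <- findInterval(v, breaks, rightmost.closed = TRUE)
  out <- data.frame(lower = breaks[-(bins + 1L)], upper = breaks[-1L],
                    count = tabulate(bin, nbins = bins))
  if (!is.null(reference)) {
    rb <- findInterval(reference, breaks, rightmost.closed = TRUE)
    attr(out, "referenceBin") <- rb
  }
  out
}

#' Regularity patterns of a code
#'
#' Quantitative proxies for the two regularities of error-minimizing codes.
#' Pattern I ("column" pattern): amino acids are more similar along the
#' first codon position than along the second.  `pattern1` is the mean
#' within-group property variance when sense codons are grouped by bases 2+3
#' (so the first base varies within a group) minus the same quantity with
#' grouping by bases 1+3; a negative value indicates Pattern I.  Pattern II:
#' along the second position, amino acids with a pyrimidine (U, C) or a
#' purine (A, G) second base are more similar within these sets than between
#' them.  `pattern2` is the mean squared property difference across the
#' second-base pyrimidine/purine boundary minus the pooled within-set mean;
#' a positive value indicates Pattern II.  Both are zero under a constant
#' property scale.
#'
#' @param code a [GeneticCode][GeneticCode-class].
#' @param scale a [PropertyScale][PropertyScale-class].
#' @return named numeric `c(pattern1 = ..., pattern2 = ...)`.
#' @examples
#' patternScores(canonicalCode())  # pattern1 < 0, pattern2 > 0
#' @export
patternScores <- function(code, scale = polarRequirement()) {
  a <- code@assignment
  sense <- which(a != .STOP_CHAR)
  x <- propertyValues(scale)[a[sense]]
  cb <- .CODON_BASE[sense, , drop = FALSE]

  group_var <- function(key) {
    vs <- tapply(x, key, function(v)
      if (length(v) >= 2L) stats::var(v) else NA_real_)
    mean(vs, na.rm = TRUE)
  }
  v_base1_varies <- group_var(paste(cb[, 2L], cb[, 3L]))
  v_base2_varies <- group_var(paste(cb[, 1L], cb[, 3L]))
  pattern1 <- v_base1_varies - v_base2_varies

  py <- cb[, 2L] <= 2L                   # second base U or C
  d2 <- outer(x, x, `-`)^2
  between <- mean(d2[py, !py])
  ut <- upper.tri(d2)
  within_pairs <- c(d2[py, py][upper.tri(d2[py, py])],
                    d2[!py, !py][upper.tri(d2[!py, !py])])
  pattern2 <- between - mean(within_pairs)
  c(pattern1 = pattern1, pattern2 = pattern2)
}

#' Full optimality analysis for one experimental arm
#'
#' Runs one (model, fitness) arm end-to-end: scores the canonical code,
#' samples `nRandom` random codes of the model for the random-code mean,
#' runs the genetic algorithm for the best achievable error, and assembles
#' the p.d.m.
#'
#' @param model 1 or 2.
#' @param fitnessKind `"MS"` or `"tMS"`.
#' @param nRandom number of random codes for the mean (default 10000).
#' @param config an [EvolutionConfig][EvolutionConfig-class] for the search;
#'   defaults to `evolutionConfig(model, fitnessKind, seed = seed)`.
#' @param seed base seed (random sample uses a derived seed).
#' @return a list with elements `deltaCode`, `deltaMean`, `deltaLow`,
#'   `pdm` (a [PdmResult][PdmResult-class]), `trace` (the
#'   [EvolutionTrace][EvolutionTrace-class]) and `sample` (the
#'   [FitnessSample][FitnessSample-class]).
#' @export
optimalityAnalysis <- function(model = 1, fitnessKind = c("MS", "tMS"),
                               nRandom = 10000, config = NULL, seed = 1) {
  fitnessKind <- match.arg(fitnessKind)
  if (is.null(config))
    config <- evolutionConfig(model = model, fitnessKind = fitnessKind,
                              seed = seed)
  canon <- canonicalCode()
  delta_code <- if (fitnessKind == "MS") ms(canon, config@scale)
                else tms(canon, config@scale, config@weights)
  sample <- sampleRandomCodes(nRandom, model = model,
                              fitnessKind = fitnessKind,
                              scale = config@scale, weights = config@weights,
                              seed = .derive_seed(config@seed, 0L))
  trace <- evolveCodes(config)
  delta_mean <- mean(sampleValues(sample))
  delta_low <- min(bestValues(trace))
  list(deltaCode = delta_code, deltaMean = delta_mean, deltaLow = delta_low,
       pdm = pdm(delta_mean, delta_code, delta_low),
       trace = trace, sample = sample)
}
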