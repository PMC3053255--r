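#' Mean-square error (MS) of a genetic code
#'
#' The MS statistic is the mean squared change in an amino-acid property over
#' all single-base substitutions of all codons of a code.  Substitutions from
#' or to stop codons are ignored; synonymous substitutions are included (they
#' contribute zero to the numerator but are counted in the denominator).
#' Lower values mean the code buffers point mutations and mistranslations
#' better.
#'
#' @param code a [GeneticCode][GeneticCode-class].
#' @param scale a [PropertyScale][PropertyScale-class]; defaults to the
#'   embedded Woese polar requirement scale.
#' @param ... unused.
#' @return a single nonnegative numeric value.  For the canonical code under
#'   polar requirement the value is 5.19 (to 3 significant figures).
#' @examples
#' ms(canonicalCode())
#' @export
setGeneric("ms", function(code, scale = polarRequirement(), ...)
  standardGeneric("ms"))

#' Mistranslation-weighted mean-square error (tMS)
#'
#' Like [ms()], but each substitution is weighted by codon position and
#' mutation class (transition/transversion) to reflect empirical
#' mistranslation biases; the result is the weighted mean of squared property
#' differences.  With all six weights equal to 1, tMS equals MS exactly.
#'
#' @inheritParams ms
#' @param weights a [MistranslationWeights][MistranslationWeights-class];
#'   defaults to the embedded table (transitions 1, 0.5, 1; transversions
#'   0.5, 0.1, 1 for positions 1-3).
#' @return a single nonnegative numeric value.
#' @examples
#' tms(canonicalCode())
#' @export
setGeneric("tms", function(code, scale = polarRequirement(),
                           weights = mistranslationWeights(), ...)
  standardGeneric("tms"))

#' All amino-acid substitution events of a code
#'
#' Enumerates the ordered single-base codon substitutions counted by [ms()]
#' and [tms()]: one event per ordered (codon, neighbor) pair in which both
#' codons encode amino acids.  For any code with the canonical stop codons
#' there are 526 events (61 sense codons x 9 neighbors, minus the 23 ordered
#' sense-to-stop pairs, counted in both directions).
#'
#' @param code a [GeneticCode][GeneticCode-class].
#' @return a data.frame with columns `from`, `to` (amino-acid one-letter
#'   codes), `position` (mutated codon position, 1-3) and `class`
#'   (`"transition"` or `"transversion"`).
#' @export
setGeneric("substitutionEvents", function(code)
  standardGeneric("substitutionEvents"))

#' @rdname accessors
#' @export
setGeneric("codeString", function(x) standardGeneric("codeString"))

#' @rdname accessors
#' @export
setGeneric("stopCodons", function(x) standardGeneric("stopCodons"))

#' @rdname accessors
#' @export
setGeneric("codonAssignments", function(x) standardGeneric("codonAssignments"))

#' @rdname accessors
#' @export
setGeneric("degeneracy", function(x) standardGeneric("degeneracy"))

#' @rdname accessors
#' @export
setGeneric("propertyValues", function(x) standardGeneric("propertyValues"))

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname trace-accessors
#' @export
setGeneric("bestValues", function(x) standardGeneric("bestValues"))

#' @rdname trace-accessors
#' @export
setGeneric("bestCodes", function(x) standardGeneric("bestCodes"))

#' @rdname trace-accessors
#' @export
setGeneric("bestCode", function(x) standardGeneric("bestCode"))

#' @rdname trace-accessors
#' @export
setGeneric("traceSummary", function(x) standardGeneric("traceSummary"))

#' @rdname sample-accessors
#' @export
setGeneric("sampleValues", function(x) standardGeneric("sampleValues"))

#' @rdname pdm
#' @export
setGeneric("pdmValue", function(x) standardGeneric("pdmValue"))
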