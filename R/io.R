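# io: text serialization of code tables (modeled on NCBI translation-table
# "ncbieaa" strings) and TSV readers for property scales and weights.

.CODE_TABLE_HEADER <- "# codon-order=U C A G, base1-major"

#' Read and write code tables
#'
#' A code table file is the header line `# codon-order=U C A G, base1-major`
#' followed by a 64-character amino-acid string (one-letter codes, `*` for
#' stop) over the codons enumerated with the first base slowest and base
#' order U, C, A, G — the same convention as NCBI "ncbieaa" translation
#' strings.  `parseCodeTable` also accepts a bare 64-character string and
#' treats `T` in comments/headers as `U` equivalent input.  The round trip
#' `parseCodeTable(writeCodeTable(code))` is the identity for every valid
#' code.
#'
#' @param text a character vector of lines, a single string, or (if `file`
#'   is given) ignored.
#' @param file optional path to read from / write to.
#' @param code a [GeneticCode][GeneticCode-class].
#' @return `parseCodeTable`: a validated
#'   [GeneticCode][GeneticCode-class]; `writeCodeTable`: the file content
#'   as a character vector of lines (invisibly, when writing to `file`).
#' @examples
#' writeCodeTable(canonicalCode())
#' @export
parseCodeTable <- function(text = NULL, file = NULL) {
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  if (is.null(text)) stop("provide 'text' or 'file'")
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) != 1L)
    stop("expected exactly one 64-character code line, found ",
         length(lines))
  s <- lines[[1L]]
  if (nchar(s) != 64L)
    stop("code string must have exactly 64 characters, got ", nchar(s))
  geneticCode(s)                         # validity reports stops/missing aa
}

#' @rdname parseCodeTable
#' @export
writeCodeTable <- function(code, file = NULL) {
  stopifnot(is(code, "GeneticCode"))
  out <- c(.CODE_TABLE_HEADER, codeString(code))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read an amino-acid property scale from TSV
#'
#' Two tab-separated columns: amino-acid one-letter code and value.  Lines
#' starting with `#` are ignored.
#'
#' @param file path.
#' @return a [PropertyScale][PropertyScale-class].
#' @export
readPropertyScale <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE,
                         col.names = c("aa", "value"))
  if (anyDuplicated(d$aa))
    stop("duplicate amino acid in scale file")
  if (!setequal(d$aa, .AA_LETTERS))
    stop("scale file must cover exactly the 20 standard amino acids")
  propertyScale(stats::setNames(d$value, d$aa))
}

#' Read mistranslation weights from TSV
#'
#' Three tab-separated columns: codon position (1-3), class (`transition` or
#' `transversion`) and weight; all six combinations must be present.
#'
#' @param file path.
#' @return a [MistranslationWeights][MistranslationWeights-class].
#' @export
readMistranslationWeights <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE,
                         col.names = c("position", "class", "weight"))
  d$class <- tolower(d$class)
  if (nrow(d) != 6L ||
      anyDuplicated(d[, c("position", "class")]) ||
      !all(d$position %in% 1:3) ||
      !all(d$class %in% c("transition", "transversion")))
    stop("weights file must contain exactly the 6 (position, class) pairs")
  w <- matrix(NA_real_, 3L, 2L, dimnames = dimnames(.DEFAULT_WEIGHTS))
  w[cbind(d$position, match(d$class, colnames(w)))] <- d$weight
  new("MistranslationWeights", weights = w)
}
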