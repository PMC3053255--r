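# Independent brute-force oracles, deliberately written with plain string
# manipulation and explicit nested loops (no shared code with the package
# internals).

ORACLE_BASES <- c("U", "C", "A", "G")

oracle_neighbors <- function(codon) {
  sp <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) for (b in ORACLE_BASES) {
    if (b == sp[p]) next
    nb <- sp
    nb[p] <- b
    out <- c(out, paste(nb, collapse = ""))
  }
  out
}

# weighted mean squared property change over all single-base substitutions,
# stop-involving pairs dropped; weights = NULL gives plain MS
oracle_delta2 <- function(code, scale, weights = NULL) {
  a <- codonAssignments(code)
  x <- propertyValues(scale)
  num <- 0
  den <- 0
  for (cd in names(a)) {
    if (a[[cd]] == "*") next
    sp <- strsplit(cd, "")[[1]]
    for (p in 1:3) {
      for (b in ORACLE_BASES) {
        if (b == sp[p]) next
        nb <- sp
        nb[p] <- b
        nbc <- paste(nb, collapse = "")
        if (a[[nbc]] == "*") next
        w <- 1
        if (!is.null(weights)) {
          is_transition <- (sp[p] %in% c("A", "G")) == (b %in% c("A", "G"))
          w <- weights[p, if (is_transition) 1L else 2L]
        }
        num <- num + w * (x[[a[[cd]]]] - x[[a[[nbc]]]])^2
        den <- den + w
      }
    }
  }
  num / den
}

# brute-force equal-width binning over [min, max], last bin right-closed
oracle_histogram <- function(values, bins) {
  lo <- min(values)
  hi <- max(values)
  width <- (hi - lo) / bins
  counts <- integer(bins)
  for (v in values) {
    k <- if (v >= hi) bins else floor((v - lo) / width) + 1
    counts[k] <- counts[k] + 1L
  }
  counts
}

# nested-loop pattern proxies (see patternScores for the definitions)
oracle_patterns <- function(code, scale) {
  a <- codonAssignments(code)
  x <- propertyValues(scale)
  sense <- names(a)[a != "*"]
  val <- x[a[sense]]
  b <- do.call(rbind, strsplit(sense, ""))

  mean_group_var <- function(key) {
    vs <- c()
    for (k in unique(key)) {
      v <- val[key == k]
      if (length(v) >= 2) vs <- c(vs, var(v))
    }
    mean(vs)
  }
  p1 <- mean_group_var(paste(b[, 2], b[, 3])) -
        mean_group_var(paste(b[, 1], b[, 3]))

  py <- b[, 2] %in% c("U", "C")
  between <- c()
  within <- c()
  n <- length(sense)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- (val[i] - val[j])^2
      if (py[i] != py[j]) between <- c(between, d) else within <- c(within, d)
    }
  }
  c(pattern1 = p1, pattern2 = mean(between) - mean(within))
}
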