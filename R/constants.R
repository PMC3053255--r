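# Internal reference data: codon enumeration, the standard genetic code,
# the Woese polar requirement scale, and the mistranslation weights.
#
# Codon order used throughout (and in serialized code tables): first base
# slowest, third base fastest, base order U, C, A, G.  This coincides with
# the codon order of NCBI "ncbieaa" translation-table strings (T read as U).

.BASES <- c("U", "C", "A", "G")

# purines are A and G (indices 3:4); pyrimidines U and C (indices 1:2)
.is_purine_idx <- function(i) i >= 3L

.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.STOP_CHAR <- "*"
.STOP_IDX <- 21L
.LABELS <- c(.AA_LETTERS, .STOP_CHAR)

.CODONS <- local({
  g <- expand.grid(b3 = .BASES, b2 = .BASES, b1 = .BASES,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  paste0(g$b1, g$b2, g$b3)
})

# 64 x 3 matrix of base indices (1=U, 2=C, 3=A, 4=G)
.CODON_BASE <- matrix(match(unlist(strsplit(.CODONS, "")), .BASES),
                      nrow = 64L, ncol = 3L, byrow = TRUE,
                      dimnames = list(.CODONS, NULL))

.codon_index <- function(b1, b2, b3) (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3

# The standard genetic code in the codon order above (identical to the
# NCBI standard-table ncbieaa string).
.CANONICAL_STRING <-
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.CANONICAL_AAIDX <- match(strsplit(.CANONICAL_STRING, "")[[1]], .LABELS)
.CANONICAL_STOPS <- .CODONS[.CANONICAL_AAIDX == .STOP_IDX]

# canonical synonym blocks, one per amino acid, indexed in .AA_LETTERS order
.BLOCK_CODONS <- lapply(seq_len(20L),
                        function(k) which(.CANONICAL_AAIDX == k))
.BLOCK_OF_CODON <- local({
  b <- rep(NA_integer_, 64L)
  for (k in seq_len(20L)) b[.BLOCK_CODONS[[k]]] <- k
  b
})

# All 576 ordered single-base neighbor pairs: codon i -> codon j, mutated
# position (1-3) and class (1 = transition, 2 = transversion).
.NB <- local({
  n <- 64L * 9L
  ii <- jj <- pp <- cl <- integer(n)
  k <- 0L
  for (i in seq_len(64L)) {
    cb <- .CODON_BASE[i, ]
    for (p in 1:3) {
      for (b in 1:4) {
        if (b == cb[p]) next
        nb <- cb
        nb[p] <- b
        k <- k + 1L
        ii[k] <- i
        jj[k] <- .codon_index(nb[1L], nb[2L], nb[3L])
        pp[k] <- p
        cl[k] <- if (.is_purine_idx(b) == .is_purine_idx(cb[p])) 1L else 2L
      }
    }
  }
  list(i = ii, j = jj, pos = pp, class = cl)
})

# Sense-codon structures for a fixed stop-codon set: index maps, the ordered
# sense-sense neighbor pairs (in sense coordinates), and for each sense codon
# the padded list of its sense neighbors (used by the reassignment operator).
.sense_structure <- function(stop_codons) {
  stop_idx <- match(stop_codons, .CODONS)
  sense <- setdiff(seq_len(64L), stop_idx)
  s_of <- rep(NA_integer_, 64L)
  s_of[sense] <- seq_along(sense)
  keep <- !(.NB$i %in% stop_idx) & !(.NB$j %in% stop_idx)
  si <- s_of[.NB$i[keep]]
  sj <- s_of[.NB$j[keep]]
  deg <- tabulate(si, nbins = length(sense))
  nbm <- matrix(NA_integer_, nrow = max(deg), ncol = length(sense))
  slot <- integer(length(sense))
  for (k in seq_along(si)) {
    s <- si[k]
    slot[s] <- slot[s] + 1L
    nbm[slot[s], s] <- sj[k]
  }
  list(sense = sense, s_of = s_of,
       pair_i = si, pair_j = sj,
       pair_pos = .NB$pos[keep], pair_class = .NB$class[keep],
       nb_mat = nbm, nb_deg = deg)
}

.CANONICAL_SENSE <- .sense_structure(.CANONICAL_STOPS)

# Woese polar requirement scale (water/dimethylpyridine partitioning),
# as used throughout the load-minimization literature.
.POLAR_REQUIREMENT <- c(
  A = 7.0, C = 4.8, D = 13.0, E = 12.5, F = 5.0,
  G = 7.9, H = 8.4, I = 4.9, K = 10.1, L = 4.9,
  M = 5.3, N = 10.0, P = 6.6, Q = 8.6, R = 9.1,
  S = 7.5, T = 6.6, V = 5.6, W = 5.2, Y = 5.4)

# Default mistranslation weights per (codon position, mutation class):
# relative efficiency of the three bases for transitions and transversions.
.DEFAULT_WEIGHTS <- matrix(c(1, 0.5, 1, 0.5, 0.1, 1), nrow = 3L,
                           dimnames = list(position = c("1", "2", "3"),
                                           class = c("transition",
                                                     "transversion")))
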