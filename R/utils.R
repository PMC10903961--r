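#' @importFrom stats rpois runif rbinom setNames p.adjust wilcox.test fisher.test cor rnorm
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string(s)
#'
#' @param n number of strings
#' @param len length of each string
#' @return character vector of uppercase DNA
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] so all orientation
#' handling goes through one code path.
#'
#' @param x character vector of DNA strings
#' @return character vector
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character scalars or vectors (recycled)
#' @return integer vector of distances
#' @export
hamming <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

# Overlap length of interval [s1,e1) with [s2,e2); vectors allowed.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Gap between [s1,e1) and [s2,e2): 0 if they touch/overlap.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

# Deterministic child seed derived from a master seed; stays < 2^31.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 1103L + 7919 * as.numeric(k)) %% 2147483647
}

# Collapse an exon-block matrix (cols start,end; 0-based half-open) to an
# intron-chain key string; "" for mono-exon.
chain_key <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2L) return("")
  paste(blocks[-n, 2L], blocks[-1L, 1L], sep = "-", collapse = ";")
}

# Intron junctions of a block matrix as a 2-col matrix (donor end, acceptor
# start in genomic 0-based coordinates); 0 rows for mono-exon.
chain_junctions <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  cbind(blocks[-n, 2L], blocks[-1L, 1L])
}
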