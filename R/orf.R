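STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Predict the representative ORF of a transcript sequence
#'
#' Scans the three forward reading frames of a 5'->3' transcript sequence
#' and enumerates candidate ORFs of four shapes: complete (ATG...stop),
#' 5'-open (frame start to the first stop with no upstream ATG), 3'-open
#' (ATG to the sequence end with no downstream stop), and open at both ends
#' (a stop-free, ATG-free frame). The longest candidate (ties: leftmost,
#' then lowest frame) is the representative ORF; if no candidate reaches
#' `min_length_aa` amino acids, a below-threshold marker is returned.
#'
#' @param transcript_sequence uppercase DNA, transcript orientation
#' @param min_length_aa minimum ORF length in amino acids (default 100, the
#'   conventional coding-potential threshold)
#' @return a one-row data.frame (an `ORFResult`): orf_start, orf_end
#'   (0-based half-open transcript coordinates, stop codon included when
#'   present), frame, has_start_codon, has_stop_codon, length_aa,
#'   below_threshold
#' @export
predict_orf <- function(transcript_sequence, min_length_aa = 100L) {
  s <- toupper(transcript_sequence)
  if (grepl("[^ACGT]", s)) stop("input error: non-DNA characters in sequence")
  L <- nchar(s)
  best <- NULL
  for (f in 0:2) {
    n_codons <- (L - f) %/% 3L
    if (n_codons < 1L) next
    cod <- substring(s, f + 3L * (seq_len(n_codons) - 1L) + 1L,
                     f + 3L * seq_len(n_codons))
    stops <- which(cod %in% STOP_CODONS)
    atgs <- which(cod == "ATG")
    cands <- list()
    seg_start <- 1L
    for (st in stops) {
      seg_atgs <- atgs[atgs >= seg_start & atgs < st]
      if (length(seg_atgs) > 0L) {
        cands[[length(cands) + 1L]] <-
          c(start = seg_atgs[1L], end = st, s1 = 1L, s2 = 1L)
      } else if (seg_start == 1L && st > 1L) {
        cands[[length(cands) + 1L]] <-
          c(start = 1L, end = st, s1 = 0L, s2 = 1L)
      }
      seg_start <- st + 1L
    }
    if (seg_start <= n_codons || length(stops) == 0L) {
      seg_atgs <- atgs[atgs >= seg_start]
      if (length(seg_atgs) > 0L) {
        cands[[length(cands) + 1L]] <-
          c(start = seg_atgs[1L], end = n_codons + 1L, s1 = 1L, s2 = 0L)
      } else if (length(stops) == 0L && n_codons >= 1L) {
        cands[[length(cands) + 1L]] <-
          c(start = 1L, end = n_codons + 1L, s1 = 0L, s2 = 0L)
      }
    }
    for (cd in cands) {
      len_aa <- (cd[["end"]] - cd[["start"]])  # non-stop codons
      tx_start <- f + 3L * (cd[["start"]] - 1L)
      tx_end <- f + 3L * (min(cd[["end"]], n_codons) - 1L) +
        if (cd[["s2"]] == 1L) 3L else 0L
      if (cd[["s2"]] == 0L) tx_end <- f + 3L * (cd[["end"]] - 1L)
      cand <- data.frame(
        orf_start = tx_start, orf_end = tx_end, frame = f,
        has_start_codon = cd[["s1"]] == 1L,
        has_stop_codon = cd[["s2"]] == 1L,
        length_aa = as.integer(len_aa), below_threshold = FALSE)
      if (is.null(best) || orf_better(cand, best)) best <- cand
    }
  }
  if (is.null(best)) {
    best <- data.frame(orf_start = NA_integer_, orf_end = NA_integer_,
                       frame = NA_integer_, has_start_codon = FALSE,
                       has_stop_codon = FALSE, length_aa = 0L,
                       below_threshold = TRUE)
  } else if (best$length_aa < min_length_aa) {
    best$below_threshold <- TRUE
  }
  best
}

# Candidate ranking: longest; ties prefer a start codon, then a stop codon,
# then the leftmost start, then the lowest frame.
orf_better <- function(a, b) {
  ka <- c(a$length_aa, a$has_start_codon, a$has_stop_codon,
          -a$orf_start, -a$frame)
  kb <- c(b$length_aa, b$has_start_codon, b$has_stop_codon,
          -b$orf_start, -b$frame)
  d <- ka - kb
  nz <- which(d != 0)
  length(nz) > 0L && d[nz[1L]] > 0
}

#' ORF-integrity type of a transcript
#'
#' Maps an `ORFResult` to the five-way integrity taxonomy: `complete`
#' (start and stop codon), `three_prime_partial` (start, no stop: the
#' protein lacks its C-terminus), `five_prime_partial` (stop, no start),
#' `internal` (neither end), and `others` (no ORF above the length
#' threshold).
#'
#' @param orf an `ORFResult` from [predict_orf()]
#' @return one of `complete`, `five_prime_partial`, `three_prime_partial`,
#'   `internal`, `others`
#' @export
classify_orf_type <- function(orf) {
  if (isTRUE(orf$below_threshold)) return("others")
  if (orf$has_start_codon && orf$has_stop_codon) return("complete")
  if (orf$has_start_codon) return("three_prime_partial")
  if (orf$has_stop_codon) return("five_prime_partial")
  "internal"
}

#' ORF-type transcripts from their spliced sequences
#'
#' Convenience wrapper: predicts the representative ORF of each sequence
#' and returns the typing table, optionally with the predicted protein
#' length relative to a matched reference ORF.
#'
#' @param sequences character vector of transcript sequences
#' @param min_length_aa passed to [predict_orf()]
#' @param reference_orf_aa optional numeric vector (parallel to
#'   `sequences`) of matched reference ORF lengths in amino acids
#' @return data.frame with the `ORFResult` columns plus `orf_type` and
#'   `relative_length`
#' @export
classify_transcripts <- function(sequences, min_length_aa = 100L,
                                 reference_orf_aa = NULL) {
  res <- do.call(rbind, lapply(sequences, predict_orf,
                               min_length_aa = min_length_aa))
  res$orf_type <- vapply(seq_len(nrow(res)), function(i)
    classify_orf_type(res[i, ]), character(1))
  res$relative_length <- if (is.null(reference_orf_aa)) {
    NA_real_
  } else {
    res$length_aa / reference_orf_aa
  }
  res
}
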