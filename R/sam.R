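#' Spliced alignment tables
#'
#' The package represents spliced alignments as a plain data.frame with one
#' row per alignment segment and the exon blocks of each segment in a list
#' column. Coordinates are 0-based half-open internally; SAM I/O converts
#' to/from the 1-based convention of the format.
#'
#' Columns: `read_id`, `chrom`, `strand`, `start`, `end` (genomic span),
#' `mapq`, `is_primary`, `is_supplementary`, `is_secondary`, and `blocks`
#' (list of two-column matrices, columns `start`,`end`).
#'
#' @name spliced_alignments
NULL

new_alignments <- function(read_id, chrom, strand, mapq, blocks,
                           is_primary = TRUE, is_supplementary = FALSE,
                           is_secondary = FALSE) {
  if (length(read_id) == 0L) {
    df <- data.frame(read_id = character(0), chrom = character(0),
                     strand = character(0), start = numeric(0),
                     end = numeric(0), mapq = integer(0),
                     is_primary = logical(0), is_supplementary = logical(0),
                     is_secondary = logical(0), stringsAsFactors = FALSE)
    df$blocks <- list()
    class(df) <- c("spliced_alignments", "data.frame")
    return(df)
  }
  start <- vapply(blocks, function(b) b[1L, 1L], numeric(1))
  end <- vapply(blocks, function(b) b[nrow(b), 2L], numeric(1))
  df <- data.frame(
    read_id = read_id, chrom = chrom, strand = strand,
    start = start, end = end, mapq = mapq,
    is_primary = is_primary, is_supplementary = is_supplementary,
    is_secondary = is_secondary, stringsAsFactors = FALSE
  )
  df$blocks <- blocks
  class(df) <- c("spliced_alignments", "data.frame")
  df
}

blocks_to_cigar <- function(blocks) {
  n <- nrow(blocks)
  lens <- blocks[, 2L] - blocks[, 1L]
  if (n == 1L) return(paste0(lens, "M"))
  gaps <- blocks[-1L, 1L] - blocks[-n, 2L]
  paste0(paste0(lens[-n], "M", gaps, "N", collapse = ""), lens[n], "M")
}

#' Write alignments to a SAM file
#'
#' Emits minimal SAM: header with `@SQ` lines, then one record per alignment
#' segment with an M/N CIGAR derived from the exon blocks. Sequences may be
#' supplied per read; supplementary and non-primary records get `*`.
#'
#' @param alignments a [spliced_alignments] data.frame
#' @param ref_lengths named integer vector of chromosome lengths
#' @param path output file
#' @param sequences optional named character vector (`read_id` -> sequence,
#'   given in the orientation of the primary alignment's strand)
#' @return `path`, invisibly
#' @export
write_sam <- function(alignments, ref_lengths, path, sequences = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                     as.integer(ref_lengths)), con)
  if (nrow(alignments) == 0L) return(invisible(path))
  flag <- ifelse(alignments$strand == "-", 16L, 0L) +
    ifelse(alignments$is_supplementary, 2048L, 0L) +
    ifelse(alignments$is_secondary, 256L, 0L)
  cigar <- vapply(alignments$blocks, blocks_to_cigar, character(1))
  seqf <- rep("*", nrow(alignments))
  if (!is.null(sequences)) {
    idx <- match(alignments$read_id, names(sequences))
    use <- !is.na(idx) & alignments$is_primary & !alignments$is_supplementary
    sq <- sequences[idx[use]]
    # SAM stores the sequence in reference-forward orientation
    rev <- alignments$strand[use] == "-"
    sq[rev] <- revcomp(sq[rev])
    seqf[use] <- sq
  }
  rec <- paste(alignments$read_id, flag, alignments$chrom,
               alignments$start + 1L, alignments$mapq, cigar,
               "*", 0L, 0L, seqf, "*", sep = "\t")
  writeLines(rec, con)
  invisible(path)
}

#' Read spliced alignments from a SAM file
#'
#' Parses mapped records of a plain-text SAM file into the package's
#' alignment table. CIGAR strings are converted to exon blocks with
#' [GenomicAlignments::cigarRangesAlongReferenceSpace()], merging `M`, `D`,
#' `=`/`X` into blocks and splitting at `N` gaps.
#'
#' @param path SAM file
#' @param min_mapq drop records below this mapping quality (default 0)
#' @return a [spliced_alignments] data.frame
#' @export
read_sam <- function(path, min_mapq = 0L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(new_alignments(character(0), character(0), character(0),
                          integer(0), list()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, character(1), 1L)
  flag <- as.integer(vapply(f, `[[`, character(1), 2L))
  rname <- vapply(f, `[[`, character(1), 3L)
  pos <- as.integer(vapply(f, `[[`, character(1), 4L))
  mapq <- as.integer(vapply(f, `[[`, character(1), 5L))
  cigar <- vapply(f, `[[`, character(1), 6L)
  mapped <- bitwAnd(flag, 4L) == 0L & cigar != "*"
  keep <- mapped & mapq >= min_mapq
  if (!any(keep)) {
    return(new_alignments(character(0), character(0), character(0),
                          integer(0), list()))
  }
  qname <- qname[keep]; flag <- flag[keep]; rname <- rname[keep]
  pos <- pos[keep]; mapq <- mapq[keep]; cigar <- cigar[keep]
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "D", "=", "X"), reduce.ranges = TRUE
  )
  blocks <- lapply(seq_along(rng), function(i) {
    r <- rng[[i]]
    cbind(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  new_alignments(
    read_id = qname, chrom = rname,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    mapq = mapq, blocks = blocks,
    is_primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    is_supplementary = bitwAnd(flag, 2048L) != 0L,
    is_secondary = bitwAnd(flag, 256L) != 0L
  )
}
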