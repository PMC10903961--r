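#' Identify a full-length read and extract its architecture
#'
#' A read is full-length (FL) when both the 5' and the 3' primer are found
#' in the expected orientation; the forward orientation is tried first, then
#' the reverse complement. Reads with exactly one primer hit are `non-FL`;
#' reads with none are `unknown`. For FL reads the cell barcode and UMI are
#' taken from the positions immediately after the 5' primer, and a polyA run
#' (at least `polya_min` A's ending within `polya_slack` nt of the 3'
#' primer) is trimmed off the insert. The insert is always reported 5'->3'.
#'
#' @param read a single read sequence (character)
#' @param primer_5,primer_3 primer sequences as present in the read layout
#' @param max_mismatch maximum mismatches tolerated per primer hit
#' @param bc_len,umi_len barcode/UMI lengths
#' @param polya_min minimum A-run length recognised as a polyA tail
#' @param polya_slack maximum distance between polyA end and the 3' primer
#' @param read_id identifier carried into the record
#' @return a one-row data.frame (an `FLNCRecord`): read_id, fl_status
#'   (`FL`/`non-FL`/`unknown`), orientation, raw_barcode, umi,
#'   insert_sequence
#' @export
identify_flnc <- function(read, primer_5 = "AAGCAGTGGTATCAACGCAGAGT",
                          primer_3 = "CATGTAGCCGATTCAGGCCATTCA",
                          max_mismatch = 2L,
                          bc_len = 16L, umi_len = 10L, polya_min = 10L,
                          polya_slack = 5L, read_id = "read") {
  stopifnot(nchar(read) > 0L)
  try_orient <- function(sq) {
    hit5 <- find_primer(sq, primer_5, max_mismatch, from_end = FALSE)
    hit3 <- find_primer(sq, primer_3, max_mismatch, from_end = TRUE)
    list(hit5 = hit5, hit3 = hit3, n = sum(!is.na(c(hit5, hit3))))
  }
  fwd <- try_orient(read)
  rc <- revcomp(read)
  rev <- try_orient(rc)
  use_rev <- rev$n > fwd$n
  o <- if (use_rev) rev else fwd
  sq <- if (use_rev) rc else read

  rec <- data.frame(read_id = read_id, fl_status = "unknown",
                    orientation = if (use_rev) "-" else "+",
                    raw_barcode = NA_character_, umi = NA_character_,
                    insert_sequence = NA_character_,
                    stringsAsFactors = FALSE)
  if (o$n == 0L) return(rec)
  if (o$n == 1L) { rec$fl_status <- "non-FL"; return(rec) }

  rec$fl_status <- "FL"
  inner <- substr(sq, o$hit5 + nchar(primer_5), o$hit3 - 1L)
  if (nchar(inner) < bc_len + umi_len + 1L) {
    rec$fl_status <- "non-FL"
    return(rec)
  }
  rec$raw_barcode <- substr(inner, 1L, bc_len)
  rec$umi <- substr(inner, bc_len + 1L, bc_len + umi_len)
  insert <- substr(inner, bc_len + umi_len + 1L, nchar(inner))
  # trim a polyA tail ending near the 3' primer
  m <- regexpr(sprintf("A{%d,}A{0,}.{0,%d}$", polya_min, polya_slack),
               insert)
  if (m > 0L) {
    tail_part <- substr(insert, m, nchar(insert))
    if (grepl(sprintf("^A{%d,}", polya_min), tail_part)) {
      insert <- substr(insert, 1L, m - 1L)
    }
  }
  rec$insert_sequence <- insert
  rec
}

# Position (1-based start) of the best primer hit near the read start/end,
# or NA. Searches a window of 3x primer length.
find_primer <- function(sq, primer, max_mismatch, from_end) {
  L <- nchar(sq); pl <- nchar(primer)
  win <- min(L, 3L * pl)
  region <- if (from_end) substr(sq, L - win + 1L, L) else substr(sq, 1L, win)
  m <- Biostrings::matchPattern(primer, Biostrings::DNAString(region),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  if (length(m) == 0L) return(NA_integer_)
  st <- if (from_end) {
    BiocGenerics::start(m)[length(m)] + (L - win)
  } else {
    BiocGenerics::start(m)[1L]
  }
  as.integer(st)
}

#' Process a read set into FLNC records with barcode correction
#'
#' Vectorised equivalent of applying [identify_flnc()] to every read,
#' followed by barcode correction against the whitelist with the
#' [correct_barcode()] rule (exact, unique distance-1 neighbour, or
#' dropped).
#'
#' @param reads named character vector of read sequences (names = read ids)
#' @param whitelist character vector of valid cell barcodes
#' @inheritParams identify_flnc
#' @return data.frame of FLNC records with columns of [identify_flnc()] plus
#'   `corrected_barcode` and `bc_status` (`exact`/`corrected`/`dropped`)
#' @export
process_reads <- function(reads, whitelist,
                          primer_5 = "AAGCAGTGGTATCAACGCAGAGT",
                          primer_3 = "CATGTAGCCGATTCAGGCCATTCA",
                          max_mismatch = 2L, bc_len = 16L, umi_len = 10L,
                          polya_min = 10L, polya_slack = 5L) {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  seqs <- unname(as.character(reads))
  x <- Biostrings::DNAStringSet(seqs)
  rcx <- Biostrings::reverseComplement(x)
  h5f <- vfind_primer(x, primer_5, max_mismatch, from_end = FALSE)
  h3f <- vfind_primer(x, primer_3, max_mismatch, from_end = TRUE)
  h5r <- vfind_primer(rcx, primer_5, max_mismatch, from_end = FALSE)
  h3r <- vfind_primer(rcx, primer_3, max_mismatch, from_end = TRUE)
  n_f <- (!is.na(h5f)) + (!is.na(h3f))
  n_r <- (!is.na(h5r)) + (!is.na(h3r))
  use_rev <- n_r > n_f
  sq <- ifelse(use_rev, as.character(rcx), seqs)
  h5 <- ifelse(use_rev, h5r, h5f)
  h3 <- ifelse(use_rev, h3r, h3f)
  n_hit <- ifelse(use_rev, n_r, n_f)

  recs <- data.frame(
    read_id = ids,
    fl_status = c("unknown", "non-FL", "FL")[n_hit + 1L],
    orientation = ifelse(use_rev, "-", "+"),
    raw_barcode = NA_character_, umi = NA_character_,
    insert_sequence = NA_character_, stringsAsFactors = FALSE)

  fl <- which(recs$fl_status == "FL")
  if (length(fl) > 0L) {
    inner <- substr(sq[fl], h5[fl] + nchar(primer_5), h3[fl] - 1L)
    short <- nchar(inner) < bc_len + umi_len + 1L
    recs$fl_status[fl[short]] <- "non-FL"
    fl <- fl[!short]; inner <- inner[!short]
    recs$raw_barcode[fl] <- substr(inner, 1L, bc_len)
    recs$umi[fl] <- substr(inner, bc_len + 1L, bc_len + umi_len)
    insert <- substr(inner, bc_len + umi_len + 1L, nchar(inner))
    m <- regexpr(sprintf("A{%d,}.{0,%d}$", polya_min, polya_slack), insert)
    trim <- m > 0L
    insert[trim] <- substr(insert[trim], 1L, m[trim] - 1L)
    recs$insert_sequence[fl] <- insert
  }

  recs$corrected_barcode <- NA_character_
  recs$bc_status <- NA_character_
  fl <- which(recs$fl_status == "FL" & !is.na(recs$raw_barcode))
  if (length(fl) > 0L) {
    cb <- correct_barcodes_vec(recs$raw_barcode[fl], whitelist)
    recs$corrected_barcode[fl] <- cb$barcode
    recs$bc_status[fl] <- cb$status
  }
  recs
}

# Vectorised primer search near the start/end of each read; returns 1-based
# start of the hit in each read or NA.
vfind_primer <- function(xset, primer, max_mismatch, from_end) {
  L <- Biostrings::width(xset)
  pl <- nchar(primer)
  win <- pmin(L, 3L * pl)
  region <- if (from_end) {
    Biostrings::subseq(xset, start = L - win + 1L, end = L)
  } else {
    Biostrings::subseq(xset, start = 1L, width = win)
  }
  m <- Biostrings::vmatchPattern(primer, region,
                                 max.mismatch = max_mismatch,
                                 with.indels = FALSE)
  st <- vapply(seq_along(m), function(i) {
    s <- IRanges::start(m[[i]])
    if (length(s) == 0L) return(NA_integer_)
    if (from_end) s[length(s)] else s[1L]
  }, integer(1))
  if (from_end) st + (L - win) else st
}

#' Correct raw cell barcodes against a whitelist
#'
#' Exact whitelist members pass through unchanged; otherwise, if exactly one
#' whitelist barcode lies at Hamming distance 1, the read is corrected to
#' it; anything else (distance >1, or an ambiguous tie) is dropped.
#'
#' @param raw raw barcode(s)
#' @param whitelist character vector of whitelist barcodes, all the same
#'   length as the raw barcodes
#' @return data.frame with one row per input: `barcode` (corrected barcode
#'   or `NA`) and `status` (`exact`, `corrected`, or `dropped`)
#' @export
correct_barcode <- function(raw, whitelist) {
  if (any(nchar(whitelist) != nchar(raw))) {
    stop("whitelist barcodes must match the raw barcode length")
  }
  r <- correct_barcodes_vec(raw, whitelist)
  data.frame(barcode = r$barcode, status = r$status,
             stringsAsFactors = FALSE)
}

# Vectorised barcode correction.
correct_barcodes_vec <- function(raw, whitelist) {
  status <- rep("dropped", length(raw))
  out <- rep(NA_character_, length(raw))
  exact <- raw %in% whitelist
  out[exact] <- raw[exact]
  status[exact] <- "exact"
  todo <- which(!exact)
  if (length(todo) > 0L) {
    wl_mat <- do.call(rbind, strsplit(whitelist, "", fixed = TRUE))
    for (i in todo) {
      rv <- strsplit(raw[i], "", fixed = TRUE)[[1L]]
      d <- rowSums(wl_mat != matrix(rv, nrow = nrow(wl_mat),
                                    ncol = length(rv), byrow = TRUE))
      hit <- which(d == 1L)
      if (length(hit) == 1L) {
        out[i] <- whitelist[hit]
        status[i] <- "corrected"
      }
    }
  }
  list(barcode = out, status = status)
}

#' Collapse reads to molecules by UMI
#'
#' Identical (barcode, UMI, feature) triples are one molecule; the count for
#' a (barcode, feature) pair is its number of distinct UMIs. UMI matching is
#' exact (no mismatch clustering), appropriate for high-accuracy consensus
#' reads.
#'
#' @param records data.frame with columns `barcode`, `umi`, `feature`
#' @return data.frame(barcode, feature, count)
#' @export
deduplicate_molecules <- function(records) {
  stopifnot(all(c("barcode", "umi", "feature") %in% names(records)))
  u <- unique(records[, c("barcode", "umi", "feature")])
  agg <- stats::aggregate(list(count = u$umi),
                          by = list(barcode = u$barcode,
                                    feature = u$feature), FUN = length)
  agg[order(agg$barcode, agg$feature), , drop = FALSE]
}

#' Library-level summary statistics of FLNC processing
#'
#' Computes the read-level yield table of a run: FL / non-FL / unknown
#' partition, whitelist hits, corrected barcodes, and total assigned
#' barcodes, with percentages.
#'
#' @param flnc_records output of [process_reads()]
#' @return a `library_stats` list: n_reads, n_fl, pct_fl, n_non_fl,
#'   n_unknown, n_cb_in_whitelist, pct_cb_in_whitelist, n_cb_corrected,
#'   pct_cb_corrected, n_total_assigned, pct_total_assigned (percentages on
#'   the conventional denominators: FL% of all reads, barcode percentages of
#'   FL reads)
#' @export
summarize_library <- function(flnc_records) {
  n <- nrow(flnc_records)
  n_fl <- sum(flnc_records$fl_status == "FL")
  n_nfl <- sum(flnc_records$fl_status == "non-FL")
  n_unk <- sum(flnc_records$fl_status == "unknown")
  n_exact <- sum(flnc_records$bc_status == "exact", na.rm = TRUE)
  n_corr <- sum(flnc_records$bc_status == "corrected", na.rm = TRUE)
  pct <- function(a, b) if (b == 0L) 0 else round(100 * a / b, 2L)
  out <- list(
    n_reads = n, n_fl = n_fl, pct_fl = pct(n_fl, n),
    n_non_fl = n_nfl, pct_non_fl = pct(n_nfl, n),
    n_unknown = n_unk, pct_unknown = pct(n_unk, n),
    n_cb_in_whitelist = n_exact,
    pct_cb_in_whitelist = pct(n_exact, n_fl),
    n_cb_corrected = n_corr,
    pct_cb_corrected = pct(n_corr, n_fl),
    n_total_assigned = n_exact + n_corr,
    pct_total_assigned = pct(n_exact + n_corr, n_fl),
    empty = n == 0L)
  class(out) <- "library_stats"
  out
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("reads %d | FL %d (%.2f%%) non-FL %d unknown %d\n",
              x$n_reads, x$n_fl, x$pct_fl, x$n_non_fl, x$n_unknown))
  cat(sprintf("CB in whitelist %d (%.2f%%) | corrected %d (%.2f%%) | total %d (%.2f%%)\n",
              x$n_cb_in_whitelist, x$pct_cb_in_whitelist,
              x$n_cb_corrected, x$pct_cb_corrected,
              x$n_total_assigned, x$pct_total_assigned))
  invisible(x)
}

#' Write library statistics as a two-column TSV
#'
#' @param stats a `library_stats` object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_library_stats <- function(stats, path) {
  df <- data.frame(metric = names(stats)[names(stats) != "empty"])
  df$value <- unlist(stats[df$metric], use.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write FLNC inserts as FASTA with `read_id|CB|UMI` names
#'
#' @param flnc_records output of [process_reads()]; only FL records with an
#'   assigned barcode are written
#' @param path output FASTA
#' @return `path`, invisibly
#' @export
write_flnc_fasta <- function(flnc_records, path) {
  keep <- flnc_records$fl_status == "FL" &
    !is.na(flnc_records$corrected_barcode)
  r <- flnc_records[keep, ]
  x <- Biostrings::DNAStringSet(r$insert_sequence)
  names(x) <- paste(r$read_id, r$corrected_barcode, r$umi, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Split `read_id|CB|UMI` names into components
#'
#' @param x character vector of composite read names
#' @return data.frame(read_id, barcode, umi)
#' @export
parse_read_names <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  data.frame(read_id = vapply(parts, `[`, character(1), 1L),
             barcode = vapply(parts, `[`, character(1), 2L),
             umi = vapply(parts, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}
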