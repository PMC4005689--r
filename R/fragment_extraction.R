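## Fragment extraction: from raw read pairs / paired alignments to the
## canonical fragment representation.  A fragment is the pair
## (termination site, priming site): the termination site is the last
## reverse-transcribed RNA nucleotide (5'-most aligned position of mate 1,
## after untemplated-nucleotide trimming) and the priming site is the first
## sequenced nucleotide of mate 2 (the 3'-most reference coordinate of the
## pair).  Coordinates are 1-based and inclusive on the sense strand.

#' Split the ligation barcode off a raw read pair
#'
#' The first `L` bases of read 1 are the barcode; they are removed from
#' read 1, and the last `L` bases (the read-through into the barcode) are
#' removed from read 2.  Pairs in which either trimmed read is shorter than
#' `min_len` nucleotides are flagged as discarded; a read 1 shorter than the
#' barcode itself is discarded with its own reason code.  Barcodes containing
#' `N` are retained but flagged ambiguous.
#'
#' @param read1,read2 character vectors of raw read sequences (vectorised).
#' @param L barcode length.
#' @param min_len minimum post-trimming read length to keep a pair.
#' @return data.frame with columns `barcode`, `read1`, `read2`, `keep`
#'   (logical), `reason` (`"ok"`, `"read1_shorter_than_barcode"`,
#'   `"trimmed_read_too_short"`), `ambiguous` (barcode contains N).
#' @export
split_barcode <- function(read1, read2, L = 7L, min_len = 15L) {
  n <- length(read1)
  if (length(read2) != n) stop("read1 and read2 must pair up")
  too_short <- nchar(read1) <= L
  barcode <- ifelse(too_short, NA_character_, substr(read1, 1L, L))
  r1 <- ifelse(too_short, NA_character_, substr(read1, L + 1L, nchar(read1)))
  r2 <- substr(read2, 1L, pmax(0L, nchar(read2) - L))
  short_after <- !too_short & (nchar(r1) < min_len | nchar(r2) < min_len)
  reason <- rep("ok", n)
  reason[short_after] <- "trimmed_read_too_short"
  reason[too_short] <- "read1_shorter_than_barcode"
  data.frame(barcode = barcode, read1 = r1, read2 = r2,
             keep = !(too_short | short_after), reason = reason,
             ambiguous = !is.na(barcode) & grepl("N", barcode, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Trim untemplated nucleotides at the cDNA 3' end
#'
#' Reverse transcriptase's terminal transferase activity appends 1-3
#' untemplated bases to the cDNA 3' end, which the aligner places at the
#' 5'-most (termination) end of mate 1 and which shift the apparent
#' termination site upstream.  Contiguous bases that mismatch the reference at
#' that end are trimmed, up to `max_trim`; the termination position moves
#' downstream (increases) by the number trimmed.  Matching bases are never
#' trimmed, so an untemplated base that happens to match the reference is not
#' corrected (the known ~25%-per-base blind spot of mismatch trimming).
#'
#' @param query character vector of mate-1 aligned sequences (soft clips
#'   removed, aligned orientation).
#' @param pos integer vector of 1-based leftmost reference positions.
#' @param reference single reference sequence (character).
#' @param max_trim maximum number of bases to trim (default 3).
#' @return integer vector of adjusted termination positions.
#' @export
trim_untemplated <- function(query, pos, reference, max_trim = 3L) {
  reference <- toupper(chartr("U", "T", reference))
  n_trim <- integer(length(query))
  for (i in seq_along(query)) {
    q <- query[i]
    upto <- min(max_trim, nchar(q))
    t <- 0L
    while (t < upto) {
      refbase <- substr(reference, pos[i] + t, pos[i] + t)
      if (refbase == "" || substr(q, t + 1L, t + 1L) == refbase) break
      t <- t + 1L
    }
    n_trim[i] <- t
  }
  as.integer(pos + n_trim)
}

#' Build a fragment table from resolved paired alignments
#'
#' Consumes the pair table produced by [read_alignments()]: one row per
#' properly paired, sense-orientation alignment with mate-1 sequence/position
#' and the mate-2 3'-most coordinate.  Applies untemplated-nucleotide trimming
#' to the termination site, validates `termination_pos <= priming_pos` and
#' reference bounds, and aggregates to the barcode level.
#'
#' @param pairs data.frame from [read_alignments()] (columns `rna_id`, `pos1`,
#'   `seq1`, `priming_pos`, `barcode`).
#' @param reference named character vector of reference sequences (see
#'   [read_reference()]).
#' @param max_trim untemplated trimming cap; 0 disables trimming.
#' @return barcode-level fragment table (`rna_id`, `termination_pos`,
#'   `priming_pos`, `barcode`, `read_count`), with a `tallies` attribute
#'   counting input/kept/rejected pairs.
#' @export
fragments_from_alignments <- function(pairs, reference, max_trim = 3L) {
  n_in <- nrow(pairs)
  if (n_in == 0L) {
    out <- empty_fragment_table()
    attr(out, "tallies") <- c(input = 0L, kept = 0L, invalid_span = 0L,
                              out_of_bounds = 0L)
    return(out)
  }
  term <- pairs$pos1
  for (rid in unique(pairs$rna_id)) {
    if (!rid %in% names(reference))
      stop("alignment references unknown sequence: ", rid)
    sel <- pairs$rna_id == rid
    if (max_trim > 0L)
      term[sel] <- trim_untemplated(pairs$seq1[sel], pairs$pos1[sel],
                                    reference[[rid]], max_trim = max_trim)
  }
  ref_len <- nchar(reference)[pairs$rna_id]
  in_bounds <- term >= 1L & pairs$priming_pos <= ref_len
  valid_span <- term <= pairs$priming_pos
  keep <- in_bounds & valid_span
  rows <- data.frame(rna_id = pairs$rna_id[keep],
                     termination_pos = term[keep],
                     priming_pos = pairs$priming_pos[keep],
                     barcode = pairs$barcode[keep],
                     stringsAsFactors = FALSE)
  out <- records_to_fragments(cbind(rows, read_count = 1L))
  attr(out, "tallies") <- c(input = n_in, kept = sum(keep),
                            invalid_span = sum(in_bounds & !valid_span),
                            out_of_bounds = sum(!in_bounds))
  out
}

empty_fragment_table <- function() {
  data.frame(rna_id = character(), termination_pos = integer(),
             priming_pos = integer(), barcode = character(),
             read_count = integer(), stringsAsFactors = FALSE)
}

#' Aggregate a barcode-level fragment table to the fragment level
#'
#' Collapses to one row per (rna_id, termination_pos, priming_pos) with the
#' total read count and the number of distinct barcodes `k`.  Barcodes
#' containing `N` count toward `read_count` but are excluded from `k`
#' (consistent with their exclusion from frequency estimation).
#'
#' @param fragments barcode-level fragment table.
#' @return data.frame with columns `rna_id`, `termination_pos`, `priming_pos`,
#'   `read_count`, `k`.
#' @export
aggregate_fragments <- function(fragments) {
  if (nrow(fragments) == 0L)
    return(data.frame(rna_id = character(), termination_pos = integer(),
                      priming_pos = integer(), read_count = integer(),
                      k = integer(), stringsAsFactors = FALSE))
  key <- paste(fragments$rna_id, fragments$termination_pos,
               fragments$priming_pos, sep = "\r")
  unambiguous <- !grepl("N", fragments$barcode, fixed = TRUE)
  s <- rowsum(cbind(fragments$read_count, as.integer(unambiguous)), key)
  parts <- strsplit(rownames(s), "\r", fixed = TRUE)
  agg <- data.frame(
    rna_id = vapply(parts, `[`, "", 1L),
    termination_pos = as.integer(vapply(parts, `[`, "", 2L)),
    priming_pos = as.integer(vapply(parts, `[`, "", 3L)),
    read_count = as.integer(s[, 1L]), k = as.integer(s[, 2L]),
    stringsAsFactors = FALSE)
  agg <- agg[order(agg$rna_id, agg$termination_pos, agg$priming_pos), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Filter fragments by span
#'
#' Removes fragments spanning fewer than `min_span` nucleotides, where the
#' span is `priming_pos - termination_pos + 1` (inclusive count of covered
#' nucleotides).  Short fragments are depleted by library size selection, so
#' dropping them (default threshold 100 nt for random-primed libraries)
#' removes the length regime where size selection distorts coverage;
#' `min_span = 0` leaves the table unchanged (single-primer analyses use all
#' fragments).
#'
#' @param fragments fragment table (barcode-level or aggregated).
#' @param min_span minimum inclusive span in nucleotides.
#' @return filtered table.
#' @export
span_filter <- function(fragments, min_span = 100L) {
  if (min_span <= 0L || nrow(fragments) == 0L) return(fragments)
  span <- fragments$priming_pos - fragments$termination_pos + 1L
  out <- fragments[span >= min_span, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a fragment table TSV
#'
#' @param fragments fragment table.
#' @param path file path.
#' @param extra named character vector of extra header fields.
#' @return `read_fragment_table` returns the data.frame.
#' @export
write_fragment_table <- function(fragments, path, extra = character()) {
  write_tsv_commented(fragments, path, extra = extra)
}

#' @rdname write_fragment_table
#' @export
read_fragment_table <- function(path) {
  df <- read_tsv_commented(path)
  int_cols <- intersect(c("termination_pos", "priming_pos", "read_count", "k",
                          "euc"), names(df))
  for (cl in int_cols) df[[cl]] <- as.integer(df[[cl]])
  if ("rna_id" %in% names(df)) df$rna_id <- as.character(df$rna_id)
  if ("barcode" %in% names(df)) df$barcode <- as.character(df$barcode)
  df
}
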