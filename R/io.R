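## Shared format readers: reference FASTA and paired SAM/BAM alignments.

#' Read a reference FASTA
#'
#' Sequences are upper-cased and U is normalised to T (alignments are in DNA
#' space even for RNA references).
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readBStringSet(path)   # tolerate RNA (U) input
  if (length(seqs) == 0L) stop("no sequences in FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(chartr("Uu", "Tt", as.character(seqs)))
  names(out) <- ids
  out
}

#' Read paired alignments and resolve mates
#'
#' Reads SAM (converted in place via [Rsamtools::asBam()]) or BAM, keeps
#' primary, mapped, properly oriented pairs (mate 1 on the forward strand,
#' mate 2 reverse -- the libraries are mapped sense-only), and resolves each
#' pair into one row.  The ligation barcode is taken from the standard `BC:Z`
#' optional tag on mate 1 (`N`-padded when absent).
#'
#' Skipped records are tallied, not silently dropped: the returned data.frame
#' carries a `tallies` attribute with counts of secondary/supplementary,
#' unmapped, unpaired (missing mate) and reverse-orientation records.
#'
#' @param path SAM or BAM file.
#' @param barcode_length barcode length used when the `BC` tag is missing.
#' @return data.frame with one row per resolved pair: `qname`, `rna_id`,
#'   `pos1` (mate-1 leftmost), `seq1`, `priming_pos` (mate-2 3'-most),
#'   `barcode`.
#' @export
read_alignments <- function(path, barcode_length = 7L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "BC")
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  flag <- rec$flag
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  unmapped <- bitwAnd(flag, 4L) > 0L
  use <- !secondary & !unmapped
  df <- data.frame(qname = rec$qname[use], flag = flag[use],
                   rna_id = as.character(rec$rname)[use], pos = rec$pos[use],
                   cigar = rec$cigar[use],
                   seq = as.character(rec$seq)[use],
                   stringsAsFactors = FALSE)
  bc <- rec$tag$BC
  df$bc <- if (is.null(bc)) rep(NA_character_, nrow(df)) else bc[use]
  is1 <- bitwAnd(df$flag, 64L) > 0L
  m1 <- df[is1, , drop = FALSE]
  m2 <- df[!is1, , drop = FALSE]
  idx <- match(m1$qname, m2$qname)
  unpaired <- sum(is.na(idx)) + sum(!m2$qname %in% m1$qname)
  ok <- !is.na(idx)
  m1 <- m1[ok, , drop = FALSE]
  m2 <- m2[idx[ok], , drop = FALSE]
  fwd1 <- bitwAnd(m1$flag, 16L) == 0L
  rev2 <- bitwAnd(m2$flag, 16L) > 0L
  same_ref <- m1$rna_id == m2$rna_id
  sense <- fwd1 & rev2 & same_ref
  n_reverse <- sum(!sense)
  m1 <- m1[sense, , drop = FALSE]
  m2 <- m2[sense, , drop = FALSE]
  ## strip leading soft clips from mate 1 so seq1 starts at pos1
  clip <- cigar_lead_clip(m1$cigar)
  seq1 <- substr(m1$seq, clip + 1L, nchar(m1$seq))
  barcode <- m1$bc
  barcode[is.na(barcode)] <- strrep("N", barcode_length)
  out <- data.frame(qname = m1$qname, rna_id = m1$rna_id, pos1 = m1$pos,
                    seq1 = seq1,
                    priming_pos = m2$pos + cigar_ref_width(m2$cigar) - 1L,
                    barcode = barcode, stringsAsFactors = FALSE)
  attr(out, "tallies") <- c(records = n,
                            secondary_or_supplementary = sum(secondary),
                            unmapped = sum(unmapped & !secondary),
                            unpaired = unpaired,
                            reverse_orientation = n_reverse,
                            pairs = nrow(out))
  out
}
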