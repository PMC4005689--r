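#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

#' Moving average with an upstream offset
#'
#' Smooths a per-position profile with a moving average of odd width, shifted
#' toward the 5' end. With the defaults (`window = 3`, `offset_upstream = 1`)
#' the smoothed value at position p is `mean(x[p:(p + 2)])`: reverse
#' transcription stops one nucleotide 3' of the backbone break, so shifting the
#' window upstream re-centres the signal on the cleaved position.
#'
#' Positions whose window reaches outside the profile, or covers any `NA`
#' (masked) value, are `NA` in the result.
#'
#' @param x numeric vector (per-position profile; `NA` = masked).
#' @param window odd integer window width in nucleotides.
#' @param offset_upstream integer shift of the window toward the 3' end of the
#'   indices (equivalently, of the signal toward the 5' end).
#' @return numeric vector of `length(x)`.
#' @export
moving_average_offset <- function(x, window = 3L, offset_upstream = 1L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be a positive odd integer")
  half <- (window - 1L) %/% 2L
  n <- length(x)
  idx <- seq_len(n)
  acc <- rep(0, n)
  for (j in seq_len(window) - 1L) {
    k <- idx + as.integer(offset_upstream) - half + j
    v <- rep(NA_real_, n)
    ok <- k >= 1L & k <= n
    v[ok] <- x[k[ok]]
    acc <- acc + v
  }
  acc / window
}

#' Pearson correlation over shared unmasked positions
#'
#' @param x,y numeric vectors of equal length; `NA` marks masked positions.
#' @param min_n minimum number of complete pairs required.
#' @return Pearson correlation coefficient.
#' @export
pearson_shared <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) stop("profiles must be aligned (equal length)")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_n)
    stop(sprintf("need at least %d shared positions, have %d", min_n, sum(ok)))
  stats::cor(x[ok], y[ok])
}

## CIGAR helper: reference-space width of an alignment.  GenomicAlignments
## (which ships cigarWidthAlongReferenceSpace) is not a dependency; the
## consumed CIGARs come from Bowtie-2-style end-to-end alignments and from the
## package's own simulator, so M/I/D/N/S/=/X coverage is sufficient.
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

## leading soft-clip length (bases of the read not aligned at the 5' end)
cigar_lead_clip <- function(cigar) {
  vapply(cigar, function(cg) {
    m <- regmatches(cg, regexpr("^\\d+S", cg))
    if (length(m) == 0L || is.na(cg)) 0L else as.integer(sub("S", "", m))
  }, integer(1), USE.NAMES = FALSE)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a TSV with a commented provenance header
#'
#' All interchange files are tab-separated with `#`-prefixed header lines
#' carrying the tool version, a hash of the run configuration and the seed;
#' coordinates are 1-based and inclusive throughout.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param extra named character vector of additional header fields.
#' @export
write_tsv_commented <- function(df, path, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("hrfseq"))
  hdr <- c(sprintf("# hrfseq v%s", ver),
           "# coordinates: 1-based, inclusive, sense strand")
  if (length(extra))
    hdr <- c(hdr, sprintf("# %s: %s", names(extra), as.character(extra)))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented TSV written by [write_tsv_commented()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tf))
}
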