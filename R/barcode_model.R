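## Barcode model: unequal-frequency random barcodes and saturation-corrected
## estimated unique counts (EUC).
##
## A 7-nt degenerate barcode is ligated to each cDNA before PCR, so the number
## of distinct barcodes k observed on a fragment counts pre-PCR molecules.  At
## high coverage barcodes saturate (the same barcode is ligated twice), and the
## synthesised adaptor pool carries barcodes at very unequal frequencies, so k
## underestimates the true number of ligation events n.  The model estimates
## per-position nucleotide frequencies from the data, derives per-barcode
## probabilities P_i assuming positional independence, tabulates the occupancy
## expectation
##
##   E[k | n] = sum_{i=1..m} (1 - (1 - P_i)^n),   m = 4^L,
##
## and inverts the table to read estimated unique counts n(k).

#' Estimate per-position barcode nucleotide frequencies
#'
#' Tallies nucleotide frequencies at each barcode position over the observed
#' set of barcodes (each distinct barcode of a fragment counted once), using
#' only fragments whose total read count lies within the three lowest quartiles
#' of per-fragment read counts.  Excluding the top read-count quartile avoids
#' bias from clonal PCR amplification of specific fragments.  The quartile is
#' the linear-interpolation (type 7) 75th percentile; fragments with read count
#' strictly greater than Q3 are excluded.
#'
#' Barcodes containing `N` are excluded from the tally (their count is recorded
#' in the `n_ambiguous` attribute); barcodes with characters outside
#' `{A,C,G,T,N}` or of the wrong length are rejected and counted in the
#' `n_rejected` attribute.
#'
#' @param fragments barcode-level fragment table: data.frame with columns
#'   `rna_id`, `termination_pos`, `priming_pos`, `barcode`, `read_count`
#'   (one row per distinct barcode of each fragment).
#' @param L barcode length (default 7).
#' @return an object of class `barcode_distribution`: list with elements `L`,
#'   `freq` (L x 4 matrix, columns A,C,G,T, rows summing to 1), `n_barcodes`
#'   (observations used), plus tally attributes.
#' @export
estimate_position_frequencies <- function(fragments, L = 7L) {
  required <- c("rna_id", "termination_pos", "priming_pos", "barcode",
                "read_count")
  if (!all(required %in% names(fragments)))
    stop("fragment table must have columns: ", paste(required, collapse = ", "))
  if (nrow(fragments) == 0L) stop("empty fragment table: nothing to estimate")
  frag_id <- paste(fragments$rna_id, fragments$termination_pos,
                   fragments$priming_pos, sep = "\r")
  frag_counts <- rowsum(fragments$read_count, frag_id)
  q3 <- stats::quantile(frag_counts[, 1L], 0.75, names = FALSE, type = 7)
  keep_frag <- rownames(frag_counts)[frag_counts[, 1L] <= q3]
  rows <- fragments[frag_id %in% keep_frag, , drop = FALSE]
  ## the observed *set* of barcodes of each fragment: one vote per distinct
  ## (fragment, barcode) combination
  rows <- rows[!duplicated(paste(frag_id[frag_id %in% keep_frag],
                                 rows$barcode, sep = "\r")), , drop = FALSE]
  bc <- rows$barcode
  bad_len <- nchar(bc) != L
  bad_chr <- grepl("[^ACGTN]", bc)
  n_rejected <- sum(bad_len | bad_chr)
  bc <- bc[!(bad_len | bad_chr)]
  has_n <- grepl("N", bc, fixed = TRUE)
  n_ambiguous <- sum(has_n)
  bc <- bc[!has_n]
  if (length(bc) == 0L)
    stop("no usable barcodes after the quartile filter and N/alphabet checks")
  chars <- matrix(unlist(strsplit(bc, "", fixed = TRUE), use.names = FALSE),
                  ncol = L, byrow = TRUE)
  freq <- t(apply(chars, 2L, function(col) {
    tab <- table(factor(col, levels = BASES))
    as.numeric(tab) / length(col)
  }))
  colnames(freq) <- BASES
  rownames(freq) <- paste0("pos", seq_len(L))
  out <- structure(list(L = as.integer(L), freq = freq,
                        n_barcodes = length(bc)),
                   class = "barcode_distribution")
  attr(out, "n_rejected") <- n_rejected
  attr(out, "n_ambiguous") <- n_ambiguous
  if (n_rejected > 0L)
    warning(sprintf("%d barcode(s) rejected (wrong length or non-ACGTN)",
                    n_rejected))
  out
}

#' @export
print.barcode_distribution <- function(x, ...) {
  cat(sprintf("barcode_distribution: L = %d, %d observations\n",
              x$L, x$n_barcodes))
  print(round(x$freq, 4))
  invisible(x)
}

#' Per-barcode probabilities from a position-frequency matrix
#'
#' Positions in the barcode are assumed independent, so the probability of a
#' barcode is the product of its per-position nucleotide frequencies:
#' `P(b1..bL) = prod_j freq[j, b_j]`.  Barcodes are ordered lexicographically
#' over the alphabet A,C,G,T with position 1 most significant.
#'
#' @param freq an L x 4 frequency matrix (columns A,C,G,T) or a
#'   `barcode_distribution`.
#' @return numeric vector of length `4^L` summing to 1, with attribute `L`.
#' @export
barcode_probabilities <- function(freq) {
  if (inherits(freq, "barcode_distribution")) freq <- freq$freq
  freq <- as.matrix(freq)
  if (ncol(freq) != 4L) stop("frequency matrix must have 4 columns (A,C,G,T)")
  L <- nrow(freq)
  if (L > 12L)
    stop("barcode length ", L, " would need a 4^", L,
         "-entry table; reduce L to at most 12")
  rs <- rowSums(freq)
  if (any(abs(rs - 1) > 1e-9))
    stop("each row of the frequency matrix must sum to 1")
  probs <- 1
  for (j in seq_len(L)) probs <- as.vector(outer(probs, freq[j, ]))
  structure(probs, L = L)
}

#' Barcode strings in the probability-vector order
#'
#' @param L barcode length (<= 8 to keep the character vector small).
#' @return character vector of length `4^L` matching
#'   [barcode_probabilities()] ordering.
#' @export
barcode_strings <- function(L) {
  if (L > 8L) stop("refusing to materialise 4^", L, " barcode strings")
  s <- ""
  for (j in seq_len(L)) s <- as.vector(outer(s, BASES, paste0))
  s
}

## collapse a probability vector to (unique value, multiplicity) pairs --
## E[k|n] only depends on the multiset of P_i, and equal-frequency pools
## collapse to a single term.
collapse_probs <- function(probs) {
  if (abs(sum(probs) - 1) > 1e-6) stop("barcode probabilities must sum to 1")
  if (any(probs < 0)) stop("barcode probabilities must be non-negative")
  r <- rle(sort(probs))
  list(p = r$values, w = r$lengths, m = length(probs))
}

#' Expected number of distinct barcodes after n ligation events
#'
#' The occupancy expectation `E[k] = sum_i (1 - (1 - P_i)^n)`, evaluated in
#' log space (`(1-P_i)^n = exp(n * log1p(-P_i))`) so large `n` does not
#' underflow.  With equal frequencies this reduces to
#' `m * (1 - (1 - 1/m)^n)`.
#'
#' @param n non-negative ligation-event count(s); vectorised.
#' @param probs barcode probability vector (sums to 1).
#' @return expected distinct-barcode count(s), same length as `n`.
#' @export
expected_unique_barcodes <- function(n, probs) {
  if (any(n < 0)) stop("`n` must be non-negative")
  cp <- collapse_probs(probs)
  lp <- log1p(-cp$p)             # -Inf when P_i = 1, handled by exp() -> 0
  vapply(n, function(ni) {
    if (ni == 0) return(0)
    sum(cp$w * -expm1(ni * lp))
  }, numeric(1))
}

#' Tabulate the k(n) curve and invert it to an n(k) lookup
#'
#' `k_of_n[n]` is the expected distinct-barcode count after `n` ligations.
#' The inverse maps each achievable integer `k` to the `n` whose `k(n)` is
#' nearest to `k`, ties going to the smaller `n` (a conservative correction);
#' rounding to the nearest tabulated point makes `n_of_k` a non-decreasing
#' integer lookup.
#'
#' Sizing: pass `n_max` directly, or pass `k_max` and the table is sized (by
#' monotone root finding on the forward curve) just large enough to invert
#' `k_max`.  With both `NULL`, `n_max` defaults to the smallest `n` with
#' `k(n) >= m - 0.5` (full saturation), capped at 1e7 -- only sensible for
#' small `m`.
#'
#' Exact tabulation of every integer `n` costs O(U * n_max) where U is the
#' number of distinct `P_i` values, which is prohibitive deep into saturation
#' (unequal frequencies, `n` in the 1e5 range).  The table is therefore exact
#' for `n` up to a work cap (at least 4096, more when U is small) and switches
#' to a dense geometric grid (ratio 1.02) beyond it, inverting by monotone
#' interpolation of `n` against `k` in log space; in that regime the
#' interpolation error is orders of magnitude below the sampling noise of a
#' saturated `k`.  Everything the saturation-scale analyses touch
#' (`k <= sqrt(m)` and far beyond) stays on the exact path.
#'
#' @param probs barcode probability vector.
#' @param n_max largest tabulated `n` (optional, see above).
#' @param k_max largest observed-unique-barcode count the table must cover
#'   (optional).
#' @param n_exact_budget approximate number of curve evaluations allowed for
#'   the exact integer tabulation.
#' @return an object of class `euc_table`: list with `k_of_n` (numeric vector,
#'   index = n, exact up to `n_exact`), `n_of_k` (integer vector, index = k),
#'   `n_exact`, `n_max`, `k_max`, `m`, and the interpolation grid
#'   (`grid_n`, `grid_k`) when one was needed.
#' @export
build_euc_table <- function(probs, n_max = NULL, k_max = NULL,
                            n_exact_budget = 4e7) {
  cp <- collapse_probs(probs)
  m <- cp$m
  lp <- log1p(-cp$p)
  kfun <- function(n) sum(cp$w * -expm1(n * lp))
  n_for_k <- function(k_target) {
    ## smallest n with k(n) >= k_target (k is concave increasing in n)
    lo <- max(1, floor(k_target)); hi <- lo
    while (kfun(hi) < k_target) {
      hi <- hi * 2
      if (hi > 1e9) stop("target k = ", k_target, " is not reachable")
    }
    ceiling(stats::uniroot(function(n) kfun(n) - k_target, c(lo / 2, hi),
                           tol = 0.25)$root)
  }
  if (is.null(n_max)) {
    if (!is.null(k_max)) {
      if (k_max >= m)
        stop("k_max = ", k_max, " >= m = ", m,
             ": more distinct barcodes than exist")
      n_max <- n_for_k(min(k_max + 0.5, m - 0.5))
    } else {
      n_max <- min(n_for_k(m - 0.5), 1e7)
    }
  }
  n_max <- as.integer(n_max)
  if (n_max < 1L) stop("n_max must be >= 1")
  n_exact <- min(n_max,
                 max(4096L, as.integer(n_exact_budget / length(cp$p))))
  eval_k <- function(nn) {
    ## chunked so the (unique-probs x n) matrix stays small
    out <- numeric(length(nn))
    chunk <- max(1L, as.integer(2^22 / length(cp$p)))
    for (start in seq(1L, length(nn), by = chunk)) {
      sel <- start:min(start + chunk - 1L, length(nn))
      out[sel] <- as.vector(crossprod(cp$w, -expm1(outer(lp, nn[sel]))))
    }
    out
  }
  k_of_n <- eval_k(seq_len(n_exact))
  grid_n <- NULL
  grid_k <- NULL
  if (n_max > n_exact) {
    grid_n <- unique(c(n_exact,
                       ceiling(n_exact * 1.02^seq_len(
                         ceiling(log(n_max / n_exact) / log(1.02)))),
                       n_max))
    grid_n <- grid_n[grid_n <= n_max]
    grid_k <- eval_k(grid_n)
  }
  k_top <- floor(if (is.null(grid_k)) k_of_n[n_exact] else max(grid_k))
  n_of_k <- integer(max(k_top, 0L))
  if (k_top >= 1L) {
    k_exact_top <- floor(k_of_n[n_exact])
    ks <- seq_len(k_exact_top)
    lo <- findInterval(ks, k_of_n)            # largest n with k(n) <= k
    lo[lo < 1L] <- 1L
    hi <- pmin(lo + 1L, n_exact)
    n_of_k[ks] <- ifelse(ks - k_of_n[lo] <= k_of_n[hi] - ks, lo, hi)
    if (k_top > k_exact_top) {                # interpolated saturation regime
      ks2 <- (k_exact_top + 1L):k_top
      ln <- stats::approx(grid_k, log(grid_n), xout = ks2, rule = 2)$y
      n_of_k[ks2] <- as.integer(round(exp(ln)))
    }
    n_of_k <- as.integer(cummax(n_of_k))      # tie -> smaller n; monotone
  }
  structure(list(k_of_n = k_of_n, n_of_k = n_of_k,
                 n_exact = n_exact, n_max = n_max, k_max = length(n_of_k),
                 m = m, grid_n = grid_n, grid_k = grid_k),
            class = "euc_table")
}

#' @export
print.euc_table <- function(x, ...) {
  cat(sprintf("euc_table: m = %d barcodes, n tabulated to %d, invertible k <= %d\n",
              x$m, x$n_max, x$k_max))
  invisible(x)
}

#' Estimated unique count for an observed distinct-barcode count
#'
#' Reads the saturation-corrected EUC `n` for observed `k` off an inverted
#' occupancy table.  `k = 0` maps to `n = 0`; `k` beyond the invertible range
#' of the table (at or past saturation) is an error.
#'
#' @param k observed distinct-barcode count(s); vectorised.
#' @param table an `euc_table`.
#' @return integer EUC(s).
#' @export
estimate_unique_count <- function(k, table) {
  if (!inherits(table, "euc_table")) stop("`table` must be an euc_table")
  k <- as.integer(k)
  if (any(k < 0L)) stop("`k` must be non-negative")
  bad <- k > table$k_max
  if (any(bad))
    stop(sprintf(paste0("observed k = %d is saturated beyond the table ",
                        "(largest invertible k = %d of m = %d barcodes); ",
                        "rebuild with a larger k_max"),
                 max(k[bad]), table$k_max, table$m))
  out <- integer(length(k))
  nz <- k > 0L
  out[nz] <- table$n_of_k[k[nz]]
  out
}

#' Attach EUCs to an aggregated fragment table
#'
#' Convenience wrapper: builds an [build_euc_table()] sized for the largest
#' observed `k` and maps every fragment's distinct-barcode count to its EUC.
#'
#' @param fragments aggregated fragment table with column `k`
#'   (see [aggregate_fragments()]).
#' @param probs barcode probability vector for this library's ligation
#'   reaction.
#' @return `fragments` with an integer `euc` column.
#' @export
add_euc <- function(fragments, probs) {
  if (!"k" %in% names(fragments))
    stop("aggregated fragment table required (missing `k` column)")
  tab <- build_euc_table(probs, k_max = max(fragments$k, 1L))
  fragments$euc <- estimate_unique_count(fragments$k, tab)
  fragments
}

#' Write a barcode frequency matrix as TSV
#'
#' Layout mirrors a position-by-nucleotide table: one row per barcode
#' position, columns A, C, G, T.
#'
#' @param bd `barcode_distribution` (or bare frequency matrix).
#' @param path output path.
#' @export
write_frequency_matrix <- function(bd, path) {
  freq <- if (inherits(bd, "barcode_distribution")) bd$freq else bd
  df <- data.frame(position = seq_len(nrow(freq)), freq, check.names = FALSE)
  write_tsv_commented(df, path)
}
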