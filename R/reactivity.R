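## Reactivity: per-position accessibility from EUC-weighted fragments.
##
## The termination-coverage ratio TCR[p] is the fraction of reverse
## transcriptases reaching position p that terminate there: termination EUC at
## p divided by the effective coverage at p.  The treated library's TCR is
## probing signal plus spontaneous-termination background; the control's TCR
## is background only, so dTCR = TCR_treated - TCR_control is the per-position
## accessibility signal.

#' Per-position termination EUC
#'
#' @param fragments aggregated fragment table with an `euc` column (single
#'   reference).
#' @param ref_len reference length.
#' @return numeric vector of length `ref_len`; `termination_euc[p]` is the sum
#'   of EUCs of fragments terminating at p.
#' @export
termination_counts <- function(fragments, ref_len) {
  check_euc_table_cols(fragments, ref_len)
  out <- numeric(ref_len)
  if (nrow(fragments) == 0L) return(out)
  s <- rowsum(as.numeric(fragments$euc), fragments$termination_pos)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Per-position effective coverage EUC
#'
#' `coverage[p]` sums the EUCs of fragments terminating at or spanning p.
#' With `min_priming_distance > 0`, a fragment contributes to a position only
#' if its priming site is at least that far downstream
#' (`priming_pos - p >= min_priming_distance`), which excludes the length
#' regime where library size selection decides whether a fragment terminating
#' near p would have been sequenced at all.  Use 0 for single-primer
#' (run-off) libraries and 100 nt for random-primed, size-selected ones.
#'
#' @inheritParams termination_counts
#' @param min_priming_distance minimum position-to-priming-site distance.
#' @return numeric coverage vector of length `ref_len`.
#' @export
effective_coverage <- function(fragments, ref_len, min_priming_distance = 0L) {
  check_euc_table_cols(fragments, ref_len)
  if (min_priming_distance < 0L) stop("min_priming_distance must be >= 0")
  delta <- numeric(ref_len + 1L)
  if (nrow(fragments) > 0L) {
    from <- fragments$termination_pos
    to <- fragments$priming_pos - as.integer(min_priming_distance)
    keep <- to >= from
    from <- from[keep]; to <- to[keep]
    euc <- as.numeric(fragments$euc[keep])
    s1 <- rowsum(euc, from)
    delta[as.integer(rownames(s1))] <- delta[as.integer(rownames(s1))] + s1[, 1L]
    s2 <- rowsum(euc, to + 1L)
    idx <- as.integer(rownames(s2))
    ok <- idx <= ref_len + 1L
    delta[idx[ok]] <- delta[idx[ok]] - s2[ok, 1L]
  }
  cumsum(delta)[seq_len(ref_len)]
}

check_euc_table_cols <- function(fragments, ref_len) {
  need <- c("termination_pos", "priming_pos", "euc")
  if (!all(need %in% names(fragments)))
    stop("fragment table with EUC required (columns ",
         paste(need, collapse = ", "), ")")
  if (nrow(fragments) > 0L &&
      (min(fragments$termination_pos) < 1L ||
       max(fragments$priming_pos) > ref_len))
    stop("fragment coordinates outside [1, ", ref_len, "]")
  invisible(TRUE)
}

#' Termination-coverage ratio profile
#'
#' @param termination_euc,coverage aligned per-position vectors.
#' @return `termination_euc / coverage`, `NA` (masked) where coverage is 0.
#' @export
tcr_profile <- function(termination_euc, coverage) {
  if (length(termination_euc) != length(coverage))
    stop("termination and coverage vectors must be aligned")
  out <- rep(NA_real_, length(coverage))
  pos <- coverage > 0
  out[pos] <- termination_euc[pos] / coverage[pos]
  out
}

#' Background-normalised accessibility (delta-TCR)
#'
#' Subtracts the control library's TCR from the treated library's, position by
#' position.  Values can be negative (e.g. control-specific nuclease stops)
#' and are deliberately not clipped; positions masked in either library are
#' masked in the difference.
#'
#' @param treated_tcr,control_tcr aligned TCR vectors.
#' @return per-position dTCR.
#' @export
delta_tcr <- function(treated_tcr, control_tcr) {
  if (length(treated_tcr) != length(control_tcr))
    stop("treated and control profiles must be aligned")
  treated_tcr - control_tcr
}

#' Coverage cutoff for reliable termination detection
#'
#' The smallest coverage `c` at which a termination event would be observed
#' with probability at least `detection_prob`, given a per-position cleavage
#' probability `p` (the median dTCR): `1 - (1 - p)^c >= detection_prob`, i.e.
#' `c = ceiling(log(1 - detection_prob) / log(1 - p))`.
#'
#' @param median_delta_tcr average cleavage probability per nucleotide,
#'   in (0, 1).
#' @param detection_prob target detection probability (default 0.9).
#' @return integer minimum coverage.
#' @export
coverage_cutoff <- function(median_delta_tcr, detection_prob = 0.9) {
  p <- median_delta_tcr
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("median dTCR must lie in (0, 1); got ", format(p))
  if (detection_prob >= 1) stop("detection_prob must be < 1")
  max(1L, as.integer(ceiling(log1p(-detection_prob) / log1p(-p))))
}

#' Smooth a dTCR profile (moving average, offset upstream)
#'
#' Thin wrapper around [moving_average_offset()] kept as the reactivity-facing
#' name; see there for the windowing convention.
#'
#' @inheritParams moving_average_offset
#' @export
smooth_offset <- function(x, window = 3L, offset_upstream = 1L) {
  moving_average_offset(x, window = window, offset_upstream = offset_upstream)
}

#' Background signal fraction of the treated library
#'
#' `100 * sum(control TCR) / sum(treated TCR)` over an analysis region chosen
#' to exclude the 5' run-off; only positions where both profiles are defined
#' contribute.
#'
#' @param treated_tcr,control_tcr aligned TCR vectors.
#' @param region integer positions to sum over (default: all).
#' @return background percentage.
#' @export
background_fraction <- function(treated_tcr, control_tcr,
                                region = seq_along(treated_tcr)) {
  t <- treated_tcr[region]; c <- control_tcr[region]
  ok <- is.finite(t) & is.finite(c)
  ts <- sum(t[ok])
  if (!any(ok) || ts == 0)
    stop("treated TCR sums to zero on the region; background undefined")
  100 * sum(c[ok]) / ts
}

#' Average cleavage spacing implied by a median dTCR
#'
#' The median dTCR is the average per-nucleotide cleavage probability, so its
#' reciprocal is the expected number of nucleotides per hydroxyl-radical
#' cleavage (e.g. 0.0033 -> one cleavage per ~303 nt).
#'
#' @param median_delta_tcr average per-nucleotide cleavage probability.
#' @return nucleotides per cleavage event.
#' @export
cleavage_spacing <- function(median_delta_tcr) {
  if (any(median_delta_tcr <= 0)) stop("median dTCR must be positive")
  1 / median_delta_tcr
}

#' Probability of at least one hit on a molecule
#'
#' Diagnostic companion to [cleavage_spacing()]: `1 - (1 - p)^len`, the chance
#' a molecule of `len` analysed nucleotides carries at least one cleavage.
#'
#' @param median_delta_tcr per-nucleotide cleavage probability.
#' @param len number of nucleotides at risk.
#' @return probability in (0, 1).
#' @export
single_hit_probability <- function(median_delta_tcr, len) {
  -expm1(len * log1p(-median_delta_tcr))
}

#' Full reactivity profile from treated and control fragment tables
#'
#' Runs the per-library signal computation and the treated-minus-control
#' normalisation in the stated order: termination EUC and effective coverage
#' per library; TCR; dTCR on positions defined in both; restriction to the
#' analysis `region`; a first-pass median dTCR over all covered region
#' positions; the coverage cutoff derived from that median, applied to both
#' libraries (one iteration -- deterministic); the final median dTCR over the
#' surviving positions; and moving-average smoothing with the upstream offset.
#'
#' @param treated,control aggregated fragment tables with `euc` (single
#'   reference each).
#' @param ref_len reference length.
#' @param region `c(start, end)` analysis interval (1-based inclusive),
#'   default the whole molecule; positions outside are masked.  Choose the
#'   start downstream of the 5' run-off pile-up.
#' @param min_priming_distance see [effective_coverage()].
#' @param window,offset_upstream see [smooth_offset()].
#' @param detection_prob see [coverage_cutoff()].
#' @param apply_cutoff set `FALSE` to skip coverage masking (diagnostics).
#' @return object of class `reactivity_profile`: list with per-position
#'   vectors (`termination_euc_t/c`, `coverage_t/c`, `tcr_t/c`, `delta_tcr`,
#'   `smoothed`, `masked`) and scalars (`median_delta_tcr`,
#'   `median_delta_tcr_prepass`, `cutoff`, `background_percent`, `region`).
#' @export
reactivity_profile <- function(treated, control, ref_len,
                               region = c(1L, ref_len),
                               min_priming_distance = 0L,
                               window = 3L, offset_upstream = 1L,
                               detection_prob = 0.9,
                               apply_cutoff = TRUE) {
  if (length(region) != 2L || region[1] > region[2])
    stop("`region` must be c(start, end) with start <= end")
  term_t <- termination_counts(treated, ref_len)
  term_c <- termination_counts(control, ref_len)
  cov_t <- effective_coverage(treated, ref_len, min_priming_distance)
  cov_c <- effective_coverage(control, ref_len, min_priming_distance)
  tcr_t <- tcr_profile(term_t, cov_t)
  tcr_c <- tcr_profile(term_c, cov_c)
  dt <- delta_tcr(tcr_t, tcr_c)
  in_region <- seq_len(ref_len) >= region[1] & seq_len(ref_len) <= region[2]
  valid <- in_region & is.finite(dt)
  if (!any(valid)) stop("no covered positions inside the analysis region")
  p1 <- stats::median(dt[valid])
  cutoff <- NA_integer_
  if (apply_cutoff && p1 > 0 && p1 < 1) {
    cutoff <- coverage_cutoff(p1, detection_prob)
    valid <- valid & cov_t >= cutoff & cov_c >= cutoff
    if (!any(valid))
      stop("coverage cutoff ", cutoff, " masks every region position")
  }
  dt_masked <- ifelse(valid, dt, NA_real_)
  structure(list(
    ref_len = ref_len, region = as.integer(region),
    termination_euc_t = term_t, termination_euc_c = term_c,
    coverage_t = cov_t, coverage_c = cov_c,
    tcr_t = tcr_t, tcr_c = tcr_c,
    delta_tcr = dt_masked,
    smoothed = smooth_offset(dt_masked, window, offset_upstream),
    masked = !valid,
    median_delta_tcr = stats::median(dt_masked, na.rm = TRUE),
    median_delta_tcr_prepass = p1,
    cutoff = cutoff,
    background_percent = background_fraction(tcr_t, tcr_c,
                                             region[1]:region[2])),
    class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat(sprintf(paste0("reactivity_profile: %d nt, region %d-%d\n",
                     "  median dTCR %.5f (~1 cleavage per %.0f nt), ",
                     "background %.1f%%, coverage cutoff %s\n"),
              x$ref_len, x$region[1], x$region[2], x$median_delta_tcr,
              cleavage_spacing(max(x$median_delta_tcr, 1e-12)),
              x$background_percent,
              ifelse(is.na(x$cutoff), "none", x$cutoff)))
  invisible(x)
}

#' Write a reactivity profile as TSV (+ JSON summary sidecar)
#'
#' @param profile `reactivity_profile`.
#' @param path output TSV path; the summary goes to `<path>.summary.json`.
#' @param extra extra header fields for the TSV.
#' @return invisible path.
#' @export
write_reactivity <- function(profile, path, extra = character()) {
  df <- data.frame(position = seq_len(profile$ref_len),
                   termination_euc_t = profile$termination_euc_t,
                   termination_euc_c = profile$termination_euc_c,
                   coverage_t = profile$coverage_t,
                   coverage_c = profile$coverage_c,
                   tcr_t = round(profile$tcr_t, 8),
                   tcr_c = round(profile$tcr_c, 8),
                   delta_tcr = round(profile$delta_tcr, 8),
                   smoothed = round(profile$smoothed, 8),
                   masked = as.integer(profile$masked))
  write_tsv_commented(df, path, extra = extra)
  summary <- list(median_delta_tcr = profile$median_delta_tcr,
                  median_delta_tcr_prepass = profile$median_delta_tcr_prepass,
                  background_percent = profile$background_percent,
                  coverage_cutoff = profile$cutoff,
                  region = profile$region,
                  cleavage_spacing_nt =
                    unname(cleavage_spacing(max(profile$median_delta_tcr,
                                                1e-12))))
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
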