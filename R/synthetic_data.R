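## Synthetic HRF-Seq experiments with fully known truth: per-position cleavage
## probabilities, spontaneous RT-termination background, unequal barcode
## ligation frequencies, length-biased geometric PCR duplication and library
## size selection.  Every downstream module can be exercised against the
## recorded truth without any external data.

#' Simulation configuration
#'
#' Defaults state a single-primer experiment in the single-hit probing regime:
#' a 300-nt RNA, 1e5 reverse-transcription events per library, background
#' (spontaneous) termination 0.002 per nucleotide, per-position cleavage
#' probabilities spanning 0-0.02 with median ~0.0025, a 7-nt barcode pool with
#' unequal per-position nucleotide frequencies (Dirichlet perturbation of
#' uniform), and modest length-biased PCR duplication.  Random-primed mode
#' (`priming = "random"`) adds uniform priming across the molecule and a
#' 100-600 nt insert size-selection window.
#'
#' @param rna_length reference length (nt).
#' @param rna_seq reference sequence; generated from `seed` when `NULL`.
#' @param cleavage per-position cleavage probability vector (recycled checks
#'   apply); generated when `NULL`: `0.02 * u^3`, `u ~ U(0,1)` i.i.d.
#' @param background spontaneous termination probability per nucleotide.
#' @param priming `"single"` (one primer at the 3' end) or `"random"`.
#' @param n_events reverse-transcription events per library.
#' @param barcode_length barcode length L.
#' @param barcode_freq true L x 4 position-frequency matrix; generated when
#'   `NULL` (`rgamma(4, 5)` rows, normalised).
#' @param pcr_max_factor mean duplication factor for the shortest fragments
#'   (geometric model; 1 = no duplication).
#' @param pcr_length_decay e-folding length (nt) of the duplication bias.
#' @param size_window `c(min, max)` insert span retained by size selection,
#'   or `NULL` for none.
#' @param seed integer random seed (drives every draw).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(rna_length = 300L, rna_seq = NULL, cleavage = NULL,
                       background = 0.002,
                       priming = c("single", "random"),
                       n_events = 1e5, barcode_length = 7L,
                       barcode_freq = NULL,
                       pcr_max_factor = 10, pcr_length_decay = 100,
                       size_window = NULL, seed = 1L) {
  priming <- match.arg(priming)
  if (is.null(size_window) && priming == "random")
    size_window <- c(100L, 600L)
  cfg <- list(rna_length = as.integer(rna_length), rna_seq = rna_seq,
              cleavage = cleavage, background = background, priming = priming,
              n_events = as.integer(n_events),
              barcode_length = as.integer(barcode_length),
              barcode_freq = barcode_freq,
              pcr_max_factor = pcr_max_factor,
              pcr_length_decay = pcr_length_decay,
              size_window = size_window, seed = as.integer(seed))
  set.seed(cfg$seed)
  if (is.null(cfg$rna_seq))
    cfg$rna_seq <- paste(sample(BASES, cfg$rna_length, replace = TRUE),
                         collapse = "")
  cfg$rna_length <- nchar(cfg$rna_seq)
  if (is.null(cfg$cleavage))
    cfg$cleavage <- 0.02 * stats::runif(cfg$rna_length)^3
  if (length(cfg$cleavage) != cfg$rna_length)
    stop("cleavage vector must have one entry per nucleotide")
  if (any(cfg$cleavage < 0 | cfg$cleavage > 1) ||
      cfg$background < 0 || cfg$background > 1)
    stop("probabilities must lie in [0, 1]")
  if (is.null(cfg$barcode_freq)) {
    cfg$barcode_freq <- t(vapply(seq_len(cfg$barcode_length), function(j) {
      w <- stats::rgamma(4L, shape = 5)
      w / sum(w)
    }, numeric(4)))
    colnames(cfg$barcode_freq) <- BASES
  }
  if (!is.null(cfg$size_window) &&
      (length(cfg$size_window) != 2L || any(cfg$size_window <= 0)))
    stop("size_window must be a positive c(min, max)")
  structure(cfg, class = "sim_config")
}

## termination-site distribution for one priming site: RT primes at pr and
## walks 5'-ward; a break between p-1 and p (probability hazard[p]) leaves p
## as the last transcribed nucleotide; surviving to the 5' end terminates at 1
terminal_distribution <- function(hazard, pr) {
  h <- hazard[seq_len(pr)]
  q <- 1 - h
  cc <- c(1, cumprod(rev(q)))            # cc[j+1] = prod of last j survival
  tail_prod <- cc[pr - seq_len(pr) + 1L] # prod_{j = p+1..pr} q[j]
  p_term <- h * tail_prod
  p_term[1L] <- p_term[1L] + cc[pr + 1L] # run-off mass
  p_term
}

draw_barcodes <- function(n, freq) {
  cols <- apply(freq, 1L, function(f)
    sample(BASES, n, replace = TRUE, prob = f))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  do.call(paste0, as.data.frame(cols, stringsAsFactors = FALSE))
}

#' Simulate one sequencing library
#'
#' Draws `n_events` reverse-transcription events: a priming site, a 5'-ward
#' walk terminating at each nucleotide with probability `cleavage + background`
#' (treated) or `background` alone (control), a ligation barcode from the true
#' unequal-frequency pool, a geometric PCR copy number whose mean decays with
#' fragment span, and size selection on the span.  The treated and control
#' libraries of one experiment use seeds `seed` and `seed + 1`.
#'
#' @param config a [sim_config()].
#' @param type `"treated"` or `"control"`.
#' @return molecule-level data.frame (`rna_id`, `molecule`, `termination_pos`,
#'   `priming_pos`, `barcode`, `read_count`), with attribute `truth`: a list
#'   holding the config, the hazard vector used and the per-fragment true
#'   unique counts (`n_true` per (termination_pos, priming_pos)).
#' @export
simulate_library <- function(config, type = c("treated", "control")) {
  type <- match.arg(type)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + (type == "control"))
  L <- config$rna_length
  ## break between p-1 and p leaves p as the last transcribed nucleotide:
  ## termination at p reports cleavage of the ribose at p-1, the same 1-nt
  ## upstream offset the smoothing step undoes
  cleav_haz <- if (type == "treated") c(0, config$cleavage[-L]) else rep(0, L)
  hazard <- pmin(1, config$background + cleav_haz)
  priming_pos <- if (config$priming == "single") {
    rep(L, config$n_events)
  } else {
    sample.int(L, config$n_events, replace = TRUE)
  }
  term <- integer(config$n_events)
  for (pr in sort(unique(priming_pos))) {
    sel <- priming_pos == pr
    counts <- as.vector(stats::rmultinom(1L, sum(sel),
                                         terminal_distribution(hazard, pr)))
    term[sel] <- sample(rep.int(seq_len(pr), counts))
  }
  barcode <- draw_barcodes(config$n_events, config$barcode_freq)
  span <- priming_pos - term + 1L
  mean_dup <- 1 + (config$pcr_max_factor - 1) *
    exp(-(span - 1) / config$pcr_length_decay)
  read_count <- 1L + stats::rgeom(config$n_events, prob = 1 / mean_dup)
  rec <- data.frame(rna_id = "sim_rna", molecule = seq_len(config$n_events),
                    termination_pos = term, priming_pos = priming_pos,
                    barcode = barcode, read_count = read_count,
                    stringsAsFactors = FALSE)
  if (!is.null(config$size_window)) {
    keep <- span >= config$size_window[1] & span <= config$size_window[2]
    rec <- rec[keep, , drop = FALSE]
    rownames(rec) <- NULL
  }
  tf <- rowsum(rep(1L, nrow(rec)),
               paste(rec$termination_pos, rec$priming_pos, sep = "\r"))
  tf_key <- strsplit(rownames(tf), "\r", fixed = TRUE)
  truth_frag <- data.frame(
    termination_pos = as.integer(vapply(tf_key, `[`, "", 1L)),
    priming_pos = as.integer(vapply(tf_key, `[`, "", 2L)),
    n_true = tf[, 1L])
  truth_frag <- truth_frag[order(truth_frag$termination_pos,
                                 truth_frag$priming_pos), , drop = FALSE]
  rownames(truth_frag) <- NULL
  attr(rec, "truth") <- list(type = type, config = config, hazard = hazard,
                             cleavage = if (type == "treated") config$cleavage
                                        else rep(0, L),
                             fragments = truth_frag)
  rec
}

#' Simulate a treated/control experiment pair
#'
#' @param config a [sim_config()].
#' @return list with `treated` and `control` molecule tables (see
#'   [simulate_library()]) and the shared `config`.
#' @export
simulate_experiment <- function(config) {
  list(treated = simulate_library(config, "treated"),
       control = simulate_library(config, "control"),
       config = config)
}

#' Collapse molecule-level simulation records to a barcode-level table
#'
#' PCR copies of the same molecule carry the same barcode, so the barcode-level
#' `read_count` sums `read_count` over molecules sharing
#' (fragment, barcode).
#'
#' @param records output of [simulate_library()].
#' @return barcode-level fragment table (same shape as
#'   [fragments_from_alignments()] output).
#' @export
records_to_fragments <- function(records) {
  if (nrow(records) == 0L) return(empty_fragment_table())
  key <- paste(records$rna_id, records$termination_pos, records$priming_pos,
               records$barcode, sep = "\r")
  s <- rowsum(records$read_count, key)
  parts <- strsplit(rownames(s), "\r", fixed = TRUE)
  agg <- data.frame(
    rna_id = vapply(parts, `[`, "", 1L),
    termination_pos = as.integer(vapply(parts, `[`, "", 2L)),
    priming_pos = as.integer(vapply(parts, `[`, "", 3L)),
    barcode = vapply(parts, `[`, "", 4L),
    read_count = as.integer(s[, 1L]), stringsAsFactors = FALSE)
  agg <- agg[order(agg$rna_id, agg$termination_pos, agg$priming_pos,
                   agg$barcode), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Emit simulated records as paired SAM (and optionally FASTQ)
#'
#' Writes one properly paired record pair per sequenced read copy: mate 1
#' forward from the termination site (carrying the barcode in the standard
#' `BC:Z` tag), mate 2 reverse ending at the priming site.  With
#' `untemplated_prob > 0`, each molecule independently receives 1-3 random
#' untemplated bases at the cDNA 3' end; the emitted mate-1 alignment then
#' starts upstream of the true termination site with those bases in its
#' sequence (as an end-to-end aligner would place them), and the truth is
#' returned so trimming can be scored.
#'
#' @param records molecule-level table from [simulate_library()].
#' @param reference reference sequence (character) for `rna_id` `"sim_rna"`,
#'   or named vector.
#' @param path output SAM path.
#' @param read_len sequenced read length after barcode removal.
#' @param untemplated_prob per-molecule probability of untemplated additions.
#' @param fastq_prefix if non-`NULL`, also write `<prefix>_1.fastq` /
#'   `<prefix>_2.fastq` with the barcode prepended to read 1 and its reverse
#'   complement read through at the end of read 2.
#' @param seed seed for the untemplated draws.
#' @return invisibly, a data.frame of emitted molecules with columns
#'   `molecule`, `n_add`, `true_termination_pos`, `emitted_pos`.
#' @export
emit_alignments <- function(records, reference, path, read_len = 50L,
                            untemplated_prob = 0, fastq_prefix = NULL,
                            seed = 1L) {
  if (!is.null(names(reference)) && length(reference) > 1L)
    stop("single-reference emission only")
  ref <- unname(reference[1L])
  rna_id <- if (!is.null(names(reference))) names(reference)[1L] else "sim_rna"
  set.seed(seed)
  n_mol <- nrow(records)
  n_add <- integer(n_mol)
  if (untemplated_prob > 0 && n_mol > 0L)
    n_add <- ifelse(stats::runif(n_mol) < untemplated_prob,
                    sample(1:3, n_mol, replace = TRUE), 0L)
  n_add <- pmin(n_add, records$termination_pos - 1L)
  add_bases <- vapply(n_add, function(k)
    if (k == 0L) "" else paste(sample(BASES, k, replace = TRUE), collapse = ""),
    character(1))
  term <- records$termination_pos
  prime <- records$priming_pos
  span <- prime - term + 1L
  core1 <- pmin(pmax(read_len - n_add, 1L), span)
  len2 <- pmin(read_len, span)
  seq1 <- paste0(add_bases, substr(rep(ref, length(term)), term, term + core1 - 1L))
  pos1 <- term - n_add
  cig1 <- sprintf("%dM", n_add + core1)
  pos2 <- prime - len2 + 1L
  seq2 <- substr(rep(ref, length(pos2)), pos2, prime)
  cig2 <- sprintf("%dM", len2)
  ## expand to one pair per read copy
  rep_idx <- rep(seq_len(n_mol), records$read_count)
  copy <- sequence(records$read_count)
  qname <- sprintf("sim%07d.%d", records$molecule[rep_idx], copy)
  qual1 <- strrep("I", nchar(seq1))
  lines <- c(
    "@HD\tVN:1.6\tSO:queryname",
    sprintf("@SQ\tSN:%s\tLN:%d", rna_id, nchar(ref)),
    sprintf("@PG\tID:hrfseq\tPN:hrfseq\tVN:%s",
            utils::packageVersion("hrfseq")),
    as.vector(rbind(
      sprintf("%s\t99\t%s\t%d\t42\t%s\t=\t%d\t%d\t%s\t%s\tBC:Z:%s",
              qname, rna_id, pos1[rep_idx], cig1[rep_idx], pos2[rep_idx],
              prime[rep_idx] - pos1[rep_idx] + 1L, seq1[rep_idx],
              qual1[rep_idx], records$barcode[rep_idx]),
      sprintf("%s\t147\t%s\t%d\t42\t%s\t=\t%d\t%d\t%s\t%s",
              qname, rna_id, pos2[rep_idx], cig2[rep_idx], pos1[rep_idx],
              -(prime[rep_idx] - pos1[rep_idx] + 1L), seq2[rep_idx],
              strrep("I", nchar(seq2[rep_idx]))))))
  writeLines(lines, path)
  if (!is.null(fastq_prefix)) {
    r1 <- paste0(records$barcode[rep_idx], seq1[rep_idx])
    r2 <- paste0(reverse_complement(seq2[rep_idx]),
                 reverse_complement(records$barcode[rep_idx]))
    writeLines(as.vector(rbind(paste0("@", qname, "/1"), r1, "+",
                               strrep("I", nchar(r1)))),
               paste0(fastq_prefix, "_1.fastq"))
    writeLines(as.vector(rbind(paste0("@", qname, "/2"), r2, "+",
                               strrep("I", nchar(r2)))),
               paste0(fastq_prefix, "_2.fastq"))
  }
  invisible(data.frame(molecule = records$molecule, n_add = n_add,
                       true_termination_pos = term, emitted_pos = pos1))
}

#' Synthetic RNA-like helical structure (labelled synthetic)
#'
#' Generates idealised A-form-like helical coordinates with a full sugar-atom
#' complement per residue, for exercising the structure metrics without any
#' deposited crystal structure.  Riboses sit on a helix of the given radius,
#' rise and twist; each residue's nine sugar atoms are placed at fixed offsets
#' around its bead with small seeded jitter.  This is a stand-in object, not a
#' physically refined model.
#'
#' @param n_res number of residues.
#' @param radius,rise,twist_deg helix parameters (defaults near A-form RNA).
#' @param chain chain identifier.
#' @param jitter coordinate jitter s.d. in Angstrom.
#' @param seed random seed.
#' @return atom data.frame compatible with [read_pdb()] output.
#' @export
synthetic_rna_structure <- function(n_res = 60L, radius = 9, rise = 2.8,
                                    twist_deg = 32.7, chain = "A",
                                    jitter = 0.1, seed = 1L) {
  set.seed(seed)
  theta <- (seq_len(n_res) - 1L) * twist_deg * pi / 180
  bead <- cbind(radius * cos(theta), radius * sin(theta),
                (seq_len(n_res) - 1L) * rise)
  offs <- rbind("C1'" = c(1.2, 0.0, 0.4), "C2'" = c(0.8, 1.1, -0.5),
                "C3'" = c(-0.6, 1.2, 0.3), "C4'" = c(-1.2, 0.1, -0.4),
                "O4'" = c(-0.2, -1.2, 0.2), "C5'" = c(-2.0, 0.8, -1.1),
                "O2'" = c(1.4, 2.1, -0.9), "O3'" = c(-1.1, 2.2, 0.9),
                "O5'" = c(-2.6, 0.2, -2.3))
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    rot <- matrix(c(cos(theta[i]), -sin(theta[i]), 0,
                    sin(theta[i]), cos(theta[i]), 0, 0, 0, 1), 3L, 3L)
    xyz <- sweep(offs %*% rot, 2L, bead[i, ], `+`) +
      matrix(stats::rnorm(3L * nrow(offs), sd = jitter), ncol = 3L)
    data.frame(record = "ATOM", serial = 0L, name = rownames(offs),
               resname = sample(c("A", "C", "G", "U"), 1L), chain = chain,
               resno = i, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               occupancy = 1, element = guess_element(rownames(offs)),
               stringsAsFactors = FALSE)
  }))
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  atoms
}

#' Write / read a flat key=value simulation config
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  scalar <- config[c("rna_length", "background", "priming", "n_events",
                     "barcode_length", "pcr_max_factor", "pcr_length_decay",
                     "seed")]
  lines <- sprintf("%s = %s", names(scalar), vapply(scalar, format, ""))
  if (!is.null(config$size_window))
    lines <- c(lines, sprintf("size_window = %d,%d", config$size_window[1],
                              config$size_window[2]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  sw <- if ("size_window" %in% names(vals))
    as.integer(strsplit(vals[["size_window"]], ",")[[1]]) else NULL
  sim_config(rna_length = num("rna_length", 300),
             background = num("background", 0.002),
             priming = if ("priming" %in% names(vals)) vals[["priming"]]
                       else "single",
             n_events = num("n_events", 1e5),
             barcode_length = num("barcode_length", 7),
             pcr_max_factor = num("pcr_max_factor", 10),
             pcr_length_decay = num("pcr_length_decay", 100),
             size_window = sw, seed = num("seed", 1))
}
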