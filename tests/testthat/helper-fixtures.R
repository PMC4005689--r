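# Shared fixture builders: everything is generated in code at test time.

# barcode-level fragment table from parallel vectors
frag_table <- function(term, prime, barcode, read_count = 1L,
                       rna_id = "rna1") {
  data.frame(rna_id = rna_id, termination_pos = as.integer(term),
             priming_pos = as.integer(prime), barcode = barcode,
             read_count = as.integer(read_count), stringsAsFactors = FALSE)
}

# aggregated fragment table with EUC already assigned
euc_table_fixture <- function(term, prime, euc, rna_id = "rna1") {
  data.frame(rna_id = rna_id, termination_pos = as.integer(term),
             priming_pos = as.integer(prime),
             read_count = as.integer(euc), k = as.integer(euc),
             euc = as.integer(euc), stringsAsFactors = FALSE)
}

# equal-frequency L x 4 matrix
uniform_freq <- function(L) {
  matrix(0.25, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
}

# seeded random unequal frequency matrix (rows sum to 1)
random_freq <- function(L, seed, shape = 5) {
  set.seed(seed)
  f <- t(vapply(seq_len(L), function(j) {
    w <- rgamma(4, shape)
    w / sum(w)
  }, numeric(4)))
  colnames(f) <- c("A", "C", "G", "T")
  f
}

# Monte-Carlo distinct-barcode counts: reps draws of n ligations over probs
mc_unique_barcodes <- function(n, probs, reps, seed) {
  set.seed(seed)
  counts <- stats::rmultinom(reps, n, probs)
  colSums(counts > 0L)
}

# small deterministic experiment for IO / CLI tests
small_experiment <- function(seed = 11, n_events = 4000) {
  sim_config(rna_length = 120L, n_events = n_events, seed = seed,
             pcr_max_factor = 3)
}

write_sam_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}
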