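test_that("position frequencies: degenerate pool, quartile filter, rejects", {
  # degenerate pool: all observed barcodes identical
  tab <- frag_table(1:4, 11:14, rep("AAAAAAA", 4))
  bd <- estimate_position_frequencies(tab)
  expect_equal(unname(bd$freq[, "A"]), rep(1, 7))
  expect_equal(rowSums(bd$freq), rep(1, 7), ignore_attr = TRUE)

  # two fragments with counts {1, 1000}: Q3 = 750.25 (type-7 quantile), so the
  # clonal fragment is excluded and only "AAAAAAA" votes
  tab2 <- frag_table(c(1, 2), c(50, 60), c("AAAAAAA", "CCCCCCC"),
                     read_count = c(1L, 1000L))
  expect_equal(unname(quantile(c(1, 1000), 0.75)), 750.25)
  bd2 <- estimate_position_frequencies(tab2)
  expect_equal(unname(bd2$freq[1, "A"]), 1)
  expect_equal(bd2$n_barcodes, 1L)

  # empty input errors; bad alphabet is rejected with a logged tally
  expect_error(estimate_position_frequencies(tab[0, ]), "empty")
  tab3 <- frag_table(1:3, 21:23, c("AAAAAAA", "AAXAAAA", "AAAANAA"))
  expect_warning(bd3 <- estimate_position_frequencies(tab3), "rejected")
  expect_equal(attr(bd3, "n_rejected"), 1L)
  expect_equal(attr(bd3, "n_ambiguous"), 1L)
  expect_equal(bd3$n_barcodes, 1L)
})

test_that("position frequencies converge to the pool under uniform draws", {
  set.seed(41)
  n <- 1e5
  bcs <- apply(matrix(sample(c("A", "C", "G", "T"), 7 * n, replace = TRUE),
                      ncol = 7), 1, paste, collapse = "")
  tab <- frag_table(seq_len(n) %% 500 + 1L, 600, bcs)
  bd <- estimate_position_frequencies(tab)
  expect_true(all(abs(bd$freq - 0.25) < 0.01))
})

test_that("barcode probabilities follow the product rule", {
  p7 <- barcode_probabilities(uniform_freq(7))
  expect_length(p7, 4^7)
  expect_equal(sum(p7), 1)
  expect_true(all(abs(p7 - 4^-7) < 1e-15))

  # L = 1 is the identity
  f1 <- matrix(c(0.5, 0.3, 0.1, 0.1), 1, 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(as.numeric(barcode_probabilities(f1)), c(0.5, 0.3, 0.1, 0.1))

  # L = 2 product rule with zeros
  f2 <- rbind(c(0.5, 0.5, 0, 0), c(1, 0, 0, 0))
  colnames(f2) <- c("A", "C", "G", "T")
  p2 <- barcode_probabilities(f2)
  names(p2) <- barcode_strings(2)
  expect_equal(unname(p2["AA"]), 0.5)
  expect_equal(unname(p2["CA"]), 0.5)
  expect_equal(sum(p2 > 0), 2L)

  expect_error(barcode_probabilities(uniform_freq(13)), "reduce L")
  bad <- uniform_freq(3); bad[2, 1] <- 0.3
  expect_error(barcode_probabilities(bad), "sum to 1")
})

test_that("expected unique barcodes: boundary values and equal-freq closed form", {
  probs <- barcode_probabilities(uniform_freq(7))
  expect_equal(expected_unique_barcodes(0, probs), 0)
  expect_equal(expected_unique_barcodes(1, probs), 1)
  m <- 4^7
  # matches the equal-frequency closed form and saturates at m
  for (n in c(10, 1000, 1e5))
    expect_equal(expected_unique_barcodes(n, probs),
                 m * (1 - (1 - 1 / m)^n), tolerance = 1e-10)
  expect_equal(expected_unique_barcodes(1e8, probs), m, tolerance = 1e-6)
  expect_error(expected_unique_barcodes(-1, probs), "non-negative")
})

test_that("k(n) is strictly increasing and concave", {
  probs <- barcode_probabilities(random_freq(3, seed = 5))
  ngrid <- c(1:50, seq(60, 2000, by = 37))
  k <- expected_unique_barcodes(ngrid, probs)
  expect_true(all(diff(k) > 0))
  d <- diff(k) / diff(ngrid)                 # secant slopes decrease
  expect_true(all(diff(d) < 1e-12))
  expect_true(all(k <= length(probs)))
})

test_that("formula matches Monte-Carlo ligation for unequal frequencies", {
  # reduced-size version of the acceptance check (full reps there)
  for (L in 2:3) {
    probs <- barcode_probabilities(random_freq(L, seed = 100 + L))
    for (n in c(10, 100)) {
      ks <- mc_unique_barcodes(n, probs, reps = 2e4, seed = n + L)
      se <- sd(ks) / sqrt(length(ks))
      # + 1e-6 absorbs float noise when the pool is fully saturated (se = 0)
      expect_lt(abs(expected_unique_barcodes(n, probs) - mean(ks)),
                3 * se + 1e-6)
    }
  }
})

test_that("EUC table inversion: identity regime, saturation, round trip", {
  probs <- barcode_probabilities(uniform_freq(7))
  m <- 4^7
  tab <- build_euc_table(probs, k_max = 8000)
  expect_equal(tab$m, m)
  expect_equal(estimate_unique_count(1, tab), 1L)   # k(1) = 1 exactly
  # far below the sqrt(m) = 128 saturation scale the correction is an identity
  expect_equal(estimate_unique_count(5, tab), 5L)
  # deep saturation: the correction exceeds k substantially and matches the
  # equal-frequency closed-form inverse n = log(1 - k/m) / log(1 - 1/m)
  n8000 <- estimate_unique_count(8000, tab)
  expect_gt(n8000, 8000)
  expect_lt(abs(n8000 - log(1 - 8000 / m) / log(1 - 1 / m)), 2)
  # n_of_k non-decreasing, n_of_k(k) >= k
  ks <- seq_len(tab$k_max)
  expect_true(all(diff(tab$n_of_k) >= 0L))
  expect_true(all(tab$n_of_k >= ks))
  # round trip within +-1 below half the saturation scale
  for (n in c(1L, 7L, 23L, 64L)) {
    k <- round(tab$k_of_n[n])
    expect_lte(abs(estimate_unique_count(k, tab) - n), 1L)
  }
})

test_that("saturated k and invalid inputs raise explicit errors", {
  probs <- barcode_probabilities(uniform_freq(2))   # m = 16
  tab <- build_euc_table(probs, k_max = 12)
  expect_error(estimate_unique_count(tab$k_max + 5L, tab), "saturated")
  expect_error(build_euc_table(probs, k_max = 16), ">= m")
  expect_error(estimate_unique_count(-1, tab), "non-negative")
  expect_equal(estimate_unique_count(0, tab), 0L)
  expect_equal(estimate_unique_count(c(0, 1, 3), tab)[1:2], c(0L, 1L))
})

test_that("EUC recovers the true ligation count near saturation onset", {
  # simulated fragments with true n = 500 over m = 16384 equal barcodes
  probs <- barcode_probabilities(uniform_freq(7))
  tab <- build_euc_table(probs, k_max = 600)
  set.seed(77)
  est <- vapply(1:100, function(i) {
    k <- length(unique(sample.int(4^7, 500, replace = TRUE)))
    estimate_unique_count(k, tab)
  }, integer(1))
  expect_lt(abs(mean(est) - 500) / 500, 0.05)
})

test_that("EUC removes PCR-duplication bias (CV criterion)", {
  # 40 fragments, identical true n = 200, PCR duplication factors 1..50
  set.seed(99)
  n_true <- 200L
  dup <- seq(1, 50, length.out = 40)
  k <- vapply(seq_along(dup), function(i)
    length(unique(sample.int(4^7, n_true, replace = TRUE))), integer(1))
  reads <- vapply(seq_along(dup), function(i)
    sum(1L + rgeom(n_true, prob = 1 / dup[i])), numeric(1))
  probs <- barcode_probabilities(uniform_freq(7))
  tab <- build_euc_table(probs, k_max = max(k))
  euc <- estimate_unique_count(k, tab)
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(reads), 0.5)
  expect_lt(cv(euc), 0.1)
})

test_that("add_euc wires the table through a fragment table", {
  tab <- frag_table(c(1, 1, 1, 2), c(90, 90, 90, 95),
                    c("AAAAAAA", "CCCCCCC", "GGGGGGG", "AAAAAAA"))
  agg <- aggregate_fragments(tab)
  out <- add_euc(agg, barcode_probabilities(uniform_freq(7)))
  expect_equal(out$euc, c(3L, 1L))
})
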