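ribose_res <- function(resno, center, chain = "A", spread = 0) {
  names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  off <- if (spread > 0) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, 0, 1)) * spread
  } else matrix(0, 5, 3)
  data.frame(record = "ATOM", serial = 0L, name = names, resname = "A",
             chain = chain, resno = resno,
             x = center[1] + off[, 1], y = center[2] + off[, 2],
             z = center[3] + off[, 3], occupancy = 1, element = "C",
             stringsAsFactors = FALSE)
}

test_that("ribose bead is the mean of the five sugar atoms", {
  a <- ribose_res(1, c(1, 2, 3))
  b1 <- ribose_bead_positions(a)
  expect_equal(unlist(b1[c("x", "y", "z")], use.names = FALSE), c(1, 2, 3))
  # atoms at unit-cube corners: bead = arithmetic mean, by hand
  a2 <- ribose_res(2, c(0, 0, 0), spread = 1)
  b2 <- ribose_bead_positions(a2)
  expect_equal(unlist(b2[c("x", "y", "z")], use.names = FALSE),
               c(3 / 5, 2 / 5, 2 / 5))
  # a residue missing O4' is skipped and reported
  incomplete <- rbind(a, a2[a2$name != "O4'", ])
  expect_message(b3 <- ribose_bead_positions(incomplete), "skipped")
  expect_equal(nrow(b3), 1L)
  expect_length(attr(b3, "skipped"), 1L)
  expect_error(ribose_bead_positions(a, chains = "Z"), "no ribose atoms")
})

test_that("through-space contacts: adjacency rule and brute-force oracle", {
  beads <- data.frame(chain = "A", resno = 1:3, x = c(0, 5, 10), y = 0, z = 0)
  cc <- through_space_contacts(beads, radius = 14)
  expect_equal(cc$contact_count, c(1L, 0L, 1L))    # only the 0-10 pair counts
  beads2 <- data.frame(chain = "A", resno = 1:4, x = (0:3) * 20, y = 0, z = 0)
  expect_equal(through_space_contacts(beads2)$contact_count, rep(0L, 4))

  # 200 random beads in a 50 A box: exact match with an all-pairs loop
  set.seed(12)
  rb <- data.frame(chain = sample(c("A", "B"), 200, TRUE),
                   resno = rep(1:100, 2),
                   x = runif(200, 0, 50), y = runif(200, 0, 50),
                   z = runif(200, 0, 50))
  got <- through_space_contacts(rb, radius = 14)$contact_count
  oracle <- integer(200)
  for (i in 1:200) {
    for (j in 1:200) {
      if (i == j) next
      if (rb$chain[i] == rb$chain[j] && abs(rb$resno[i] - rb$resno[j]) <= 1)
        next
      d <- sqrt(sum((rb[i, c("x", "y", "z")] - rb[j, c("x", "y", "z")])^2))
      if (d <= 14) oracle[i] <- oracle[i] + 1L
    }
  }
  expect_equal(got, oracle)
  # symmetry of the underlying relation
  expect_equal(sum(got %% 1), 0)
  expect_equal(sum(got), 2 * sum(oracle) / 2)
})

test_that("dot-lattice SASA: analytic sphere, burial, non-interacting limit", {
  carbon <- function(resno, x) data.frame(record = "ATOM", serial = resno,
                                          name = "C1'", resname = "A",
                                          chain = "A", resno = resno, x = x,
                                          y = 0, z = 0, occupancy = 1,
                                          element = "C")
  iso <- 4 * pi * (1.7 + 1.4)^2                     # 120.76 A^2
  expect_equal(atom_sasa(carbon(1, 0)), iso, tolerance = 1e-12)
  expect_equal(iso, 120.7628, tolerance = 1e-4)
  # two atoms beyond 2 (r + probe): both isolated
  far <- rbind(carbon(1, 0), carbon(2, 10))
  expect_equal(atom_sasa(far), rep(iso, 2), tolerance = 1e-12)
  # fully enclosed atom: zero exposure
  sphere <- fibonacci_sphere(60) * 2.2
  shell <- do.call(rbind, lapply(1:60, function(i)
    carbon(i + 1, 0)))
  shell$x <- sphere[, 1]; shell$y <- sphere[, 2]; shell$z <- sphere[, 3]
  buried <- rbind(carbon(1, 0), shell)
  expect_equal(atom_sasa(buried)[1], 0)
})

test_that("two-sphere SASA matches the spherical-cap closed form", {
  # analytic: exposed area of sphere 1 = 4 pi R1^2 - 2 pi R1 h, with
  # h = R1 - (d^2 + R1^2 - R2^2) / (2 d)
  two_sphere_oracle <- function(R1, R2, d) {
    h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
    4 * pi * R1^2 - 2 * pi * R1 * h
  }
  at <- data.frame(record = "ATOM", serial = 1:2, name = "C1'", resname = "A",
                   chain = "A", resno = 1:2, x = c(0, 2.5), y = 0, z = 0,
                   occupancy = 1, element = c("C", "O"))
  R1 <- 1.7 + 1.4; R2 <- 1.52 + 1.4
  got <- atom_sasa(at, probe_radius = 1.4, dot_density = 3)
  expect_equal(got[1], two_sphere_oracle(R1, R2, 2.5), tolerance = 0.02)
  expect_equal(got[2], two_sphere_oracle(R2, R1, 2.5), tolerance = 0.02)
  # error decreases with dot density
  err <- vapply(1:4, function(dd)
    abs(atom_sasa(at, dot_density = dd)[1] - two_sphere_oracle(R1, R2, 2.5)),
    numeric(1))
  expect_lt(err[4], err[1])
  expect_lt(err[3] / two_sphere_oracle(R1, R2, 2.5), 0.02)
})

test_that("per-residue ribose SASA sums sugar atoms and records metadata", {
  atoms <- synthetic_rna_structure(n_res = 12, seed = 4)
  rs <- ribose_sasa(atoms, probe_radius = 1.4, dot_density = 2)
  expect_equal(nrow(rs), 12L)
  expect_true(all(rs$ribose_sasa >= 0))
  expect_equal(attr(rs, "probe_radius"), 1.4)
  # a wider probe reaches less surface between packed residues
  rs3 <- ribose_sasa(atoms, probe_radius = 3.0, dot_density = 2)
  expect_true(mean(rs3$ribose_sasa) != mean(rs$ribose_sasa))
  # unknown element falls back with a warning
  weird <- atoms[1:5, ]; weird$element <- "X"
  expect_warning(atom_sasa(weird), "default radius")
})

test_that("correlations: exact limits, sampling oracle, offsets", {
  x <- sin(seq(0, 6 * pi, length.out = 120))
  expect_equal(correlate_with_structure(x, x, window = 1L), 1)
  expect_equal(correlate_with_structure(x, -x, window = 1L), -1)
  expect_error(pearson_shared(c(1, 2, NA), c(1, NA, 3)), "at least 3")

  set.seed(21)
  z <- matrix(rnorm(200), ncol = 2)
  rho <- 0.5
  y <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  r <- pearson_shared(z[, 1], y)
  expect_lt(abs(r - rho), 3 * (1 - rho^2) / sqrt(100))

  # helical periodicity: period-11 sinusoid autocorrelation peaks at 11, 22
  s <- sin(2 * pi * (1:300) / 11)
  oc <- offset_correlation(s, s, offsets = 0:25)
  expect_equal(oc$r[oc$offset == 0], 1)
  for (peak in c(11, 22)) {
    expect_gt(oc$r[oc$offset == peak], oc$r[oc$offset == peak - 2])
    expect_gt(oc$r[oc$offset == peak], oc$r[oc$offset == peak + 2])
  }
  expect_error(offset_correlation(s[1:5], s[1:5], offsets = 10), "at least 3")
})

test_that("PDB writer/reader round trip on the synthetic structure", {
  atoms <- synthetic_rna_structure(n_res = 8, seed = 9)
  path <- tempfile(fileext = ".pdb")
  write_pdb(atoms, path)
  back <- read_pdb(path)
  expect_equal(nrow(back), nrow(atoms))
  expect_equal(back$name, atoms$name)
  expect_equal(back$resno, atoms$resno)
  expect_equal(back$element, atoms$element)
  expect_equal(back$x, atoms$x, tolerance = 1e-3)  # fixed format: 3 decimals
  expect_equal(back$z, atoms$z, tolerance = 1e-3)
  # altloc resolution: duplicate atom keeps the higher occupancy
  dup <- rbind(atoms[1, ], atoms[1, ])
  dup$x[2] <- dup$x[2] + 5; dup$occupancy <- c(0.3, 0.7)
  write_pdb(dup, path)
  lines <- readLines(path)
  substr(lines[1], 17, 17) <- "A"; substr(lines[2], 17, 17) <- "B"
  writeLines(lines, path)
  resolved <- read_pdb(path)
  expect_equal(nrow(resolved), 1L)
  expect_equal(resolved$x, dup$x[2], tolerance = 1e-3)
})
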