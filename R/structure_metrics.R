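## Structure-derived validation metrics.  Hydroxyl radicals attack the ribose,
## so the reference quantities from a crystal structure are per-residue: the
## number of non-adjacent riboses within 14 A of a residue's ribose bead
## (through-space contacts, anti-correlates with accessibility) and the
## solvent-accessible surface area of the sugar moiety (correlates with it).

## Bondi van der Waals radii (A); unknown elements fall back to `default`.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)

RIBOSE_BEAD_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "O4'")
RIBOSE_SASA_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "C5'",
                       "O2'", "O3'", "O4'", "O5'")

#' Ribose bead positions
#'
#' One surrogate sugar position per residue: the arithmetic mean of the C1',
#' C2', C3', C4' and O4' coordinates.  Residues missing any of the five atoms
#' are skipped and reported via the `skipped` attribute.
#'
#' @param atoms atom table from [read_pdb()].
#' @param chains optional chain id filter.
#' @param residues optional residue-number filter.
#' @return data.frame with columns `chain`, `resno`, `x`, `y`, `z`.
#' @export
ribose_bead_positions <- function(atoms, chains = NULL, residues = NULL) {
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  if (!is.null(residues)) atoms <- atoms[atoms$resno %in% residues, , drop = FALSE]
  atoms <- atoms[atoms$name %in% RIBOSE_BEAD_ATOMS, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("selection contains no ribose atoms")
  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  n_atoms <- rowsum(rep(1L, nrow(atoms)), key)
  complete <- rownames(n_atoms)[n_atoms[, 1L] == length(RIBOSE_BEAD_ATOMS)]
  skipped <- setdiff(unique(key), complete)
  atoms <- atoms[key %in% complete, , drop = FALSE]
  key <- key[key %in% complete]
  xyz <- rowsum(as.matrix(atoms[c("x", "y", "z")]), key) /
    length(RIBOSE_BEAD_ATOMS)
  parts <- strsplit(rownames(xyz), "\r", fixed = TRUE)
  out <- data.frame(chain = vapply(parts, `[`, "", 1L),
                    resno = as.integer(vapply(parts, `[`, "", 2L)),
                    x = xyz[, "x"], y = xyz[, "y"], z = xyz[, "z"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  if (length(skipped))
    message(length(skipped), " residue(s) skipped (incomplete ribose)")
  out
}

#' Through-space ribose contact counts
#'
#' For each residue, the number of other ribose beads within `radius`
#' (default 14 A), excluding the residue itself and, when
#' `exclude_adjacent`, its sequence neighbours (residue-number difference
#' <= 1 within the same chain; numbering gaps count as non-adjacent).
#'
#' @param beads bead table from [ribose_bead_positions()].
#' @param radius contact radius in Angstrom.
#' @param exclude_adjacent drop sequence-adjacent residues from the count.
#' @return `beads` with an integer `contact_count` column.
#' @export
through_space_contacts <- function(beads, radius = 14, exclude_adjacent = TRUE) {
  xyz <- as.matrix(beads[c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  within <- d <= radius
  diag(within) <- FALSE
  if (exclude_adjacent) {
    same_chain <- outer(beads$chain, beads$chain, `==`)
    adj <- same_chain & abs(outer(beads$resno, beads$resno, `-`)) <= 1L
    within[adj] <- FALSE
  }
  beads$contact_count <- as.integer(rowSums(within))
  beads
}

## deterministic, near-uniform unit-sphere lattice (golden-angle spiral):
## reproducible bit-for-bit, unlike random dot placement
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Dot-lattice (Shrake-Rupley-style) solvent accessible surface area
#'
#' Each atom's van der Waals sphere is expanded by the probe radius and
#' covered with a deterministic spiral lattice of test dots; the accessible
#' area is the exposed-dot fraction times the expanded sphere area.  The dot
#' count follows the icosahedral-subdivision ladder `10 * 4^density + 2`
#' (density 3 -> 642 dots).
#'
#' @param atoms atom table from [read_pdb()].
#' @param probe_radius probe sphere radius in Angstrom (1.4 for water; the
#'   16S analysis in this field uses 3.0 to emulate the reach of the radical).
#' @param dot_density subdivision level (default 3).
#' @param radii named van der Waals radius table by element (defaults to
#'   Bondi).
#' @param default_radius fallback for unknown elements (warned once).
#' @return numeric per-atom SASA vector (A^2) in `atoms` row order.
#' @export
atom_sasa <- function(atoms, probe_radius = 1.4, dot_density = 3L,
                      radii = VDW_RADII, default_radius = 1.5) {
  el <- atoms$element
  if (is.null(el)) el <- guess_element(atoms$name)
  r <- unname(radii[el])
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ","),
            ": using default radius ", default_radius, " A")
    r[is.na(r)] <- default_radius
  }
  re <- r + probe_radius
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  n_dots <- 10L * 4L^as.integer(dot_density) + 2L
  dots <- fibonacci_sphere(n_dots)
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    dv <- sweep(xyz, 2L, xyz[i, ])
    d2 <- rowSums(dv^2)
    nb <- which(d2 < (re + re[i])^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      out[i] <- 4 * pi * re[i]^2
      next
    }
    pts <- sweep(dots * re[i], 2L, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_dots)
    for (j in nb[order(d2[nb])]) {
      if (!any(exposed)) break
      dd <- sweep(pts[exposed, , drop = FALSE], 2L, xyz[j, ])
      exposed[exposed] <- rowSums(dd^2) > re[j]^2
    }
    out[i] <- 4 * pi * re[i]^2 * sum(exposed) / n_dots
  }
  out
}

#' Per-residue ribose SASA
#'
#' Sums [atom_sasa()] over each residue's sugar-moiety atoms (default C1'-C5'
#' and O2'-O5'; the set is configurable since "ribose accessibility" does not
#' pin down the exact atom list).
#'
#' @inheritParams atom_sasa
#' @param chains,residues optional selection filters.
#' @param ribose_atoms atom names summed per residue.
#' @return data.frame with columns `chain`, `resno`, `ribose_sasa` plus
#'   metadata attributes (`probe_radius`, `dot_density`).
#' @export
ribose_sasa <- function(atoms, probe_radius = 1.4, dot_density = 3L,
                        chains = NULL, residues = NULL,
                        ribose_atoms = RIBOSE_SASA_ATOMS,
                        radii = VDW_RADII) {
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  if (!is.null(residues)) atoms <- atoms[atoms$resno %in% residues, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("empty atom selection")
  ## occlusion must see every atom of the selection, not just sugar atoms
  sasa <- atom_sasa(atoms, probe_radius, dot_density, radii = radii)
  sel <- atoms$name %in% ribose_atoms
  key <- paste(atoms$chain[sel], atoms$resno[sel], sep = "\r")
  s <- rowsum(sasa[sel], key)
  parts <- strsplit(rownames(s), "\r", fixed = TRUE)
  out <- data.frame(chain = vapply(parts, `[`, "", 1L),
                    resno = as.integer(vapply(parts, `[`, "", 2L)),
                    ribose_sasa = s[, 1L], stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "probe_radius") <- probe_radius
  attr(out, "dot_density") <- as.integer(dot_density)
  out
}

#' Correlate a reactivity profile with a structure metric
#'
#' Pearson correlation between the smoothed reactivity signal and the
#' structure metric smoothed with the same centred moving average (the metric
#' is not offset: it is already indexed by the probed residue).
#'
#' @param smoothed_reactivity per-residue reactivity vector indexed by
#'   residue number (`NA` = masked).
#' @param structure_metric per-residue metric vector, same indexing.
#' @param window moving-average width applied to the metric (odd; 1 = none).
#' @return Pearson R over shared unmasked residues.
#' @export
correlate_with_structure <- function(smoothed_reactivity, structure_metric,
                                     window = 3L) {
  sm <- moving_average_offset(structure_metric, window = window,
                              offset_upstream = 0L)
  pearson_shared(smoothed_reactivity, sm)
}

#' Correlation as a function of residue offset
#'
#' For each offset `d`, the Pearson correlation between `signal[p]` and
#' `reference_metric[p + d]` over residues where both are defined.  Peaks at
#' offsets ~11 and ~22 reveal the helical periodicity of accessibility
#' (one side of an A-form helix faces the solvent every full turn).
#'
#' @param signal,reference_metric aligned per-residue vectors.
#' @param offsets integer offsets to evaluate.
#' @return data.frame with columns `offset`, `r`, `n` (pairs used).
#' @export
offset_correlation <- function(signal, reference_metric, offsets = -15:15) {
  n <- length(signal)
  if (length(reference_metric) != n) stop("profiles must be aligned")
  res <- lapply(offsets, function(d) {
    p <- seq_len(n)
    q <- p + d
    ok <- q >= 1L & q <= n
    x <- signal[p[ok]]; y <- reference_metric[q[ok]]
    data.frame(offset = d, r = pearson_shared(x, y),
               n = sum(is.finite(x) & is.finite(y)))
  })
  do.call(rbind, res)
}

#' Write per-residue structure metrics as TSV
#'
#' @param contacts output of [through_space_contacts()].
#' @param sasa output of [ribose_sasa()].
#' @param path output path.
#' @export
write_structure_metrics <- function(contacts, sasa, path) {
  df <- merge(contacts[c("chain", "resno", "contact_count")],
              sasa[c("chain", "resno", "ribose_sasa")],
              by = c("chain", "resno"), all = TRUE)
  df <- df[order(df$chain, df$resno), , drop = FALSE]
  write_tsv_commented(df, path,
                      extra = c(probe_radius = attr(sasa, "probe_radius"),
                                dot_density = attr(sasa, "dot_density")))
}
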