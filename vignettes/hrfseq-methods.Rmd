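---
title: "Models and methods behind hrfseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hrfseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

Hydroxyl radicals cleave the RNA backbone where the ribose is exposed to
solvent. Sequencing-based hydroxyl radical footprinting reads those breaks out
as reverse-transcription (RT) stops: a primer is extended 5′-ward until the
enzyme falls off at a break (or stops spontaneously), an adaptor carrying a
7-nt degenerate barcode is ligated to the cDNA 3′ end, and paired-end
sequencing reports, for every molecule, the *termination site* (the last
transcribed nucleotide, one position 3′ of the actual break) and the *priming
site*. `hrfseq` implements the computational half of that experiment: fragment
extraction from paired alignments, barcode-based de-duplication with
saturation correction, accessibility estimation, and structure-derived
validation metrics — plus a simulator that generates the whole experiment with
known truth.

# Estimated unique counts with an unequal-frequency barcode pool

Distinct barcodes on the same fragment count pre-PCR molecules. Two effects
spoil the naive count `k`:

1. **Saturation.** With `m = 4^L` barcodes, two of `n` ligation events start
   colliding once `n` approaches `sqrt(m)` (~128 for L = 7), so `k < n`.
2. **Unequal pool frequencies.** Synthesised degenerate oligos are far from
   uniform, which makes collisions more frequent than the equal-frequency
   theory predicts.

The model estimates per-position nucleotide frequencies from the observed
barcodes of fragments in the three lowest read-count quartiles (the top
quartile is excluded to avoid clonal PCR amplification feeding back into the
pool estimate; we use R's type-7 linear-interpolation quantile and exclude
fragments *strictly above* Q3). Positions are assumed independent, so a
barcode's probability is the product of its per-position frequencies. The
expected number of distinct barcodes after `n` ligations is the occupancy
expectation

    E[k | n] = sum_i ( 1 - (1 - P_i)^n ),

evaluated in log space so `(1 - P_i)^n` does not underflow. The curve is
tabulated over integer `n` and inverted to an `n(k)` lookup (nearest tabulated
`k`, ties to the smaller `n` — a conservative choice), giving the estimated
unique count (EUC) for each fragment.

**Numerical choice: deep saturation.** Exact tabulation costs
`O(U * n_max)` where `U` is the number of distinct `P_i`; for an unequal L = 7
pool with a saturated run-off fragment, `n_max` can reach `1e5`–`1e6`, which
is wasteful precision — the sampling noise of a saturated `k` dwarfs any
tabulation detail. The table is therefore exact up to a work cap (never less
than `n = 4096`, much deeper when `U` is small, e.g. always for an
equal-frequency pool) and uses a geometric grid (ratio 1.02) with log-space
monotone interpolation beyond it. The maximum relative inversion error
observed against a fully exact table is `2.4e-4`. Barcodes containing `N` are
excluded from both `k` and frequency estimation (counted and logged); this is
unbiased under any error model that is independent of the barcode identity.

# Fragment extraction conventions

* Coordinates are 1-based, inclusive, on the sense strand.
* Termination site = leftmost reference position of mate 1 after
  untemplated-nucleotide trimming; priming site = 3′-most reference position
  of mate 2. Pairs violating `termination <= priming`, reverse-orientation
  pairs, secondary/supplementary and unmapped records are rejected with
  logged tallies (kept + rejected always equals input).
* **Untemplated trimming.** RT's terminal transferase appends 1–3 bases to
  the cDNA 3′ end. Contiguous reference mismatches at the termination end are
  trimmed, capped at 3 (the artifact is localised to those three positions).
  An appended base that happens to match the reference (~25% per base) is
  invisible to any trimming rule; the simulator measures the resulting
  recovery rate rather than asserting perfection.
* **Span filter.** Fragments spanning `< 100` nt (span defined inclusively,
  `priming - termination + 1`; the boundary case span = 100 is kept) are
  dropped in random-primed mode to neutralise library size selection; the
  single-primer mode keeps all fragments. The inclusive-difference choice is
  within 1 nt of the alternative and is configurable.

# From EUCs to accessibility

Per position `p`: termination EUC is the summed EUC of fragments terminating
at `p`; effective coverage sums fragments terminating at or spanning `p`,
optionally requiring the priming site to be at least 100 nt downstream (so
size selection cannot decide whether a molecule terminating near `p` would
have been sequenced). Their ratio, TCR, is the fraction of transcriptases
reaching `p` that stop there. The control library's TCR is pure
spontaneous-termination background, so

    dTCR[p] = TCR_treated[p] - TCR_control[p]

is the per-position cleavage probability. Negative values (e.g.
control-specific nuclease stops) are preserved, not floored.

The **coverage cutoff** masks positions where a termination would likely not
have been seen at all: the smallest `c` with `1 - (1 - p)^c >= 0.9`, where `p`
is the median dTCR (e.g. `p = 0.0033` gives `c = 697`). The order of
operations is ambiguous in principle (the cutoff depends on the median, which
depends on the mask); we iterate exactly once — first-pass median over all
covered region positions, cutoff from that median, final median over the
surviving positions — which is deterministic and documented. The stored
`median_delta_tcr` is the final-pass value and always equals the median of the
reported unmasked `delta_tcr`.

Smoothing uses a 3-nt moving average offset one position upstream
(`smoothed[p] = mean(dTCR[p..p+2])`): RT stops one nucleotide 3′ of the break,
so the shifted window re-centres the signal on the cleaved ribose. Windows
touching a masked position or the profile edge are masked. The analysis
region should start downstream of the 5′ run-off pile-up; the run-off extent
is data-dependent, so the region is a configuration parameter rather than a
hard-coded number.

Two scalar summaries: `cleavage_spacing(p) = 1/p`, the expected nucleotides
per cleavage (0.0033 → one per ~303 nt; 0.0018 → one per ~556 nt), and
`single_hit_probability(p, len) = 1 - (1 - p)^len`, the chance a molecule
carries at least one hit. The background share of the treated signal is
`100 * sum(TCR_control) / sum(TCR_treated)` over the analysis region.

# Structure metrics

Validation against a crystal structure uses two per-residue quantities:

* **Through-space contacts** — the number of ribose *beads* (mean of the C1′,
  C2′, C3′, C4′, O4′ coordinates) within 14 Å, excluding the residue itself
  and its sequence neighbours (residue-number difference ≤ 1 within a chain;
  numbering gaps count as non-adjacent). Buried riboses have many contacts,
  so this anti-correlates with accessibility.
* **Ribose SASA** — dot-lattice (Shrake–Rupley-style) solvent-accessible
  surface area summed over the sugar-moiety atoms (C1′–C5′, O2′–O5′; the set
  is configurable because "ribose accessibility" does not pin down an atom
  list). Van der Waals radii are the Bondi values frozen in the package; dots
  are placed on a deterministic golden-angle spiral (`10 * 4^density + 2`
  points, density 3 → 642) so results are reproducible bit-for-bit, unlike
  random dot placement. Probe radius 1.4 Å models water; 3 Å is the
  wide-probe variant used for large rRNA. Structures are handled
  hydrogen-free (crystal structures rarely resolve hydrogens; this matches
  the upstream practice).

Correlations with reactivity smooth the structure metric with the same 3-nt
(offset-0) moving average; `offset_correlation()` scans residue offsets to
expose the ~11-nt helical periodicity of accessibility.

No pre-installed R package parses PDB coordinate files, so a minimal
fixed-column ATOM/HETATM reader/writer is included (altloc resolution by
highest occupancy). It is round-tripped in the tests against structures the
package generates itself.

# What the simulator states, and what a green test establishes

`sim_config()` defaults are a fixed "stated world", not tuning knobs: a
300-nt random-sequence RNA, `1e5` RT events per library, background
termination 0.002/nt, i.i.d. per-position cleavage probabilities
`0.02 * u^3` (range 0–0.02, median ≈ 0.0025 — the single-hit probing regime),
a single 3′ primer, an unequal barcode pool drawn once from a Dirichlet-like
(`rgamma(4, 5)`) perturbation of uniform, and geometric PCR duplication whose
mean decays with fragment length (mean 10 for the shortest fragments,
e-folding 100 nt). Random-primed mode adds uniform priming and a 100–600 nt
size-selection window (size selection belongs to that protocol). The
termination-offset convention is explicit: a break between `p-1` and `p`
terminates RT at `p`, so the simulator's hazard at `p` carries the cleavage
probability of ribose `p-1`, and the upstream smoothing offset re-aligns the
two.

The simulator emulates: stochastic priming, hazard-based termination walks,
run-off at the 5′ end, barcode ligation from an unequal pool, length-biased
PCR duplication, size selection, untemplated-addition injection, and
paired-SAM/FASTQ emission. It does **not** emulate: sequencing errors outside
the barcode/untemplated mechanism, ligation chimeras, barcode-deletion
artifacts, secondary structure pausing of RT, or nuclease contamination.
A green end-to-end test therefore establishes that the estimator chain is
self-consistent and unbiased under the stated generative model — not that any
particular biological dataset would reproduce a given correlation with a
crystal structure.

# Design decisions taken where the design was open

* Quartile filter computed per library (each ligation reaction gets its own
  pool estimate), since pools can differ between reactions.
* One frequency matrix per library, applied to all its fragments.
* EUC table sizing is demand-driven (`k_max` = largest observed `k`) instead
  of tabulating to full saturation up front; the construction is unchanged.
* The background-fraction region and the 5′ run-off exclusion are a single
  configurable analysis interval.
* `N`-containing barcodes: excluded from `k`, included in read counts.
* Reverse-orientation pairs are rejected, not rescued (libraries are mapped
  sense-only).

# Known limitations

* The untemplated-trimming rule cannot correct additions that match the
  reference; the expected per-base blind-spot rate is 25% with unbiased base
  composition.
* EUC accuracy degrades near full saturation (`k → m`): the inversion is
  well-defined but its variance grows without bound; deep-saturation EUCs
  (interpolated regime) are accurate to ~0.1% in the curve but dominated by
  the sampling noise of `k` itself.
* The positional-independence assumption of the barcode model is inherited
  from the upstream method; correlated synthesis biases would propagate into
  the `P_i`.
* Single-reference analyses only; multi-RNA inputs are handled at the
  fragment-table level but the reactivity profile is computed per reference.
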