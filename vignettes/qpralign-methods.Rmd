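---
title: "Dot-plot alignment by simulated quantum pattern recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dot-plot alignment by simulated quantum pattern recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpralign)
```

## The problem and the approach

Two homologous sequences produce diagonal runs of matching cells on the
dot-matrix plane: cell (x, y) is set when the reference word at position x
equals the query word at position y. Finding alignment anchors is therefore
a line-detection problem on a sparse binary image. `qpralign` detects those
lines with a simulated quantum pattern recognition routine: the cell index
of an N x M window is held in two quantum registers (n = log2 N qubits for
the column, m = log2 M for the row), a black-box oracle entangles a flag
qubit with the cell contents, measuring the flag collapses the register
onto the matching cells, and a quantum Fourier transform concentrates the
amplitude on the wave-numbers of any periodic structure. A line sampled one
cell per row is periodic in the linear index z = x + N*y, so few QFT
measurements reveal it; classical Laue-style indexing of the measured
wave-numbers then recovers the line's length, angle and position.

The package simulates the quantum routine on amplitude vectors: each
circuit phase is applied as a direct vector transform over the 2^(n+m)
cell indices (gate-level unitaries are never materialized — for this
circuit the two are mathematically identical). The collapsed flag=1 state
of a window is unique (uniform over its matching cells), so its QFT
spectrum is computed once per window state and one wave-number is drawn
per repetition; the per-repetition flag measurement and its retries are
still simulated, as geometric variates in the cell density rho. The retry
cap scales as 16/rho — sixteen geometric expectations — so only a window
whose density collapses to zero terminates the loop, which is reported as
an explicit empty-window result.

## The line model and its spectrum

A line of length `L_D` cells starting at (x0, y0) with angle theta
(deviation from vertical) occupies cells

    x = x0 + [l * tan(theta)],  y = y0 + l,   l = 0 .. L_D - 1

with half-up rounding. Angles live on the grid `tan(theta) = j/M` for
integer j: the line advances j columns over the M rows of the window. In
the linear index the per-row step is `d = N + tan(theta)`, so the QFT
spectrum is a Laue pattern: main peaks on the reciprocal lattice
`k = [I * S/d]` (S = N*M, integer orders I folded into [0, S); the power
spectrum of a real cell set is symmetric, so negative orders mirror into
the upper half), each with first-zero half-width `(S/d)/L_D`, and the
intensity envelope given by the Laue interference function
`f_Laue(xi, kappa) = sin^2(pi*xi*kappa)/sin^2(pi*kappa)`. Rounding the
per-row advance to whole cells modulates the step sequence; the sawtooth
harmonics add satellites at offsets `m * tan(theta) * S/d` (|m| <= 2 are
retained in `predict_peaks()`). Transposing the window turns the step into
`d' = 1 + M*tan(theta)`; for a vertical line all transposed orders collapse
onto k' = 0. The pair of orientations therefore separates the angle (peak
spacings) from the length (envelope widths).

`predict_spectrum()` gives the exact wave-number distribution of a
hypothesized line — the closed Laue form for vertical lines, the FFT of
the canonical cell set otherwise — and is the basis of both the peak
prediction and the inference.

## Inference, degeneracy, and localization

`infer_line()` is maximum-likelihood template matching: the log-likelihood
of the original-orientation samples under each hypothesis spectrum plus
that of the transposed samples under the transposed spectrum, over the
grid L_D in [2, M], j in [-min(M,16), min(M,16)]. This subsumes the
closed-form inversion of the peak equations (solve the spacings for the
angle, the widths for the length) but uses the entire envelope, and it is
the statistically optimal estimator for the sampling model. Three details
matter:

* **Noise floor.** Sampled input is scored against
  `(1-eps) * p + eps/S` with `eps = 0.02`, so a background dot that throws
  a sample off the template support penalizes rather than annihilates a
  hypothesis. Weighted histogram input (predicted peak structures fed back
  through the inference) is scored with `eps = 0`; Gibbs' inequality then
  guarantees that the true hypothesis maximizes the weighted
  log-likelihood, which is why the round-trip over the whole grid is exact.
* **Density cap.** A line cannot hold more cells than the window does, so
  hypotheses with `L_D > ceiling(rho*S)` are excluded. For a noiseless
  single-line window this is sharp; in noisy windows `rho*S` far exceeds
  any line length and the cap is inert.
* **Friedel degeneracy.** The power spectrum of a real cell set is
  invariant under point reflection, so a line whose step sequence is the
  reverse of another grid line's produces identical distributions in both
  orientations; no estimator can separate such mates from wave-number
  samples alone. Ties resolve toward the largest consistent L_D (a longer
  line shades shorter co-resident ones) and then the smallest |j|;
  `friedel_mate()` exposes the partner, and `localize()` walks both
  rasterizations through the actual window to disambiguate.

`localize()` bisects the window symmetrically across rows, re-running the
QPR routine in each candidate top half. A half counts as containing the
line when enough of its sampled wave-numbers fall on the line's reciprocal
lattice (adapted to the half's dimensions); plain occupancy would be
hijacked by a single background dot above the line. Halves with at most
four estimated cells cannot support a spectral signature and fall back to
the flag-collapse probe. The descent stops at a two-row band whose
occupied cells are examined classically — this stage of the routine is
classical by construction — and the cell whose stepping path has the
highest occupancy becomes the start. If the best path stays below
`min_path_density` the band is treated as a distractor, cleared in a
working copy, and the bisection restarts below it; after eight fruitless
rounds (or one full retry with a fresh substream) localization fails
explicitly.

## The window protocol

`qpr_align()` orchestrates detection end to end:

1. **Dot matrix.** Sparse coordinate storage; `word` controls the match
   criterion (a word-length substring identity). Word 1 is the classical
   dot plot; larger words suppress the alphabet noise (a uniform DNA pair
   sets a quarter of all cells at word 1) and are standard dot-plot
   practice. The benchmark uses word 8.
2. **Shear.** With `shear = TRUE` (default) the matrix is mapped
   x -> (x - y) mod C, so slope-1 homology diagonals become vertical
   lines. Vertical lines have the sharpest spectra (all transposed mass at
   k' = 0), and indel-shifted continuations land in neighbouring columns
   rather than other angles; per-window inference then uses j_grid = {0}.
3. **Candidate windows.** Non-overlapping L_W x L_W windows holding at
   least `min_window_dots` (default L_0/2) dots are examined,
   main-diagonal band first. Windows adjacent (half a window along the
   query axis) to a positive window are re-examined, catching lines cut
   by window borders.
4. **Exhaustion.** Each window loops QPR -> inference -> localization ->
   record -> suppression until the detected line falls below the length
   cutoff L_0 or `max_lines_per_window` is reached. Suppression clears the
   band of the accepted line (half-width L_D/4 to each side, a line width
   of L_D/2) so that a long line stops shading shorter co-resident ones.
   The inferred length reflects the spectral coherence length — for
   mutation-thinned lines the typical unbroken run, not the full extent —
   so the record's extent comes from a classical walk of the stepping path
   across the whole window, tolerating gaps up to `4*word` cells (one
   substitution blanks `word` consecutive cells).
5. **Validation.** Records map back to sequence coordinates, are extended
   along the slope-1 diagonal with an X-drop rule (match +1, mismatch -2,
   drop 6), and must reach per-base identity `1 - elasticity` and length
   `L_0 + word - 1`; overlapping records (reciprocal overlap >= 50% on
   both axes) are deduplicated keeping the longest. Every accepted anchor
   is therefore verified against the sequences, not just detected — the
   quantum routine is probabilistic, the anchors are not.

The repetition number per window follows
`Omega = min(ceil(c1 * rho/(beta_min * delta_rho^2)), ceil(c2/sqrt(beta_min)))`
with c1 = 1, c2 = 2: the first factor inverts the single-run detection
probability for a pattern occupying a fraction beta of the array, the
second is the cap in 1/sqrt(beta_min). With the default
`beta_min = L_0/L_W^2` and 256-cell windows this gives Omega ≈ 91.

## Synthetic data: what it emulates and what it does not

`generate_pair()` emulates a read-mapping benchmark at desk scale: a
uniform-random reference, `n_segments` non-overlapping segments (one per
equal-width block, uniformly placed within it), and a query concatenating
mutated copies in shuffled order with uniform random linkers.
Substitutions always change the letter; insertions and deletions each
occur at `indel_rate/2` per base and split the planted diagonal, so truth
intervals are emitted per maximal ungapped sub-diagonal. `plant_line()`
plants a rasterized line over independent Bernoulli background noise.
Neither generator models base-composition bias, repeat families,
sequencing error profiles or quality scores; passing tests demonstrate
correct recovery of planted structure under uniform noise, not performance
on real genomes. The benchmark defaults (50 kb reference, 200 segments of
200 bp, 5% substitutions, window 256, elasticity 0.15, L_0 = 32, five
seeds) are the package's scaled-down study conditions; a uniform 50 kb
random reference has essentially no 8-word background matches, which makes
the task easier than real genomic repeats — another reason anchors are
validated against the sequences.

## Numerical choices

* Half-up rounding (`floor(x + 0.5)`) everywhere an integer bracket
  appears; base R's round-half-even would make the rasterization and the
  peak indexing disagree between code paths.
* Norms are checked to 1e-9; spectra are clamped at 1e-300 before taking
  logs so dense likelihood products stay NaN-free (the clamp changes
  log-likelihoods by less than S * 1e-300).
* Register caps: n + m <= 24 bounds the amplitude vector; templates are
  cached per (N, M, grid) and evaluated as one matrix product
  (`infer_line_many()` batches whole grids through a single BLAS call).
* Randomness: one top-level seed; per-window substreams derived by window
  id through a multiplicative hash, so windows are independent and every
  run is reproducible bit for bit. Omega wave-numbers are drawn in one
  vectorized call after the per-repetition geometric retry counts.
* Degenerate inputs: empty windows yield explicit empty results (never a
  retry loop); empty prediction sets leave precision undefined rather
  than zero; ties in DP traceback resolve diagonal, then up, then left.

## Resource estimation

`estimate_resources()` counts elementary gates for one routine execution:
u register Hadamards, a QFT of u(u+1)/2 elementary gates (u Hadamards plus
u(u-1)/2 controlled rotations, truncated to degree-d rotations per line
for the approximate QFT), and an oracle modeled as one cNOT plus one phase
shift per marked cell. Published platform gate durations (superconducting
transmon: 130 ns single-qubit, 650 ns cNOT; trapped ion: 20 us and 250 us)
convert counts to time; error-correcting codes multiply counts by fixed
documented factors (none = 1, [[5,1,3]] = 12, [[7,1,3]] = 16, reflecting
encoded-circuit overheads dominated by encoding and recovery). The oracle
decomposition and code overheads are declared models — the estimator's
output is model-dependent and intended for scaling comparisons, not
hardware forecasts.

## Known limitations

* The angle grid is tan(theta) = j/M; continuous angles, curved or dashed
  patterns are out of scope, and Friedel mates are indistinguishable
  without the window itself.
* Localization in noisy windows can start a record at a gap-adjacent cell;
  the base-space extension step absorbs this in the protocol, but raw
  `localize()` output on noisy windows is approximate.
* The statevector simulator is exact but exponential in qubits; it is a
  desk-scale model of the routine, not an efficiency claim.
* Banded alignment supports linear gap costs only; affine costs are
  available in the unbanded aligners.
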