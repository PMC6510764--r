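#' @name qpr_sim
#' @title Statevector simulation of the quantum pattern recognition routine
#'
#' @description
#' The quantum core operates on a register pair (regX: n qubits for the
#' horizontal cell coordinate x, regY: m qubits for the vertical coordinate
#' y) plus a one-qubit flag register. States are tracked as full complex
#' amplitude vectors over the linear cell index z = x + N*y (length S =
#' 2^(n+m)), or over z tensored with the flag bit (length 2S) between the
#' oracle and the flag measurement. Gate-level unitaries are never
#' materialized; each phase of the routine is applied as a direct vector
#' transform, which is exactly equivalent for this circuit.
#'
#' Phases: uniform superposition (Hadamards on both coordinate registers),
#' black-box oracle entangling the flag with the cell contents, measurement
#' of the flag (collapse to the reflective or absorptive subset), quantum
#' Fourier transform over z, and sampling of the wave-number k.
NULL

.QPR_QUBIT_CAP <- 24L   # n + m cap: bounds the amplitude vector at 2^24

# Flag-measurement retry cap per repetition. The success probability per
# oracle invocation is rho, so the cap scales with the geometric
# expectation 1/rho (16 expected successes' worth of trials); exceeding it
# signals a pathologically sparse window instead of looping forever.
qpr_retry_cap <- function(rho) max(16, ceiling(16 / rho))

new_state <- function(amp, n, m, phase, flag = NA_integer_) {
  structure(list(amplitudes = amp, n = n, m = m, S = 2L^(n + m),
                 phase = phase, flag = flag),
            class = "qpr_state")
}

#' @export
print.qpr_state <- function(x, ...) {
  cat(sprintf("<qpr_state> n=%d m=%d (S=%d), phase=%s, %d amplitudes\n",
              x$n, x$m, x$S, x$phase, length(x$amplitudes)))
  invisible(x)
}

state_norm <- function(state) sum(Mod(state$amplitudes)^2)

check_phase <- function(state, expected) {
  if (!inherits(state, "qpr_state")) stop_domain("not a qpr_state")
  if (!state$phase %in% expected)
    stop_domain("state is in phase '", state$phase, "', expected ",
                paste(expected, collapse = " or "))
}

#' Initialize the coordinate registers in uniform superposition
#'
#' Hadamards on every qubit of regX (n qubits) and regY (m qubits) take
#' |0...0> to the uniform superposition over all S = 2^(n+m) cell indices:
#' every amplitude equals 1/sqrt(S).
#'
#' @param n,m Qubits of the horizontal (regX) and vertical (regY) registers;
#'   both at least 1, n + m at most 24.
#' @return A `qpr_state` in phase `"initialized"` (length-S amplitude vector).
#' @export
init_registers <- function(n, m) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || is.na(m) || n < 1L || m < 1L)
    stop_domain("register sizes n and m must be >= 1")
  if (n + m > .QPR_QUBIT_CAP)
    stop_domain("n + m exceeds the simulation cap of ", .QPR_QUBIT_CAP, " qubits")
  S <- 2L^(n + m)
  new_state(rep(complex(real = 1 / sqrt(S)), S), n, m, "initialized")
}

#' Apply the black-box oracle of a window
#'
#' The oracle computes the cell classifier f(x, y) (1 on reflective cells,
#' 0 on absorptive cells) into the flag register in parallel over the whole
#' superposition: |z>|0> -> |z>|f(z)>. Amplitudes are unchanged; the state
#' length doubles to 2S (flag bit is the high index block).
#'
#' @param state A `qpr_state` in phase `"initialized"`.
#' @param window A [qpr_window] whose (N, M) match the register sizes.
#' @return A `qpr_state` in phase `"entangled"` (length 2S).
#' @export
apply_black_box <- function(state, window) {
  check_phase(state, "initialized")
  if (window$N != 2L^state$n || window$M != 2L^state$m)
    stop_domain("window dimensions (", window$N, " x ", window$M,
                ") do not match registers (n=", state$n, ", m=", state$m, ")")
  S <- state$S
  f <- as.integer(t(window$cells))          # f(z) in z = x + N*y order
  amp <- complex(length.out = 2L * S)
  amp[seq_len(S) + S * f] <- state$amplitudes
  st <- new_state(amp, state$n, state$m, "entangled")
  st$window_rho <- window$rho
  st
}

#' Measure the flag qubit
#'
#' Returns 1 with probability rho (the window density) and collapses the
#' coordinate registers to a uniform superposition over the reflective cells
#' with amplitude 1/sqrt(rho*S); on outcome 0 the absorptive complement
#' survives. The caller repeats the oracle step on outcome 0.
#'
#' @param state A `qpr_state` in phase `"entangled"`.
#' @return A list `(bit, state)`; the collapsed state has phase
#'   `"collapsed"` and length S. Uses the current R random stream.
#' @export
measure_flag <- function(state) {
  check_phase(state, "entangled")
  S <- state$S
  p1 <- sum(Mod(state$amplitudes[(S + 1L):(2L * S)])^2)
  if (p1 <= 0)
    stop_domain("no reflective cells: flag can never measure 1")
  bit <- if (stats::runif(1L) < p1) 1L else 0L
  keep <- if (bit == 1L) (S + 1L):(2L * S) else seq_len(S)
  amp <- state$amplitudes[keep]
  nrm <- sqrt(sum(Mod(amp)^2))
  st <- new_state(amp / nrm, state$n, state$m, "collapsed", flag = bit)
  list(bit = bit, state = st)
}

#' Apply the quantum Fourier transform over the cell index
#'
#' amplitude'(k) = (1/sqrt(S)) * sum_z amplitude(z) exp(+2*pi*i*z*k/S);
#' for the collapsed reflective superposition this is
#' (1/(S*sqrt(rho))) * sum_l exp(2*pi*i*z_l*k/S). Unitary, so the norm is
#' preserved.
#'
#' @param state A `qpr_state` in phase `"collapsed"`.
#' @return A `qpr_state` in phase `"transformed"`.
#' @export
apply_qft <- function(state) {
  check_phase(state, "collapsed")
  amp <- stats::fft(state$amplitudes, inverse = TRUE) / sqrt(state$S)
  st <- new_state(amp, state$n, state$m, "transformed", flag = state$flag)
  st
}

#' Inverse quantum Fourier transform
#'
#' @param state A `qpr_state` in phase `"transformed"`.
#' @return The state back in phase `"collapsed"`.
#' @export
apply_qft_inverse <- function(state) {
  check_phase(state, "transformed")
  amp <- stats::fft(state$amplitudes) / sqrt(state$S)
  new_state(amp, state$n, state$m, "collapsed", flag = state$flag)
}

#' Sample wave-numbers from a transformed state
#'
#' Draws `omega` independent measurements of |k> from the squared-amplitude
#' distribution of the transformed state.
#'
#' @param state A `qpr_state` in phase `"transformed"`.
#' @param omega Number of draws (>= 1).
#' @return Integer vector of wave-numbers in [0, S).
#' @export
sample_k <- function(state, omega) {
  check_phase(state, "transformed")
  omega <- as.integer(omega)
  if (is.na(omega) || omega < 1L) stop_domain("omega must be >= 1")
  p <- Mod(state$amplitudes)^2
  sample.int(state$S, omega, replace = TRUE, prob = p) - 1L
}

#' Analytic wave-number spectrum of a window
#'
#' Closed form of the full pipeline conditioned on flag outcome 1:
#' p(k) = |(1/(S*sqrt(rho))) * sum_{z: cell=1} exp(2*pi*i*z*k/S)|^2.
#' Serves as the oracle the statevector path is checked against, and as the
#' sampling distribution inside [routine_qpr()].
#'
#' @param window A [qpr_window] with rho > 0.
#' @return Numeric probability vector over k = 0..S-1 (sums to 1).
#' @export
analytic_spectrum <- function(window) {
  if (window$rho <= 0) stop_domain("window has no reflective cells (rho = 0)")
  v <- as.numeric(t(window$cells))
  amp <- stats::fft(v, inverse = TRUE) / (window$S * sqrt(window$rho))
  Mod(amp)^2
}

#' Export a spectrum or sample list as plain text
#'
#' @param p Probability vector over k (spectrum) or integer sample vector.
#' @param path Output path. Spectra are written as two-column `k p` lines,
#'   samples as one k per line; k is 0-based.
#' @export
write_spectrum <- function(p, path) {
  writeLines(sprintf("%d %.17g", seq_along(p) - 1L, p), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
write_samples <- function(p, path) {
  writeLines(sprintf("%d", as.integer(p)), path)
  invisible(path)
}

#' Run the QPR routine on a window and its transpose
#'
#' Executes the superposition -> oracle -> flag measurement -> QFT ->
#' measurement pipeline `omega` times on the window and `omega` times on the
#' transposed array (orientation rotated by pi/2), as the Laue inference
#' needs both orientations. Each repetition re-measures the flag, retrying
#' the oracle step on outcome 0 up to 16 times. The collapsed reflective
#' state is identical across successful repetitions, so its QFT spectrum is
#' computed once via the statevector pipeline and one wave-number is drawn
#' per repetition.
#'
#' @param window A [qpr_window].
#' @param omega Repetitions per orientation (>= 1).
#' @param seed Optional integer; when given, a private stream
#'   `derive_seed(seed, window id)` makes the call reproducible and
#'   windows independent.
#' @return Object of class `qpr_samples` with fields `window_id`, `omega`,
#'   `k_orig`, `k_trans`, `rho`, `N`, `M`, `empty`, `retries`. Windows with
#'   no reflective cells (or a repetition exhausting the retry cap) return an
#'   explicit empty result with zero-length sample vectors.
#' @export
routine_qpr <- function(window, omega, seed = NULL) {
  omega <- as.integer(omega)
  if (is.na(omega) || omega < 1L) stop_domain("omega must be >= 1")
  run <- function() {
    empty <- structure(
      list(window_id = window$id, omega = omega, k_orig = integer(),
           k_trans = integer(), rho = window$rho, N = window$N, M = window$M,
           empty = TRUE, retries = 0L),
      class = "qpr_samples")
    if (window$rho <= 0) return(empty)
    draw_orientation <- function(win) {
      st <- apply_qft(collapse_to_reflective(win))
      p <- Mod(st$amplitudes)^2
      # trials until the flag measures 1: geometric with success prob rho,
      # one per repetition; then one wave-number draw per repetition
      cap <- qpr_retry_cap(win$rho)
      tries <- stats::rgeom(omega, win$rho) + 1L
      if (any(tries > cap)) return(NULL)
      ks <- sample.int(win$S, omega, replace = TRUE, prob = p) - 1L
      list(k = ks, retries = sum(tries - 1L))
    }
    a <- draw_orientation(window)
    if (is.null(a)) return(empty)
    b <- draw_orientation(transpose_window(window))
    if (is.null(b)) return(empty)
    structure(
      list(window_id = window$id, omega = omega, k_orig = a$k, k_trans = b$k,
           rho = window$rho, N = window$N, M = window$M, empty = FALSE,
           retries = a$retries + b$retries),
      class = "qpr_samples")
  }
  if (is.null(seed)) run() else with_seed(derive_seed(seed, window$id), run())
}

# init -> oracle -> (flag = 1 branch): the unique collapsed reflective state.
collapse_to_reflective <- function(window) {
  st <- init_registers(window$n, window$m)
  st <- apply_black_box(st, window)
  S <- st$S
  amp <- st$amplitudes[(S + 1L):(2L * S)]
  nrm <- sqrt(sum(Mod(amp)^2))
  if (nrm <= 0) stop_domain("window has no reflective cells (rho = 0)")
  new_state(amp / nrm, st$n, st$m, "collapsed", flag = 1L)
}

#' @export
print.qpr_samples <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<qpr_samples> window %d: empty window (rho = %.3g)\n", x$window_id, x$rho))
  } else {
    cat(sprintf("<qpr_samples> window %d: omega = %d per orientation, rho = %.4g\n",
                x$window_id, x$omega, x$rho))
  }
  invisible(x)
}

#' Gate-count and run-time model for one routine execution
#'
#' Counts the elementary gates of one pipeline execution for a register
#' total of u qubits and converts them to a time with published platform
#' gate durations (superconducting transmon: H and X 130 ns, cNOT 650 ns;
#' trapped ion: 20 us single-qubit, 250 us cNOT). The full QFT contributes
#' u(u+1)/2 elementary gates (u Hadamards plus u(u-1)/2 controlled
#' rotations); the approximate QFT of degree d keeps at most d-1 controlled
#' rotations per qubit line. The oracle is modeled as one cNOT plus one
#' phase shift per marked (reflective) cell; error-correcting codes multiply
#' all counts by a fixed documented factor. The counting model is declared,
#' not measured, and the output is labeled model-dependent.
#'
#' @param u Total register size in qubits (>= 2).
#' @param platform `"superconducting"` or `"trapped-ion"`.
#' @param code `"none"`, `"[[5,1,3]]"` or `"[[7,1,3]]"`.
#' @param aqft_degree Approximation degree of the QFT; `Inf` (or >= u) gives
#'   the full QFT. Default 2.
#' @param marked_cells Reflective cells the oracle marks; defaults to
#'   2^floor(u/2) (a full-height line in a square window).
#' @return Object of class `resource_estimate`: gate counts, code factor and
#'   estimated time in microseconds.
#' @export
estimate_resources <- function(u, platform = c("superconducting", "trapped-ion"),
                               code = c("none", "[[5,1,3]]", "[[7,1,3]]"),
                               aqft_degree = 2, marked_cells = NULL) {
  u <- as.integer(u)
  if (is.na(u) || u < 2L) stop_domain("u must be >= 2")
  platform <- match.arg(platform)
  code <- match.arg(code)
  if (is.null(marked_cells)) marked_cells <- 2^(u %/% 2L)
  # QFT line i (from the bottom) holds 1 Hadamard + (i - 1) controlled
  # rotations, truncated at aqft_degree - 1 rotations per line.
  rot_per_line <- pmin(seq_len(u) - 1L, max(0, aqft_degree - 1))
  counts <- c(
    hadamard = u + u,                                # initial layer + QFT
    cnot = marked_cells,                             # oracle model
    phase_shift = marked_cells + sum(rot_per_line)   # oracle + QFT rotations
  )
  code_factor <- c("none" = 1, "[[5,1,3]]" = 12, "[[7,1,3]]" = 16)[[code]]
  counts <- counts * code_factor
  dur <- switch(platform,                            # nanoseconds per gate
    "superconducting" = c(hadamard = 130, cnot = 650, phase_shift = 130),
    "trapped-ion" = c(hadamard = 20000, cnot = 250000, phase_shift = 20000))
  est_time_us <- sum(counts * dur[names(counts)]) / 1000
  structure(
    list(u = u, platform = platform, code = code, aqft_degree = aqft_degree,
         marked_cells = marked_cells, gate_counts = counts,
         qft_gate_count = u + sum(rot_per_line), code_factor = code_factor,
         est_time_us = est_time_us),
    class = "resource_estimate")
}

#' @export
print.resource_estimate <- function(x, ...) {
  cat(sprintf("<resource_estimate> u=%d, %s, code %s, AQFT degree %s (model-dependent)\n",
              x$u, x$platform, x$code, format(x$aqft_degree)))
  cat(sprintf("  gates: H=%g cNOT=%g phase=%g (QFT alone: %g); est. time %.4g us\n",
              x$gate_counts[["hadamard"]], x$gate_counts[["cnot"]],
              x$gate_counts[["phase_shift"]], x$qft_gate_count, x$est_time_us))
  invisible(x)
}
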