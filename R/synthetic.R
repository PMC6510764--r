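#' @name synthetic
#' @title Synthetic fixtures: planted homologies and planted line patterns
#'
#' @description
#' Generators for the two test substrates every other module runs on:
#' sequence pairs whose homologous segments (with configurable substitution
#' and indel rates) are known exactly, and binary windows holding a planted
#' rasterized line over uniform background noise. Both are deterministic
#' under a seed.
NULL

#' Plant a line pattern in a binary window
#'
#' Sets the cells x = x0 + [l*j/M], y = y0 + l for l = 0..L_D-1 (half-up
#' rounding; tan(theta) = j/M on the supported angle grid), then switches
#' each background cell on independently with probability `noise_rho`.
#'
#' @param N,M Window columns and rows (powers of 2).
#' @param L_D Line length in cells.
#' @param j Integer angle index (tan(theta) = j/M); default 0 (vertical).
#' @param x0,y0 Window-local start cell (0-based).
#' @param noise_rho Background reflective-cell density in [0, 1).
#' @param seed Optional integer seed.
#' @param id Window id.
#' @return List with elements `window` ([qpr_window]) and `line`
#'   (the true [line_pattern]).
#' @export
plant_line <- function(N, M, L_D, j = 0L, x0 = 0L, y0 = 0L, noise_rho = 0,
                       seed = NULL, id = 0L) {
  if (noise_rho < 0 || noise_rho >= 1) stop_domain("noise_rho must be in [0, 1)")
  cl <- line_cells(L_D, j, M, x0, y0)
  if (any(cl$x < 0L | cl$x >= N | cl$y < 0L | cl$y >= M))
    stop_domain("line does not fit inside the ", N, " x ", M, " window")
  build <- function() {
    cells <- matrix(0L, nrow = M, ncol = N)
    if (noise_rho > 0)
      cells[stats::runif(N * M) < noise_rho] <- 1L
    cells[cbind(cl$y + 1L, cl$x + 1L)] <- 1L
    cells
  }
  cells <- if (is.null(seed)) build() else with_seed(seed, build())
  list(window = qpr_window(cells, id = id),
       line = line_pattern(L_D, j, N, M, x0 = x0, y0 = y0))
}

#' Generate a sequence pair with planted homologous segments
#'
#' The reference is uniform-random over the alphabet. `n_segments`
#' non-overlapping reference segments of length `seg_len` are chosen (one
#' per equal-width reference block, uniformly placed within its block), and
#' the query is the concatenation of mutated copies of those segments in
#' shuffled order, separated by random linkers. Substitutions replace a base
#' with a different one; insertions and deletions each occur at rate
#' `indel_rate/2` per base and split the true diagonal, so truth records are
#' emitted per maximal ungapped sub-diagonal.
#'
#' @param L_R Reference length.
#' @param n_segments,seg_len Number and length of planted segments.
#' @param sub_rate,indel_rate Per-base substitution and indel rates (< 0.5).
#' @param alphabet Character vector (default DNA).
#' @param linker_max Maximum random linker length between segments.
#' @param seed Optional integer seed.
#' @return List with `query`, `reference` ([qpr_seq]) and `truth`, a data
#'   frame with 0-based half-open columns `segment`, `q_start`, `q_end`,
#'   `r_start`, `r_end`.
#' @export
generate_pair <- function(L_R, n_segments, seg_len, sub_rate = 0.05,
                          indel_rate = 0, alphabet = c("A", "C", "G", "T"),
                          linker_max = 20L, seed = NULL) {
  if (sub_rate < 0 || sub_rate >= 0.5 || indel_rate < 0 || indel_rate >= 0.5)
    stop_domain("mutation rates must be in [0, 0.5)")
  block <- L_R %/% n_segments
  if (n_segments * seg_len > L_R || seg_len > block)
    stop_domain("infeasible packing: ", n_segments, " x ", seg_len,
                " segments do not fit in L_R = ", L_R)
  run <- function() {
    ref <- sample(alphabet, L_R, replace = TRUE)
    starts <- (seq_len(n_segments) - 1L) * block +
      vapply(seq_len(n_segments), function(i) sample.int(block - seg_len + 1L, 1L) - 1L, 0L)
    order_q <- sample.int(n_segments)
    qparts <- character(0)
    truth <- vector("list", n_segments)
    qpos <- 0L
    for (seg in order_q) {
      linker <- sample(alphabet, sample.int(linker_max + 1L, 1L) - 1L, replace = TRUE)
      qparts <- c(qparts, linker)
      qpos <- qpos + length(linker)
      r0 <- starts[seg]
      out <- character(0)
      runs <- list()
      run_q0 <- qpos; run_r0 <- r0
      qp <- qpos
      for (i in seq_len(seg_len)) {
        rp <- r0 + i - 1L
        u <- stats::runif(1L)
        if (u < indel_rate / 2) {                       # deletion of this base
          if (rp > run_r0)
            runs[[length(runs) + 1L]] <- c(run_q0, qp, run_r0, rp)
          run_q0 <- qp; run_r0 <- rp + 1L
          next
        }
        if (u < indel_rate) {                           # insertion before base
          if (rp > run_r0)
            runs[[length(runs) + 1L]] <- c(run_q0, qp, run_r0, rp)
          out <- c(out, sample(alphabet, 1L))
          qp <- qp + 1L
          run_q0 <- qp; run_r0 <- rp
        }
        base <- ref[rp + 1L]
        if (stats::runif(1L) < sub_rate)
          base <- sample(setdiff(alphabet, base), 1L)
        out <- c(out, base)
        qp <- qp + 1L
      }
      if (r0 + seg_len > run_r0)
        runs[[length(runs) + 1L]] <- c(run_q0, qp, run_r0, r0 + seg_len)
      qparts <- c(qparts, out)
      qpos <- qp
      truth[[seg]] <- do.call(rbind, runs)
    }
    tr <- do.call(rbind, lapply(seq_len(n_segments), function(seg) {
      m <- truth[[seg]]
      data.frame(segment = seg, q_start = m[, 1L], q_end = m[, 2L],
                 r_start = m[, 3L], r_end = m[, 4L])
    }))
    tr <- tr[order(tr$q_start), , drop = FALSE]
    rownames(tr) <- NULL
    list(query = qpr_seq("query", paste(qparts, collapse = "")),
         reference = qpr_seq("reference", paste(ref, collapse = "")),
         truth = tr)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write planted truth intervals as BED-like text
#'
#' 0-based half-open intervals on the query with mate coordinates on the
#' reference in extra columns.
#'
#' @param truth Truth data frame from [generate_pair()].
#' @param path Output path.
#' @param query_id,ref_id Sequence ids for the first and mate columns.
#' @export
write_truth_bed <- function(truth, path, query_id = "query", ref_id = "reference") {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\tsegment_%d", query_id,
                   truth$q_start, truth$q_end, ref_id, truth$r_start,
                   truth$r_end, truth$segment)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(segment = as.integer(sub("segment_", "", df[[7L]])),
             q_start = df[[2L]], q_end = df[[3L]],
             r_start = df[[5L]], r_end = df[[6L]])
}
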