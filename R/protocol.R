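#' @name protocol
#' @title Window protocol: fragmentation, detection, records, suppression
#'
#' @description
#' Orchestrates the alignment protocol: the dot matrix is (optionally)
#' sheared so slope-1 homology diagonals become vertical lines, fragmented
#' into power-of-two window spaces, and each candidate window is exhausted
#' by a loop of QPR runs, Laue inference, localization, record keeping and
#' suppression of the detected band, until no line of length at least L_0
#' remains. Accepted records are mapped back to sequence coordinates,
#' greedily extended, validated against per-base identity, deduplicated and
#' sorted.
NULL

#' Protocol configuration
#'
#' @param L_W Window edge (power of 2).
#' @param L_0 Minimum accepted diagonal length, in dot-matrix cells. Must be
#'   below L_W; a warning is issued when L_0 > L_W/4 (the cutoff should be
#'   well below the window size).
#' @param omega Repetitions of the QPR routine per window and orientation;
#'   `"auto"` chooses per window via [choose_omega()].
#' @param overlap Window overlap in cells for the base tiling.
#' @param elasticity Allowed mismatch fraction within a detected line
#'   (default 0.15).
#' @param delta_rho Acceptable deviation of within-line dot density.
#' @param beta_min Smallest pattern fraction of interest; default
#'   L_0 / L_W^2.
#' @param shear Shear the dot matrix (x -> (x - y) mod C) so slope-1
#'   diagonals become vertical lines; on by default.
#' @param seed Integer seed; all per-window randomness is derived from it.
#' @param max_lines_per_window Cap on records extracted from one window.
#' @param word Word length of the dot-matrix match criterion.
#' @param widen Re-examine half-shifted neighbours of positive windows
#'   (catches diagonals cut by window borders).
#' @param diag_first Scan windows on the main-diagonal band first.
#' @param c1,c2 Constants of the omega bounds (see [choose_omega()]).
#' @param j_grid Angle-index grid for per-window inference; with shearing on
#'   the homology lines are vertical and the default is 0.
#' @param min_window_dots Minimum dot count for a window to be examined;
#'   default ceiling(L_0 / 2).
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(L_W = 256L, L_0 = 32L, omega = "auto",
                            overlap = 0L, elasticity = 0.15, delta_rho = 0.1,
                            beta_min = NULL, shear = TRUE, seed = 1L,
                            max_lines_per_window = 8L, word = 1L,
                            widen = TRUE, diag_first = TRUE,
                            c1 = 1, c2 = 2, j_grid = NULL,
                            min_window_dots = NULL) {
  if (!is_pow2(L_W)) stop_domain("L_W must be a power of 2")
  L_0 <- as.integer(L_0)
  if (L_0 >= L_W) stop_domain("L_0 must be smaller than L_W")
  if (L_0 > L_W / 4)
    warning("L_0 > L_W/4: the length cutoff should be well below the window size")
  if (elasticity < 0 || elasticity >= 1) stop_domain("elasticity must be in [0, 1)")
  beta_min <- beta_min %||% (L_0 / (as.double(L_W) * L_W))
  if (!identical(omega, "auto")) {
    omega <- as.integer(omega)
    cap <- ceiling(c2 / sqrt(beta_min))
    if (omega > cap)
      warning("omega exceeds the O(1/sqrt(beta_min)) cap of ", cap)
  }
  structure(
    list(L_W = as.integer(L_W), L_0 = L_0, omega = omega,
         overlap = as.integer(overlap), elasticity = elasticity,
         delta_rho = delta_rho, beta_min = beta_min, shear = isTRUE(shear),
         seed = as.integer(seed),
         max_lines_per_window = as.integer(max_lines_per_window),
         word = as.integer(word), widen = isTRUE(widen),
         diag_first = isTRUE(diag_first), c1 = c1, c2 = c2,
         j_grid = j_grid %||% if (isTRUE(shear)) 0L else seq.int(-16L, 16L),
         min_window_dots = as.integer(min_window_dots %||% max(2L, ceiling(L_0 / 2)))),
    class = "protocol_config")
}

#' Choose the QPR repetition number
#'
#' The single-run probability of locating a pattern occupying a fraction
#' beta of the array scales like beta * delta_rho^2 / rho, so the required
#' repetitions scale like its inverse; independently the repetition number
#' is capped at O(1/sqrt(beta_min)). Omega is the smaller of
#' ceiling(c1 * rho / (beta_min * delta_rho^2)) and
#' ceiling(c2 / sqrt(beta_min)), and at least 1.
#'
#' @param beta_min Smallest pattern fraction of interest, in (0, 1].
#' @param delta_rho Acceptable within-line density deviation.
#' @param rho Window density (> 0).
#' @param c1,c2 Model constants (defaults 1 and 2).
#' @return Integer omega.
#' @export
choose_omega <- function(beta_min, delta_rho, rho, c1 = 1, c2 = 2) {
  if (!is.numeric(beta_min) || beta_min <= 0 || beta_min > 1)
    stop_domain("beta_min must be in (0, 1]")
  if (rho <= 0) stop_domain("rho must be > 0")
  o1 <- ceiling(c1 * rho / (beta_min * delta_rho^2))
  o2 <- ceiling(c2 / sqrt(beta_min))
  max(1L, as.integer(min(o1, o2)))
}

empty_records <- function() {
  data.frame(id = integer(), window_id = integer(), L_D = integer(),
             theta_rad = numeric(), x0 = integer(), x1 = integer(),
             y0 = integer(), y1 = integer(), density = numeric())
}

new_record <- function(id, window_id, L_D, theta, x0, y0, density) {
  data.frame(id = as.integer(id), window_id = as.integer(window_id),
             L_D = as.integer(L_D), theta_rad = theta,
             x0 = as.integer(x0), x1 = as.integer(x0 + L_D),
             y0 = as.integer(y0), y1 = as.integer(y0 + L_D),
             density = density)
}

#' Suppress the band of a detected diagonal in a window
#'
#' Zeroes the cells within the record's band — the line's stepping path
#' widened by `half_width` columns to each side, across the record's rows —
#' leaving all other cells unchanged. Used to stop the longest line from
#' shading shorter co-resident lines on the next detection pass.
#'
#' @param window A [qpr_window].
#' @param record One-row record data frame (global coordinates, as produced
#'   by [exhaust_window()]).
#' @param half_width Band half-width in columns; defaults to one quarter of
#'   the record length (a line width of L_D/2).
#' @return The window with the band cleared.
#' @export
suppress_region <- function(window, record, half_width = NULL) {
  x0 <- record$x0 - window$origin[1L]
  y0 <- record$y0 - window$origin[2L]
  L <- record$L_D
  if (y0 + L <= 0L || y0 >= window$M || x0 >= window$N)
    stop_domain("record lies outside the window")
  half_width <- half_width %||% max(1L, ceiling(L / 4))
  j <- as.integer(rnd(tan(record$theta_rad) * window$M))
  cl <- line_cells(L, j, window$M, x0, y0)
  cells <- window$cells
  for (i in seq_len(nrow(cl))) {
    y <- cl$y[i]
    if (y < 0L || y >= window$M) next
    xs <- max(0L, cl$x[i] - half_width):min(window$N - 1L, cl$x[i] + half_width)
    if (length(xs)) cells[y + 1L, xs + 1L] <- 0L
  }
  qpr_window(cells, origin = window$origin, id = window$id)
}

# Classical validation walk: extend the stepping path of (line, x0, y0)
# through the whole window (the inferred L_D reflects the spectral
# coherence length, which for mutation-thinned lines is the typical run
# length, not the full extent), then take the maximal occupied run around
# the localized start, tolerating internal gaps of up to max_gap cells
# (a single mismatch at word length w blanks w consecutive cells).
# Returns the refined local start, length and dot density, or NULL.
trim_line <- function(window, line, x0, y0, max_gap = 1L) {
  l <- seq.int(-y0, window$M - 1L - y0)
  xs <- as.integer(x0 + rnd(l * line$j / window$M))
  ys <- y0 + l
  ok <- xs >= 0L & xs < window$N
  occ <- logical(length(l))
  occ[ok] <- window$cells[cbind(ys[ok] + 1L, xs[ok] + 1L)] == 1L
  idx <- which(occ)
  if (length(idx) == 0L) return(NULL)
  # split occupied positions into runs separated by gaps > max_gap
  brk <- c(0L, which(diff(idx) > max_gap + 1L), length(idx))
  anchor <- y0 + 1L - ys[1L]          # path index of the localized start
  best <- NULL
  for (b in seq_len(length(brk) - 1L)) {
    run <- idx[(brk[b] + 1L):brk[b + 1L]]
    covers <- anchor >= run[1L] - max_gap && anchor <= run[length(run)] + max_gap
    if (is.null(best) || (covers && !best$covers) ||
        (covers == best$covers && length(run) > best$n)) {
      best <- list(first = run[1L], last = run[length(run)],
                   n = length(run), covers = covers)
    }
  }
  first <- best$first; last <- best$last
  list(x0 = xs[first], y0 = ys[first], L = last - first + 1L,
       density = mean(occ[first:last]))
}

#' Exhaust a window: detect, record and suppress until below threshold
#'
#' Repeats {QPR run, Laue inference, localization, record, suppression}
#' until no line of length at least L_0 is detected or the per-window cap is
#' reached. Detected lines are trimmed to their occupied extent and must
#' reach the within-line density `(1 - elasticity)^word` (per-cell match
#' probability under the mismatch elasticity at the configured word length).
#' Records carry global dot-matrix coordinates via the window origin and
#' are returned longest first.
#'
#' @param window A [qpr_window].
#' @param config A [protocol_config].
#' @param seed Optional seed overriding `config$seed`.
#' @return Record data frame (possibly empty) with columns `id`,
#'   `window_id`, `L_D`, `theta_rad`, `x0`, `x1`, `y0`, `y1`, `density`.
#' @export
exhaust_window <- function(window, config = protocol_config(L_W = window$N),
                           seed = NULL) {
  seed <- seed %||% config$seed
  with_seed(derive_seed(seed, window$id), exhaust_window_impl(window, config))
}

exhaust_window_impl <- function(window, config) {
  recs <- empty_records()
  win <- window
  dens_min <- (1 - config$elasticity)^config$word
  max_gap <- max(2L, 4L * config$word)
  L_grid <- seqesc(2L, win$M)
  for (it in seq_len(config$max_lines_per_window)) {
    if (win$rho <= 0) break
    omega <- if (identical(config$omega, "auto"))
      choose_omega(config$beta_min, config$delta_rho, win$rho,
                   config$c1, config$c2)
    else config$omega
    smp <- routine_qpr(win, omega)
    if (smp$empty) break
    line <- infer_line(smp, L_grid = L_grid, j_grid = config$j_grid)
    if (is.null(line)) break
    loc <- localize(win, line, omega = min(omega, 8L),
                    min_path_density = max(0.25, dens_min / 2))
    if (is.null(loc)) break
    jloc <- attr(loc, "j") %||% line$j
    if (jloc != line$j) line <- line_pattern(line$L_D, jloc, win$N, win$M)
    tl <- trim_line(win, line, loc[["x0"]], loc[["y0"]], max_gap = max_gap)
    if (is.null(tl)) break
    if (tl$L < config$L_0) break   # window exhausted: below the cutoff
    rec <- new_record(nrow(recs) + 1L, win$id, tl$L, line$theta,
                      win$origin[1L] + tl$x0, win$origin[2L] + tl$y0,
                      tl$density)
    if (tl$density >= dens_min) recs <- rbind(recs, rec)
    win <- suppress_region(win, rec)
  }
  if (nrow(recs) > 1L) {
    recs <- recs[order(-recs$L_D, recs$y0, recs$x0), , drop = FALSE]
    recs$id <- seq_len(nrow(recs))
    rownames(recs) <- NULL
  }
  recs
}

# X-drop extension of an exact/near-exact slope-1 run in base space.
# qv, rv: raw byte vectors of the sequences; q0, r0, len: initial run
# (0-based). Returns refined (q0, r0, len, identity).
extend_record <- function(qv, rv, q0, r0, len, xdrop = 6L) {
  lq <- length(qv); lr <- length(rv)
  len <- min(len, lq - q0, lr - r0)
  if (len <= 0L) return(NULL)
  # right extension
  best <- 0; sc <- 0; best_i <- 0L
  i <- len
  while (q0 + i < lq && r0 + i < lr) {
    sc <- sc + if (qv[q0 + i + 1L] == rv[r0 + i + 1L]) 1 else -2
    i <- i + 1L
    if (sc > best) { best <- sc; best_i <- i - len }
    if (best - sc > xdrop) break
  }
  right <- len + best_i
  # left extension
  best <- 0; sc <- 0; best_i <- 0L
  i <- 0L
  while (q0 - i > 0L && r0 - i > 0L) {
    sc <- sc + if (qv[q0 - i] == rv[r0 - i]) 1 else -2
    i <- i + 1L
    if (sc > best) { best <- sc; best_i <- i }
    if (best - sc > xdrop) break
  }
  q0 <- q0 - best_i; r0 <- r0 - best_i
  len <- right + best_i
  m <- qv[(q0 + 1L):(q0 + len)] == rv[(r0 + 1L):(r0 + len)]
  # trim mismatching ends
  w <- which(m)
  if (length(w) == 0L) return(NULL)
  q0 <- q0 + w[1L] - 1L; r0 <- r0 + w[1L] - 1L
  len <- w[length(w)] - w[1L] + 1L
  m <- m[w[1L]:w[length(w)]]
  list(q0 = q0, r0 = r0, len = len, identity = mean(m))
}

#' Align two sequences via the window protocol
#'
#' Builds the dot matrix, shears it (if configured), scans candidate
#' windows (main-diagonal band first), exhausts each positive window, maps
#' the detections back to sequence coordinates, extends them along the
#' slope-1 diagonal, validates per-base identity against the mismatch
#' elasticity, deduplicates overlapping records and returns them sorted by
#' (x0, y0). Deterministic under the configured seed.
#'
#' @param query,reference [qpr_seq] objects (or strings).
#' @param config A [protocol_config].
#' @return Data frame of anchor records in base coordinates: `id`,
#'   `window_id`, `L_D`, `theta_rad`, `x0`, `x1` (reference range, printed
#'   closed as \[x0, x0+L_D\], interpreted half-open), `y0`, `y1` (query
#'   range), `density` (per-base identity).
#' @export
qpr_align <- function(query, reference, config = protocol_config()) {
  query <- as_qpr_seq(query, "query")
  reference <- as_qpr_seq(reference, "reference")
  if (query$length == 0L || reference$length == 0L)
    stop_domain("sequences must be non-empty")
  dot <- build_dot_matrix(query, reference, config$word)
  C <- dot$nx
  sheared <- dot
  if (config$shear) sheared$x <- (dot$x - dot$y) %% C
  L_W <- config$L_W
  # candidate windows by dot count
  wx <- sheared$x %/% L_W; wy <- sheared$y %/% L_W
  nwx <- max(1L, ceiling(C / L_W)); nwy <- max(1L, ceiling(dot$ny / L_W))
  wid <- wx + nwx * wy
  cnt <- table(wid)
  cand <- as.integer(names(cnt))[as.integer(cnt) >= config$min_window_dots]
  if (length(cand) == 0L) return(empty_records())
  X0 <- (cand %% nwx) * L_W; Y0 <- (cand %/% nwx) * L_W
  if (config$diag_first) {
    dd <- if (config$shear) pmin(X0, C - X0) else abs(X0 - Y0)
    ord <- order(dd, Y0, X0)
  } else ord <- order(Y0, X0)
  X0 <- X0[ord]; Y0 <- Y0[ord]
  qv <- charToRaw(query$residues); rv <- charToRaw(reference$residues)
  # dot counts on the half-stride grid: every examined origin is a multiple
  # of L_W/2, so any window's count is the sum of four half-grid cells
  h <- L_W %/% 2L
  nhx <- C %/% h + 2L; nhy <- dot$ny %/% h + 2L
  hcnt <- matrix(0L, nrow = nhx, ncol = nhy)   # rows = x cell, cols = y cell
  htab <- table((sheared$x %/% h) + nhx * (sheared$y %/% h))
  hcnt[as.integer(names(htab)) + 1L] <- as.integer(htab)
  win_count <- function(x0w, y0w) {
    ix <- x0w %/% h + 1L; iy <- y0w %/% h + 1L
    sum(hcnt[ix:min(ix + 1L, nhx), iy:min(iy + 1L, nhy)])
  }
  done <- new.env(parent = emptyenv())
  queue <- data.frame(X0 = X0, Y0 = Y0)
  out <- list()
  qi <- 1L
  while (qi <= nrow(queue)) {
    x0w <- queue$X0[qi]; y0w <- queue$Y0[qi]; qi <- qi + 1L
    key <- paste(x0w, y0w)
    if (!is.null(done[[key]])) next
    done[[key]] <- TRUE
    if (win_count(x0w, y0w) < config$min_window_dots) next
    wkey <- (x0w %/% h) + 100003L * (y0w %/% h)
    win <- extract_window(sheared, x0w, y0w, L_W, id = wkey)
    if (win$rho <= 0) next
    recs <- exhaust_window(win, config)
    if (nrow(recs) == 0L) next
    out[[length(out) + 1L]] <- recs
    if (config$widen) {                    # half-shifted neighbour windows
      nb <- rbind(c(x0w, y0w - h), c(x0w, y0w + h))
      if (!config$shear)                   # unsheared lines can cross x borders
        nb <- rbind(nb, c(x0w - h, y0w), c(x0w + h, y0w))
      nb <- nb[nb[, 1L] >= 0L & nb[, 2L] >= 0L &
               nb[, 1L] < C & nb[, 2L] < dot$ny, , drop = FALSE]
      if (nrow(nb))
        queue <- rbind(queue, data.frame(X0 = nb[, 1L], Y0 = nb[, 2L]))
    }
  }
  if (length(out) == 0L) return(empty_records())
  raw_recs <- do.call(rbind, out)
  # map to base coordinates: unshear, extend, validate identity
  final <- list()
  for (i in seq_len(nrow(raw_recs))) {
    r <- raw_recs[i, ]
    yd <- r$y0
    xd <- if (config$shear) (r$x0 + yd) %% C else r$x0
    len0 <- r$L_D + config$word - 1L
    ext <- extend_record(qv, rv, yd, xd, len0)
    if (is.null(ext)) next
    if (ext$identity < 1 - config$elasticity) next
    if (ext$len < config$L_0 + config$word - 1L) next
    final[[length(final) + 1L]] <-
      new_record(0L, r$window_id, ext$len, 0, ext$r0, ext$q0, ext$identity)
  }
  if (length(final) == 0L) return(empty_records())
  recs <- do.call(rbind, final)
  recs <- recs[order(recs$x0, recs$y0, -recs$L_D), , drop = FALSE]
  # dedup by reciprocal overlap >= 50% on both ranges, keep the longest
  keep <- rep(TRUE, nrow(recs))
  for (i in seq_len(nrow(recs))) {
    if (!keep[i]) next
    for (k in seq_len(nrow(recs))) {
      if (k == i || !keep[k]) next
      if (recs$L_D[k] > recs$L_D[i]) next
      ox <- interval_overlap(recs$x0[i], recs$x1[i], recs$x0[k], recs$x1[k])
      oy <- interval_overlap(recs$y0[i], recs$y1[i], recs$y0[k], recs$y1[k])
      if (ox >= 0.5 && oy >= 0.5) keep[k] <- FALSE
    }
  }
  recs <- recs[keep, , drop = FALSE]
  recs <- recs[order(recs$x0, recs$y0), , drop = FALSE]
  recs$id <- seq_len(nrow(recs))
  rownames(recs) <- NULL
  recs
}

# reciprocal overlap fraction of two half-open intervals
interval_overlap <- function(a0, a1, b0, b1) {
  ov <- max(0, min(a1, b1) - max(a0, b0))
  if (ov == 0) return(0)
  min(ov / (a1 - a0), ov / (b1 - b0))
}

#' Write protocol records as TSV
#'
#' @param records Record data frame from [qpr_align()].
#' @param path Output path.
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
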