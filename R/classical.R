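#' @name classical_analogue
#' @title Classical diagonal scanning and precision/recall evaluation
#'
#' @description
#' The classical counterpart of the quantum detection loop: diagonals of a
#' window are scanned directly and their dot sums compared against a
#' threshold; a matrix of positive windows indexes the regions of
#' similarity. Also houses the precision/recall evaluator used to score
#' predictions against planted truth.
NULL

#' Scan the diagonals of a window for dot sums
#'
#' Sums the 1-cells along each scanned diagonal offset (offset = x - y) and
#' reports whether the best sum reaches the threshold. By default the
#' central ~50% of offsets are scanned; with `scan_fraction = 1` every
#' offset is scanned.
#'
#' @param window A [qpr_window] (or plain binary matrix).
#' @param threshold Positive integer dot-sum threshold.
#' @param scan_fraction Fraction of diagonal offsets scanned, centred on
#'   offset 0 (default 0.5).
#' @return List with `positive` (flag), `best_run` (best diagonal dot sum
#'   over the scanned offsets) and `best_offset`. Ties prefer the smallest
#'   |offset|, then the smallest offset.
#' @export
scan_diagonals <- function(window, threshold, scan_fraction = 0.5) {
  if (threshold < 1) stop_domain("threshold must be >= 1")
  cells <- if (inherits(window, "qpr_window")) window$cells else window
  M <- nrow(cells); N <- ncol(cells)
  offsets <- seq.int(-(M - 1L), N - 1L)
  n_scan <- max(1L, rnd(length(offsets) * scan_fraction))
  scan <- offsets[order(abs(offsets), offsets)][seq_len(n_scan)]
  idx <- which(cells == 1L, arr.ind = TRUE)
  sums <- setNames(rep(0L, length(scan)), scan)
  if (nrow(idx) > 0L) {
    o <- (idx[, 2L] - idx[, 1L])        # x - y
    tab <- table(o[o %in% scan])
    sums[names(tab)] <- as.integer(tab)
  }
  ord <- order(-sums, abs(scan), scan)
  best <- ord[1L]
  list(positive = sums[[best]] >= threshold,
       best_run = as.integer(sums[[best]]),
       best_offset = as.integer(scan[best]))
}

#' Matrix of positive windows over a dot matrix
#'
#' Tiles the dot matrix with non-overlapping L_W windows and marks each
#' window whose best scanned diagonal sum reaches the threshold; the
#' resulting binary matrix (window-grid rows = query, columns = reference)
#' indexes the regions of similarity.
#'
#' @param dot A `dot_matrix`.
#' @param L_W Window edge (power of 2).
#' @param threshold Dot-sum threshold; the default ties it to the window
#'   size as round(0.85 * L_W * 0.5).
#' @param scan_fraction Fraction of offsets scanned per window.
#' @return Binary integer matrix over the window grid.
#' @export
positive_window_matrix <- function(dot, L_W, threshold = NULL,
                                   scan_fraction = 0.5) {
  if (!is_pow2(L_W)) stop_domain("L_W must be a power of 2")
  threshold <- threshold %||% max(1L, rnd(0.85 * L_W * 0.5))
  nwx <- max(1L, ceiling(dot$nx / L_W)); nwy <- max(1L, ceiling(dot$ny / L_W))
  out <- matrix(0L, nrow = nwy, ncol = nwx)
  if (dot$n_dots == 0L) return(out)
  # sparse path: group dots by (window, local offset) without densifying
  wx <- dot$x %/% L_W; wy <- dot$y %/% L_W
  lo <- (dot$x %% L_W) - (dot$y %% L_W)
  offsets <- seq.int(-(L_W - 1L), L_W - 1L)
  n_scan <- max(1L, rnd(length(offsets) * scan_fraction))
  scan <- offsets[order(abs(offsets), offsets)][seq_len(n_scan)]
  keep <- lo %in% scan
  if (!any(keep)) return(out)
  key <- paste(wx[keep], wy[keep], lo[keep])
  tab <- table(key)
  hit <- tab[as.integer(tab) >= threshold]
  if (length(hit) > 0L) {
    parts <- do.call(rbind, strsplit(names(hit), " "))
    out[cbind(as.integer(parts[, 2L]) + 1L, as.integer(parts[, 1L]) + 1L)] <- 1L
  }
  out
}

#' Precision and recall of predicted homology intervals
#'
#' A prediction is a true positive when some truth interval matches it with
#' reciprocal overlap of at least `min_overlap` on both the query and the
#' reference ranges; truth intervals matched by no prediction are false
#' negatives. Precision = TP/(TP+FP), recall = TP/(TP+FN); an empty
#' prediction set leaves precision undefined (NA, flagged), not zero.
#'
#' @param truth,predicted Data frames with 0-based half-open columns
#'   `q_start`, `q_end`, `r_start`, `r_end` (the truth format of
#'   [generate_pair()]; [records_to_intervals()] converts protocol
#'   records).
#' @param batches Optional list of `(truth, predicted)` pairs; metrics are
#'   then computed per batch and reported with mean and standard deviation.
#' @param min_overlap Reciprocal-overlap threshold (default 0.5).
#' @return List of class `eval_metrics` with `TP`, `FP`, `FN`, `precision`,
#'   `recall` (and `per_batch`, `mean`, `sd` when batches are given).
#' @export
precision_recall <- function(truth = NULL, predicted = NULL, batches = NULL,
                             min_overlap = 0.5) {
  if (!is.null(batches)) {
    per <- lapply(batches, function(b)
      precision_recall(b$truth, b$predicted, min_overlap = min_overlap))
    pr <- vapply(per, `[[`, 0, "precision")
    rc <- vapply(per, `[[`, 0, "recall")
    return(structure(
      list(per_batch = per,
           mean = c(precision = mean(pr, na.rm = TRUE), recall = mean(rc)),
           sd = c(precision = stats::sd(pr), recall = stats::sd(rc))),
      class = "eval_metrics"))
  }
  matched_truth <- rep(FALSE, nrow(truth))
  tp <- 0L
  fp <- 0L
  if (nrow(predicted) > 0L) for (i in seq_len(nrow(predicted))) {
    hit <- FALSE
    for (k in seq_len(nrow(truth))) {
      oq <- interval_overlap(predicted$q_start[i], predicted$q_end[i],
                             truth$q_start[k], truth$q_end[k])
      or <- interval_overlap(predicted$r_start[i], predicted$r_end[i],
                             truth$r_start[k], truth$r_end[k])
      if (oq >= min_overlap && or >= min_overlap) {
        hit <- TRUE
        matched_truth[k] <- TRUE
      }
    }
    if (hit) tp <- tp + 1L else fp <- fp + 1L
  }
  fn <- sum(!matched_truth)
  structure(
    list(TP = tp, FP = fp, FN = fn,
         precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
         precision_defined = tp + fp > 0L,
         recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_),
    class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  if (!is.null(x$per_batch)) {
    cat(sprintf("<eval_metrics> %d batches: precision %.4f (+/- %.4f), recall %.4f (+/- %.4f)\n",
                length(x$per_batch), x$mean[["precision"]], x$sd[["precision"]],
                x$mean[["recall"]], x$sd[["recall"]]))
  } else {
    cat(sprintf("<eval_metrics> TP=%d FP=%d FN=%d, precision=%s, recall=%s\n",
                x$TP, x$FP, x$FN, format(x$precision), format(x$recall)))
  }
  invisible(x)
}

#' Convert protocol records to evaluation intervals
#'
#' @param records Record data frame from [qpr_align()].
#' @return Data frame with `q_start`, `q_end`, `r_start`, `r_end`.
#' @export
records_to_intervals <- function(records) {
  data.frame(q_start = records$y0, q_end = records$y1,
             r_start = records$x0, r_end = records$x1)
}
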