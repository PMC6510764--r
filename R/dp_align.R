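#' @name dp_align
#' @title Dynamic-programming refinement of anchor records
#'
#' @description
#' Classic global (Needleman-Wunsch), local (Smith-Waterman) and banded
#' alignment, used to refine the anchor records the window protocol emits
#' into gapped alignments. Linear gap costs by default; affine
#' (open/extend) costs via Gotoh's three-state recursion. Traceback ties
#' are broken deterministically: diagonal, then up (gap in the second
#' sequence), then left.
NULL

#' Scoring scheme
#'
#' @param match Match score (> mismatch).
#' @param mismatch Mismatch score.
#' @param gap Linear per-gap-character penalty (negative); ignored when
#'   affine costs are given.
#' @param gap_open,gap_extend Optional affine costs: a gap of length g costs
#'   `gap_open + g * gap_extend` (both non-positive, `gap_extend` < 0).
#' @return List of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap = -2,
                           gap_open = NULL, gap_extend = NULL) {
  if (match <= mismatch) stop_domain("match score must exceed mismatch score")
  affine <- !is.null(gap_open) || !is.null(gap_extend)
  if (affine) {
    gap_open <- gap_open %||% 0
    if (is.null(gap_extend) || gap_extend >= 0)
      stop_domain("gap_extend must be negative for affine costs")
    if (gap_open > 0) stop_domain("gap_open must be non-positive")
  } else if (gap >= 0) stop_domain("gap penalty must be negative")
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 gap_open = gap_open, gap_extend = gap_extend,
                 affine = affine),
            class = "scoring_scheme")
}

seq_chars <- function(x, what) {
  x <- as_qpr_seq(x, what)
  strsplit(x$residues, "", fixed = TRUE)[[1L]]
}

new_alignment <- function(aq, ar, score, q0, q1, r0, r1, type) {
  structure(list(aligned_query = aq, aligned_reference = ar, score = score,
                 q_start = q0, q_end = q1, r_start = r0, r_end = r1,
                 type = type),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  a <- strsplit(x$aligned_query, "")[[1L]]
  b <- strsplit(x$aligned_reference, "")[[1L]]
  bar <- ifelse(a == b & a != "-", "|", " ")
  cat(sprintf("# %s alignment, score %g\n", x$type, x$score))
  cat(sprintf("# query [%d, %d)  reference [%d, %d)\n",
              x$q_start, x$q_end, x$r_start, x$r_end))
  for (o in seq.int(1L, max(1L, length(a)), by = 60L)) {
    e <- min(o + 59L, length(a))
    if (e < o) break
    cat("query  ", paste(a[o:e], collapse = ""), "\n")
    cat("       ", paste(bar[o:e], collapse = ""), "\n")
    cat("ref    ", paste(b[o:e], collapse = ""), "\n\n")
  }
  invisible(x)
}

#' CIGAR string of an alignment (query as the read, SAM conventions)
#'
#' @param aln An `alignment_result`.
#' @return Character CIGAR (M/I/D operations).
#' @export
alignment_cigar <- function(aln) {
  a <- strsplit(aln$aligned_query, "")[[1L]]
  b <- strsplit(aln$aligned_reference, "")[[1L]]
  if (length(a) == 0L) return("")
  op <- ifelse(a == "-", "D", ifelse(b == "-", "I", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

#' Recompute an alignment's score from its traceback
#'
#' @param aln An `alignment_result`.
#' @param scheme The [scoring_scheme] used.
#' @return Numeric score (equals `aln$score` for a consistent DP).
#' @export
score_alignment <- function(aln, scheme) {
  a <- strsplit(aln$aligned_query, "")[[1L]]
  b <- strsplit(aln$aligned_reference, "")[[1L]]
  if (length(a) == 0L) return(0)
  gap <- a == "-" | b == "-"
  sub <- sum(ifelse(a[!gap] == b[!gap], scheme$match, scheme$mismatch))
  if (!scheme$affine) return(sub + scheme$gap * sum(gap))
  r <- rle(ifelse(a == "-", "D", ifelse(b == "-", "I", "M")))
  gl <- r$lengths[r$values != "M"]
  sub + length(gl) * scheme$gap_open + sum(gl) * scheme$gap_extend
}

# Shared DP engine. type: "global" or "local". Returns alignment_result.
dp_engine <- function(a, b, scheme, type) {
  A <- seq_chars(a, "a"); B <- seq_chars(b, "b")
  la <- length(A); lb <- length(B)
  NEG <- -1e18
  if (!scheme$affine) {
    go <- 0; ge <- scheme$gap
  } else {
    go <- scheme$gap_open; ge <- scheme$gap_extend
  }
  local <- type == "local"
  H <- matrix(0, la + 1L, lb + 1L)       # best score ending (i, j)
  X <- matrix(NEG, la + 1L, lb + 1L)     # gap in b (consume a) state
  Y <- matrix(NEG, la + 1L, lb + 1L)     # gap in a (consume b) state
  if (!local) {
    for (i in seqesc(1L, la)) { X[i + 1L, 1L] <- go + ge * i; H[i + 1L, 1L] <- X[i + 1L, 1L] }
    for (j in seqesc(1L, lb)) { Y[1L, j + 1L] <- go + ge * j; H[1L, j + 1L] <- Y[1L, j + 1L] }
  }
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seqesc(1L, la)) {
    for (j in seqesc(1L, lb)) {
      s <- if (A[i] == B[j]) scheme$match else scheme$mismatch
      X[i + 1L, j + 1L] <- max(H[i, j + 1L] + go + ge, X[i, j + 1L] + ge)
      Y[i + 1L, j + 1L] <- max(H[i + 1L, j] + go + ge, Y[i + 1L, j] + ge)
      h <- max(H[i, j] + s, X[i + 1L, j + 1L], Y[i + 1L, j + 1L])
      if (local && h < 0) h <- 0
      H[i + 1L, j + 1L] <- h
      if (local && h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  tol <- 1e-9
  if (local) {
    i <- bi; j <- bj
    score <- best
  } else {
    i <- la; j <- lb
    score <- H[la + 1L, lb + 1L]
  }
  aq <- character(0); ar <- character(0)
  state <- "H"
  ei <- i; ej <- j
  while (TRUE) {
    if (local && H[i + 1L, j + 1L] <= tol && state == "H") break
    if (!local && i == 0L && j == 0L) break
    if (state == "H") {
      h <- H[i + 1L, j + 1L]
      if (i > 0L && j > 0L) {
        s <- if (A[i] == B[j]) scheme$match else scheme$mismatch
        if (abs(h - (H[i, j] + s)) < tol) {           # diagonal first
          aq <- c(A[i], aq); ar <- c(B[j], ar); i <- i - 1L; j <- j - 1L
          next
        }
      }
      if (i > 0L && abs(h - X[i + 1L, j + 1L]) < tol) { state <- "X"; next }
      if (j > 0L && abs(h - Y[i + 1L, j + 1L]) < tol) { state <- "Y"; next }
      stop("traceback failed")                         # nocov
    } else if (state == "X") {
      x <- X[i + 1L, j + 1L]
      aq <- c(A[i], aq); ar <- c("-", ar)
      if (abs(x - (H[i, j + 1L] + go + ge)) < tol) state <- "H"
      i <- i - 1L
    } else {
      y <- Y[i + 1L, j + 1L]
      aq <- c("-", aq); ar <- c(B[j], ar)
      if (abs(y - (H[i + 1L, j] + go + ge)) < tol) state <- "H"
      j <- j - 1L
    }
  }
  q0 <- i; r0 <- j
  if (local && best <= tol) { q0 <- 0L; r0 <- 0L; ei <- 0L; ej <- 0L; score <- 0 }
  new_alignment(paste(aq, collapse = ""), paste(ar, collapse = ""),
                score, q0, ei, r0, ej, type)
}

#' Global (Needleman-Wunsch) alignment
#'
#' @param a,b Sequences ([qpr_seq] or strings); `a` is the query.
#' @param scheme A [scoring_scheme].
#' @return An `alignment_result` with the optimal global score.
#' @export
nw_align <- function(a, b, scheme = scoring_scheme()) dp_engine(a, b, scheme, "global")

#' Local (Smith-Waterman) alignment
#'
#' @inheritParams nw_align
#' @return An `alignment_result`; score >= 0, empty alignment at score 0.
#' @export
sw_align <- function(a, b, scheme = scoring_scheme()) dp_engine(a, b, scheme, "local")

#' Banded global alignment along a record's diagonal
#'
#' Restricts the DP to cells with |(j - i) - offset| <= band around the
#' record's diagonal offset (reference start minus query start). Linear gap
#' costs only.
#'
#' @param a,b Sequences; `a` is the query.
#' @param record Optional one-row record (from [qpr_align()]) providing the
#'   diagonal offset `x0 - y0`; alternatively give `offset` directly.
#' @param band Band half-width (>= 0).
#' @param scheme A [scoring_scheme] (linear).
#' @param offset Diagonal offset if no record is given.
#' @return An `alignment_result`; its score never exceeds the unbanded
#'   global score.
#' @export
banded_align <- function(a, b, record = NULL, band = 0L,
                         scheme = scoring_scheme(), offset = NULL) {
  if (scheme$affine) stop_domain("banded alignment supports linear gap costs only")
  offset <- offset %||% if (!is.null(record)) record$x0 - record$y0 else 0L
  A <- seq_chars(a, "a"); B <- seq_chars(b, "b")
  la <- length(A); lb <- length(B)
  if (abs(0L - offset) > band || abs((lb - la) - offset) > band)
    stop_domain("band excludes the start or end corner of the DP matrix")
  NEG <- -1e18
  H <- matrix(NEG, la + 1L, lb + 1L)
  H[1L, 1L] <- 0
  inband <- function(i, j) abs((j - i) - offset) <= band
  for (j in seqesc(1L, lb)) if (inband(0L, j)) H[1L, j + 1L] <- scheme$gap * j
  for (i in seqesc(1L, la)) {
    if (inband(i, 0L)) H[i + 1L, 1L] <- scheme$gap * i
    for (j in seqesc(max(1L, i + offset - band), min(lb, i + offset + band))) {
      s <- if (A[i] == B[j]) scheme$match else scheme$mismatch
      h <- H[i, j] + s
      if (H[i, j + 1L] > NEG) h <- max(h, H[i, j + 1L] + scheme$gap)
      if (H[i + 1L, j] > NEG) h <- max(h, H[i + 1L, j] + scheme$gap)
      H[i + 1L, j + 1L] <- h
    }
  }
  # traceback (diagonal, up, left)
  i <- la; j <- lb
  aq <- character(0); ar <- character(0)
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    h <- H[i + 1L, j + 1L]
    if (i > 0L && j > 0L) {
      s <- if (A[i] == B[j]) scheme$match else scheme$mismatch
      if (H[i, j] > NEG && abs(h - (H[i, j] + s)) < tol) {
        aq <- c(A[i], aq); ar <- c(B[j], ar); i <- i - 1L; j <- j - 1L
        next
      }
    }
    if (i > 0L && H[i, j + 1L] > NEG && abs(h - (H[i, j + 1L] + scheme$gap)) < tol) {
      aq <- c(A[i], aq); ar <- c("-", ar); i <- i - 1L
      next
    }
    aq <- c("-", aq); ar <- c(B[j], ar); j <- j - 1L
  }
  new_alignment(paste(aq, collapse = ""), paste(ar, collapse = ""),
                H[la + 1L, lb + 1L], 0L, la, 0L, lb, "banded")
}
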