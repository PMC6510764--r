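# Shared fixtures and independent oracles, built in code at test time.

random_window <- function(N, M, rho, seed, id = 0L) {
  withr::with_seed(seed, {
    cells <- matrix(rbinom(N * M, 1L, rho), nrow = M, ncol = N)
    if (sum(cells) == 0L) cells[1L, 1L] <- 1L
    qpr_window(cells, id = id)
  })
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# Rasterization equivalence of two angle indices at length L: identical cell
# offsets, or point-reflected offsets (Friedel mates are indistinguishable
# from power spectra).
raster_equivalent <- function(L, j1, j2, M) {
  off <- function(j) {
    o <- floor((seq_len(L) - 1L) * j / M + 0.5)
    as.integer(o - o[1L])
  }
  a <- off(j1); b <- off(j2)
  identical(a, b) || identical(a, as.integer(b[length(b)] - rev(b)))
}

# ---- exhaustive alignment oracle -------------------------------------------
# A global alignment with linear gap costs is equivalent to a monotone
# matching of positions: score = sum of substitution scores over matched
# pairs + gap * (la + lb - 2m). A local alignment is a nonempty matching
# scored with gaps inside its span only. Enumerating all monotone matchings
# is therefore an exhaustive, DP-free oracle.

enum_matchings <- local({
  cache <- new.env(parent = emptyenv())
  function(la, lb) {
    key <- paste(la, lb)
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- list(list(I = integer(), J = integer()))
    for (m in seq_len(min(la, lb))) {
      Is <- utils::combn(la, m, simplify = FALSE)
      Js <- utils::combn(lb, m, simplify = FALSE)
      for (I in Is) for (J in Js) out[[length(out) + 1L]] <- list(I = I, J = J)
    }
    cache[[key]] <- out
    out
  }
})

oracle_scores <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  la <- length(A); lb <- length(B)
  ms <- enum_matchings(la, lb)
  gscore <- -Inf; lscore <- 0
  for (mt in ms) {
    m <- length(mt$I)
    sub <- if (m == 0L) 0 else
      sum(ifelse(A[mt$I] == B[mt$J], scheme$match, scheme$mismatch))
    g <- sub + scheme$gap * (la + lb - 2L * m)
    if (g > gscore) gscore <- g
    if (m > 0L) {
      span_gaps <- (mt$I[m] - mt$I[1L]) + (mt$J[m] - mt$J[1L]) - 2L * (m - 1L)
      l <- sub + scheme$gap * span_gaps
      if (l > lscore) lscore <- l
    }
  }
  list(global = gscore, local = lscore)
}

# exact discrete Fourier probability oracle for a set of surviving indices
dft_spectrum_oracle <- function(z, S) {
  k <- 0:(S - 1)
  p <- vapply(k, function(kk)
    Mod(sum(exp(2i * pi * z * kk / S)))^2, 0) / (S * length(z))
  p
}
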