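#' Sequence container
#'
#' A minimal sequence record: an identifier plus an uppercase residue string
#' over some alphabet (DNA, alpha = 4; protein, alpha = 20). All coordinates
#' in the package are 0-based.
#'
#' @param id Record identifier (single string).
#' @param residues Residue string; stored uppercased.
#' @return An object of class `qpr_seq` with fields `id`, `residues`,
#'   `length`.
#' @export
qpr_seq <- function(id, residues) {
  if (!is.character(id) || length(id) != 1L || is.na(id))
    stop_domain("sequence id must be a single string")
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop_domain("residues must be a single string")
  structure(
    list(id = id, residues = toupper(residues), length = nchar(residues)),
    class = "qpr_seq"
  )
}

#' @export
print.qpr_seq <- function(x, ...) {
  head <- substr(x$residues, 1L, 60L)
  if (x$length > 60L) head <- paste0(head, "...")
  cat(sprintf("<qpr_seq> %s (%d residues)\n%s\n", x$id, x$length, head))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()]; residues are uppercased
#' and record order is preserved.
#'
#' @param path Path to a (possibly multi-record, line-wrapped) FASTA file.
#' @return List of [qpr_seq] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_domain("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_domain("FASTA format error in '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L)
    stop_domain("FASTA format error in '", path, "': no records")
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) qpr_seq(ids[[i]], as.character(set[[i]])))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A [qpr_seq] or list of them.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "qpr_seq")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

as_qpr_seq <- function(x, id = "seq") {
  if (inherits(x, "qpr_seq")) return(x)
  if (is.character(x) && length(x) == 1L) return(qpr_seq(id, x))
  stop_domain("expected a qpr_seq or a single string")
}

# word-start k-mer strings of a residue string
kmer_strings <- function(s, word) {
  n <- nchar(s)
  if (word > n) return(character())
  substring(s, 1:(n - word + 1L), word:n)
}

#' Build a binary dot matrix from two sequences
#'
#' Cell (x, y) is set iff the `word`-length substrings starting at reference
#' position x (0-based, horizontal axis) and query position y (vertical axis)
#' are identical. The matrix is stored sparsely as coordinate vectors; for
#' `word > 1` it has (L_Q - word + 1) rows by (L_R - word + 1) columns
#' (word-start positions), reducing to the full L_Q x L_R shape at word = 1.
#'
#' @param query,reference [qpr_seq] objects (or plain strings).
#' @param word Word length of the match criterion (default 1). Larger words
#'   suppress the background noise that a small alphabet produces.
#' @return An object of class `dot_matrix` with fields `x`, `y` (0-based
#'   integer coordinate vectors), `nx`, `ny` (columns, rows), `word`,
#'   `n_dots` and density `rho`.
#' @export
build_dot_matrix <- function(query, reference, word = 1L) {
  query <- as_qpr_seq(query, "query")
  reference <- as_qpr_seq(reference, "reference")
  if (query$length == 0L || reference$length == 0L)
    stop_domain("sequences must be non-empty")
  word <- as.integer(word)
  if (word < 1L || word > min(query$length, reference$length))
    stop_domain("word must be in [1, min(L_Q, L_R)]")
  kq <- kmer_strings(query$residues, word)
  kr <- kmer_strings(reference$residues, word)
  ref_pos <- split(seq_along(kr) - 1L, kr)
  hits <- ref_pos[kq]            # absent k-mers yield NULL entries
  cnt <- lengths(hits)
  x <- as.integer(unlist(hits, use.names = FALSE))
  y <- rep.int(seq_along(kq) - 1L, cnt)
  nx <- length(kr)
  ny <- length(kq)
  structure(
    list(x = x, y = y, nx = nx, ny = ny, word = word,
         n_dots = length(x), rho = length(x) / (as.double(nx) * ny)),
    class = "dot_matrix"
  )
}

#' @export
print.dot_matrix <- function(x, ...) {
  cat(sprintf("<dot_matrix> %d rows (query) x %d cols (reference), word %d, %d dots, rho = %.4g\n",
              x$ny, x$nx, x$word, x$n_dots, x$rho))
  invisible(x)
}

#' Densify a dot matrix
#'
#' @param x A `dot_matrix`.
#' @param ... Unused.
#' @return Integer 0/1 matrix with `ny` rows (query y) and `nx` columns
#'   (reference x).
#' @export
as.matrix.dot_matrix <- function(x, ...) {
  m <- matrix(0L, nrow = x$ny, ncol = x$nx)
  if (x$n_dots > 0L) m[cbind(x$y + 1L, x$x + 1L)] <- 1L
  m
}

#' Window space over a dot matrix
#'
#' Constructs the unit the quantum routine operates on: an N-column by M-row
#' binary array of reflective (1) and absorptive (0) cells, N and M powers of
#' two, carrying its global origin on the dot-matrix plane. The linear cell
#' index is z = x + N*y with x the 0-based column and y the 0-based row.
#'
#' @param cells Binary matrix, M rows (y) by N columns (x).
#' @param origin Global (X0, Y0) of the window's (0,0) cell.
#' @param id Integer window id.
#' @return Object of class `qpr_window` with fields `id`, `N`, `M`, `n`, `m`,
#'   `S`, `origin`, `cells`, `rho`.
#' @export
qpr_window <- function(cells, origin = c(0L, 0L), id = 0L) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  N <- ncol(cells); M <- nrow(cells)
  if (!is_pow2(N) || !is_pow2(M))
    stop_domain("window dimensions must be powers of 2 (got ", N, " x ", M, ")")
  if (any(cells != 0L & cells != 1L)) stop_domain("window cells must be binary")
  ones <- sum(cells)
  structure(
    list(id = as.integer(id), N = N, M = M, n = log2i(N), m = log2i(M),
         S = N * M, origin = as.integer(origin), cells = cells,
         rho = ones / (N * M)),
    class = "qpr_window"
  )
}

#' @export
print.qpr_window <- function(x, ...) {
  cat(sprintf("<qpr_window> id %d: %d cols x %d rows at origin (%d, %d), rho = %.4g\n",
              x$id, x$N, x$M, x$origin[1], x$origin[2], x$rho))
  invisible(x)
}

# Linear cell indices (z = x + N*y, 0-based) of the reflective cells.
window_z <- function(win) {
  idx <- which(win$cells == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(integer())
  sort((idx[, 2L] - 1L) + win$N * (idx[, 1L] - 1L))
}

# Transposed window: array orientation rotated by pi/2, (N M -> M N).
transpose_window <- function(win) {
  qpr_window(t(win$cells), origin = win$origin[c(2L, 1L)], id = win$id)
}

# Rectangular sub-window (localize descends through these); nx/ny powers of 2.
sub_window <- function(win, x0, y0, nx, ny) {
  cells <- win$cells[(y0 + 1L):(y0 + ny), (x0 + 1L):(x0 + nx), drop = FALSE]
  qpr_window(cells, origin = win$origin + c(x0, y0), id = win$id)
}

#' Extract one dense window from a sparse dot matrix
#'
#' @param dot A `dot_matrix`.
#' @param X0,Y0 Global 0-based origin of the window.
#' @param L_W Window edge (power of 2). Cells beyond the matrix bounds are
#'   zero-padded (absorptive).
#' @param id Window id.
#' @return A [qpr_window].
#' @export
extract_window <- function(dot, X0, Y0, L_W, id = 0L) {
  if (!is_pow2(L_W)) stop_domain("L_W must be a power of 2")
  sel <- dot$x >= X0 & dot$x < X0 + L_W & dot$y >= Y0 & dot$y < Y0 + L_W
  cells <- matrix(0L, nrow = L_W, ncol = L_W)
  if (any(sel)) cells[cbind(dot$y[sel] - Y0 + 1L, dot$x[sel] - X0 + 1L)] <- 1L
  qpr_window(cells, origin = c(X0, Y0), id = id)
}

#' Fragment a dot matrix into window spaces
#'
#' Tiles the (zero-padded) matrix with stride `L_W - overlap`; each window
#' records its global origin and local density. Windows are returned in
#' row-major order (x fastest).
#'
#' @param dot A `dot_matrix`.
#' @param L_W Window edge; must be a power of 2.
#' @param overlap Cells of overlap between adjacent windows (< L_W).
#' @return List of [qpr_window] objects.
#' @export
make_windows <- function(dot, L_W, overlap = 0L) {
  if (!is_pow2(L_W)) stop_domain("L_W must be a power of 2")
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= L_W) stop_domain("overlap must be in [0, L_W)")
  stride <- L_W - overlap
  ox <- seq.int(0L, max(0L, dot$nx - 1L), by = stride)
  oy <- seq.int(0L, max(0L, dot$ny - 1L), by = stride)
  grid <- expand.grid(X0 = ox, Y0 = oy, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    extract_window(dot, grid$X0[i], grid$Y0[i], L_W, id = i)
  })
}

#' Export / import the sparse coordinate format
#'
#' MTX-style plain-text coordinate format: a comment header, one line with
#' `ncols nrows nnz word`, then one 0-based `x y` pair per line.
#'
#' @param dot A `dot_matrix`.
#' @param path File path.
#' @export
write_dot_matrix <- function(dot, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("%%qpralign dot-matrix coordinate 0-based", con)
  writeLines(sprintf("%d %d %d %d", dot$nx, dot$ny, dot$n_dots, dot$word), con)
  if (dot$n_dots > 0L)
    writeLines(sprintf("%d %d", dot$x, dot$y), con)
  invisible(path)
}

#' @rdname write_dot_matrix
#' @export
read_dot_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%")]
  hdr <- as.integer(strsplit(lines[1L], "\\s+")[[1L]])
  if (length(hdr) < 4L || anyNA(hdr)) stop_domain("malformed dot-matrix file header")
  coords <- if (hdr[3L] > 0L) {
    m <- do.call(rbind, lapply(strsplit(lines[-1L], "\\s+"), as.integer))
    list(x = m[, 1L], y = m[, 2L])
  } else list(x = integer(), y = integer())
  structure(
    list(x = coords$x, y = coords$y, nx = hdr[1L], ny = hdr[2L], word = hdr[4L],
         n_dots = length(coords$x),
         rho = length(coords$x) / (as.double(hdr[1L]) * hdr[2L])),
    class = "dot_matrix"
  )
}

#' Export / import a window in sparse coordinate format
#'
#' @param win A [qpr_window].
#' @param path File path.
#' @export
write_window <- function(win, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("%%qpralign window coordinate 0-based", con)
  z <- window_z(win)
  writeLines(sprintf("%d %d %d %d %d %d", win$N, win$M, length(z),
                     win$id, win$origin[1], win$origin[2]), con)
  if (length(z) > 0L)
    writeLines(sprintf("%d %d", z %% win$N, z %/% win$N), con)
  invisible(path)
}

#' @rdname write_window
#' @export
read_window <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%")]
  hdr <- as.integer(strsplit(lines[1L], "\\s+")[[1L]])
  if (length(hdr) < 6L || anyNA(hdr)) stop_domain("malformed window file header")
  cells <- matrix(0L, nrow = hdr[2L], ncol = hdr[1L])
  if (hdr[3L] > 0L) {
    m <- do.call(rbind, lapply(strsplit(lines[-1L], "\\s+"), as.integer))
    cells[cbind(m[, 2L] + 1L, m[, 1L] + 1L)] <- 1L
  }
  qpr_window(cells, origin = hdr[5:6], id = hdr[4L])
}
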