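# Internal helpers shared across modules.

# Half-up rounding. base::round() rounds half to even, which would make the
# line-rasterization and peak-indexing conventions platform-looking but
# irreproducible across the two code paths; every [.]_integer bracket in the
# package goes through this.
rnd <- function(x) floor(x + 0.5)

is_pow2 <- function(x) {
  x <- as.numeric(x)
  x >= 1 && abs(x - rnd(x)) < .Machine$double.eps * 4 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

log2i <- function(x) as.integer(rnd(log2(x)))

# Derive a reproducible per-stream seed from a top-level seed and a stream id
# (e.g. a window id), kept below 2^31.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + as.double(stream) * 1299721 + 12345) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
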