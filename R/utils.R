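## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dietbiome <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_dietbiome(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper)
    stop_dietbiome(sprintf("`%s` must be in [%s, %s], got %s",
                           name, format(lower), format(upper), format(x)))
  invisible(x)
}

## 32-bit FNV-1a hash of a character scalar, returned in [0, 2^31 - 2].
## Used to derive per-operation permutation substreams and config hashes;
## kept dependency-free and stable across platforms.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    ## XOR with a byte only touches the low 8 bits; keep h a double since it
    ## exceeds R's integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    ## 32-bit modular multiply by the FNV prime 16777619, done in pieces to
    ## stay within double precision
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  h %% 2147483647
}

## Derive a reproducible substream seed for a named operation so that adding
## one analysis to a run does not shift the permutation stream of another.
substream_seed <- function(seed, op) {
  assert_scalar_number(seed, "seed")
  as.integer((as.double(seed) * 48271 + fnv1a32(op)) %% 2147483647)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the
## caller's RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Short stable hash of an R object (used to stamp output tables with the
## configuration they came from).
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames", "showAttributes")),
             collapse = "\n")
  sprintf("%08x", fnv1a32(s))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
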