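#' @keywords internal
"_PACKAGE"

## Deterministic seed derivation from a small set of integer keys.
## All products stay far below 2^53 so the arithmetic is exact in doubles;
## the result is always a valid 32-bit seed.
derive_seed <- function(...) {
  keys <- as.numeric(c(...))
  h <- 0
  for (k in keys) {
    h <- (h * 31 + (abs(k) %% 2147483629)) %% 2147483629
  }
  as.integer(h %% 2147483647L)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG stream afterwards.
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

## FNV-1a style hash of an arbitrary R object, used to stamp run outputs.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

clamp01 <- function(x) {
  y <- pmin(1, pmax(0, x))
  attributes(y) <- attributes(x)  # pmin/pmax may drop dim
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
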