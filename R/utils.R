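#' @keywords internal
"_PACKAGE"

#' @useDynLib gaitscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile predict coef
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## FNV-1a 32-bit hash over raw bytes; used for config fingerprints and for
## deriving named RNG substreams from a single base seed.
fnv1a <- function(bytes) {
  h <- 2166136261
  for (b in as.integer(bytes)) {
    ## xor against the low byte only (h may exceed the 32-bit signed range)
    lowb <- h %% 256
    h <- h - lowb + bitwXor(as.integer(lowb), b)
    ## 32-bit modular multiply by 16777619 done in two 16-bit halves
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h
}

hash_obj <- function(x) {
  h <- fnv1a(serialize(x, NULL, version = 2))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Deterministic substream seed in [0, 2^31-2] from a base seed and a name
## (plus optional integer counters). Keeps all derived seeds 32-bit safe.
derive_seed <- function(seed, name, ...) {
  key <- paste(c(name, as.character(list(...))), collapse = "/")
  h <- fnv1a(c(as.integer(charToRaw(key)),
               as.integer(seed %% 256), as.integer((seed %/% 256) %% 256),
               as.integer((seed %/% 65536) %% 256)))
  as.integer(h %% 2147483647)
}

## Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

## parameter-tree helpers: parameters, gradients and optimiser moments are
## nested named lists with numeric leaves
tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

tree_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x)); names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(x[[i]], y[[i]], f)
    out
  } else f(x, y)
}

tree_zeros <- function(x) tree_map(x, function(a) a * 0)

tree_add <- function(x, y) tree_map2(x, y, `+`)
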