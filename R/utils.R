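# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a global seed; keeps independent
# stages decoupled while remaining reproducible. Result stays inside the
# 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 2039L + (sum(utf8ToInt(stream)) %% 1009L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("`%s` must lie in [0, 1]", name)
}

# Gene-wise z-scoring of a genes x samples matrix; errors on constant genes.
standardize_genes <- function(expr) {
  sds <- apply(expr, 1L, sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    stopf("cannot standardize constant gene(s): %s",
          paste(rownames(expr)[bad], collapse = ", "))
  (expr - rowMeans(expr)) / sds
}
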