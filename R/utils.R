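# Internal helpers shared across modules.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round-half-up: group sizes from fractions are floor(x + 0.5), never banker's.
roundHalfUp <- function(x) floor(x + 0.5)

# Row variances (denominator n - 1) of a numeric matrix.
rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Coerce an ExpressionMatrix or a plain named matrix to the underlying matrix.
asExprMatrix <- function(x) {
  if (is(x, "ExpressionMatrix")) x@values
  else if (is.matrix(x)) x
  else stop("expected an ExpressionMatrix or a matrix")
}
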