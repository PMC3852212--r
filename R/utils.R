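#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministically derive a child seed from a base seed and integer tags,
# staying inside the 32-bit signed range set.seed() accepts.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed) %% 2147483647
  for (t in tags) {
    x <- (x * 69069 + as.double(t) * 9973 + 1) %% 2147483647
  }
  as.integer(x)
}

stop_arg <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Per-feature standardisation of a patients x features matrix.  `center`
# subtracts the feature mean; scaling always divides by the feature sd
# (constant features are left on their original scale rather than 0/0).
scale_features <- function(x, center = TRUE) {
  s <- apply(x, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  if (center) {
    x <- sweep(x, 2, colMeans(x), "-")
  }
  sweep(x, 2, s, "/")
}
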