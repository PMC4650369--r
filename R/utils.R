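# internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards. A `NULL` seed evaluates the
#' code under the current RNG stream.
#' @param seed integer seed or `NULL`
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic per-replicate sub-seed below 2^31, never 0
subseed <- function(seed, i, offset = 0L) {
  s <- (as.double(seed) %% 2147483647) + 104729 * as.double(i) +
    7919 * as.double(offset)
  s <- s %% 2147483647
  as.integer(if (s < 1) s + 1 else s)
}

# stratified fold assignment; uses the current RNG stream
make_folds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# percentage truncated (not rounded) to one decimal, as printed in clinical biomarker
# reports: 4/88 -> 4.5, 224/3828 -> 5.8
pct_trunc <- function(num, den) {
  stopifnot(den > 0)
  floor(num / den * 1000) / 10
}

# standardized mean difference between two groups of a numeric covariate
smd <- function(x, is_case) {
  m1 <- mean(x[is_case]); m0 <- mean(x[!is_case])
  s <- sqrt((stats::var(x[is_case]) + stats::var(x[!is_case])) / 2)
  if (s == 0) return(0)
  (m1 - m0) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bootstrap resample of an index vector, safe for length-1 input
# (sample(x, replace = TRUE) would expand a scalar x to 1:x)
resample <- function(idx) idx[sample.int(length(idx), replace = TRUE)]
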