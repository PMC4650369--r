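# fixture builders shared across test files; everything is generated in code

# random expression matrix with ids, optionally with a detection matrix
fx_expression <- function(p = 20, n = 10, seed = 1, detected = NULL) {
  set.seed(seed)
  vals <- matrix(rnorm(p * n, 8, 1.5), p, n,
                 dimnames = list(sprintf("miR-%03d", seq_len(p)),
                                 sprintf("S%02d", seq_len(n))))
  expression_matrix(vals, detected)
}

# features x samples matrix with the first `k` rows mean-shifted in cases
fx_spiked <- function(p = 50, n_case = 13, n_control = 26, k = 5,
                      delta = 1.5, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("f%02d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  lab <- rep(c("case", "control"), c(n_case, n_control))
  if (k > 0) X[seq_len(k), lab == "case"] <-
    X[seq_len(k), lab == "case"] + delta
  list(X = X, labels = lab)
}

# hand-constructed bootstrap_ranking object (bypasses the selectors)
fx_ranking <- function(occ, cooc = NULL, B = max(occ)) {
  ids <- names(occ)
  if (is.null(cooc)) {
    cooc <- matrix(0L, length(ids), length(ids),
                   dimnames = list(ids, ids))
  }
  out <- structure(list(B = B, occ = occ, cooc = cooc, n_redrawn = 0L,
                        per_replicate_masks = NULL),
                   class = "bootstrap_ranking")
  out$rank_order <- rank_features(out)
  out
}

# independent R implementation of the tie-adjusted two-sample AD statistic,
# written directly from the midrank formula (oracle for the C++ version)
oracle_ad_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  z <- sort(unique(c(x, y)))
  A <- 0
  for (j in seq_along(z)) {
    lj <- sum(x == z[j]) + sum(y == z[j])
    Baj <- sum(c(x, y) < z[j]) + lj / 2
    M1 <- sum(x < z[j]) + sum(x == z[j]) / 2
    M2 <- sum(y < z[j]) + sum(y == z[j]) / 2
    den <- Baj * (N - Baj) - N * lj / 4
    if (den > 0)
      A <- A + (lj / N) * ((N * M1 - n1 * Baj)^2 / n1 +
                             (N * M2 - n2 * Baj)^2 / n2) / den
  }
  A * (N - 1) / N
}

# brute-force BH step-up: q_i = min over all j with p_(j) ranked >= i
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) min(1, p[o[j]] * m / j))
    q[o[i]] <- min(cand)
  }
  q
}
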