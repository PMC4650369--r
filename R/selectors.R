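# Three conceptually different feature-selection algorithms behind one
# contract: X is a features x samples block, labels are per-sample
# case/control, the result is a selector_result with a selected id set,
# per-feature scores and the tuning record.

selector_result <- function(selected, scores, tuning) {
  structure(list(selected = selected, scores = scores, tuning = tuning),
            class = "selector_result")
}

#' @export
print.selector_result <- function(x, ...) {
  cat("selector_result:", length(x$selected), "of", length(x$scores),
      "features selected\n")
  invisible(x)
}

as_pm1 <- function(labels) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("case", "control")))
  ifelse(labels == "case", 1, -1)
}

#' The SCAD penalty and its derivative
#'
#' Smoothly clipped absolute deviation: linear (`lambda * |w|`) up to
#' `lambda`, a quadratic blend on `(lambda, a*lambda]`, constant
#' `(a + 1) * lambda^2 / 2` beyond — nearly unbiased for large weights,
#' sparsity-inducing near zero.
#'
#' @param w numeric weights (any sign)
#' @param lambda penalty level (>= 0)
#' @param a shape parameter (> 2; default 3.7)
#' @return penalty values, same length as `w`
#' @export
scad_penalty <- function(w, lambda, a = 3.7) {
  stopifnot(lambda >= 0, a > 2)
  t <- abs(w)
  out <- numeric(length(t))
  r1 <- t <= lambda
  r2 <- t > lambda & t <= a * lambda
  r3 <- t > a * lambda
  out[r1] <- lambda * t[r1]
  out[r2] <- (2 * a * lambda * t[r2] - t[r2]^2 - lambda^2) / (2 * (a - 1))
  out[r3] <- (a + 1) * lambda^2 / 2
  out
}

#' @rdname scad_penalty
#' @export
scad_penalty_deriv <- function(w, lambda, a = 3.7) {
  stopifnot(lambda >= 0, a > 2)
  t <- abs(w)
  ifelse(t <= lambda, lambda, pmax(a * lambda - t, 0) / (a - 1))
}

# ---------------------------------------------------------------------------
# Nearest shrunken centroids (PAM)

nsc_stats <- function(vals, y) {
  n <- ncol(vals)
  cls <- c("case", "control")
  nk <- c(sum(y == "case"), sum(y == "control"))
  cent <- cbind(rowMeans(vals[, y == "case", drop = FALSE]),
                rowMeans(vals[, y == "control", drop = FALSE]))
  overall <- rowMeans(vals)
  # pooled within-class SD, df = n - K
  ss <- rowSums((vals[, y == "case", drop = FALSE] - cent[, 1])^2) +
    rowSums((vals[, y == "control", drop = FALSE] - cent[, 2])^2)
  s <- sqrt(ss / (n - 2))
  s0 <- stats::median(s)
  mk <- sqrt(1 / nk - 1 / n)
  d <- sweep(cent - overall, 2, mk, "/") / (s + s0)
  list(cent = cent, overall = overall, s = s, s0 = s0, mk = mk, d = d,
       prior = nk / n, classes = cls)
}

nsc_shrink <- function(st, delta) {
  sign(st$d) * pmax(abs(st$d) - delta, 0)
}

nsc_predict <- function(st, dshr, newx) {
  shrunk <- st$overall + sweep((st$s + st$s0) * dshr, 2, st$mk, "*")
  disc <- vapply(1:2, function(k) {
    colSums((newx - shrunk[, k])^2 / (st$s + st$s0)^2) - 2 * log(st$prior[k])
  }, numeric(ncol(newx)))
  st$classes[max.col(-matrix(disc, ncol = 2), ties.method = "first")]
}

#' Nearest-shrunken-centroid (PAM) feature selection
#'
#' Standardized class-centroid differences are soft-thresholded at Delta;
#' Delta is chosen from a grid by stratified cross-validated
#' misclassification, ties resolved toward the larger Delta (fewer
#' features). Selected features keep a nonzero shrunken difference for at
#' least one class at the chosen Delta.
#'
#' @param X features x samples numeric matrix (rownames = feature ids)
#' @param labels per-sample "case"/"control"
#' @param delta_grid thresholds to try (default: `n_delta` values spanning 0
#'   to the largest standardized difference)
#' @param cv_folds stratified CV folds (default 5)
#' @param seed RNG seed for fold assignment (`NULL`: current stream)
#' @param n_delta grid size when `delta_grid` is `NULL` (default 30)
#' @return a `selector_result`; scores are the absolute standardized
#'   centroid differences (case column), tuning records the chosen Delta and
#'   the CV error path
#' @export
nsc_select <- function(X, labels, delta_grid = NULL, cv_folds = 5,
                       seed = NULL, n_delta = 30) {
  X <- values_of(X)
  y <- as.character(labels)
  stopifnot(all(y %in% c("case", "control")),
            sum(y == "case") >= 2, sum(y == "control") >= 2)
  st_full <- nsc_stats(X, y)
  dmax <- max(abs(st_full$d))
  if (is.null(delta_grid))
    delta_grid <- seq(0, dmax, length.out = n_delta)
  if (length(delta_grid) == 0) stop("empty delta grid")

  with_seed(seed, {
    fold <- make_folds(y, cv_folds)
    err <- numeric(length(delta_grid))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      st <- nsc_stats(X[, tr, drop = FALSE], y[tr])
      for (g in seq_along(delta_grid)) {
        pred <- nsc_predict(st, nsc_shrink(st, delta_grid[g]),
                            X[, !tr, drop = FALSE])
        err[g] <- err[g] + sum(pred != y[!tr])
      }
    }
    # ties -> larger Delta (sparser)
    best <- max(which(err == min(err)))
    dshr <- nsc_shrink(st_full, delta_grid[best])
    sel <- rownames(X)[rowSums(abs(dshr)) > 0]
    selector_result(
      selected = sel,
      scores = stats::setNames(abs(st_full$d[, 1]), rownames(X)),
      tuning = list(delta = delta_grid[best], cv_errors = err,
                    delta_grid = delta_grid))
  })
}

# ---------------------------------------------------------------------------
# Boruta with random forests

#' Boruta all-relevant feature selection with random forests
#'
#' Each iteration augments the data with shuffled "shadow" copies of every
#' feature, fits a random forest, and scores a hit when a feature's OOB
#' permutation importance exceeds the best shadow importance. Two-sided
#' binomial tests at a Bonferroni-corrected level mark features Confirmed or
#' Rejected; the loop stops when all are decided or `max_iter` is reached.
#' Features still Tentative at the end count as not selected.
#'
#' @param X features x samples numeric matrix
#' @param labels per-sample "case"/"control"
#' @param max_iter maximum Boruta iterations (>= 10)
#' @param ntree random-forest trees per iteration (default 500)
#' @param alpha test level before Bonferroni correction (default 0.05)
#' @param seed RNG seed (`NULL`: current stream)
#' @return a `selector_result`; scores are hit fractions, tuning records the
#'   iteration count and the Confirmed/Rejected/Tentative partition
#' @export
boruta_rf_select <- function(X, labels, max_iter = 50, ntree = 500,
                             alpha = 0.05, seed = NULL) {
  if (max_iter < 10)
    stop("max_iter must be >= 10 (binomial decisions are underpowered)")
  X <- values_of(X)
  y <- as.integer(as_pm1(labels) > 0)
  p <- nrow(X)
  ids <- rownames(X) %||% paste0("f", seq_len(p))
  Xn <- t(X)
  thr <- alpha / p  # Bonferroni over the input features

  with_seed(seed, {
    hits <- integer(p)
    status <- rep("Tentative", p)
    iter <- 0L
    while (iter < max_iter && any(status == "Tentative")) {
      iter <- iter + 1L
      # Rejected features (and their shadows) leave the design, the usual
      # Boruta refinement that concentrates the forest on what remains
      active <- which(status != "Rejected")
      Xa <- Xn[, active, drop = FALSE]
      shadow <- apply(Xa, 2, sample)
      aug <- cbind(Xa, shadow)
      imp <- rf_importance_cpp(aug, y, ntree = ntree)$importance
      na <- length(active)
      smax <- max(imp[(na + 1):(2 * na)])
      hits[active] <- hits[active] + as.integer(imp[seq_len(na)] > smax)
      und <- status == "Tentative"
      p_hi <- stats::pbinom(hits[und] - 1L, iter, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[und], iter, 0.5)
      status[und][p_hi < thr] <- "Confirmed"
      status[und][p_lo < thr] <- "Rejected"
    }
    selector_result(
      selected = ids[status == "Confirmed"],
      scores = stats::setNames(hits / iter, ids),
      tuning = list(iterations = iter, ntree = ntree,
                    status = stats::setNames(status, ids)))
  })
}

# ---------------------------------------------------------------------------
# Elastic SCAD SVM

#' Elastic SCAD SVM feature selection
#'
#' Linear SVM with hinge loss and penalty `SCAD(lambda1) + lambda2 ||w||^2`;
#' the ridge term keeps groups of correlated features together while the
#' SCAD term prunes irrelevant ones. Fitted by successive quadratic
#' surrogates of the SCAD term (each surrogate an exactly-solved
#' weighted-ridge hinge SVM); `(lambda1, lambda2)` chosen by stratified CV
#' misclassification, ties resolved toward the sparser penalty (larger
#' lambda1, then larger lambda2). Features are standardized internally;
#' selection is reported on the original ids.
#'
#' @param X features x samples numeric matrix
#' @param labels per-sample "case"/"control"
#' @param lambda1_grid SCAD levels (default 5 log-spaced in 2^-8..2^0)
#' @param lambda2_grid ridge levels (default 6 log-spaced in 2^-8..2^2)
#' @param cv_folds stratified CV folds (default 5)
#' @param seed RNG seed for fold assignment
#' @param max_outer surrogate iterations per fit (default 200)
#' @return a `selector_result`; scores are absolute SVM weights from the
#'   full-block refit, tuning records the chosen penalties and convergence
#' @export
elastic_scad_svm_select <- function(X, labels,
                                    lambda1_grid = 2^seq(-8, 0, by = 2),
                                    lambda2_grid = 2^seq(-8, 2, by = 2),
                                    cv_folds = 5, seed = NULL,
                                    max_outer = 200) {
  X <- values_of(X)
  yv <- as_pm1(labels)
  stopifnot(sum(yv > 0) >= 2, sum(yv < 0) >= 2,
            length(lambda1_grid) > 0, length(lambda2_grid) > 0)
  ids <- rownames(X) %||% paste0("f", seq_len(nrow(X)))
  # standardize on the training block; constant features stay at zero
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- t((X - mu) / sdv)  # samples x features

  grid <- expand.grid(l1 = lambda1_grid, l2 = lambda2_grid)
  with_seed(seed, {
    fold <- make_folds(yv, cv_folds)
    err <- numeric(nrow(grid))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(yv[tr])) < 2) next
      for (g in seq_len(nrow(grid))) {
        fit <- scad_svm_cpp(Xs[tr, , drop = FALSE], yv[tr],
                            grid$l1[g], grid$l2[g], max_outer = max_outer)
        pred <- sign(Xs[!tr, , drop = FALSE] %*% fit$w + fit$b)
        err[g] <- err[g] + sum(pred != yv[!tr])
      }
    }
    # ties -> sparser: larger lambda1, then larger lambda2
    cand <- which(err == min(err))
    cand <- cand[order(-grid$l1[cand], -grid$l2[cand])]
    best <- cand[1]
    fit <- scad_svm_cpp(Xs, yv, grid$l1[best], grid$l2[best],
                        max_outer = max_outer)
    w <- stats::setNames(as.numeric(fit$w), ids)
    selector_result(
      selected = ids[abs(w) > 1e-8],
      scores = abs(w),
      tuning = list(lambda1 = grid$l1[best], lambda2 = grid$l2[best],
                    converged = fit$converged, cv_errors = err))
  })
}
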