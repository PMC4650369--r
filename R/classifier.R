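#' Youden index
#'
#' `J = sensitivity + specificity - 1`; 0 at chance, 1 for a perfect
#' classifier.
#'
#' @param sens,spec values in \[0, 1\]
#' @return the Youden index in \[-1, 1\]
#' @export
youden <- function(sens, spec) {
  if (any(sens < 0 | sens > 1) || any(spec < 0 | spec > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  sens + spec - 1
}

sens_spec <- function(pred, truth) {
  tp <- sum(pred == "case" & truth == "case")
  fn <- sum(pred == "control" & truth == "case")
  tn <- sum(pred == "control" & truth == "control")
  fp <- sum(pred == "case" & truth == "control")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  c(sens = sens, spec = spec)
}

#' Leave-one-out cross-validated SVM performance
#'
#' Each sample is predicted by a linear SVM with fixed `(cost, weights)`
#' fitted on the other n - 1 samples; sensitivity counts cases (hemolyzed)
#' as the positive class. Deterministic: nothing is tuned per fold.
#'
#' @param X features x samples matrix (the top-k block)
#' @param labels per-sample "case"/"control"
#' @param cost,weights SVM parameters (see [fit_linear_svm()])
#' @return named numeric: `sens`, `spec`, `youden`
#' @export
loocv_performance <- function(X, labels, cost = 1, weights = c(0.5, 0.5)) {
  X <- values_of(X)
  labels <- as.character(labels)
  n <- ncol(X)
  if (n < 3) stop("need at least 3 samples for LOOCV")
  if (min(table(factor(labels, levels = c("case", "control")))) < 2)
    stop("LOOCV needs both classes with >= 2 samples so every fold retains both")
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- fit_linear_svm(X[, -i, drop = FALSE], labels[-i], cost, weights)
    pred[i] <- predict(fit, X[, i, drop = FALSE])
  }
  ss <- sens_spec(pred, labels)
  c(sens = unname(ss["sens"]), spec = unname(ss["spec"]),
    youden = unname(youden(ss["sens"], ss["spec"])))
}

#' Build the forward-inclusion model family
#'
#' One candidate model per `(k, cost, weights)` combination, using the top-k
#' features of the bootstrap ranking, each scored by LOOCV. `k` values
#' beyond the available ranking are truncated (with a warning).
#'
#' @param X features x samples matrix covering the ranked features
#' @param labels per-sample "case"/"control"
#' @param rank_order ranked feature ids (best first)
#' @param k_grid numbers of top features to include (default `1:min(50, length(rank_order))`)
#' @param cost_grid SVM costs (default `c(0.01, 0.1, 1, 10, 100)`)
#' @param weight_grid list of `(w_case, w_control)` pairs (default the four
#'   pairs 0.5:0.5 through 0.2:0.8)
#' @return a `model_family` data frame: `k`, `cost`, `w_case`, `w_control`,
#'   `sens`, `spec`, `youden`
#' @export
build_model_family <- function(X, labels, rank_order,
                               k_grid = NULL,
                               cost_grid = c(0.01, 0.1, 1, 10, 100),
                               weight_grid = list(c(0.5, 0.5), c(0.4, 0.6),
                                                  c(0.3, 0.7), c(0.2, 0.8))) {
  X <- values_of(X)
  stopifnot(length(rank_order) > 0, length(cost_grid) > 0,
            length(weight_grid) > 0)
  if (is.null(k_grid)) k_grid <- seq_len(min(50L, length(rank_order)))
  if (any(k_grid > length(rank_order))) {
    warning("k values beyond the ", length(rank_order),
            " ranked features were truncated")
    k_grid <- pmin(k_grid, length(rank_order))
  }
  k_grid <- sort(unique(k_grid))
  rows <- list()
  for (k in k_grid) {
    Xk <- X[rank_order[seq_len(k)], , drop = FALSE]
    for (cost in cost_grid) for (w in weight_grid) {
      perf <- loocv_performance(Xk, labels, cost, w)
      rows[[length(rows) + 1L]] <-
        data.frame(k = k, cost = cost, w_case = w[1], w_control = w[2],
                   sens = perf["sens"], spec = perf["spec"],
                   youden = perf["youden"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("model_family", class(out))
  out
}

#' Group models by their exact position in ROC space
#'
#' Models sharing an identical (FPR, TPR) pair form one group; groups are
#' ranked by descending Youden index (group 1 = best), ties by descending
#' specificity then sensitivity. Performances are rational numbers with
#' denominator n, so exact grouping is well defined.
#'
#' @param records a `model_family`
#' @return the records with `fpr`, `tpr`, `group_id` and `group_size` added
#' @export
group_models_roc <- function(records) {
  records$fpr <- 1 - records$spec
  records$tpr <- records$sens
  key <- paste(round(records$fpr, 10), round(records$tpr, 10))
  uk <- unique(key)
  meta <- data.frame(key = uk,
                     youden = records$youden[match(uk, key)],
                     spec = records$spec[match(uk, key)],
                     sens = records$sens[match(uk, key)])
  meta <- meta[order(-meta$youden, -meta$spec, -meta$sens), ]
  meta$group_id <- seq_len(nrow(meta))
  records$group_id <- meta$group_id[match(key, meta$key)]
  records$group_size <- as.integer(table(records$group_id)[
    as.character(records$group_id)])
  records
}

#' Choose the parsimonious model within a ROC group
#'
#' Smallest number of features wins; remaining ties go to the smallest cost,
#' then to the most balanced class weights.
#'
#' @param records output of [group_models_roc()]
#' @param group_id which group
#' @return the single chosen record (one-row data frame)
#' @export
choose_parsimonious <- function(records, group_id) {
  g <- records[records$group_id == group_id, , drop = FALSE]
  if (nrow(g) == 0) stop("empty group: ", group_id)
  g <- g[order(g$k, g$cost, abs(g$w_case - 0.5)), , drop = FALSE]
  g[1, , drop = FALSE]
}

#' Evaluate a chosen model on the validation set
#'
#' The model (its top-k features, cost and weights) is refitted on the full
#' training set and applied to the validation samples; 95 % percentile
#' confidence intervals come from stratified bootstrap resampling of the
#' validation set.
#'
#' @param record one-row model record (needs `k`, `cost`, `w_case`,
#'   `w_control`)
#' @param X_train,labels_train full training block and labels
#' @param X_val,labels_val validation block and labels
#' @param rank_order ranked feature ids used for the forward inclusion
#' @param B_ci bootstrap resamples (default 1000)
#' @param seed RNG seed for the bootstrap
#' @return the record with `val_sens`, `val_spec`, `val_youden` and the six
#'   CI bounds added
#' @export
evaluate_validation <- function(record, X_train, labels_train,
                                X_val, labels_val, rank_order,
                                B_ci = 1000, seed = NULL) {
  X_train <- values_of(X_train); X_val <- values_of(X_val)
  labels_val <- as.character(labels_val)
  if (length(unique(labels_val)) < 2)
    stop("validation set must contain both classes")
  feats <- rank_order[seq_len(record$k)]
  fit <- fit_linear_svm(X_train[feats, , drop = FALSE], labels_train,
                        record$cost, c(record$w_case, record$w_control))
  pred <- predict(fit, X_val[feats, , drop = FALSE])
  ss <- sens_spec(pred, labels_val)
  ci <- with_seed(seed, {
    icase <- which(labels_val == "case")
    ictrl <- which(labels_val == "control")
    stat <- matrix(NA_real_, B_ci, 3)
    for (b in seq_len(B_ci)) {
      idx <- c(resample(icase), resample(ictrl))
      sb <- sens_spec(pred[idx], labels_val[idx])
      stat[b, ] <- c(sb, youden(sb["sens"], sb["spec"]))
    }
    apply(stat, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  })
  record$val_sens <- unname(ss["sens"])
  record$val_spec <- unname(ss["spec"])
  record$val_youden <- unname(youden(ss["sens"], ss["spec"]))
  record$val_sens_lo <- ci[1, 1]; record$val_sens_hi <- ci[2, 1]
  record$val_spec_lo <- ci[1, 2]; record$val_spec_hi <- ci[2, 2]
  record$val_youden_lo <- ci[1, 3]; record$val_youden_hi <- ci[2, 3]
  record
}
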