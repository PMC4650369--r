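# linear SVM used by the classifier stage: hinge loss, cost and class
# weights. With equal class weights (0.5, 0.5) the per-sample cost reduces
# to the plain SVM cost; weights (w_case, w_control) summing to 1 scale the
# per-class costs as 2 * cost * w_class.

#' Fit a weighted linear SVM
#'
#' @param X features x samples numeric matrix
#' @param labels per-sample "case"/"control"
#' @param cost SVM cost parameter
#' @param weights length-2 numeric `(w_case, w_control)` summing to 1
#' @return list of class `linear_svm`: `w` (named weights), `b`,
#'   `features`, `cost`, `weights`
#' @export
fit_linear_svm <- function(X, labels, cost = 1, weights = c(0.5, 0.5)) {
  stopifnot(cost > 0, length(weights) == 2, all(weights > 0),
            abs(sum(weights) - 1) < 1e-8)
  X <- values_of(X)
  yv <- as_pm1(labels)
  if (sum(yv > 0) < 1 || sum(yv < 0) < 1)
    stop("both classes must be present")
  Ci <- ifelse(yv > 0, 2 * cost * weights[1], 2 * cost * weights[2])
  fit <- svm_dcd_cpp(t(X), yv, Ci)
  structure(list(w = stats::setNames(as.numeric(fit$w), rownames(X)),
                 b = fit$b, features = rownames(X),
                 cost = cost, weights = weights),
            class = "linear_svm")
}

#' Predict case/control labels from a linear SVM
#'
#' @param object a `linear_svm`
#' @param newdata features x samples matrix covering the model's features
#' @param ... unused
#' @return character vector of "case"/"control"; the decision values are
#'   attached as attribute `decision`
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- values_of(newdata)
  if (!is.null(object$features) && !is.null(rownames(newdata)))
    newdata <- newdata[object$features, , drop = FALSE]
  dec <- as.numeric(crossprod(newdata, object$w) + object$b)
  out <- ifelse(dec > 0, "case", "control")
  attr(out, "decision") <- dec
  out
}
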