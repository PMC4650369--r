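#' Filter features by detection fraction
#'
#' Keeps a feature when it is detected in at least `min_frac` of the
#' reference samples (boundary is `>=`; the workflow default is 90 %). The
#' reference set defaults to the training samples when a split is available
#' to the caller; passing all samples reproduces the looser Methods wording.
#'
#' @param x an [expression_matrix()]
#' @param min_frac minimum detection proportion in (0, 1]
#' @param reference_ids sample ids over which detection is counted
#'   (default: all samples in `x`)
#' @return the filtered `expression_matrix`; per-feature detection fractions
#'   are attached as attribute `detection_fraction`
#' @export
filter_by_detection <- function(x, min_frac = 0.90, reference_ids = NULL) {
  stopifnot(inherits(x, "expression_matrix"),
            min_frac > 0, min_frac <= 1)
  if (is.null(reference_ids)) reference_ids <- sample_ids(x)
  if (length(reference_ids) == 0) stop("empty reference sample set")
  bad <- setdiff(reference_ids, sample_ids(x))
  if (length(bad)) stop("unknown reference sample id(s): ",
                        paste(bad, collapse = ", "))
  frac <- rowMeans(x$detected[, reference_ids, drop = FALSE])
  keep <- frac >= min_frac
  out <- expression_matrix(x$values[keep, , drop = FALSE],
                           x$detected[keep, , drop = FALSE])
  attr(out, "detection_fraction") <- frac
  out
}

#' Build all pairwise log-ratio features
#'
#' Ratio-based normalization: every feature serves in turn as normalizer,
#' each unordered pair appearing exactly once, so n features yield
#' n(n-1)/2 ratios. On the log2 scale the ratio is a difference:
#' `value(A/B) = log2(A) - log2(B)`, with the numerator the feature that
#' comes first in the input feature order.
#'
#' @param x an [expression_matrix()] on the log2 scale with >= 2 features
#' @return an object of class `ratio_matrix`: list with `values`
#'   (ratios x samples, rownames "A/B"), `numerator_ids`, `denominator_ids`,
#'   `parent_features`
#' @export
make_ratio_features <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale_tag != "log2") stop("ratio features require log2-scale input")
  n <- nrow(x$values)
  if (n < 2) stop("need at least 2 features to form ratios")
  ids <- feature_ids(x)
  pr <- utils::combn(n, 2L)
  num <- pr[1L, ]
  den <- pr[2L, ]
  vals <- x$values[num, , drop = FALSE] - x$values[den, , drop = FALSE]
  rownames(vals) <- paste(ids[num], ids[den], sep = "/")
  structure(list(values = vals,
                 numerator_ids = ids[num],
                 denominator_ids = ids[den],
                 parent_features = ids),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat("ratio_matrix:", nrow(x$values), "log2 ratios over",
      length(x$parent_features), "features x", ncol(x$values), "samples\n")
  invisible(x)
}

#' @export
dim.ratio_matrix <- function(x) dim(x$values)

# uniform access to the numeric block of any pipeline carrier
values_of <- function(x) {
  if (inherits(x, c("expression_matrix", "ratio_matrix"))) x$values
  else as.matrix(x)
}

#' Distinct parent features underlying a set of ratio ids
#'
#' @param ratio_ids character vector of "A/B" ratio ids
#' @return character vector of the distinct constituent feature ids
#' @export
ratio_constituents <- function(ratio_ids) {
  unique(unlist(strsplit(ratio_ids, "/", fixed = TRUE)))
}
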