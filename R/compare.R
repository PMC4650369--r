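#' Two-sample t-test with the case-up sign convention
#'
#' Classical pooled-variance two-sample t-test (Welch available by flag).
#' Positive statistics mean higher values in `x` (the cases). Two identical
#' constant groups give statistic 0, p 1.
#'
#' @param x case values, `y` control values (>= 2 each)
#' @param y control values
#' @param variant `"pooled"` (default) or `"welch"`
#' @return list: `statistic`, `p.value`, `df`
#' @export
t_test <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 values per group")
  r <- row_t(matrix(x, 1), matrix(y, 1), variant)
  list(statistic = r$stat[1], p.value = r$p[1], df = r$df[1])
}

# vectorized per-row two-sample t over matrices (cases | controls)
row_t <- function(xc, xk, variant = "pooled") {
  n1 <- ncol(xc); n2 <- ncol(xk)
  m1 <- rowMeans(xc); m2 <- rowMeans(xk)
  v1 <- rowSums((xc - m1)^2) / (n1 - 1)
  v2 <- rowSums((xk - m2)^2) / (n2 - 1)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- (m1 - m2) / se
  # zero variance in both groups: equal means -> (0, 1); else +-Inf, p = 0
  const <- se == 0
  stat[const & m1 == m2] <- 0
  p <- 2 * stats::pt(-abs(stat), df)
  p[const & m1 == m2] <- 1
  p[const & m1 != m2] <- 0
  list(stat = stat, p = p, df = df)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, monotone in p, capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted values in the input order
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Class comparison by the t-test / Anderson-Darling union rule
#'
#' Runs both tests on every feature, adjusts each p-value family separately
#' by Benjamini-Hochberg, and calls a feature significant when either
#' adjusted p-value falls below `alpha` (the union rule). Each feature is
#' also placed in a concordance quadrant (`both`, `t_only`, `ad_only`,
#' `neither`). Features constant across all samples get p = 1 in both tests
#' so that feature indexing stays stable.
#'
#' @param x an [expression_matrix()], [make_ratio_features()] result, or
#'   plain numeric matrix (features x samples)
#' @param labels per-sample labels; values "case"/"control" (other labels
#'   are dropped with their columns)
#' @param alpha FDR level for each family (default 0.05)
#' @param t_variant `"pooled"` or `"welch"`
#' @return a `comparison_result` data frame with one row per feature:
#'   `feature_id`, `fc_log2`, `t_stat`, `t_p`, `t_q`, `ad_stat`, `ad_p`,
#'   `ad_q`, `significant`, `quadrant`
#' @export
compare_classes <- function(x, labels, alpha = 0.05,
                            t_variant = c("pooled", "welch")) {
  t_variant <- match.arg(t_variant)
  vals <- values_of(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(vals))
  keep <- labels %in% c("case", "control")
  vals <- vals[, keep, drop = FALSE]
  labels <- labels[keep]
  n1 <- sum(labels == "case"); n2 <- sum(labels == "control")
  if (n1 < 2 || n2 < 2)
    stop("each class needs at least 2 samples (got ", n1, " cases, ",
         n2, " controls)")
  xc <- vals[, labels == "case", drop = FALSE]
  xk <- vals[, labels == "control", drop = FALSE]

  tt <- row_t(xc, xk, t_variant)
  m <- nrow(vals)
  ad_stat <- numeric(m); ad_p <- numeric(m)
  const <- apply(vals, 1, function(v) length(unique(v)) == 1L)
  for (i in seq_len(m)) {
    if (const[i]) { ad_stat[i] <- 0; ad_p[i] <- 1; next }
    r <- ad_test(xc[i, ], xk[i, ])
    ad_stat[i] <- r$statistic; ad_p[i] <- r$p.value
  }
  t_p <- tt$p
  t_p[const] <- 1
  t_stat <- tt$stat
  t_stat[const] <- 0

  t_q <- bh_adjust(t_p)
  ad_q <- bh_adjust(ad_p)
  sig_t <- t_q < alpha
  sig_ad <- ad_q < alpha
  quadrant <- ifelse(sig_t & sig_ad, "both",
                     ifelse(sig_t, "t_only",
                            ifelse(sig_ad, "ad_only", "neither")))
  out <- data.frame(feature_id = rownames(vals),
                    fc_log2 = rowMeans(xc) - rowMeans(xk),
                    t_stat = t_stat, t_p = t_p, t_q = t_q,
                    ad_stat = ad_stat, ad_p = ad_p, ad_q = ad_q,
                    significant = sig_t | sig_ad,
                    quadrant = quadrant,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "n_case") <- n1
  attr(out, "n_control") <- n2
  attr(out, "t_variant") <- t_variant
  class(out) <- c("comparison_result", class(out))
  out
}

#' Volcano-plot data table
#' @param cr a `comparison_result`
#' @return data frame: feature_id, fc_log2, neg_log10_t_q, significant
#' @export
volcano_table <- function(cr) {
  data.frame(feature_id = cr$feature_id, fc_log2 = cr$fc_log2,
             neg_log10_t_q = -log10(pmax(cr$t_q, 1e-300)),
             significant = cr$significant, stringsAsFactors = FALSE)
}

#' Concordance-plot data table (t vs AD adjusted significance)
#' @param cr a `comparison_result`
#' @return data frame: feature_id, neg_log10_t_q, neg_log10_ad_q, quadrant
#' @export
concordance_table <- function(cr) {
  data.frame(feature_id = cr$feature_id,
             neg_log10_t_q = -log10(pmax(cr$t_q, 1e-300)),
             neg_log10_ad_q = -log10(pmax(cr$ad_q, 1e-300)),
             quadrant = cr$quadrant, stringsAsFactors = FALSE)
}

#' Summary counts and percentages for a class comparison
#'
#' The reporting layer: significant counts with percentages truncated to one
#' decimal (a common reporting convention, under which 4/88 prints as 4.5 %
#' and 224/3828 as 5.8 %), and t-significant up/down counts.
#'
#' @param cr a `comparison_result`
#' @return list: `n_features`, `n_significant`, `pct_significant`,
#'   `n_t_up`, `n_t_down`, `n_t_total`, `quadrants` (named counts)
#' @export
summarize_comparison <- function(cr) {
  stopifnot(inherits(cr, "comparison_result"))
  alpha <- attr(cr, "alpha")
  sig_t <- cr$t_q < alpha
  list(n_features = nrow(cr),
       n_significant = sum(cr$significant),
       pct_significant = pct_trunc(sum(cr$significant), nrow(cr)),
       n_t_up = sum(sig_t & cr$fc_log2 > 0),
       n_t_down = sum(sig_t & cr$fc_log2 < 0),
       n_t_total = sum(sig_t & cr$fc_log2 != 0),
       quadrants = table(factor(cr$quadrant,
                                levels = c("both", "t_only", "ad_only",
                                           "neither"))))
}
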