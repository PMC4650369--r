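#' Fit the propensity-score model
#'
#' Logistic regression of case membership on the matching covariates
#' (disease status, age at drawing, drawing year). The propensity score (PS)
#' is the fitted probability of being a case given those covariates.
#'
#' @param samples a labelled sample table (see [label_samples()]) restricted
#'   to case/control rows, with columns `disease_status`, `age_at_drawing`,
#'   `drawing_year`.
#' @return named numeric vector of propensities in (0,1), one per sample
#' @export
fit_propensity <- function(samples) {
  stopifnot(is.data.frame(samples))
  need <- c("sample_id", "label", "disease_status", "age_at_drawing",
            "drawing_year")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  samples <- samples[samples$label %in% c("case", "control"), , drop = FALSE]
  if (sum(samples$label == "case") < 1 || sum(samples$label == "control") < 1)
    stop("need at least one case and one control")
  for (v in c("disease_status", "age_at_drawing", "drawing_year"))
    if (anyNA(samples[[v]]))
      stop("missing values in covariate '", v, "'")
  y <- as.integer(samples$label == "case")
  dat <- data.frame(y = y,
                    disease_status = samples$disease_status,
                    age_at_drawing = samples$age_at_drawing,
                    drawing_year = samples$drawing_year)
  # drop constant covariates (intercept-only model remains valid)
  keep <- vapply(dat[-1], function(v) length(unique(v)) > 1, logical(1))
  form <- if (any(keep))
    stats::reformulate(names(dat[-1])[keep], response = "y") else y ~ 1
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  ps <- stats::fitted(fit)
  if (sep || any(ps <= 1e-8) || any(ps >= 1 - 1e-8))
    stop("complete separation in the propensity model: ",
         "caliper matching on the PS logit is degenerate")
  names(ps) <- samples$sample_id
  ps
}

#' Caliper width for propensity matching
#'
#' The recommended caliper: `mult` times the standard deviation (n-1
#' denominator) of the propensity-score logit, with `mult = 0.2` by default.
#'
#' @param ps propensities strictly inside (0,1)
#' @param mult caliper multiplier
#' @return caliper width on the logit scale
#' @export
caliper_width <- function(ps, mult = 0.2) {
  stopifnot(all(ps > 0), all(ps < 1))
  w <- mult * stats::sd(stats::qlogis(ps))
  if (!is.finite(w) || w <= 0)
    stop("constant propensity scores: caliper width is zero, no matching possible")
  w
}

#' Greedy 1:k nearest-neighbor caliper matching
#'
#' Matches each case to `ratio` controls with the closest propensity-score
#' logit, without replacement, accepting only controls within the caliper.
#' Cases are processed in descending order of logit-PS extremeness (distance
#' from the mean logit PS), ties broken by sample id, so the result is
#' reproducible and independent of input ordering. A case with fewer than
#' `ratio` in-caliper controls is reported unmatched and consumes none.
#'
#' @param cases,controls character vectors of sample ids
#' @param ps named propensity vector covering all ids
#' @param caliper caliper width on the logit scale (> 0)
#' @param ratio controls per case (default 2)
#' @return an object of class `match_result`: list with `triplets` (data
#'   frame `case_id`, `control_1`, ..., `control_k`), `unmatched_cases`,
#'   `ps`, `caliper`.
#' @export
match_1to2 <- function(cases, controls, ps, caliper, ratio = 2L) {
  stopifnot(caliper > 0, ratio >= 1)
  if (!all(c(cases, controls) %in% names(ps)))
    stop("ps must be named and cover every case and control id")
  lp <- stats::qlogis(ps)
  center <- mean(lp[c(cases, controls)])
  ord <- order(-abs(lp[cases] - center), cases)
  cases <- cases[ord]
  avail <- controls
  rows <- vector("list", length(cases))
  unmatched <- character(0)
  for (i in seq_along(cases)) {
    cid <- cases[i]
    d <- abs(lp[avail] - lp[cid])
    ok <- which(d <= caliper)
    if (length(ok) < ratio) {
      unmatched <- c(unmatched, cid)
      next
    }
    pick <- avail[ok][order(d[ok], avail[ok])][seq_len(ratio)]
    rows[[i]] <- c(cid, pick)
    avail <- setdiff(avail, pick)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  trip <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (nrow(trip) > 0)
    names(trip) <- c("case_id", paste0("control_", seq_len(ratio)))
  else
    trip <- stats::setNames(
      as.data.frame(matrix(character(0), 0, ratio + 1)),
      c("case_id", paste0("control_", seq_len(ratio))))
  structure(list(triplets = trip, unmatched_cases = sort(unmatched),
                 ps = ps, caliper = caliper, ratio = as.integer(ratio)),
            class = "match_result")
}

#' Matched cohort sample ids
#' @param m a `match_result`
#' @return character vector of all matched ids (cases then controls)
#' @export
matched_ids <- function(m) {
  stopifnot(inherits(m, "match_result"))
  unlist(m$triplets, use.names = FALSE)
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result: ", nrow(x$triplets), " matched sets (1:", x$ratio,
      "), cohort size ", nrow(x$triplets) * (x$ratio + 1), "; ",
      length(x$unmatched_cases), " unmatched case(s); caliper ",
      signif(x$caliper, 4), "\n", sep = "")
  invisible(x)
}

#' Split the matched cohort in half into training and validation sets
#'
#' Whole matched sets (a case plus its controls) are randomized to the two
#' halves, so the 1:ratio class balance and the matched structure are both
#' preserved within each set. An odd number of sets puts the extra set in
#' training, with a warning.
#'
#' @param matched a `match_result`
#' @param seed integer seed; the assignment is deterministic given the seed
#' @return data frame: `sample_id`, `role` (case/control), `set_id` (matched
#'   set index), `split` ("training"/"validation")
#' @export
split_train_validation <- function(matched, seed) {
  stopifnot(inherits(matched, "match_result"))
  tn <- nrow(matched$triplets)
  if (tn < 2) stop("need at least two matched sets to split")
  n_train <- ceiling(tn / 2)
  if (tn %% 2 == 1)
    warning("odd number of matched sets (", tn,
            "): assigning the extra set to training")
  train_sets <- with_seed(seed, sample.int(tn, n_train))
  out <- do.call(rbind, lapply(seq_len(tn), function(i) {
    ids <- unlist(matched$triplets[i, ], use.names = FALSE)
    data.frame(sample_id = ids,
               role = c("case", rep("control", matched$ratio)),
               set_id = i,
               split = if (i %in% train_sets) "training" else "validation",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences (case vs control) of the matching
#' covariates, computed on the full pool and on the matched cohort — the
#' usual matching diagnostic table.
#'
#' @param samples labelled sample table with covariates
#' @param matched a `match_result`
#' @return data frame: covariate, smd_before, smd_after
#' @export
balance_table <- function(samples, matched) {
  covs <- c("disease_status", "age_at_drawing", "drawing_year")
  sub <- samples[samples$label %in% c("case", "control"), , drop = FALSE]
  ids <- matched_ids(matched)
  msub <- sub[sub$sample_id %in% ids, , drop = FALSE]
  one <- function(d, v) {
    x <- d[[v]]
    if (!is.numeric(x)) x <- as.numeric(as.factor(x))
    smd(x, d$label == "case")
  }
  data.frame(covariate = covs,
             smd_before = vapply(covs, function(v) one(sub, v), numeric(1)),
             smd_after = vapply(covs, function(v) one(msub, v), numeric(1)),
             row.names = NULL)
}
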