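# Bootstrap triple-algorithm intersection ranking: features are ranked by
# how often all three selection algorithms pick them simultaneously across
# stratified bootstrap replicates; pairwise joint selections feed the
# co-occurrence ("egg-shaped plot") network.

#' Stratified bootstrap replicates
#'
#' Each replicate draws `n_case` indices with replacement from the cases and
#' `n_control` from the controls, keeping the class proportion of every
#' replicate identical to the original. Replicate b is a pure function of
#' `(seed, b)`, so the list is deterministic and order-independent.
#'
#' @param labels per-sample "case"/"control"
#' @param B number of replicates (>= 1)
#' @param seed master seed
#' @return list of integer index vectors
#' @export
stratified_bootstrap <- function(labels, B, seed) {
  labels <- as.character(labels)
  icase <- which(labels == "case")
  ictrl <- which(labels == "control")
  if (length(icase) == 0 || length(ictrl) == 0)
    stop("both classes must be non-empty")
  stopifnot(B >= 1)
  lapply(seq_len(B), function(b)
    with_seed(subseed(seed, b), c(resample(icase), resample(ictrl))))
}

#' Control settings for the bootstrap selection driver
#'
#' The per-replicate selector configuration. The default is a reduced
#' "fast" profile (fewer trees, coarser SCAD grid, 3-fold CV) sized so that
#' a B = 1000 run on a training-set-scale block stays tractable on one CPU;
#' stand-alone selector calls keep their own richer defaults.
#'
#' @param nsc,boruta,scad named lists of arguments forwarded to the three
#'   selectors
#' @param max_fail_frac abort when more than this fraction of replicates
#'   fails even after redraws (default 0.1)
#' @return list of class `bootstrap_control`
#' @export
bootstrap_control <- function(nsc = list(cv_folds = 3, n_delta = 15),
                              boruta = list(max_iter = 25, ntree = 100),
                              scad = list(lambda1_grid = 2^c(-3, -2, -1),
                                          lambda2_grid = 2^c(-4, -2, 0),
                                          cv_folds = 3, max_outer = 30),
                              max_fail_frac = 0.1) {
  structure(list(nsc = nsc, boruta = boruta, scad = scad,
                 max_fail_frac = max_fail_frac),
            class = "bootstrap_control")
}

run_selectors_once <- function(X, labels, control, seed) {
  s1 <- do.call(nsc_select,
                c(list(X = X, labels = labels, seed = subseed(seed, 1)),
                  control$nsc))
  s2 <- do.call(boruta_rf_select,
                c(list(X = X, labels = labels, seed = subseed(seed, 2)),
                  control$boruta))
  s3 <- do.call(elastic_scad_svm_select,
                c(list(X = X, labels = labels, seed = subseed(seed, 3)),
                  control$scad))
  Reduce(intersect, list(s1$selected, s2$selected, s3$selected))
}

#' Run the bootstrap triple-selection
#'
#' For every stratified bootstrap replicate, all three selectors run on the
#' same resampled block; the replicate's joint mask is the intersection of
#' the three selected sets. Occurrence counts how often each feature lands
#' in the joint mask, co-occurrence how often each pair does. Replicates
#' where a selector errors are redrawn with a fresh sub-seed (count logged);
#' more than `max_fail_frac * B` failures abort with diagnostics.
#'
#' @param X features x samples carrier ([expression_matrix()],
#'   ratio matrix or plain matrix)
#' @param labels per-sample "case"/"control"
#' @param B bootstrap replicates (default workflow: 1000)
#' @param seed master seed
#' @param control a [bootstrap_control()]
#' @param keep_masks keep the per-replicate joint masks (features x B
#'   logical matrix)?
#' @return object of class `bootstrap_ranking`: list with `B`, `occ` (named
#'   integer), `cooc` (symmetric integer matrix), `rank_order`,
#'   `n_redrawn`, optionally `per_replicate_masks`
#' @export
run_bootstrap_selection <- function(X, labels, B = 1000, seed = 1,
                                    control = bootstrap_control(),
                                    keep_masks = FALSE) {
  vals <- values_of(X)
  ids <- rownames(vals) %||% paste0("f", seq_len(nrow(vals)))
  rownames(vals) <- ids
  labels <- as.character(labels)
  p <- length(ids)
  occ <- stats::setNames(integer(p), ids)
  cooc <- matrix(0L, p, p, dimnames = list(ids, ids))
  masks <- if (keep_masks) matrix(FALSE, p, B, dimnames = list(ids, NULL))
  n_redrawn <- 0L
  max_fail <- ceiling(control$max_fail_frac * B)

  for (b in seq_len(B)) {
    attempt <- 0L
    joint <- NULL
    repeat {
      sseed <- subseed(seed, b, offset = attempt * 7L)
      idx <- with_seed(sseed, {
        icase <- which(labels == "case"); ictrl <- which(labels == "control")
        c(resample(icase), resample(ictrl))
      })
      joint <- tryCatch(
        run_selectors_once(vals[, idx, drop = FALSE], labels[idx],
                           control, subseed(sseed, 99L)),
        error = function(e) e)
      if (!inherits(joint, "error")) break
      attempt <- attempt + 1L
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_fail)
        stop("more than ", max_fail, " failed bootstrap replicates; last: ",
             conditionMessage(joint))
    }
    if (length(joint)) {
      occ[joint] <- occ[joint] + 1L
      cooc[joint, joint] <- cooc[joint, joint] + 1L
      if (keep_masks) masks[joint, b] <- TRUE
    }
  }
  diag(cooc) <- 0L
  out <- structure(list(B = B, occ = occ, cooc = cooc,
                        n_redrawn = n_redrawn,
                        per_replicate_masks = masks),
                   class = "bootstrap_ranking")
  out$rank_order <- rank_features(out)
  out
}

#' @export
print.bootstrap_ranking <- function(x, ...) {
  cat("bootstrap_ranking: B =", x$B, ",", sum(x$occ > 0), "of",
      length(x$occ), "features selected at least once\n")
  if (length(x$rank_order))
    cat("top:", paste(utils::head(x$rank_order, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Rank features by bootstrap occurrence
#'
#' Descending occurrence; ties broken by descending total co-occurrence
#' with all other features, then lexicographic id. Features never selected
#' are dropped from the ranking.
#'
#' @param ranking a `bootstrap_ranking`
#' @return ordered character vector of feature ids
#' @export
rank_features <- function(ranking) {
  occ <- ranking$occ
  tot_cooc <- rowSums(ranking$cooc)
  keep <- names(occ)[occ > 0]
  keep[order(-occ[keep], -tot_cooc[keep], keep)]
}

#' Export the co-occurrence network (egg-shaped plot data)
#'
#' Nodes are features incident to at least one surviving edge, carrying
#' their occurrence count; edges carry co-occurrence counts and pairs below
#' `min_cooc` are removed (workflow default: 300 at B = 1000). Written as
#' GraphML when `path` is given.
#'
#' @param ranking a `bootstrap_ranking`
#' @param min_cooc minimum co-occurrence for an edge
#' @param path optional GraphML output path
#' @return an igraph graph (invisibly if written to file)
#' @export
export_cooccurrence_graph <- function(ranking, min_cooc = 300, path = NULL) {
  ad <- ranking$cooc
  ad[ad < min_cooc] <- 0L
  g <- igraph::graph_from_adjacency_matrix(ad, mode = "undirected",
                                           weighted = "cooc", diag = FALSE)
  igraph::V(g)$occ <- as.numeric(ranking$occ[igraph::V(g)$name])
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (!is.null(path)) {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(g))
  }
  g
}
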