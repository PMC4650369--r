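# readers/writers for pipeline result objects; every pair is a lossless
# round trip on ids and labels, numeric values to full double precision

#' Write a pipeline result object to TSV
#'
#' Column order is deterministic; [read_results()] reproduces the object.
#' A `bootstrap_ranking` writes two files: the ranking table at `path` and
#' the long-format co-occurrence table at `path` with a `_cooc.tsv` suffix.
#'
#' @param obj a `comparison_result`, `bootstrap_ranking` or `model_family`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_results <- function(obj, path) {
  wr <- function(d, p) utils::write.table(
    d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(obj, "comparison_result")) {
    d <- as.data.frame(obj)
    attr_line <- sprintf("# comparison_result alpha=%.17g n_case=%d n_control=%d t_variant=%s",
                         attr(obj, "alpha"), attr(obj, "n_case"),
                         attr(obj, "n_control"), attr(obj, "t_variant"))
    con <- file(path, "w")
    writeLines(attr_line, con)
    close(con)
    suppressWarnings(utils::write.table(d, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  } else if (inherits(obj, "bootstrap_ranking")) {
    rk <- data.frame(feature_id = names(obj$occ), occ = as.integer(obj$occ),
                     rank = match(names(obj$occ), obj$rank_order),
                     stringsAsFactors = FALSE)
    # file order follows the documented tie-break; never-selected last by id
    rk <- rk[order(rk$rank, rk$feature_id, na.last = TRUE), , drop = FALSE]
    con <- file(path, "w")
    writeLines(sprintf("# bootstrap_ranking B=%d n_redrawn=%d",
                       obj$B, obj$n_redrawn), con)
    close(con)
    suppressWarnings(utils::write.table(rk, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    ut <- which(upper.tri(obj$cooc) & obj$cooc > 0, arr.ind = TRUE)
    cc <- data.frame(feature_a = rownames(obj$cooc)[ut[, 1]],
                     feature_b = colnames(obj$cooc)[ut[, 2]],
                     cooc = obj$cooc[ut], stringsAsFactors = FALSE)
    wr(cc, cooc_path(path))
  } else if (inherits(obj, "model_family")) {
    wr(as.data.frame(obj), path)
  } else stop("unsupported result object of class ",
              paste(class(obj), collapse = "/"))
  invisible(path)
}

cooc_path <- function(path) sub("(\\.[^.]*)?$", "_cooc.tsv", path)

#' Read back a pipeline result object
#'
#' @param path path written by [write_results()]
#' @param what one of "comparison", "ranking", "models"
#' @return the reconstructed object
#' @export
read_results <- function(path, what = c("comparison", "ranking", "models")) {
  what <- match.arg(what)
  if (what == "comparison") {
    hdr <- readLines(path, n = 1)
    d <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
    m <- regmatches(hdr, regexec(
      "alpha=([0-9.eE+-]+) n_case=(\\d+) n_control=(\\d+) t_variant=(\\w+)",
      hdr))[[1]]
    attr(d, "alpha") <- as.numeric(m[2])
    attr(d, "n_case") <- as.integer(m[3])
    attr(d, "n_control") <- as.integer(m[4])
    attr(d, "t_variant") <- m[5]
    class(d) <- c("comparison_result", class(d))
    d
  } else if (what == "ranking") {
    hdr <- readLines(path, n = 1)
    m <- regmatches(hdr, regexec("B=(\\d+) n_redrawn=(\\d+)", hdr))[[1]]
    rk <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
    ids <- rk$feature_id
    occ <- stats::setNames(as.integer(rk$occ), ids)
    cooc <- matrix(0L, length(ids), length(ids),
                   dimnames = list(ids, ids))
    cp <- cooc_path(path)
    if (file.exists(cp)) {
      cc <- utils::read.delim(cp, stringsAsFactors = FALSE)
      if (nrow(cc)) {
        cooc[cbind(cc$feature_a, cc$feature_b)] <- as.integer(cc$cooc)
        cooc[cbind(cc$feature_b, cc$feature_a)] <- as.integer(cc$cooc)
      }
    }
    out <- structure(list(B = as.integer(m[2]), occ = occ, cooc = cooc,
                          n_redrawn = as.integer(m[3]),
                          per_replicate_masks = NULL),
                     class = "bootstrap_ranking")
    out$rank_order <- rank_features(out)
    out
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    class(d) <- c("model_family", class(d))
    d
  }
}
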