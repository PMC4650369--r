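#' Construct an expression matrix with detection flags
#'
#' The universal data carrier of the pipeline: a feature-by-sample matrix of
#' log2 intensities plus a parallel logical matrix of detection calls (as
#' exported by array feature-extraction software, where a probe is "detected"
#' when its signal clears the local noise estimate).
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry unique row and column names (feature and sample identifiers).
#' @param detected logical matrix of the same shape, or `NULL` to derive
#'   detection from finiteness of `values`.
#' @param scale_tag `"log2"` (the internal scale) or `"linear"`; linear input
#'   is log2-transformed once at construction and tagged, so the transform is
#'   never silently repeated.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values`, `detected`, `scale_tag`, `transformed` (TRUE if the input
#'   arrived on the linear scale).
#' @export
expression_matrix <- function(values, detected = NULL,
                              scale_tag = c("log2", "linear")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  # R normalizes zero-length rownames to NULL; empty filter results are legal
  fids <- if (nrow(values) == 0) character(0) else rownames(values)
  sids <- colnames(values)
  if (is.null(fids) || is.null(sids))
    stop("values must have feature row names and sample column names")
  if (anyDuplicated(fids))
    stop("duplicate feature ids: ",
         paste(unique(fids[duplicated(fids)]), collapse = ", "))
  if (anyDuplicated(sids))
    stop("duplicate sample ids: ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "))
  if (is.null(detected)) {
    detected <- is.finite(values)
  } else {
    detected <- as.matrix(detected)
    if (!all(dim(detected) == dim(values)))
      stop("detection matrix shape (", nrow(detected), "x", ncol(detected),
           ") does not match values (", nrow(values), "x", ncol(values), ")")
    storage.mode(detected) <- "logical"
  }
  dimnames(detected) <- dimnames(values)
  transformed <- FALSE
  if (scale_tag == "linear") {
    if (any(values[is.finite(values)] <= 0))
      stop("linear-scale values must be positive for log2 transform")
    values <- log2(values)
    scale_tag <- "log2"
    transformed <- TRUE
  }
  structure(list(values = values, detected = detected,
                 scale_tag = scale_tag, transformed = transformed),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "features x",
      ncol(x$values), "samples (", x$scale_tag, "scale,",
      sprintf("%.1f%%", 100 * mean(x$detected)), "detected )\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers
#' @param x an `expression_matrix` or `ratio_matrix`
#' @return character vector of ids
#' @export
feature_ids <- function(x) rownames(x$values) %||% character(0)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a wide TSV expression table
#'
#' First column feature ids, header row sample ids, tab-delimited. An
#' optional companion detection table (0/1 cells, identical layout) carries
#' the detection calls; without one, every finite value counts as detected.
#'
#' @param path expression TSV path
#' @param detection_path optional detection TSV path
#' @param scale `"log2"` (default) or `"linear"`; see [expression_matrix()]
#' @param dialect only `"wide-tsv"` is supported
#' @return an [expression_matrix()]
#' @export
read_expression <- function(path, detection_path = NULL,
                            scale = c("log2", "linear"),
                            dialect = "wide-tsv") {
  scale <- match.arg(scale)
  stopifnot(dialect == "wide-tsv")
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE)
  fids <- as.character(tab[[1]])
  if (anyDuplicated(fids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(fids[duplicated(fids)]), collapse = ", "))
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "NA")
      if (length(bad))
        stop("non-numeric cell at feature '", fids[bad[1]],
             "', sample '", names(vals)[j], "'")
      v <- vn
    }
    vals[[j]] <- v
  }
  values <- as.matrix(vals)
  rownames(values) <- fids
  detected <- NULL
  if (!is.null(detection_path)) {
    dt <- utils::read.delim(detection_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    dm <- as.matrix(dt[, -1, drop = FALSE])
    rownames(dm) <- as.character(dt[[1]])
    if (!all(dim(dm) == dim(values)))
      stop("detection table shape does not match expression table")
    detected <- dm != 0
  }
  expression_matrix(values, detected, scale_tag = scale)
}

#' Write an expression matrix (and optionally its detection flags) as TSV
#'
#' @param x an [expression_matrix()]
#' @param path output TSV for the values
#' @param detection_path optional output TSV for the 0/1 detection flags
#' @return `path`, invisibly
#' @export
write_expression <- function(x, path, detection_path = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(detection_path)) {
    dd <- data.frame(feature_id = rownames(x$values), x$detected * 1L,
                     check.names = FALSE)
    utils::write.table(dd, detection_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Label samples as case / control / excluded by hemolysis score
#'
#' Hemolyzed "cases" have hemolysis score (HS) strictly above `hs_high`
#' (roughly visible hemolysis), not-hemolyzed "controls" have HS at or below
#' `hs_low`, and samples in between are excluded from analysis. Boundary
#' semantics are exactly: control uses `<=`, case uses `>`.
#'
#' @param samples data frame with at least `sample_id` and `hs` columns
#' @param hs_low control threshold (default 0.057)
#' @param hs_high case threshold (default 0.14)
#' @return the data frame with a `label` factor column
#'   (case/control/excluded) and a `split` column initialized to
#'   "unassigned"; label counts are attached as attribute `counts`.
#' @export
label_samples <- function(samples, hs_low = 0.057, hs_high = 0.14) {
  stopifnot(is.data.frame(samples), all(c("sample_id", "hs") %in%
                                          names(samples)))
  if (hs_low >= hs_high) stop("hs_low must be < hs_high")
  miss <- is.na(samples$hs)
  if (any(miss))
    stop("missing hemolysis score for sample(s): ",
         paste(samples$sample_id[miss], collapse = ", "))
  lab <- ifelse(samples$hs > hs_high, "case",
                ifelse(samples$hs <= hs_low, "control", "excluded"))
  samples$label <- factor(lab, levels = c("case", "control", "excluded"))
  if (is.null(samples$split)) samples$split <- "unassigned"
  attr(samples, "counts") <- table(samples$label)
  attr(samples, "hs_thresholds") <- c(hs_low = hs_low, hs_high = hs_high)
  class(samples) <- unique(c("sample_table", class(samples)))
  samples
}

#' Pipeline constants in one place
#'
#' Collects every fixed constant of the analysis strategy with its default:
#' HS thresholds (0.057 / 0.14), the 90 % detection filter, the 5 % FDR
#' level, 1000 bootstrap replicates, the co-occurrence edge filter at 300,
#' the caliper multiplier 0.2, the 1:2 control ratio, and 1000 bootstrap CI
#' resamples.
#'
#' @param hs_low,hs_high hemolysis-score thresholds
#' @param detection_frac minimum detection fraction for feature retention
#' @param alpha FDR level for the union significance rule
#' @param B_boot bootstrap replicates for feature ranking
#' @param cooc_min minimum co-occurrence for a network edge
#' @param caliper_mult caliper width as a multiple of SD(logit PS)
#' @param control_ratio controls matched per case
#' @param B_ci bootstrap resamples for validation confidence intervals
#' @param rng_seed master seed
#' @return a validated list of class `analysis_config`
#' @export
analysis_config <- function(hs_low = 0.057, hs_high = 0.14,
                            detection_frac = 0.90, alpha = 0.05,
                            B_boot = 1000L, cooc_min = 300L,
                            caliper_mult = 0.2, control_ratio = 2L,
                            B_ci = 1000L, rng_seed = 1L) {
  stopifnot(hs_low < hs_high,
            detection_frac > 0, detection_frac <= 1,
            alpha > 0, alpha <= 1,
            B_boot >= 1, cooc_min >= 0, caliper_mult > 0,
            control_ratio >= 1, B_ci >= 1)
  structure(list(hs_low = hs_low, hs_high = hs_high,
                 detection_frac = detection_frac, alpha = alpha,
                 B_boot = as.integer(B_boot), cooc_min = as.integer(cooc_min),
                 caliper_mult = caliper_mult,
                 control_ratio = as.integer(control_ratio),
                 B_ci = as.integer(B_ci), rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}
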