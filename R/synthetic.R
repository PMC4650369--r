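# Synthetic cohorts with the statistical structure the pipeline assumes:
# a small set of features up-regulated in cases (log2 mean shifts), features
# with equal means but different shape (case-only variance inflation or a
# two-component mixture) that only an omnibus test can flag, a correlated
# block sharing a latent factor, intensity-dependent detection dropout, and
# class-conditional hemolysis scores.

#' Specify a synthetic cohort
#'
#' Defaults mirror a typical hemolysis case-control design: 13 cases vs 26
#' controls per set, ~50 features (the 88-feature scale capped for test
#' speed), five mean-shifted features of which four share one correlated
#' block (the hemolysis-related cluster) and one is weaker, plus two
#' shape-only features at variance ratio 9.
#'
#' @param n_features total features
#' @param n_case,n_control class sizes
#' @param de_mean_set indices of mean-shifted features
#' @param delta log2 shift per mean-shifted feature (recycled)
#' @param de_shape_set indices of equal-mean, shape-different features
#'   (disjoint from `de_mean_set`)
#' @param shape_mode `"variance"` (case-only SD inflated by `sqrt(rho)`) or
#'   `"mixture"` (case values shifted by +-gamma with weight `pi_mix`,
#'   mean-centered)
#' @param rho case/control variance ratio for `"variance"` mode
#' @param pi_mix,gamma mixture weight and component gap for `"mixture"` mode
#' @param block_set indices sharing the latent factor
#' @param r pairwise correlation within the block (unit-variance factor
#'   model: the latent factor explains a fraction `r` of each block
#'   feature's variance)
#' @param baseline_mu,baseline_sd feature baselines (recycled); `NULL`
#'   baseline_mu draws means from N(8, 1.5) under the seed
#' @param dropout_midpoint,dropout_slope logistic detection model:
#'   P(detected) = plogis(slope * (value - midpoint))
#' @param hs_mu_case,hs_mu_control,hs_sd hemolysis-score generation
#' @param seed master seed
#' @return list of class `sim_spec`
#' @export
sim_spec <- function(n_features = 50, n_case = 13, n_control = 26,
                     de_mean_set = 1:5,
                     delta = c(1.5, 1.5, 1.5, 1.5, 0.75),
                     de_shape_set = 6:7,
                     shape_mode = c("variance", "mixture"),
                     rho = 9, pi_mix = 0.4, gamma = 2,
                     block_set = 1:4, r = 0.6,
                     baseline_mu = NULL, baseline_sd = 1,
                     dropout_midpoint = 4, dropout_slope = 1.5,
                     hs_mu_case = 0.25, hs_mu_control = 0.03, hs_sd = 0.04,
                     seed = 1) {
  shape_mode <- match.arg(shape_mode)
  stopifnot(n_features >= 1, n_case >= 2, n_control >= 2, rho > 0,
            all(de_mean_set %in% seq_len(n_features)),
            all(de_shape_set %in% seq_len(n_features)),
            all(block_set %in% seq_len(n_features)))
  if (length(intersect(de_mean_set, de_shape_set)))
    stop("de_mean_set and de_shape_set must be disjoint")
  structure(list(n_features = n_features, n_case = n_case,
                 n_control = n_control,
                 de_mean_set = de_mean_set,
                 delta = rep_len(delta, length(de_mean_set)),
                 de_shape_set = de_shape_set, shape_mode = shape_mode,
                 rho = rho, pi_mix = pi_mix, gamma = gamma,
                 block_set = block_set, r = r,
                 baseline_mu = baseline_mu,
                 baseline_sd = rep_len(baseline_sd, n_features),
                 dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope,
                 hs_mu_case = hs_mu_case, hs_mu_control = hs_mu_control,
                 hs_sd = hs_sd, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate a synthetic cohort
#'
#' Per feature f and sample s, the log2 value is
#' `mu_f + r * Z_s \[block\] + delta_f * case \[mean DE\] + shape term + noise`,
#' detection flags are drawn from the logistic intensity model, and
#' hemolysis scores from class-conditional normals clipped at 0.
#' Deterministic under the spec seed.
#'
#' @param spec a [sim_spec()]
#' @return list: `expression` (an [expression_matrix()]), `samples` (a
#'   labelled sample table with hs and matching covariates), `truth` (the
#'   planted feature id sets)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    p <- spec$n_features
    n <- spec$n_case + spec$n_control
    is_case <- c(rep(TRUE, spec$n_case), rep(FALSE, spec$n_control))
    fid <- sprintf("miR-%03d", seq_len(p))
    sid <- sprintf("S%03d", seq_len(n))
    mu <- spec$baseline_mu %||% stats::rnorm(p, 8, 1.5)
    mu <- rep_len(mu, p)

    vals <- mu + matrix(stats::rnorm(p * n, 0, spec$baseline_sd), p, n)
    if (length(spec$block_set) && spec$r > 0) {
      # unit-variance factor model: pairwise correlation r within the block,
      # total per-feature SD unchanged so delta stays in SD units
      z <- stats::rnorm(n)
      bs <- spec$block_set
      noise <- (vals[bs, , drop = FALSE] - mu[bs]) * sqrt(1 - spec$r)
      vals[bs, ] <- mu[bs] + noise +
        sqrt(spec$r) * matrix(z * spec$baseline_sd[bs[1]],
                              length(bs), n, byrow = TRUE)
    }
    if (length(spec$de_mean_set))
      vals[spec$de_mean_set, is_case] <-
        vals[spec$de_mean_set, is_case] + spec$delta
    for (f in spec$de_shape_set) {
      nc <- spec$n_case
      if (spec$shape_mode == "variance") {
        extra <- stats::rnorm(nc, 0, spec$baseline_sd[f] *
                                sqrt(spec$rho - 1))
        vals[f, is_case] <- vals[f, is_case] + extra
      } else {
        comp <- stats::rbinom(nc, 1, spec$pi_mix)
        shift <- ifelse(comp == 1, spec$gamma, 0)
        shift <- shift - spec$pi_mix * spec$gamma  # mean-centered
        vals[f, is_case] <- vals[f, is_case] + shift
      }
    }
    dimnames(vals) <- list(fid, sid)
    det <- matrix(stats::rbinom(p * n, 1,
                                stats::plogis(spec$dropout_slope *
                                                (vals - spec$dropout_midpoint))),
                  p, n, dimnames = list(fid, sid)) == 1

    hs <- pmax(stats::rnorm(n, ifelse(is_case, spec$hs_mu_case,
                                      spec$hs_mu_control), spec$hs_sd), 0)
    samples <- data.frame(sample_id = sid, hs = hs,
                          label = factor(ifelse(is_case, "case", "control"),
                                         levels = c("case", "control",
                                                    "excluded")),
                          disease_status = stats::rbinom(n, 1, 0.3),
                          age_at_drawing = round(stats::rnorm(n, 55, 8), 1),
                          drawing_year = sample(2001:2008, n, replace = TRUE),
                          split = "unassigned",
                          stringsAsFactors = FALSE)
    class(samples) <- unique(c("sample_table", class(samples)))
    list(expression = expression_matrix(vals, det),
         samples = samples,
         truth = list(de_mean = fid[spec$de_mean_set],
                      de_shape = fid[spec$de_shape_set],
                      block = fid[spec$block_set]))
  })
}

#' Generate an unbalanced matching pool
#'
#' Covariates are drawn with class-dependent shifts so that the raw pool is
#' imbalanced before matching (the situation propensity matching corrects).
#'
#' @param n_cases cases (hemolyzed)
#' @param n_controls_pool candidate controls
#' @param covariate_effects named numeric: `disease` (log-odds shift for
#'   cases), `age` (years added for cases), `year` (drawing-year shift)
#' @param seed master seed
#' @return a labelled sample table with hs, covariates and label
#' @export
generate_matching_pool <- function(n_cases = 26, n_controls_pool = 120,
                                   covariate_effects = c(disease = 1,
                                                         age = 5,
                                                         year = 1.5),
                                   seed = 1) {
  if (n_controls_pool < 2 * n_cases)
    warning("control pool smaller than 2x cases: matching will leave ",
            "unmatched cases")
  with_seed(seed, {
    n <- n_cases + n_controls_pool
    is_case <- c(rep(TRUE, n_cases), rep(FALSE, n_controls_pool))
    eff <- covariate_effects
    hs <- pmax(stats::rnorm(n, ifelse(is_case, 0.25, 0.03), 0.04), 0)
    hs[is_case] <- pmax(hs[is_case], 0.141)   # cases are above threshold
    hs[!is_case] <- pmin(hs[!is_case], 0.057) # controls at or below
    out <- data.frame(
      sample_id = sprintf("P%03d", seq_len(n)),
      hs = hs,
      disease_status = stats::rbinom(n, 1,
                                     stats::plogis(-1 + eff["disease"] *
                                                     is_case)),
      age_at_drawing = round(stats::rnorm(n, 55 + eff["age"] * is_case, 8),
                             1),
      drawing_year = round(stats::rnorm(n, 2004 + eff["year"] * is_case,
                                        2)),
      stringsAsFactors = FALSE)
    label_samples(out)
  })
}
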