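test_that("SCAD penalty matches its closed-form pieces and is continuous", {
  lam <- 0.5; a <- 3.7
  w <- seq(-3, 3, by = 0.01)
  t <- abs(w)
  expected <- ifelse(t <= lam, lam * t,
                     ifelse(t <= a * lam,
                            (2 * a * lam * t - t^2 - lam^2) / (2 * (a - 1)),
                            (a + 1) * lam^2 / 2))
  expect_equal(scad_penalty(w, lam, a), expected, tolerance = 1e-12)

  # continuity at the knots, and derivative continuity except at 0
  eps <- 1e-9
  expect_equal(scad_penalty(lam - eps, lam, a), scad_penalty(lam + eps, lam, a),
               tolerance = 1e-6)
  expect_equal(scad_penalty(a * lam - eps, lam, a),
               scad_penalty(a * lam + eps, lam, a), tolerance = 1e-6)
  h <- 1e-6
  for (t0 in c(0.2, 0.5, 1.2, 1.85, 2.5)) {
    num <- (scad_penalty(t0 + h, lam, a) - scad_penalty(t0 - h, lam, a)) / (2 * h)
    expect_equal(num, scad_penalty_deriv(t0, lam, a), tolerance = 1e-4)
  }
  # flat beyond a*lambda, slope lambda at 0+
  expect_equal(scad_penalty_deriv(3, lam, a), 0)
  expect_equal(scad_penalty_deriv(1e-9, lam, a), lam)
})

test_that("NSC shrinkage extremes behave as documented", {
  fx <- fx_spiked(20, 10, 10, k = 3, delta = 2, seed = 71)
  # Delta = 0: every feature with a nonzero centroid difference survives
  r0 <- nsc_select(fx$X, fx$labels, delta_grid = 0, seed = 1)
  expect_setequal(r0$selected, rownames(fx$X))
  # Delta above the largest standardized difference: empty selection
  rbig <- nsc_select(fx$X, fx$labels, delta_grid = 1e6, seed = 1)
  expect_length(rbig$selected, 0)
})

test_that("NSC recovers a 3-SD shifted feature almost always", {
  hits <- 0
  for (r in 1:100) {
    fx <- fx_spiked(50, 15, 15, k = 1, delta = 3, seed = 700 + r)
    sel <- nsc_select(fx$X, fx$labels, cv_folds = 3, seed = r)
    hits <- hits + ("f01" %in% sel$selected)
  }
  expect_gte(hits, 95)
})

test_that("selectors are deterministic under a fixed seed", {
  fx <- fx_spiked(30, 10, 20, k = 3, delta = 1.5, seed = 81)
  for (fn in list(
    function(s) nsc_select(fx$X, fx$labels, seed = s),
    function(s) boruta_rf_select(fx$X, fx$labels, max_iter = 12,
                                 ntree = 60, seed = s),
    function(s) elastic_scad_svm_select(fx$X, fx$labels,
                                        lambda1_grid = c(0.125, 0.5),
                                        lambda2_grid = c(0.1, 1),
                                        cv_folds = 3, seed = s))) {
    a <- fn(5); b <- fn(5)
    expect_identical(a$selected, b$selected)
    expect_true(all(a$selected %in% rownames(fx$X)))
    expect_named(a$scores, rownames(fx$X))
  }
})

test_that("Boruta confirms a label-duplicating feature and little else", {
  confirmed <- 0
  for (r in 1:100) {
    set.seed(900 + r)
    lab <- rep(c("case", "control"), each = 15)
    X <- rbind(sig = ifelse(lab == "case", 1, 0) + rnorm(30, 0, 0.05),
               matrix(rnorm(5 * 30), 5, 30,
                      dimnames = list(paste0("n", 1:5), NULL)))
    colnames(X) <- paste0("s", 1:30)
    sel <- boruta_rf_select(X, lab, max_iter = 15, ntree = 50, seed = r)
    confirmed <- confirmed + ("sig" %in% sel$selected)
  }
  expect_gte(confirmed, 95)
})

test_that("Boruta confirms nothing on pure noise", {
  clean <- 0
  for (r in 1:100) {
    set.seed(1200 + r)
    lab <- rep(c("case", "control"), each = 15)
    X <- matrix(rnorm(20 * 30), 20, 30,
                dimnames = list(paste0("n", 1:20), paste0("s", 1:30)))
    sel <- boruta_rf_select(X, lab, max_iter = 15, ntree = 50, seed = r)
    clean <- clean + (length(sel$selected) == 0)
  }
  expect_gte(clean, 90)
})

test_that("Boruta keeps both copies of a duplicated informative feature", {
  both <- 0
  for (r in 1:20) {
    set.seed(1500 + r)
    lab <- rep(c("case", "control"), each = 15)
    base <- ifelse(lab == "case", 1.5, 0) + rnorm(30, 0, 0.4)
    X <- rbind(sigA = base, sigB = base + rnorm(30, 0, 0.01),
               matrix(rnorm(8 * 30), 8, 30,
                      dimnames = list(paste0("n", 1:8), NULL)))
    colnames(X) <- paste0("s", 1:30)
    sel <- boruta_rf_select(X, lab, max_iter = 25, ntree = 100, seed = r)
    both <- both + all(c("sigA", "sigB") %in% sel$selected)
  }
  expect_gte(both, 16)
})

test_that("Boruta refuses an underpowered iteration budget", {
  fx <- fx_spiked(5, 5, 5, k = 0)
  expect_error(boruta_rf_select(fx$X, fx$labels, max_iter = 5), "max_iter")
})

test_that("Elastic SCAD SVM shrinkage limits", {
  fx <- fx_spiked(20, 15, 15, k = 2, delta = 2, seed = 91)
  # lambda1 large enough: empty selection
  rbig <- elastic_scad_svm_select(fx$X, fx$labels, lambda1_grid = 50,
                                  lambda2_grid = 0.1, cv_folds = 3, seed = 1)
  expect_length(rbig$selected, 0)
  # lambda1 = 0: ridge limit, no sparsity
  r0 <- elastic_scad_svm_select(fx$X, fx$labels, lambda1_grid = 0,
                                lambda2_grid = 0.1, cv_folds = 3, seed = 1)
  expect_setequal(r0$selected, rownames(fx$X))
})

test_that("elastic penalty keeps correlated informative features together", {
  together <- 0
  for (r in 1:100) {
    set.seed(1700 + r)
    lab <- rep(c("case", "control"), each = 20)
    z <- rnorm(40)
    f1 <- ifelse(lab == "case", 1.5, 0) + sqrt(0.9) * z +
      sqrt(0.1) * rnorm(40)
    f2 <- ifelse(lab == "case", 1.5, 0) + sqrt(0.9) * z +
      sqrt(0.1) * rnorm(40)
    X <- rbind(f1 = f1, f2 = f2,
               matrix(rnorm(48 * 40), 48, 40,
                      dimnames = list(paste0("n", 1:48), NULL)))
    colnames(X) <- paste0("s", 1:40)
    sel <- elastic_scad_svm_select(X, lab,
                                   lambda1_grid = 2^c(-3, -2, -1),
                                   lambda2_grid = 2^c(-4, -2, 0),
                                   cv_folds = 3, seed = r, max_outer = 30)
    together <- together + all(c("f1", "f2") %in% sel$selected)
  }
  expect_gte(together, 80)
})
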