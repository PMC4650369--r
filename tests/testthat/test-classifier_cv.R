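test_that("Youden index arithmetic and range checks", {
  expect_equal(youden(0.85, 0.96), 0.81)
  expect_equal(youden(0.77, 0.96), 0.73)
  expect_equal(youden(1, 1), 1)
  expect_equal(youden(0.5, 0.5), 0)
  expect_error(youden(1.2, 0.5), "\\[0, 1\\]")
  expect_error(youden(0.5, -0.1), "\\[0, 1\\]")
})

test_that("LOOCV is perfect on widely separated classes", {
  set.seed(201)
  lab <- rep(c("case", "control"), each = 15)
  X <- rbind(f1 = ifelse(lab == "case", 10, -10) + rnorm(30),
             f2 = rnorm(30))
  colnames(X) <- paste0("s", 1:30)
  perf <- loocv_performance(X, lab, cost = 1)
  expect_equal(unname(perf), c(1, 1, 1))
})

test_that("LOOCV confusion matrix matches the hand-worked 1-D instance", {
  # cases at 0.5, 2, 3; controls at -0.5, -2, -3; large cost.
  # Leaving out +-0.5 moves the margin past it (e.g. without 0.5 the
  # closest pair is 2 vs -0.5, boundary at 0.75, so 0.5 is called control);
  # every other fold keeps the boundary between -0.5 and 0.5.
  X <- matrix(c(0.5, 2, 3, -0.5, -2, -3), 1,
              dimnames = list("f", paste0("s", 1:6)))
  lab <- rep(c("case", "control"), each = 3)
  perf <- loocv_performance(X, lab, cost = 10)
  expect_equal(unname(perf["sens"]), 2 / 3)
  expect_equal(unname(perf["spec"]), 2 / 3)
  expect_equal(unname(perf["youden"]), 1 / 3)
})

test_that("LOOCV under label permutation is centered at chance", {
  set.seed(211)
  X <- matrix(rnorm(3 * 39), 3, 39,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:39)))
  ys <- numeric(100)
  for (r in 1:100) {
    lab <- sample(rep(c("case", "control"), c(13, 26)))
    ys[r] <- loocv_performance(X, lab, cost = 1)["youden"]
  }
  expect_lt(abs(mean(ys)), 0.1)
})

test_that("LOOCV ordering invariance and degenerate inputs", {
  set.seed(221)
  fx <- fx_spiked(4, 6, 8, k = 1, delta = 2, seed = 221)
  perm <- sample(14)
  a <- loocv_performance(fx$X, fx$labels, 1)
  b <- loocv_performance(fx$X[, perm], fx$labels[perm], 1)
  expect_equal(a, b, tolerance = 1e-8)
  expect_error(loocv_performance(fx$X[, 1:3, drop = FALSE],
                                 c("case", "control", "control"), 1),
               ">= 2")
})

test_that("model family is the Cartesian grid with LOOCV filled in", {
  fx <- fx_spiked(6, 8, 10, k = 2, delta = 6, seed = 231)
  fam <- build_model_family(fx$X, fx$labels,
                            rank_order = rownames(fx$X)[1:4],
                            k_grid = c(1, 2, 3),
                            cost_grid = c(0.1, 1),
                            weight_grid = list(c(0.5, 0.5), c(0.3, 0.7)))
  expect_equal(nrow(fam), 12L)
  expect_equal(fam$youden, fam$sens + fam$spec - 1, tolerance = 1e-12)
  # k = 1 on a cleanly separating feature is perfect
  expect_true(all(fam$youden[fam$k == 1] == 1))
  expect_warning(
    build_model_family(fx$X, fx$labels, rownames(fx$X)[1:2],
                       k_grid = c(1, 5), cost_grid = 1,
                       weight_grid = list(c(0.5, 0.5))),
    "truncated")
})

test_that("ROC grouping matches a brute-force dictionary and orders by Youden", {
  set.seed(241)
  fam <- data.frame(k = 1:20, cost = 1, w_case = 0.5, w_control = 0.5,
                    sens = sample(seq(0, 1, by = 0.25), 20, replace = TRUE),
                    spec = sample(seq(0, 1, by = 0.25), 20, replace = TRUE))
  fam$youden <- fam$sens + fam$spec - 1
  class(fam) <- c("model_family", "data.frame")
  g <- group_models_roc(fam)
  # same (FPR, TPR) -> same group; brute-force dictionary
  key <- paste(1 - fam$spec, fam$sens)
  for (kk in unique(key))
    expect_equal(length(unique(g$group_id[key == kk])), 1L)
  # group Youden strictly non-increasing in group id
  by_g <- tapply(g$youden, g$group_id, unique)
  expect_true(all(diff(unlist(by_g)[order(as.integer(names(by_g)))]) <= 0))
  expect_equal(min(g$group_id), 1L)
  # group sizes consistent
  expect_equal(unname(g$group_size), as.integer(table(g$group_id)[
    as.character(g$group_id)]))
})

test_that("parsimony choice: fewest features, then cost, then balance", {
  fam <- data.frame(k = c(35, 40, 50, 35), cost = c(10, 1, 1, 1),
                    w_case = c(0.5, 0.5, 0.5, 0.4),
                    w_control = c(0.5, 0.5, 0.5, 0.6),
                    sens = 0.85, spec = 0.96, youden = 0.81)
  class(fam) <- c("model_family", "data.frame")
  g <- group_models_roc(fam)
  pick <- choose_parsimonious(g, 1)
  expect_equal(pick$k, 35)
  expect_equal(pick$cost, 1)       # cost tie-break at equal k
  expect_equal(pick$w_case, 0.4)   # only the k=35, cost=1 row has 0.4

  single <- choose_parsimonious(g[g$k == 50, ], 1)
  expect_equal(single$k, 50)
  expect_error(choose_parsimonious(g, 99), "empty")
})

test_that("validation evaluation: point metrics, bootstrap CI and oracle", {
  set.seed(251)
  lab_tr <- rep(c("case", "control"), c(10, 20))
  X_tr <- rbind(f1 = ifelse(lab_tr == "case", 5, -5) + rnorm(30, 0, 0.3),
                f2 = rnorm(30))
  colnames(X_tr) <- paste0("t", 1:30)
  lab_va <- rep(c("case", "control"), c(13, 26))
  X_va <- rbind(f1 = ifelse(lab_va == "case", 5, -5) + rnorm(39, 0, 0.3),
                f2 = rnorm(39))
  colnames(X_va) <- paste0("v", 1:39)
  rec <- data.frame(k = 1, cost = 1, w_case = 0.5, w_control = 0.5)
  out <- evaluate_validation(rec, X_tr, lab_tr, X_va, lab_va,
                             rank_order = c("f1", "f2"), B_ci = 200,
                             seed = 9)
  # perfectly separated validation: everything 1 with degenerate CIs
  expect_equal(out$val_sens, 1)
  expect_equal(out$val_spec, 1)
  expect_equal(out$val_youden, 1)
  expect_equal(c(out$val_sens_lo, out$val_sens_hi), c(1, 1))
  expect_equal(c(out$val_youden_lo, out$val_youden_hi), c(1, 1))

  # imperfect predictions: CI equals an independent resampling recount
  X_va2 <- X_va
  X_va2["f1", 1:3] <- -5      # three cases will be missed
  out2 <- evaluate_validation(rec, X_tr, lab_tr, X_va2, lab_va,
                              rank_order = c("f1", "f2"), B_ci = 500,
                              seed = 13)
  expect_equal(out2$val_sens, 10 / 13)
  expect_equal(out2$val_spec, 1)
  pred <- c(rep("control", 3), rep("case", 10), rep("control", 26))
  set.seed(13)
  icase <- 1:13; ictrl <- 14:39
  stat <- matrix(NA_real_, 500, 3)
  for (b in 1:500) {
    idx <- c(sample(icase, replace = TRUE), sample(ictrl, replace = TRUE))
    truth <- lab_va[idx]
    sens <- mean(pred[idx][truth == "case"] == "case")
    spec <- mean(pred[idx][truth == "control"] == "control")
    stat[b, ] <- c(sens, spec, sens + spec - 1)
  }
  ci <- apply(stat, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  expect_equal(out2$val_sens_lo, ci[1, 1])
  expect_equal(out2$val_sens_hi, ci[2, 1])
  expect_equal(out2$val_youden_lo, ci[1, 3])
  expect_equal(out2$val_youden_hi, ci[2, 3])

  expect_error(evaluate_validation(rec, X_tr, lab_tr, X_va,
                                   rep("control", 39), c("f1", "f2")),
               "both classes")
})
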