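make_pool <- function(n_case, n_control, seed = 1, age_shift = 0) {
  set.seed(seed)
  n <- n_case + n_control
  s <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    hs = c(rep(0.2, n_case), rep(0.02, n_control)),
    disease_status = rbinom(n, 1, 0.4),
    age_at_drawing = rnorm(n, 55, 8) +
      age_shift * rep(c(1, 0), c(n_case, n_control)),
    drawing_year = sample(2001:2008, n, replace = TRUE))
  label_samples(s)
}

test_that("propensity model degenerates to the prevalence without covariates", {
  s <- make_pool(10, 20)
  s$disease_status <- 1; s$age_at_drawing <- 50; s$drawing_year <- 2005
  ps <- fit_propensity(s)
  expect_equal(unname(ps), rep(10 / 30, 30), tolerance = 1e-8)

  # one balanced binary covariate: 2x2 counts (10,10;10,10) -> ps 0.5
  s2 <- make_pool(20, 20)
  s2$age_at_drawing <- 50; s2$drawing_year <- 2005
  s2$disease_status <- rep(c(0, 1, 0, 1), each = 10)
  ps2 <- fit_propensity(s2)
  expect_equal(unname(ps2), rep(0.5, 40), tolerance = 1e-8)
})

test_that("propensity model recovers known coefficients within 3 SE", {
  set.seed(99)
  n <- 600
  age <- rnorm(n, 55, 8)
  dis <- rbinom(n, 1, 0.3)
  yr <- sample(2001:2008, n, replace = TRUE)
  beta <- c(intercept = -0.5, disease = 0.8, age = 0.05, year = -0.15)
  eta <- beta[1] + beta[2] * dis + beta[3] * (age - 55) + beta[4] * (yr - 2004)
  case <- rbinom(n, 1, plogis(eta)) == 1
  s <- data.frame(sample_id = sprintf("s%03d", 1:n),
                  hs = ifelse(case, 0.2, 0.02),
                  disease_status = dis,
                  age_at_drawing = age - 55,
                  drawing_year = yr - 2004)
  s <- label_samples(s)
  ps <- fit_propensity(s)
  fit <- glm(case ~ dis + I(age - 55) + I(yr - 2004), family = binomial())
  expect_equal(unname(ps), unname(fitted(fit)), tolerance = 1e-6)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - beta) < 3 * se))
})

test_that("degenerate propensity inputs are rejected", {
  s <- make_pool(10, 20)
  s$age_at_drawing[3] <- NA
  expect_error(fit_propensity(s), "age_at_drawing")

  # complete separation via a covariate identical to the label
  s2 <- make_pool(10, 20)
  s2$age_at_drawing <- ifelse(s2$label == "case", 100, 20)
  expect_error(fit_propensity(s2), "separation")
})

test_that("caliper width is 0.2 x SD of the propensity logit", {
  lp <- c(-1.2, -0.3, 0.1, 0.8, 1.5)
  lp <- (lp - mean(lp)) / sd(lp)  # SD exactly 1
  expect_equal(caliper_width(plogis(lp)), 0.2)

  expect_error(caliper_width(rep(0.4, 10)), "constant")

  set.seed(5)
  ps <- runif(50, 0.05, 0.95)
  expect_equal(caliper_width(ps, 0.2), 0.2 * sd(log(ps / (1 - ps))))
})

test_that("greedy 1:2 matching obeys caliper, no-reuse and the greedy order", {
  # enumerable instance: 3 cases, 6 controls with hand-set propensities
  lp <- c(A = 0.9, B = 0.0, C = -0.6,
          c1 = 1.0, c2 = 0.8, c3 = 0.1, c4 = -0.1, c5 = -0.5, c6 = -0.75)
  ps <- plogis(lp)
  lp <- qlogis(ps)  # the scale the matcher sees (round trip jitters ties)
  m <- match_1to2(c("A", "B", "C"), paste0("c", 1:6), ps, caliper = 0.45)
  # brute-force the documented greedy rule: order by |lp - mean|, desc
  ctr <- mean(lp)
  ord <- names(sort(-abs(lp[c("A", "B", "C")] - ctr)))
  pool <- paste0("c", 1:6)
  expected <- list()
  for (cid in ord) {
    d <- abs(lp[pool] - lp[cid])
    ok <- pool[d <= 0.45][order(d[d <= 0.45], pool[d <= 0.45])]
    if (length(ok) >= 2) {
      expected[[cid]] <- ok[1:2]
      pool <- setdiff(pool, ok[1:2])
    }
  }
  got <- setNames(lapply(seq_len(nrow(m$triplets)), function(i)
    c(m$triplets$control_1[i], m$triplets$control_2[i])),
    m$triplets$case_id)
  expect_equal(got[order(names(got))], expected[order(names(expected))])

  # invariants: controls unique, caliper holds for every matched pair
  ctrls <- unlist(m$triplets[, -1])
  expect_equal(anyDuplicated(ctrls), 0L)
  for (i in seq_len(nrow(m$triplets))) {
    cid <- m$triplets$case_id[i]
    expect_true(all(abs(lp[unlist(m$triplets[i, -1])] - lp[cid]) <= 0.45))
  }

  # 1 case with exactly 2 in-caliper controls -> one triplet
  ps1 <- plogis(c(x = 0, u = 0.1, v = -0.1))
  m1 <- match_1to2("x", c("u", "v"), ps1, caliper = 0.2)
  expect_equal(nrow(m1$triplets), 1L)
  expect_equal(length(m1$unmatched_cases), 0L)

  # input-order invariance
  m2 <- match_1to2(c("C", "A", "B"), paste0("c", 6:1), ps, caliper = 0.45)
  expect_equal(m2$triplets[order(m2$triplets$case_id), ],
               m$triplets[order(m$triplets$case_id), ],
               ignore_attr = TRUE)
})

test_that("26 matchable cases give a 78-sample cohort split 39/39 at 1:2", {
  pool <- generate_matching_pool(26, 200,
                                 covariate_effects = c(disease = 0.5,
                                                       age = 2, year = 0.5),
                                 seed = 4)
  ps <- fit_propensity(pool)
  cal <- caliper_width(ps)
  m <- match_1to2(pool$sample_id[pool$label == "case"],
                  pool$sample_id[pool$label == "control"], ps, cal)
  expect_equal(nrow(m$triplets), 26L)
  expect_equal(length(matched_ids(m)), 78L)

  sp <- split_train_validation(m, seed = 7)
  for (sid in c("training", "validation")) {
    sub <- sp[sp$split == sid, ]
    expect_equal(nrow(sub), 39L)
    expect_equal(sum(sub$role == "case"), 13L)
    expect_equal(sum(sub$role == "control"), 26L)
  }
})

test_that("splitting randomizes whole matched sets deterministically", {
  ps <- plogis(seq(-1, 1, length.out = 12))
  names(ps) <- sprintf("s%02d", 1:12)
  m <- match_1to2(names(ps)[1:4], names(ps)[5:12], ps, caliper = 10)
  expect_equal(nrow(m$triplets), 4L)
  s1 <- split_train_validation(m, seed = 1)
  s2 <- split_train_validation(m, seed = 1)
  expect_identical(s1, s2)
  # sets move as a unit
  for (i in unique(s1$set_id))
    expect_equal(length(unique(s1$split[s1$set_id == i])), 1L)

  # 2 sets -> 1 and 1
  m2 <- match_1to2(names(ps)[1:2], names(ps)[5:10], ps, caliper = 10)
  sp2 <- split_train_validation(m2, seed = 3)
  expect_equal(sort(unique(sp2$split)), c("training", "validation"))
  expect_equal(sum(sp2$split == "training"), 3L)

  # odd set count -> warning, extra set to training
  m3 <- match_1to2(names(ps)[1:3], names(ps)[4:12], ps, caliper = 10)
  expect_warning(sp3 <- split_train_validation(m3, seed = 2), "odd")
  expect_equal(sum(sp3$split == "training"), 6L)
})
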