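test_that("AUC equals the pairwise U-statistic on worked examples", {
  expect_equal(roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0),
                         direction = "larger")$auc, 1)
  # cases {1,2}, controls {2,0}: pairs give (0.5 + 1 + 0.5*? ...) = 0.625
  expect_equal(roc_curve(c(1, 2, 2, 0), c(1, 1, 0, 0),
                         direction = "larger")$auc, 0.625)
  expect_equal(brute_auc(c(1, 2, 2, 0), c(1, 1, 0, 0)), 0.625)
})

test_that("ROC curve is a valid step curve whose trapezoid area equals the AUC", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    label <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    r <- suppressWarnings(roc_curve(scores, label,
                                    direction = sample(c("larger", "smaller",
                                                         "auto"), 1)))
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    trap <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) +
                                 utils::tail(r$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
    expect_equal(r$auc, brute_auc(scores, label, r$direction),
                 tolerance = 1e-12)
  }
})

test_that("AUC complement symmetry and monotone-transform invariance hold", {
  set.seed(3)
  scores <- rnorm(30); label <- rbinom(30, 1, 0.4); label[1:2] <- c(1, 0)
  a_l <- roc_curve(scores, label, "larger")$auc
  a_s <- roc_curve(scores, label, "smaller")$auc
  expect_equal(a_l + a_s, 1)
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3))
    expect_equal(roc_curve(f(scores), label, "larger")$auc, a_l)
})

test_that("degenerate ROC inputs follow the contract", {
  expect_warning(r <- roc_curve(rep(1, 6), c(1, 1, 1, 0, 0, 0)),
                 "constant scores")
  expect_equal(r$auc, 0.5)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "no control")
  expect_error(roc_curve(1:4, c(0, 0, 0, 0)), "no case")
})

test_that("auto orientation yields AUC >= 0.5 for informative biomarkers", {
  set.seed(8)
  label <- rep(c(1, 0), each = 20)
  low_in_cases <- c(rnorm(20, -2), rnorm(20, 0))  # repression-type score
  r <- roc_curve(low_in_cases, label)
  expect_identical(r$direction, "smaller")
  expect_gt(r$auc, 0.5)
})

test_that("DeLong placements are the structural components of the AUC", {
  # perfect separation: all placements 1
  pl <- delong_placements(c(5, 6, 1, 2), c(1, 1, 0, 0), "larger")
  expect_equal(pl$case, c(1, 1))
  expect_equal(pl$control, c(1, 1))
  # single tied pair
  pl2 <- delong_placements(c(2, 2), c(1, 0), "larger")
  expect_equal(pl2$case, 0.5)
  expect_equal(pl2$control, 0.5)
  # mean of either placement vector equals the AUC (fuzz, with ties)
  set.seed(77)
  for (i in 1:300) {
    n <- sample(5:60, 1)
    label <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(1:8, n, replace = TRUE)
    pl <- delong_placements(scores, label, "larger")
    a <- brute_auc(scores, label)
    expect_equal(mean(pl$case), a, tolerance = 1e-12)
    expect_equal(mean(pl$control), a, tolerance = 1e-12)
  }
})

test_that("DeLong paired test honours its degenerate and invariance contracts", {
  set.seed(12)
  scores <- rnorm(40); label <- rep(c(1, 0), each = 20)
  self <- delong_paired_test(scores, scores, label, "larger", "larger")
  expect_identical(self$z, 0)
  expect_identical(self$p.value, 1)
  shifted <- delong_paired_test(scores, scores + 3.7, label,
                                "larger", "larger")
  expect_equal(shifted$auc_a, shifted$auc_b)
  expect_identical(shifted$z, 0)
  expect_error(delong_paired_test(scores, scores[-1], label), "same samples")
})

test_that("DeLong AUC and variance agree with pROC on random paired data", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:10) {
    label <- rep(c(1, 0), times = c(18, 14))
    a <- rnorm(32) + label
    b <- 0.6 * a + rnorm(32, 0, 0.8)
    ours <- delong_paired_test(a, b, label, "larger", "larger")
    ra <- pROC::roc(label, a, direction = "<", quiet = TRUE)
    rb <- pROC::roc(label, b, direction = "<", quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(ours$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    v <- delong_variance(a, label, "larger")
    expect_equal(sqrt(v), sqrt(pROC::var(ra, method = "delong")),
                 tolerance = 1e-10)
  }
})

test_that("Wilcoxon rank-sum uses the exact branch on small tie-free data", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p.value, 0.1)
  same <- wilcoxon_rank_sum(1:10, 1:10)
  expect_false(same$exact)  # tied data forces the approximate branch
  expect_gt(same$p.value, 0.9)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("Wilcoxon exact and approximate branches agree near the boundary", {
  set.seed(14)
  for (i in 1:40) {
    x <- rnorm(20); y <- rnorm(20, 0.3)  # 400 products: exact branch
    res <- wilcoxon_rank_sum(x, y)
    expect_true(res$exact)
    approx_p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(res$p.value - approx_p), 0.01)
  }
})

test_that("fit_ols reproduces exact fits and the normal-equations solution", {
  x <- 1:10
  exact <- fit_ols(2 * x, cbind(x = x))
  expect_equal(coef(exact)[["x"]], 2)
  expect_equal(exact$sigma2, 0, tolerance = 1e-20)
  expect_equal(exact$r.squared, 1)
  set.seed(4)
  for (i in 1:60) {
    n <- sample(10:40, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    fit <- fit_ols(y, X)
    Xi <- cbind(1, X)
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)   # explicit normal equations
    expect_equal(fit$coefficients$estimate, as.numeric(beta),
                 tolerance = 1e-8)
    s2 <- sum((y - Xi %*% beta)^2) / (n - p - 1)
    se <- sqrt(s2 * diag(solve(t(Xi) %*% Xi)))
    expect_equal(fit$coefficients$se, as.numeric(se), tolerance = 1e-8)
    # matches summary.lm t and p
    sm <- summary(stats::lm(y ~ X))$coefficients
    expect_equal(fit$coefficients$t, unname(sm[, "t value"]),
                 tolerance = 1e-8)
    expect_equal(fit$coefficients$p, unname(sm[, "Pr(>|t|)"]),
                 tolerance = 1e-8)
  }
})

test_that("fit_ols is permutation invariant and rejects bad designs", {
  set.seed(6)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- X %*% c(1, -2) + rnorm(30)
  fit <- fit_ols(y, X)
  perm <- sample(30)
  fit_p <- fit_ols(y[perm], X[perm, ])
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-10)
  expect_error(fit_ols(y, cbind(a = X[, 1], dup = X[, 1])),
               "collinear.*dup|dup.*collinear")
  expect_error(fit_ols(rnorm(3), matrix(rnorm(9), 3, 3)),
               "more observations")
})
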