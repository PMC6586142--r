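# small helper: biomarker_scores-shaped object built directly from a table
scores_from_table <- function(tab) {
  structure(list(table = tab, signatures = NULL,
                 types = stats::setNames(
                   rep(NA_character_, length(setdiff(names(tab),
                                                     c("sample", "group")))),
                   setdiff(names(tab), c("sample", "group"))),
                 labels = sample_labels(which(tab$group == "case"),
                                        nrow(tab))),
            class = "biomarker_scores")
}

test_that("associate_biomarkers recovers planted univariate and joint effects", {
  set.seed(101)
  n <- 60
  tab <- data.frame(sample = sprintf("s%02d", 1:n),
                    repr = rnorm(n), act = rnorm(n),
                    group = rep(c("case", "control"), each = n / 2),
                    stringsAsFactors = FALSE)
  sev <- data.frame(sample = tab$sample,
                    activity = 1 - 2 * tab$repr + 1.5 * tab$act +
                      rnorm(n, 0, 0.5))
  sc <- scores_from_table(tab)
  assoc <- associate_biomarkers(sc, sev, biomarkers = c("repr", "act"),
                                multivariate = list(c("repr", "act")))
  t1 <- assoc$table
  expect_equal(nrow(t1), 4L)  # 2 univariate + 2 joint coefficients
  joint <- t1[t1$model == "multivariate", ]
  expect_lt(joint$estimate[joint$term == "repr"], 0)
  expect_gt(joint$estimate[joint$term == "act"], 0)
  expect_true(all(joint$p < 0.05))
  expect_equal(assoc$n_tests, 4L)
  # coefficients agree with lm
  ref <- stats::lm(sev$activity ~ tab$repr + tab$act)
  expect_equal(joint$estimate, unname(coef(ref))[2:3], tolerance = 1e-10)
})

test_that("associate_biomarkers handles missing severity pairwise and bad input", {
  set.seed(7)
  tab <- data.frame(sample = sprintf("s%02d", 1:10), b = rnorm(10),
                    group = rep(c("case", "control"), 5))
  sev <- data.frame(sample = tab$sample, y = c(rnorm(6), rep(NA, 4)),
                    sparse = c(rnorm(2), rep(NA, 8)))
  sc <- scores_from_table(tab)
  expect_warning(assoc <- associate_biomarkers(sc, sev, biomarkers = "b"),
                 "sparse")
  expect_equal(assoc$table$covariate, "y")
  expect_equal(assoc$table$n, 6L)  # complete cases only
  expect_error(associate_biomarkers(sc, sev, biomarkers = "b",
                                    multivariate = list(c("b", "b"))),
               "collinear")
  expect_error(associate_biomarkers(sc, sev, biomarkers = "nope"), "nope")
})

test_that("repression threshold is the mean score of high-activation samples", {
  tab <- data.frame(sample = paste0("s", 1:4),
                    dux = c(6, 7, 3, 2), pax = c(-8, -10, 0, 5),
                    group = c("case", "case", "case", "control"))
  sc <- scores_from_table(tab)
  expect_equal(derive_repression_threshold(sc, "dux", "pax", 5.25), -9)
  expect_error(derive_repression_threshold(sc, "dux", "pax", 100),
               ">=2 samples")
  # adding a sample below the activation threshold changes nothing
  tab2 <- rbind(tab, data.frame(sample = "s5", dux = 1, pax = 99,
                                group = "control"))
  expect_equal(derive_repression_threshold(scores_from_table(tab2),
                                           "dux", "pax", 5.25), -9)
  # shift equivariance in the repression scores
  tab3 <- tab; tab3$pax <- tab3$pax + 4
  expect_equal(derive_repression_threshold(scores_from_table(tab3),
                                           "dux", "pax", 5.25), -9 + 4)
})

test_that("minimal_activation_threshold finds the smallest sufficient cutoff", {
  act <- c(1, 2, 3, 4, 5, 6)
  active <- c(0, 0, 1, 0, 1, 1)
  # above 4 every sample is active; above 3 sample 4 (inactive) intrudes
  expect_equal(minimal_activation_threshold(act, active), 4)
  expect_equal(minimal_activation_threshold(act, rep(1, 6)), -Inf)
  expect_equal(minimal_activation_threshold(act, c(1, 1, 1, 1, 1, 0)), 6)
})

test_that("stratified activity ratio divides high-activation samples at the repression cut", {
  tab <- data.frame(sample = paste0("s", 1:6),
                    dux = c(6, 6, 6, 6, 1, 1),
                    pax = c(-10, -11, -5, -4, 0, 0),
                    activity = c(4, 4, 2, 2, 9, 9),
                    group = c(rep("case", 5), "control"))
  sc <- scores_from_table(tab)
  st <- stratified_activity_ratio(sc, "activity", "dux", "pax",
                                  activation_threshold = 5.25,
                                  repression_threshold = -9)
  expect_equal(st$activity_ratio, 2)
  expect_equal(st$n_high_repression, 2L)
  expect_equal(st$n_low_repression, 2L)
  expect_identical(st$group[5:6], c("excluded", "excluded"))
  # identical activity in both strata gives ratio 1
  tab$activity <- 3
  st1 <- stratified_activity_ratio(scores_from_table(tab), "activity",
                                   "dux", "pax", 5.25, -9)
  expect_equal(st1$activity_ratio, 1)
  # order invariance
  perm <- c(4, 2, 6, 1, 3, 5)
  stp <- stratified_activity_ratio(scores_from_table(tab[perm, ]),
                                   "activity", "dux", "pax", 5.25, -9)
  expect_equal(stp$activity_ratio, st1$activity_ratio)
  # empty stratum and zero-denominator contracts
  expect_error(stratified_activity_ratio(sc, "activity", "dux", "pax",
                                         5.25, -99), "empty stratum")
  tab$activity <- c(4, 4, 0, 0, 1, 1)
  expect_warning(st0 <- stratified_activity_ratio(scores_from_table(tab),
                                                  "activity", "dux", "pax",
                                                  5.25, -9),
                 "ratio undefined")
  expect_false(st0$ratio_defined)
  expect_true(is.na(st0$activity_ratio))
})

test_that("planted 2x activity multiplier is recovered by the stratification", {
  hits <- 0L
  set.seed(606)
  for (r in 1:60) {
    n <- 32
    dux <- runif(n, 4, 8)
    pax <- runif(n, -14, -4)
    hi <- dux > 5.25 & pax < -9.12
    lo <- dux > 5.25 & pax >= -9.12
    if (sum(hi) < 2 || sum(lo) < 2) next
    base <- 5
    activity <- base * ifelse(hi, 2, 1) * (1 + rnorm(n, 0, 0.1))
    tab <- data.frame(sample = paste0("s", 1:n), dux = dux, pax = pax,
                      activity = activity,
                      group = rep(c("case", "control"), length.out = n))
    st <- stratified_activity_ratio(scores_from_table(tab), "activity",
                                    "dux", "pax", 5.25, -9.12)
    if (st$activity_ratio > 1.6 && st$activity_ratio < 2.4) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.9)
})

test_that("subset ROC comparison restricts, partitions, and degrades gracefully", {
  fx <- make_scored_fixture(n_samples = 12, n_cases = 6)
  sc <- score_biomarkers(fx$expr, fx$sigs, fx$labels)
  all_pos <- data.frame(sample = sc$table$sample, n_detected = 1L,
                        is_positive = TRUE)
  sub_all <- suppressWarnings(subset_roc_comparison(sc, all_pos, "positive"))
  full_cmp <- compare_biomarkers(sc)
  expect_equal(sub_all$comparisons$auc_a, full_cmp$auc_a)
  expect_equal(sub_all$comparisons$p.value, full_cmp$p.value)
  # positive and negative subsets partition the samples
  set.seed(2)
  mixed <- data.frame(sample = sc$table$sample, n_detected = 0L,
                      is_positive = rep(c(TRUE, FALSE), 6))
  sp <- subset_roc_comparison(sc, mixed, "positive")
  sn <- subset_roc_comparison(sc, mixed, "negative")
  expect_length(intersect(sp$samples, sn$samples), 0)
  expect_setequal(c(sp$samples, sn$samples), sc$table$sample)
  # a constant biomarker on the subset yields AUC 0.5 with warning
  sc0 <- sc
  sc0$table$act_sig <- 0
  w <- testthat::capture_warnings(
    s0 <- subset_roc_comparison(sc0, mixed, "negative"))
  expect_true(any(grepl("constant scores", w)))
  expect_equal(s0$rocs$act_sig$auc, 0.5)
  expect_equal(nrow(s0$comparisons), 1L)  # comparison still produced
  # subset missing a class errors with the subset named
  onesided <- data.frame(sample = sc$table$sample, n_detected = 0L,
                         is_positive = sc$table$group == "case")
  expect_error(subset_roc_comparison(sc, onesided, "positive"),
               "positive-subset lacks")
})
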