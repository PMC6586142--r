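# labels may be a sample_labels object or a 0/1 (or logical) vector
.as_label01 <- function(labels, n) {
  if (inherits(labels, "sample_labels")) labels <- labels$label
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be 0/1 (control/case)", call. = FALSE)
  if (length(labels) != n)
    stop("labels length ", length(labels), " does not match ", n, " scores",
         call. = FALSE)
  if (sum(labels == 1) == 0L) stop("no case samples", call. = FALSE)
  if (sum(labels == 0) == 0L) stop("no control samples", call. = FALSE)
  as.integer(labels)
}

# resolve "auto" orientation: the direction in which case scores exceed
# controls on average, so an informative biomarker yields AUC > 0.5
.resolve_direction <- function(scores, label, direction) {
  direction <- match.arg(direction, c("auto", "larger", "smaller"))
  if (direction == "auto") {
    direction <- if (mean(scores[label == 1]) >= mean(scores[label == 0]))
      "larger" else "smaller"
  }
  direction
}

#' DeLong structural components (placements)
#'
#' For each case, the fraction of controls it beats in the positive
#' direction (ties count 0.5); for each control, the fraction of cases it
#' loses to. The mean of either placement vector is the tie-corrected AUC.
#' Computed with midranks in O(N log N).
#'
#' @param scores numeric scores, one per sample.
#' @param labels case/control labels: a [sample_labels()] object or 0/1
#'   vector (1 = case).
#' @param direction `"larger"` if larger scores indicate a case,
#'   `"smaller"` for repression-type scores, or `"auto"` (default) to orient
#'   by the group-mean ordering; the resolved direction is returned.
#' @return List with `case` and `control` placement vectors, `auc`, and the
#'   resolved `direction`.
#' @export
delong_placements <- function(scores, labels, direction = "auto") {
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  label <- .as_label01(labels, length(scores))
  direction <- .resolve_direction(scores, label, direction)
  s <- if (direction == "smaller") -scores else scores
  x <- s[label == 1]; y <- s[label == 0]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  v_case <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v_ctrl <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  list(case = v_case, control = v_ctrl, auc = mean(v_case),
       direction = direction)
}

#' ROC curve and tie-corrected AUC
#'
#' Builds the ROC curve of a score as a binary classifier of case status over
#' all distinct score thresholds (plus endpoints). The AUC is the
#' Mann-Whitney U-statistic: the probability that a random case is more
#' extreme than a random control in the positive direction, with ties
#' credited 0.5.
#'
#' @inheritParams delong_placements
#' @return An object of class `roc_curve`: list with `thresholds` (on the
#'   original score scale; a sample is called positive when its score is
#'   `>=` the threshold for direction `"larger"`, `<=` for `"smaller"`),
#'   `fpr`, `tpr`, `auc`, `direction`, `n_case`, `n_control`.
#' @examples
#' roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0), direction = "larger")$auc  # 1
#' @export
roc_curve <- function(scores, labels, direction = "auto") {
  label <- .as_label01(labels, length(scores))
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(unique(scores)) == 1L)
    warning("constant scores: AUC = 0.5", call. = FALSE)
  pl <- delong_placements(scores, label, direction)
  s <- if (pl$direction == "smaller") -scores else scores
  cuts <- c(Inf, sort(unique(s), decreasing = TRUE))
  x <- s[label == 1]; y <- s[label == 0]
  tpr <- vapply(cuts, function(c) mean(x >= c), numeric(1))
  fpr <- vapply(cuts, function(c) mean(y >= c), numeric(1))
  thr <- if (pl$direction == "smaller") -cuts else cuts
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = pl$auc,
                 direction = pl$direction,
                 n_case = sum(label == 1), n_control = sum(label == 0)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (direction = %s; %d cases, %d controls)\n",
              x$auc, x$direction, x$n_case, x$n_control))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate (1 - specificity)",
                 ylab = "True positive rate (sensitivity)",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Export a ROC curve as CSV
#' @param x a `roc_curve`.
#' @param path output path; columns threshold, fpr, tpr.
#' @export
write_roc_csv <- function(x, path) {
  stopifnot(inherits(x, "roc_curve"))
  utils::write.csv(data.frame(threshold = x$thresholds, fpr = x$fpr,
                              tpr = x$tpr),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' DeLong variance of a single AUC
#'
#' The nonparametric variance estimate
#' `var(case placements)/m + var(control placements)/n`.
#'
#' @inheritParams delong_placements
#' @return A single non-negative number.
#' @export
delong_variance <- function(scores, labels, direction = "auto") {
  pl <- delong_placements(scores, labels, direction)
  stats::var(pl$case) / length(pl$case) +
    stats::var(pl$control) / length(pl$control)
}

#' DeLong's paired test for two correlated AUCs
#'
#' Compares the AUCs of two biomarkers measured on the same samples. The
#' variance of the AUC difference combines the 2x2 covariance matrices of
#' the paired placement vectors: `var = (S11 + S22 - 2 S12)/m` for cases
#' plus the control analogue over `n`; `z = (auc_a - auc_b)/sqrt(var)` is
#' referred to a standard normal (two-sided). A degenerate zero variance
#' (e.g. a biomarker compared with itself) yields `z = 0, p = 1`.
#'
#' @param scores_a,scores_b two score vectors over the same samples, in the
#'   same sample order.
#' @param labels case/control labels shared by both biomarkers.
#' @param direction_a,direction_b per-biomarker orientation (see
#'   [delong_placements()]).
#' @return An object of class `roc_comparison`: list with `auc_a`, `auc_b`,
#'   `var_diff`, `z`, `p.value`, `direction_a`, `direction_b`, `n_case`,
#'   `n_control`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels,
                               direction_a = "auto", direction_b = "auto") {
  if (length(scores_a) != length(scores_b))
    stop("paired biomarkers must score the same samples", call. = FALSE)
  label <- .as_label01(labels, length(scores_a))
  pa <- delong_placements(scores_a, label, direction_a)
  pb <- delong_placements(scores_b, label, direction_b)
  m <- sum(label == 1); n <- sum(label == 0)
  sx <- stats::cov(cbind(pa$case, pb$case))
  sy <- stats::cov(cbind(pa$control, pb$control))
  v <- (sx[1, 1] + sx[2, 2] - 2 * sx[1, 2]) / m +
       (sy[1, 1] + sy[2, 2] - 2 * sy[1, 2]) / n
  v <- max(v, 0)
  d <- pa$auc - pb$auc
  if (v == 0) {
    if (abs(d) > 1e-12)
      warning("zero DeLong variance with unequal AUCs", call. = FALSE)
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = v, z = z,
                 p.value = p, direction_a = pa$direction,
                 direction_b = pb$direction, n_case = m, n_control = n),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf(paste0("DeLong paired AUC comparison: AUC_a = %.4f, ",
                     "AUC_b = %.4f, z = %.3f, p = %.4g\n"),
              x$auc_a, x$auc_b, x$z, x$p.value))
  invisible(x)
}

#' Pairwise DeLong comparisons across biomarker columns
#'
#' Runs [delong_paired_test()] for every pair of the given score columns of
#' a biomarker table, on identical samples.
#'
#' @param x a `biomarker_scores` object.
#' @param columns score columns to compare (default all).
#' @param directions named character vector of per-column orientations
#'   (`"auto"` by default).
#' @param include_self also emit the diagnostic self-comparison rows
#'   (`z = 0, p = 1`).
#' @return A data.frame with one row per pair: `biomarker_a`, `biomarker_b`,
#'   `auc_a`, `auc_b`, `z`, `p.value`, plus resolved directions.
#' @export
compare_biomarkers <- function(x, columns = score_columns(x),
                               directions = NULL, include_self = FALSE) {
  stopifnot(inherits(x, "biomarker_scores"))
  lab <- x$labels
  dir_of <- function(nm) {
    if (!is.null(directions) && nm %in% names(directions))
      directions[[nm]] else "auto"
  }
  rows <- list()
  for (i in seq_along(columns)) {
    jstart <- if (include_self) i else i + 1L
    for (j in seq.int(jstart, length.out = max(0L, length(columns) - jstart + 1L))) {
      a <- columns[i]; b <- columns[j]
      cmp <- delong_paired_test(x$table[[a]], x$table[[b]], lab,
                                dir_of(a), dir_of(b))
      rows[[length(rows) + 1L]] <-
        data.frame(biomarker_a = a, biomarker_b = b,
                   auc_a = cmp$auc_a, auc_b = cmp$auc_b,
                   direction_a = cmp$direction_a,
                   direction_b = cmp$direction_b,
                   z = cmp$z, p.value = cmp$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum group test
#'
#' Two-tailed Wilcoxon (Mann-Whitney) test of a score difference between two
#' groups, as used for case/control biomarker comparisons. The exact null
#' distribution is used when `n_x * n_y <= 400` and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' Delegates to [stats::wilcox.test()] with the branch chosen explicitly.
#'
#' @param x,y numeric score vectors for the two groups (both non-empty).
#' @return List with `statistic` (Mann-Whitney U for `x` vs `y`), `p.value`,
#'   `n_x`, `n_y`, `exact` (which branch was used) and `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value  # exact: 0.1
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_x = length(x), n_y = length(y), exact = exact,
       method = "Wilcoxon rank-sum test")
}

#' Ordinary least squares with coefficient t-tests
#'
#' Fits `response ~ intercept + covariates` by QR least squares and reports
#' the standard per-coefficient summary: estimate, SE, t and the two-sided
#' Pr(>|t|) on n - p degrees of freedom, plus residual variance and R^2.
#'
#' @param response numeric response vector.
#' @param covariates numeric matrix or data.frame of covariates (one column
#'   per term), `nrow == length(response)`.
#' @param names optional covariate names (defaults to column names).
#' @return An object of class `linear_fit`: list with `coefficients` (a
#'   data.frame: term, estimate, se, t, p), `sigma2`, `r.squared`, `df`,
#'   `n`, `fitted`, `residuals`.
#' @export
fit_ols <- function(response, covariates, names = NULL) {
  y <- as.numeric(response)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y))
    stop("covariates have ", nrow(X), " rows but response has ", length(y),
         call. = FALSE)
  if (is.null(names)) names <- colnames(X)
  if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- names
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  if (n <= p)
    stop("need more observations (", n, ") than coefficients (", p, ")",
         call. = FALSE)
  qrX <- qr(Xi)
  if (qrX$rank < p) {
    dropped <- colnames(Xi)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(Xi, y)
  res <- fit$residuals
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtX_inv <- matrix(NA_real_, p, p)
  XtX_inv[qrX$pivot, qrX$pivot] <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  est <- fit$coefficients
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  structure(list(coefficients = data.frame(term = colnames(Xi),
                                           estimate = unname(est),
                                           se = unname(se),
                                           t = unname(tval),
                                           p = unname(pval),
                                           stringsAsFactors = FALSE),
                 sigma2 = sigma2, r.squared = r2, df = df, n = n,
                 fitted = fit$fitted.values, residuals = res),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit (n = %d, df = %d, R^2 = %.4f)\n", x$n, x$df,
              x$r.squared))
  print.data.frame(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.linear_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
residuals.linear_fit <- function(object, ...) object$residuals
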