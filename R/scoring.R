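#' Within-sample two-set t-score
#'
#' The repression-type biomarker: for one sample, a two-sample t-statistic
#' comparing the expression of a signature's up-regulated genes against its
#' down-regulated genes,
#' \deqn{t = (m_{up} - m_{down}) / \sqrt{s^2_{up}/n_{up} + s^2_{down}/n_{down}}}
#' with unbiased variances (Welch form; a pooled-variance variant is
#' available for sensitivity checks). Repression of the up-targets drives the
#' score downward, so affected samples trend negative.
#'
#' @param column named numeric vector of per-gene log-expression for one
#'   sample, or an unnamed vector aligned with `sig` via `gene_ids`.
#' @param sig a [gene_signature()] with non-empty up and down sets; at least
#'   2 genes of each set must be present among the names of `column`.
#' @param pooled use the pooled-variance (Student) denominator instead of
#'   Welch.
#' @return A single number. Zero-variance degenerate input with equal means
#'   returns 0 with a warning; zero variance with unequal means is an error.
#' @examples
#' sig <- gene_signature("S", up = c("g1", "g2"), down = c("g3", "g4"))
#' tscore_biomarker(c(g1 = 3, g2 = 5, g3 = 1, g4 = 3), sig)
#' @export
tscore_biomarker <- function(column, sig, pooled = FALSE) {
  stopifnot(inherits(sig, "gene_signature"))
  if (is.null(names(column)))
    stop("'column' must be named by gene ID", call. = FALSE)
  up <- column[intersect(sig$up, names(column))]
  down <- column[intersect(sig$down, names(column))]
  .tscore(up, down, pooled = pooled, context = sig$name)
}

# core two-set t; up/down are the value vectors
.tscore <- function(up, down, pooled = FALSE, context = "signature") {
  n1 <- length(up); n2 <- length(down)
  if (n1 < 2L || n2 < 2L)
    stop(context, ": need >=2 genes present in each of the up and down sets",
         call. = FALSE)
  m1 <- mean(up); m2 <- mean(down)
  v1 <- stats::var(up); v2 <- stats::var(down)
  se2 <- if (pooled) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    sp * (1 / n1 + 1 / n2)
  } else {
    v1 / n1 + v2 / n2
  }
  if (se2 == 0) {
    if (m1 == m2) {
      warning(context, ": zero variance in both sets with equal means; ",
              "t-score set to 0", call. = FALSE)
      return(0)
    }
    stop(context, ": degenerate variance (zero SE with unequal means)",
         call. = FALSE)
  }
  (m1 - m2) / sqrt(se2)
}

#' Mean-expression biomarker
#'
#' The activation-type biomarker: the arithmetic mean of a sample's
#' log-expression over the signature's up-regulated genes present in the
#' data.
#'
#' @inheritParams tscore_biomarker
#' @return A single number in log-expression units.
#' @export
mean_expression_biomarker <- function(column, sig) {
  stopifnot(inherits(sig, "gene_signature"))
  if (is.null(names(column)))
    stop("'column' must be named by gene ID", call. = FALSE)
  up <- column[intersect(sig$up, names(column))]
  if (length(up) == 0L)
    stop(sig$name, ": no up-set genes present", call. = FALSE)
  mean(up)
}

# vectorised column statistics used by score_biomarkers / simulations
.col_mean_var <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  v <- (colSums(m * m) - n * mu * mu) / (n - 1)
  v[v < 0] <- 0  # guard tiny negative from cancellation
  list(mean = mu, var = v, n = n)
}

.tscore_matrix <- function(values, sig, pooled = FALSE) {
  up <- intersect(sig$up, rownames(values))
  down <- intersect(sig$down, rownames(values))
  if (length(up) < 2L || length(down) < 2L)
    stop(sig$name, ": need >=2 genes present in each of the up and down sets",
         call. = FALSE)
  a <- .col_mean_var(values[up, , drop = FALSE])
  b <- .col_mean_var(values[down, , drop = FALSE])
  se2 <- if (pooled) {
    sp <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2)
    sp * (1 / a$n + 1 / b$n)
  } else {
    a$var / a$n + b$var / b$n
  }
  num <- a$mean - b$mean
  t <- num / sqrt(se2)
  deg <- se2 == 0
  if (any(deg)) {
    if (any(deg & num != 0))
      stop(sig$name, ": degenerate variance (zero SE with unequal means) in ",
           "sample(s) ", paste(colnames(values)[deg & num != 0],
                               collapse = ", "), call. = FALSE)
    warning(sig$name, ": zero variance with equal means in ", sum(deg),
            " sample(s); t-score set to 0", call. = FALSE)
    t[deg] <- 0
  }
  t
}

#' Score a matrix against a set of gene signatures
#'
#' The central evaluation step: computes one biomarker value per sample per
#' signature. Signatures with a non-empty down set are scored with the
#' two-set t-score ([tscore_biomarker()]); up-only signatures are scored
#' with mean expression ([mean_expression_biomarker()]). Signature genes
#' absent from the matrix are dropped (with a coverage warning), never
#' imputed.
#'
#' @param x a log-scale `expr_mat`.
#' @param sigs a list of [gene_signature()] objects (order defines column
#'   order of the result).
#' @param labels a [sample_labels()] object aligned with the columns of `x`.
#' @param pooled use pooled-variance t-scores (see [tscore_biomarker()]).
#' @param quiet suppress signature-coverage warnings.
#' @return An object of class `biomarker_scores`: list with
#'   \item{table}{data.frame with columns `sample`, one numeric column per
#'     signature, and `group` (`"case"`/`"control"`)}
#'   \item{signatures}{the restricted signatures actually scored}
#'   \item{types}{`"tscore"` or `"mean"` per signature}
#'   \item{labels}{the `sample_labels` used}
#' @seealso [summary.biomarker_scores()] for group comparisons,
#'   [write_results_csv()] for the Results.csv contract.
#' @export
score_biomarkers <- function(x, sigs, labels, pooled = FALSE, quiet = FALSE) {
  stopifnot(inherits(x, "expr_mat"))
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  if (!length(sigs)) stop("no signatures supplied", call. = FALSE)
  stopifnot(inherits(labels, "sample_labels"))
  if (length(labels$label) != ncol(x$values))
    stop("labels cover ", length(labels$label), " samples but matrix has ",
         ncol(x$values), call. = FALSE)
  if (!x$is_log)
    warning("matrix is not flagged as log scale; biomarkers are defined on ",
            "log expression", call. = FALSE)
  used <- lapply(sigs, intersect_signature, x = x, quiet = quiet)
  nms <- vapply(used, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate signature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  types <- ifelse(vapply(used, function(s) length(s$down) > 0L, logical(1)),
                  "tscore", "mean")
  scores <- lapply(seq_along(used), function(i) {
    s <- used[[i]]
    tryCatch({
      if (types[i] == "tscore")
        .tscore_matrix(x$values, s, pooled = pooled)
      else
        colMeans(x$values[s$up, , drop = FALSE])
    }, error = function(e)
      stop("scoring signature '", s$name, "': ", conditionMessage(e),
           call. = FALSE))
  })
  tab <- data.frame(sample = sample_ids(x), stats::setNames(scores, nms),
                    group = ifelse(labels$label == 1L, "case", "control"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, signatures = used,
                 types = stats::setNames(types, nms), labels = labels),
            class = "biomarker_scores")
}

#' @export
print.biomarker_scores <- function(x, ...) {
  cat(sprintf("biomarker scores: %d samples (%d case / %d control), %d signatures\n",
              nrow(x$table), sum(x$table$group == "case"),
              sum(x$table$group == "control"), length(x$signatures)))
  for (nm in names(x$types))
    cat(sprintf("  %s  [%s]\n", nm,
                if (x$types[[nm]] == "tscore") "two-set t-score"
                else "mean expression"))
  invisible(x)
}

#' @export
as.data.frame.biomarker_scores <- function(x, ...) x$table

#' Signature score columns of a biomarker table
#' @param x a `biomarker_scores` object.
#' @return Character vector of signature column names.
#' @export
score_columns <- function(x) {
  stopifnot(inherits(x, "biomarker_scores"))
  setdiff(names(x$table), c("sample", "group"))
}

#' Group comparison summary of biomarker scores
#'
#' For each signature: per-group n, median, quartiles and box-plot whisker
#' bounds (whiskers clamped at 1.5 IQR beyond the quartiles, i.e.
#' min\[1.5*IQR, max(observed value)\]), plus the two-tailed Wilcoxon
#' rank-sum p-value for the case/control difference.
#'
#' @param object a `biomarker_scores` object.
#' @param ... unused.
#' @return A data.frame with one row per (signature, group) and the Wilcoxon
#'   p-value repeated per signature; class `summary.biomarker_scores`.
#' @export
summary.biomarker_scores <- function(object, ...) {
  tab <- object$table
  rows <- lapply(score_columns(object), function(nm) {
    p <- wilcoxon_rank_sum(tab[[nm]][tab$group == "case"],
                           tab[[nm]][tab$group == "control"])$p.value
    do.call(rbind, lapply(c("case", "control"), function(g) {
      v <- tab[[nm]][tab$group == g]
      q <- stats::quantile(v, c(.25, .5, .75), names = FALSE, type = 7)
      iqr <- q[3] - q[1]
      data.frame(signature = nm, group = g, n = length(v),
                 median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = max(min(v), q[1] - 1.5 * iqr),
                 whisker_high = min(max(v), q[3] + 1.5 * iqr),
                 wilcoxon_p = p, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.biomarker_scores", "data.frame")
  out
}

#' @export
print.summary.biomarker_scores <- function(x, ...) {
  cat("biomarker group comparison (two-tailed Wilcoxon rank-sum)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Box plots of biomarker scores by group
#'
#' One case-vs-control box plot per signature, annotated with the
#' two-tailed Wilcoxon p-value, mirroring the scoring app's output plots.
#'
#' @param x a `biomarker_scores` object.
#' @param which signature names to plot (default all).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.biomarker_scores <- function(x, which = score_columns(x), ...) {
  s <- summary(x)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)))
  on.exit(graphics::par(old))
  for (nm in which) {
    p <- s$wilcoxon_p[s$signature == nm][1L]
    graphics::boxplot(x$table[[nm]] ~ factor(x$table$group,
                                             c("control", "case")),
                      xlab = "", ylab = "score", main = nm,
                      sub = sprintf("Wilcoxon P = %.3g", p), ...)
  }
  invisible(x)
}

#' Per-sample mean of selected biomarker columns
#'
#' E.g. the average of several activation biomarkers for each sample.
#'
#' @param x a `biomarker_scores` object or its `table` data.frame.
#' @param columns signature column names to average.
#' @return Named numeric vector (one value per sample).
#' @export
mean_of_biomarkers <- function(x, columns) {
  tab <- if (inherits(x, "biomarker_scores")) x$table else x
  missing_cols <- setdiff(columns, names(tab))
  if (length(missing_cols))
    stop("unknown biomarker column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- rowMeans(as.matrix(tab[, columns, drop = FALSE]))
  names(out) <- tab$sample
  out
}

#' Call per-sample signature positivity
#'
#' A sample (typically a single cell) is signature-positive when at least
#' `min_genes` of the signature's up-regulated genes exceed the detection
#' threshold. With the defaults (`min_genes = 1`, `detection_threshold = 0`)
#' "positive" means any detectable expression of any signature gene.
#'
#' @param x an `expr_mat`.
#' @param sig a [gene_signature()].
#' @param min_genes minimum number of detected signature genes, k >= 1.
#' @param detection_threshold expression strictly above this counts as
#'   detected (default 0).
#' @param quiet suppress signature-coverage warnings.
#' @return A data.frame with columns `sample`, `n_detected`, `is_positive`.
#' @export
call_positivity <- function(x, sig, min_genes = 1L, detection_threshold = 0,
                            quiet = TRUE) {
  stopifnot(inherits(x, "expr_mat"))
  min_genes <- as.integer(min_genes)
  if (min_genes < 1L) stop("min_genes must be >= 1", call. = FALSE)
  if (detection_threshold < 0)
    stop("detection_threshold must be >= 0", call. = FALSE)
  s <- intersect_signature(sig, x, quiet = quiet)
  if (min_genes > length(s$up))
    stop("min_genes = ", min_genes, " exceeds the ", length(s$up),
         " up-set genes present for signature '", sig$name, "'",
         call. = FALSE)
  n_det <- colSums(x$values[s$up, , drop = FALSE] > detection_threshold)
  data.frame(sample = sample_ids(x), n_detected = as.integer(n_det),
             is_positive = n_det >= min_genes, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write biomarker scores in the Results.csv contract
#'
#' Header `sample,<sig1>,...,<sigK>,group`; one row per sample in matrix
#' order; values at full precision so reruns are byte-identical and the file
#' round-trips through [read_results_csv()].
#'
#' @param x a `biomarker_scores` object.
#' @param path output path (conventionally `Results.csv`).
#' @export
write_results_csv <- function(x, path) {
  stopifnot(inherits(x, "biomarker_scores"))
  tab <- x$table
  num <- score_columns(x)
  out <- tab
  for (nm in num)
    out[[nm]] <- format(tab[[nm]], digits = 17, scientific = FALSE,
                        trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Results.csv biomarker table
#'
#' @param path path to a file written by [write_results_csv()].
#' @return A `biomarker_scores`-shaped object (without signature gene lists).
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "group")
  if (!all(need %in% names(tab)))
    stop("Results table must have 'sample' and 'group' columns",
         call. = FALSE)
  if (!all(tab$group %in% c("case", "control")))
    stop("group column must be 'case'/'control'", call. = FALSE)
  sc <- setdiff(names(tab), need)
  labels <- sample_labels(which(tab$group == "case"), nrow(tab))
  structure(list(table = tab[, c("sample", sc, "group")],
                 signatures = NULL,
                 types = stats::setNames(rep(NA_character_, length(sc)), sc),
                 labels = labels),
            class = "biomarker_scores")
}
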