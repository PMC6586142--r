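#' Read a per-sample severity covariate table
#'
#' CSV with a `sample` column matching the expression-matrix header plus any
#' number of numeric severity covariates (histopathology scores,
#' inflammation, MRI read-outs, fat fraction, ...). Missing values are
#' allowed and are excluded pairwise at fit time.
#'
#' @param path path to a CSV file.
#' @return A data.frame with `sample` first.
#' @export
read_severity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% names(tab))
    stop("severity table needs a 'sample' column", call. = FALSE)
  for (nm in setdiff(names(tab), "sample"))
    if (!is.numeric(tab[[nm]]))
      stop("severity covariate '", nm, "' is not numeric", call. = FALSE)
  tab[, c("sample", setdiff(names(tab), "sample"))]
}

# align a severity table to a biomarker table; error on unmatched samples
.align_severity <- function(tab, severity) {
  missing_s <- setdiff(tab$sample, severity$sample)
  extra_s <- setdiff(severity$sample, tab$sample)
  if (length(missing_s) && length(missing_s) == nrow(tab))
    stop("severity table matches none of the scored samples; unmatched: ",
         paste(utils::head(extra_s, 5), collapse = ", "), call. = FALSE)
  severity[match(tab$sample, severity$sample), , drop = FALSE]
}

#' Associate biomarkers with severity covariates by linear models
#'
#' Fits, for each severity covariate, one univariate OLS model per biomarker
#' (`covariate ~ biomarker`) and, optionally, multivariate models using
#' several biomarkers as separate covariates jointly (e.g. a repression
#' score plus a mean activation score, to test independent association).
#' Per-coefficient two-sided Pr(>|t|) values are reported unadjusted; the
#' total number of fits is recorded.
#'
#' @param x a `biomarker_scores` object.
#' @param severity a severity data.frame (see [read_severity_table()]); rows
#'   are matched to `x` by `sample`. Samples without severity values (NA)
#'   are dropped per fit (pairwise complete cases).
#' @param biomarkers biomarker columns to fit (default all).
#' @param covariates severity covariates to fit (default all numeric
#'   columns).
#' @param multivariate list of character vectors of biomarker columns to fit
#'   jointly against each covariate.
#' @param min_n minimum complete cases per fit; smaller fits are skipped
#'   with a warning.
#' @return Object of class `severity_association`: list with `fits` (named
#'   list of [fit_ols()] results), `table` (tidy per-coefficient data.frame
#'   with covariate, model, term, estimate, se, t, p, n, r.squared) and
#'   `n_tests`.
#' @export
associate_biomarkers <- function(x, severity,
                                 biomarkers = score_columns(x),
                                 covariates = setdiff(names(severity),
                                                      "sample"),
                                 multivariate = list(), min_n = 3L) {
  stopifnot(inherits(x, "biomarker_scores"))
  sev <- .align_severity(x$table, severity)
  fits <- list()
  rows <- list()
  specs <- c(lapply(biomarkers, function(b) list(terms = b,
                                                 model = "univariate")),
             lapply(multivariate, function(b) list(terms = b,
                                                   model = "multivariate")))
  for (cv in covariates) {
    yall <- sev[[cv]]
    for (sp in specs) {
      terms <- sp$terms
      bad <- setdiff(terms, names(x$table))
      if (length(bad))
        stop("unknown biomarker column(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      X <- as.matrix(x$table[, terms, drop = FALSE])
      keep <- stats::complete.cases(cbind(yall, X))
      label <- paste0(cv, " ~ ", paste(terms, collapse = " + "))
      if (sum(keep) < max(min_n, length(terms) + 2L)) {
        warning("skipping '", label, "': only ", sum(keep),
                " complete cases", call. = FALSE)
        next
      }
      fit <- fit_ols(yall[keep], X[keep, , drop = FALSE], names = terms)
      fits[[label]] <- fit
      cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
      rows[[length(rows) + 1L]] <-
        data.frame(covariate = cv, model = sp$model, term = cf$term,
                   estimate = cf$estimate, se = cf$se, t = cf$t, p = cf$p,
                   n = fit$n, r.squared = fit$r.squared,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(covariate = character(), model = character(),
               term = character(), estimate = numeric(), se = numeric(),
               t = numeric(), p = numeric(), n = integer(),
               r.squared = numeric())
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab, n_tests = nrow(tab)),
            class = "severity_association")
}

#' @export
print.severity_association <- function(x, ...) {
  cat(sprintf("biomarker-severity linear models (%d coefficient tests, unadjusted p)\n",
              x$n_tests))
  print.data.frame(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

# accept a score column name or a ready numeric vector aligned with tab
.score_vector <- function(tab, spec, what) {
  if (is.character(spec) && length(spec) == 1L) {
    if (!spec %in% names(tab))
      stop("unknown ", what, " column '", spec, "'", call. = FALSE)
    return(tab[[spec]])
  }
  v <- as.numeric(spec)
  if (length(v) != nrow(tab))
    stop(what, " vector length ", length(v), " does not match ", nrow(tab),
         " samples", call. = FALSE)
  v
}

#' Data-driven repression-score threshold
#'
#' The repression cut point used for stratification: the mean repression
#' score among the samples whose activation score lies strictly above
#' `activation_threshold` (the "high activation" samples).
#'
#' @param x a `biomarker_scores` object (or its table).
#' @param activation activation score: a column name or numeric vector.
#' @param repression repression score: a column name or numeric vector.
#' @param activation_threshold samples with activation strictly above this
#'   define the high-activation group.
#' @return The mean repression score of the high-activation samples.
#' @export
derive_repression_threshold <- function(x, activation, repression,
                                        activation_threshold) {
  tab <- if (inherits(x, "biomarker_scores")) x$table else x
  act <- .score_vector(tab, activation, "activation")
  repr <- .score_vector(tab, repression, "repression")
  hi <- act > activation_threshold
  if (sum(hi) < 2L)
    stop("need >=2 samples with activation score above ",
         activation_threshold, " (found ", sum(hi), ")", call. = FALSE)
  mean(repr[hi])
}

#' Smallest activation threshold above which all samples are active
#'
#' Scans the observed activation scores in increasing order and returns the
#' smallest value t such that every sample scoring strictly above t is
#' flagged active (ties broken toward the smaller threshold). Returns `-Inf`
#' when every sample is active.
#'
#' @param activation numeric activation scores.
#' @param active logical (or 0/1) per-sample active-disease flag.
#' @return A single threshold value.
#' @export
minimal_activation_threshold <- function(activation, active) {
  active <- as.logical(active)
  stopifnot(length(activation) == length(active), !anyNA(active))
  if (all(active)) return(-Inf)
  for (t in sort(unique(activation))) {
    if (all(active[activation > t])) return(t)
  }
  max(activation)
}

#' Stratified activity ratio among high-activation samples
#'
#' Restricts to samples with activation score strictly above
#' `activation_threshold`, splits them at the repression score (strictly
#' below `repression_threshold` = high repression; at or above = low
#' repression), and reports the ratio of mean activity between the
#' high-repression and low-repression strata.
#'
#' @inheritParams derive_repression_threshold
#' @param activity per-sample numeric disease-activity measure: a severity
#'   column name present in `x$table` or a numeric vector.
#' @param repression_threshold repression cut point (e.g. from
#'   [derive_repression_threshold()]).
#' @return Object of class `stratification`: list with the thresholds,
#'   per-sample `group` assignment (`"high_repression"`, `"low_repression"`,
#'   `"excluded"`), stratum sizes and means, `activity_ratio` and
#'   `ratio_defined` (FALSE when the low-repression mean is zero).
#' @export
stratified_activity_ratio <- function(x, activity, activation, repression,
                                      activation_threshold,
                                      repression_threshold) {
  tab <- if (inherits(x, "biomarker_scores")) x$table else x
  act <- .score_vector(tab, activation, "activation")
  repr <- .score_vector(tab, repression, "repression")
  y <- .score_vector(tab, activity, "activity")
  hi <- act > activation_threshold
  group <- rep("excluded", nrow(tab))
  group[hi & repr < repression_threshold] <- "high_repression"
  group[hi & repr >= repression_threshold] <- "low_repression"
  n_hi <- sum(group == "high_repression")
  n_lo <- sum(group == "low_repression")
  if (n_hi == 0L || n_lo == 0L)
    stop("empty stratum among high-activation samples (",
         n_hi, " high-repression, ", n_lo, " low-repression)", call. = FALSE)
  m_hi <- mean(y[group == "high_repression"])
  m_lo <- mean(y[group == "low_repression"])
  defined <- m_lo != 0
  if (!defined)
    warning("low-repression stratum has zero mean activity; ratio undefined",
            call. = FALSE)
  structure(list(activation_threshold = activation_threshold,
                 repression_threshold = repression_threshold,
                 group = group, n_high_repression = n_hi,
                 n_low_repression = n_lo,
                 mean_activity_high = m_hi, mean_activity_low = m_lo,
                 activity_ratio = if (defined) m_hi / m_lo else NA_real_,
                 ratio_defined = defined),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf(paste0("stratification of high-activation samples ",
                     "(activation > %.4g, repression < %.4g):\n"),
              x$activation_threshold, x$repression_threshold))
  cat(sprintf("  high repression: n = %d, mean activity = %.4g\n",
              x$n_high_repression, x$mean_activity_high))
  cat(sprintf("  low repression:  n = %d, mean activity = %.4g\n",
              x$n_low_repression, x$mean_activity_low))
  if (x$ratio_defined)
    cat(sprintf("  activity ratio (high/low) = %.3g\n", x$activity_ratio))
  else cat("  activity ratio undefined (zero denominator)\n")
  invisible(x)
}

#' ROC comparison restricted to a positivity-defined subset
#'
#' Restricts a biomarker table to the signature-positive (or -negative)
#' samples, recomputes each biomarker's ROC curve there, and runs pairwise
#' DeLong tests among the biomarkers on the identical subset. This is the
#' workflow that asks whether a biomarker stays discriminative on cells in
#' which an activation signature is undetectable.
#'
#' @param x a `biomarker_scores` object.
#' @param positivity data.frame from [call_positivity()], matched to `x` by
#'   `sample`.
#' @param which `"positive"` or `"negative"`: which subset to keep.
#' @param columns biomarker columns to compare (default all).
#' @param directions optional named per-column orientations.
#' @return List with `subset`, `samples`, `n_case`, `n_control`, `rocs`
#'   (named list of [roc_curve()] objects), and `comparisons` (pairwise
#'   DeLong data.frame).
#' @export
subset_roc_comparison <- function(x, positivity,
                                  which = c("negative", "positive"),
                                  columns = score_columns(x),
                                  directions = NULL) {
  stopifnot(inherits(x, "biomarker_scores"))
  which <- match.arg(which)
  idx <- match(x$table$sample, positivity$sample)
  if (anyNA(idx))
    stop("positivity calls missing for sample(s): ",
         paste(utils::head(x$table$sample[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  pos <- positivity$is_positive[idx]
  keep <- if (which == "positive") pos else !pos
  sub_tab <- x$table[keep, , drop = FALSE]
  n_case <- sum(sub_tab$group == "case")
  n_ctrl <- sum(sub_tab$group == "control")
  if (n_case == 0L || n_ctrl == 0L)
    stop("the ", which, "-subset lacks a class (", n_case, " cases, ",
         n_ctrl, " controls)", call. = FALSE)
  sub <- x
  sub$table <- sub_tab
  sub$labels <- sample_labels(which(sub_tab$group == "case"), nrow(sub_tab))
  lab01 <- as.integer(sub_tab$group == "case")
  rocs <- lapply(columns, function(nm) {
    d <- if (!is.null(directions) && nm %in% names(directions))
      directions[[nm]] else "auto"
    roc_curve(sub_tab[[nm]], lab01, direction = d)
  })
  names(rocs) <- columns
  cmp <- compare_biomarkers(sub, columns = columns, directions = directions)
  list(subset = which, samples = sub_tab$sample,
       n_case = n_case, n_control = n_ctrl, rocs = rocs, comparisons = cmp)
}
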