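#' Construct an expression matrix
#'
#' Lightweight container for a genes x samples numeric matrix. Rows are gene
#' identifiers (Ensembl-style strings), columns are sample or cell
#' identifiers. Two flags track the normalization state: whether values are
#' log-scale and whether they have been quantile normalized.
#'
#' @param values numeric matrix (genes x samples) with unique, non-empty
#'   rownames and colnames.
#' @param is_log logical; `TRUE` if values are log-expression, `FALSE` for
#'   raw (non-negative) counts or intensities.
#' @param is_quantile_normalized logical; `TRUE` if every column holds the
#'   same multiset of values.
#' @return An object of class `expr_mat`: a list with elements `values`,
#'   `is_log` and `is_quantile_normalized`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("ENSG", 1:3), c("s1", "s2")))
#' expression_matrix(m, is_log = FALSE)
#' @export
expression_matrix <- function(values, is_log = FALSE,
                              is_quantile_normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  dup_g <- unique(gid[duplicated(gid)])
  if (length(dup_g))
    stop("duplicate gene IDs: ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (!is_log && any(values < 0))
    stop("raw expression values must be non-negative", call. = FALSE)
  structure(list(values = values,
                 is_log = isTRUE(is_log),
                 is_quantile_normalized = isTRUE(is_quantile_normalized)),
            class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%s%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_log) "log scale" else "raw scale",
              if (x$is_quantile_normalized) ", quantile normalized" else ""))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x an `expr_mat` object.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a delimited expression table
#'
#' Reads a genes x samples table: header row of sample IDs, first column of
#' gene IDs, numeric cells. This is the input contract of the scoring app:
#' a table of (typically log-normalized) data where rows carry Ensembl gene
#' IDs and columns are samples.
#'
#' @param path path to the file.
#' @param delimiter field separator; `"\t"` (default) or `","` etc.
#' @param is_log,is_quantile_normalized caller-declared normalization state
#'   of the stored values (the file format itself does not record it).
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, delimiter = "\t", is_log = TRUE,
                                  is_quantile_normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  # header may or may not carry a leading cell for the gene-ID column
  n_fields <- lengths(body)
  if (length(unique(n_fields)) != 1L)
    stop("ragged rows: row(s) ",
         paste(which(n_fields != n_fields[1L]) + 1L, collapse = ", "),
         " have a different number of fields", call. = FALSE)
  ncol_body <- n_fields[1L]
  if (length(header) == ncol_body) {
    samples <- header[-1L]
  } else if (length(header) == ncol_body - 1L) {
    samples <- header
  } else {
    stop("header has ", length(header), " fields but data rows have ",
         ncol_body, call. = FALSE)
  }
  genes <- vapply(body, `[[`, character(1), 1L)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at data row %d (gene %s), column %d",
                   body[[i]][-1L][j], i, genes[i], j), call. = FALSE)
    }
    vals[i, ] <- v
  }
  expression_matrix(vals, is_log = is_log,
                    is_quantile_normalized = is_quantile_normalized)
}

#' Write an expression matrix as a delimited table
#'
#' Inverse of [read_expression_table()]: header row of sample IDs (with a
#' leading `gene_id` cell), one row per gene. Values are written at full
#' precision so a read/write round trip reproduces them exactly.
#'
#' @param x an `expr_mat`.
#' @param path output path.
#' @param delimiter field separator.
#' @export
write_expression_table <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "expr_mat"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x$values)), collapse = delimiter),
             con)
  body <- apply(x$values, 1L, function(v)
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = delimiter))
  writeLines(paste(rownames(x$values), body, sep = delimiter), con)
  invisible(path)
}

#' Log-transform raw expression values
#'
#' Applies `log2(v + pseudocount)` elementwise. The default pseudocount of 1
#' (so zero counts map to zero) is the dominant RNA-seq convention; both the
#' base and offset are configurable through `pseudocount`.
#'
#' @param x a raw-scale `expr_mat` with non-negative values.
#' @param pseudocount offset added before taking log2; default 1.
#' @return An `expr_mat` with `is_log = TRUE`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$is_log)
    stop("already log-transformed", call. = FALSE)
  if (any(x$values < 0))
    stop("negative values cannot be log-transformed", call. = FALSE)
  out <- x
  out$values <- log2(x$values + pseudocount)
  out$is_log <- TRUE
  out
}

#' Quantile normalize an expression matrix
#'
#' Forces every sample (column) onto a common reference distribution: the
#' reference is the per-rank mean of the column-sorted values, and each value
#' is replaced by the reference value at its within-column rank. Ties within
#' a column receive the mean of the reference values over the tied rank span
#' (the Bolstad convention). Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param x an `expr_mat` with at least two samples.
#' @return An `expr_mat` with `is_quantile_normalized = TRUE`; afterwards the
#'   multiset of values in every column is identical and within-column rank
#'   order is preserved.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  if (ncol(x$values) < 2L)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  out <- x
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  out$values <- v
  out$is_quantile_normalized <- TRUE
  out
}
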