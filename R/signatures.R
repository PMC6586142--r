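#' Construct a gene signature
#'
#' A named gene set with up-regulated members and, optionally, down-regulated
#' members. Signatures with both sets are scored as a within-sample two-set
#' t-score (repression biomarkers); signatures with only an up set are scored
#' as mean expression (activation biomarkers).
#'
#' @param name signature name.
#' @param up character vector of up-regulated gene IDs (non-empty).
#' @param down character vector of down-regulated gene IDs (may be empty).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, up, down = character()) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("signature name must be a single non-empty string", call. = FALSE)
  if (length(up) == 0L)
    stop("signature '", name, "': up set is empty", call. = FALSE)
  both <- intersect(up, down)
  if (length(both))
    stop("signature '", name, "': genes in both up and down sets: ",
         paste(both, collapse = ", "), call. = FALSE)
  structure(list(name = name, up = up, down = down),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene signature '%s': %d up / %d down genes\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' GMT lines are tab-separated: set name, description, then member gene IDs.
#' Lines named `<name>__up` and `<name>__down` are paired into a single
#' two-set signature `<name>`; an `__up` line without a partner yields an
#' up-only signature. Plain set names (no suffix) are treated as up-only.
#'
#' @param path path to a GMT file.
#' @return A named list of [gene_signature()] objects, in file order of first
#'   appearance.
#' @export
read_gene_signatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no gene sets in ", path, call. = FALSE)
  up <- list(); down <- list(); order <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ", ln,
           call. = FALSE)
    nm <- f[1L]; genes <- unique(f[-(1:2)])
    if (grepl("__down$", nm)) {
      base <- sub("__down$", "", nm)
      down[[base]] <- c(down[[base]], genes)
    } else {
      base <- sub("__up$", "", nm)
      up[[base]] <- c(up[[base]], genes)
    }
    if (!(base %in% order)) order <- c(order, base)
  }
  orphan <- setdiff(names(down), names(up))
  if (length(orphan))
    stop("down set(s) without a matching up set: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  sigs <- lapply(order, function(nm)
    gene_signature(nm, up[[nm]], if (is.null(down[[nm]])) character()
                   else down[[nm]]))
  names(sigs) <- order
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param sigs a list of `gene_signature` objects.
#' @param path output path.
#' @export
write_gene_signatures <- function(sigs, path) {
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  lines <- unlist(lapply(sigs, function(s) {
    out <- paste(c(paste0(s$name, "__up"), "up-regulated members", s$up),
                 collapse = "\t")
    if (length(s$down))
      out <- c(out, paste(c(paste0(s$name, "__down"),
                            "down-regulated members", s$down),
                          collapse = "\t"))
    out
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a signature to the genes present in a matrix
#'
#' Genes absent from the matrix are dropped with a warning reporting the
#' coverage fraction of each set. An error is raised only when no up-set
#' gene is present at all.
#'
#' @param sig a `gene_signature`.
#' @param x an `expr_mat` (or character vector of gene IDs).
#' @param quiet suppress the coverage warning.
#' @return The restricted `gene_signature`, with attribute `coverage` giving
#'   the retained fraction of the up and down sets.
#' @export
intersect_signature <- function(sig, x, quiet = FALSE) {
  stopifnot(inherits(sig, "gene_signature"))
  ids <- if (inherits(x, "expr_mat")) gene_ids(x) else as.character(x)
  up <- intersect(sig$up, ids)
  down <- intersect(sig$down, ids)
  if (length(up) == 0L)
    stop("signature '", sig$name,
         "': no up-set genes present in the matrix", call. = FALSE)
  cov <- c(up = length(up) / length(sig$up),
           down = if (length(sig$down)) length(down) / length(sig$down)
                  else NA_real_)
  if (!quiet && (cov[["up"]] < 1 || (!is.na(cov[["down"]]) && cov[["down"]] < 1)))
    warning(sprintf("signature '%s': %d/%d up and %d/%d down genes present",
                    sig$name, length(up), length(sig$up),
                    length(down), length(sig$down)), call. = FALSE)
  out <- sig
  out$up <- up
  out$down <- down
  attr(out, "coverage") <- cov
  out
}

#' Construct sample labels from case column positions
#'
#' Matches the scoring-app label contract: a set of 1-based column numbers
#' marking the case (e.g. FSHD) samples; all remaining columns are assumed
#' controls.
#'
#' @param case_columns integer vector of 1-based case column positions.
#' @param n_samples total number of samples (columns).
#' @return An object of class `sample_labels`: list with `case_columns` and a
#'   0/1 integer vector `label` (1 = case).
#' @export
sample_labels <- function(case_columns, n_samples) {
  case_columns <- as.integer(case_columns)
  if (anyNA(case_columns) || anyDuplicated(case_columns))
    stop("case columns must be unique integers", call. = FALSE)
  if (length(case_columns) == 0L)
    stop("at least one case sample is required", call. = FALSE)
  if (any(case_columns < 1L | case_columns > n_samples))
    stop("case column number(s) out of range 1..", n_samples, ": ",
         paste(case_columns[case_columns < 1L | case_columns > n_samples],
               collapse = ", "), call. = FALSE)
  if (length(case_columns) >= n_samples)
    stop("at least one control sample is required", call. = FALSE)
  label <- integer(n_samples)
  label[case_columns] <- 1L
  structure(list(case_columns = sort(case_columns), label = label),
            class = "sample_labels")
}

#' @export
print.sample_labels <- function(x, ...) {
  cat(sprintf("sample labels: %d cases / %d controls\n",
              sum(x$label), sum(x$label == 0L)))
  invisible(x)
}

#' Read case sample labels from a single-column file
#'
#' @param path file with one 1-based case column number per line.
#' @param n_samples total number of samples in the expression matrix.
#' @return A [sample_labels()] object.
#' @export
read_sample_labels <- function(path, n_samples) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  raw <- trimws(raw[nzchar(trimws(raw))])
  if (!length(raw)) stop("no case column numbers in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals) || any(vals != round(vals)))
    stop("non-integer entry in label file: ",
         paste(raw[is.na(vals) | vals != round(vals)], collapse = ", "),
         call. = FALSE)
  sample_labels(as.integer(vals), n_samples)
}
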