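# shared fixture builders (all data generated in code)

make_expr <- function(values, is_log = TRUE, genes = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- if (is.null(genes))
      sprintf("ENSG%06d", seq_len(nrow(values))) else genes
  if (is.null(colnames(values)))
    colnames(values) <- if (is.null(samples))
      sprintf("s%02d", seq_len(ncol(values))) else samples
  expression_matrix(values, is_log = is_log)
}

# random expression matrix with a planted two-set signature
make_scored_fixture <- function(n_genes = 20, n_samples = 8, n_cases = 4,
                                seed = 42) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples, 5, 1), n_genes, n_samples,
                 dimnames = list(sprintf("ENSG%06d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  up <- rownames(vals)[1:5]; down <- rownames(vals)[6:10]
  act <- rownames(vals)[11:16]
  vals[up, seq_len(n_cases)] <- vals[up, seq_len(n_cases)] - 2
  vals[act, seq_len(n_cases)] <- vals[act, seq_len(n_cases)] + 2
  list(expr = expression_matrix(vals, is_log = TRUE),
       labels = sample_labels(seq_len(n_cases), n_samples),
       sigs = list(rep_sig = gene_signature("rep_sig", up, down),
                   act_sig = gene_signature("act_sig", act)))
}

write_expr_tsv <- function(expr, path = tempfile(fileext = ".tsv")) {
  write_expression_table(expr, path)
  path
}

# brute-force tie-aware AUC over all case-control pairs (independent oracle)
brute_auc <- function(scores, label, direction = "larger") {
  s <- if (direction == "smaller") -scores else scores
  x <- s[label == 1]; y <- s[label == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}
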