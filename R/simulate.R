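#' Planted effect size for a target binormal AUC (repression biomarker)
#'
#' For the two-set t-score, shifting every up-set gene by `-delta` and every
#' down-set gene by `+delta` in cases shifts the per-sample t-score by
#' `2 * delta / (sd * sqrt(1/n_up + 1/n_down))` standard deviations of its
#' sampling distribution (gene-baseline spread cancels from both the shift
#' and the spread). Under the binormal model the population AUC is
#' `Phi(d / sqrt(2))`, so the per-gene shift achieving a target AUC is
#' `delta = d * sd * sqrt(1/n_up + 1/n_down) / 2` with
#' `d = sqrt(2) * qnorm(auc)`.
#'
#' @param auc target population AUC in (0.5, 1).
#' @param noise_sd per-gene per-sample log2 noise SD.
#' @param n_up,n_down signature set sizes.
#' @return The per-gene log2 shift `delta`.
#' @export
repression_effect_for_auc <- function(auc, noise_sd, n_up, n_down) {
  stopifnot(auc > 0.5, auc < 1)
  d <- sqrt(2) * stats::qnorm(auc)
  d * noise_sd * sqrt(1 / n_up + 1 / n_down) / 2
}

#' @rdname repression_effect_for_auc
#' @param n_genes number of up-set genes of the mean-expression biomarker
#'   (its sampling SD is `noise_sd / sqrt(n_genes)`).
#' @export
activation_effect_for_auc <- function(auc, noise_sd, n_genes) {
  stopifnot(auc > 0.5, auc < 1)
  sqrt(2) * stats::qnorm(auc) * noise_sd / sqrt(n_genes)
}

#' Simulation configuration
#'
#' All generator parameters for the synthetic bulk-biopsy and single-cell
#' expression data. The defaults reproduce the study conditions the
#' analyses target: a bulk cohort of 34 cases and 9 controls with a
#' two-set repression signature of 311 up / 290 down genes and three
#' activation signatures of 114, 165 and 212 genes, planted at effects
#' calibrated to a population AUC of 0.93; and a single-cell population of
#' 5133 case and 1914 control cells in which every case cell carries a weak
#' repression program (target AUC 0.651) while only a burst fraction of
#' 19.7% of case cells (and a 7.8% leak fraction of control cells) carry a
#' joint activation burst.
#'
#' @param mode `"bulk"` or `"single_cell"`.
#' @param n_cases,n_controls number of case/control samples (bulk) or cells
#'   (single cell).
#' @param n_genes total genes; must hold the disjoint signatures.
#' @param n_up,n_down repression-signature set sizes.
#' @param activation_sizes named or unnamed integer vector of activation
#'   signature sizes.
#' @param baseline_mean,baseline_sd gene-level log2 baseline distribution.
#' @param noise_sd per-gene per-sample log2 noise SD.
#' @param delta_rep planted repression shift (log2; subtracted from up-set,
#'   added to down-set genes of case samples). `NULL` = calibrate from
#'   `target_auc_rep`.
#' @param delta_act planted activation shift (log2, added to all activation
#'   genes of bursting samples). `NULL` = calibrate from `target_auc_act`
#'   (bulk; using the largest activation set) or, in single-cell mode, a
#'   burst lifting the silent program (latent `activation_baseline`) to
#'   about two expected counts per gene.
#' @param target_auc_rep,target_auc_act calibration targets used when the
#'   deltas are `NULL`.
#' @param burst_fraction fraction of case samples/cells carrying the
#'   activation burst.
#' @param control_leak_fraction fraction of control cells spuriously
#'   bursting (single cell).
#' @param dropout_rate single-cell zero-inflation probability, in \[0, 1).
#' @param activation_baseline latent log2 baseline of activation genes in
#'   single-cell mode (low: the program is silent outside bursts).
#' @param sev_intercept,sev_rep_coef,sev_act_coef,sev_noise_sd bulk severity
#'   model: `activity = a + b * rep_dose + c * act_dose + N(0, sd)`.
#' @param seed integer seed; every generator output is a pure function of
#'   the config. Sub-seeds are derived per component (genes, doses, noise,
#'   bursts/dropout, severity) so changing one field perturbs only its
#'   component.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(mode = c("bulk", "single_cell"),
                       n_cases = if (mode == "bulk") 34L else 5133L,
                       n_controls = if (mode == "bulk") 9L else 1914L,
                       n_genes = if (mode == "bulk") 5000L else 1500L,
                       n_up = 311L, n_down = 290L,
                       activation_sizes = c(activation_a = 114L,
                                            activation_b = 165L,
                                            activation_c = 212L),
                       baseline_mean = if (mode == "bulk") 5 else 1.5,
                       baseline_sd = if (mode == "bulk") 2 else 1,
                       noise_sd = 1,
                       delta_rep = NULL, delta_act = NULL,
                       target_auc_rep = if (mode == "bulk") 0.93 else 0.651,
                       target_auc_act = 0.93,
                       burst_fraction = if (mode == "bulk") 1 else 0.197,
                       control_leak_fraction = if (mode == "bulk") 0
                                               else 0.078,
                       dropout_rate = if (mode == "bulk") 0 else 0.3,
                       activation_baseline = -15,
                       sev_intercept = 1, sev_rep_coef = 2,
                       sev_act_coef = 2, sev_noise_sd = 0.5,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(names(activation_sizes)))
    names(activation_sizes) <- paste0("activation_",
                                      letters[seq_along(activation_sizes)])
  cfg <- list(mode = mode, n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_genes = as.integer(n_genes), n_up = as.integer(n_up),
              n_down = as.integer(n_down),
              activation_sizes = as.integer(activation_sizes),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd,
              delta_rep = delta_rep, delta_act = delta_act,
              target_auc_rep = target_auc_rep,
              target_auc_act = target_auc_act,
              burst_fraction = burst_fraction,
              control_leak_fraction = control_leak_fraction,
              dropout_rate = dropout_rate,
              activation_baseline = activation_baseline,
              sev_intercept = sev_intercept, sev_rep_coef = sev_rep_coef,
              sev_act_coef = sev_act_coef, sev_noise_sd = sev_noise_sd,
              seed = as.integer(seed))
  names(cfg$activation_sizes) <- names(activation_sizes)
  if (cfg$n_cases < 1L || cfg$n_controls < 1L)
    stop("need at least one case and one control", call. = FALSE)
  if (any(c(cfg$n_up, cfg$n_down, cfg$activation_sizes) < 2L))
    stop("signature sizes must be >= 2", call. = FALSE)
  n_sig <- cfg$n_up + cfg$n_down + sum(cfg$activation_sizes)
  if (n_sig > cfg$n_genes)
    stop("signature sizes (", n_sig, " genes) exceed n_genes = ",
         cfg$n_genes, call. = FALSE)
  for (f in c("burst_fraction", "control_leak_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must be in [0, 1]", call. = FALSE)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  if (cfg$noise_sd <= 0 || cfg$baseline_sd < 0)
    stop("noise_sd must be > 0 and baseline_sd >= 0", call. = FALSE)
  if (is.null(cfg$delta_rep))
    cfg$delta_rep <- if (cfg$mode == "bulk")
      repression_effect_for_auc(cfg$target_auc_rep, cfg$noise_sd,
                                cfg$n_up, cfg$n_down)
    else
      .sc_repression_effect(cfg$target_auc_rep, cfg)
  if (is.null(cfg$delta_act))
    cfg$delta_act <- if (cfg$mode == "bulk")
      activation_effect_for_auc(cfg$target_auc_act, cfg$noise_sd,
                                max(cfg$activation_sizes))
    else 1 - cfg$activation_baseline  # burst lifts the silent program to
                                      # ~2 expected counts per gene
  structure(cfg, class = "sim_config")
}

# single-cell repression shift targeting a population AUC on the
# log2(count+1) scale: the Poisson/dropout observation attenuates a latent
# log2 shift; the attenuation factor and the observed per-gene SD are
# computed numerically from the latent baseline distribution
.sc_repression_effect <- function(auc, cfg) {
  # expected observed mean/SD of log2(count+1) at latent log2 level L
  obs_moments <- function(L) {
    lam <- 2^L
    k <- 0:ceiling(max(20, lam + 10 * sqrt(lam)))
    pk <- stats::dpois(k, lam)
    pk[1] <- pk[1] + (1 - sum(pk))          # absorb tail
    pk0 <- pk * (1 - cfg$dropout_rate)
    pk0[1] <- pk0[1] + cfg$dropout_rate
    v <- log2(k + 1)
    m <- sum(pk0 * v)
    c(mean = m, sd = sqrt(max(sum(pk0 * v^2) - m^2, 0)))
  }
  # integrate over the gene-baseline + cell-noise latent distribution
  Ls <- stats::qnorm(seq(0.01, 0.99, by = 0.02), cfg$baseline_mean,
                     sqrt(cfg$baseline_sd^2 + cfg$noise_sd^2))
  mo <- vapply(Ls, obs_moments, numeric(2))
  eps <- 0.05
  slope <- mean((vapply(Ls + eps, obs_moments, numeric(2))[1, ] - mo[1, ]) /
                  eps)                       # d E[log2(count+1)] / d latent
  sd_obs <- sqrt(mean(mo[2, ]^2))            # within-gene observed SD
  d <- sqrt(2) * stats::qnorm(auc)
  d * sd_obs * sqrt(1 / cfg$n_up + 1 / cfg$n_down) / (2 * slope)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config (%s): %d cases + %d controls, %d genes\n",
                     "  repression %d up / %d down (delta = %.4g), ",
                     "activation sizes %s (delta = %.4g)\n",
                     "  burst fraction %.3g, control leak %.3g, dropout %.3g, ",
                     "seed %d\n"),
              x$mode, x$n_cases, x$n_controls, x$n_genes,
              x$n_up, x$n_down, x$delta_rep,
              paste(x$activation_sizes, collapse = "/"), x$delta_act,
              x$burst_fraction, x$control_leak_fraction, x$dropout_rate,
              x$seed))
  invisible(x)
}

# derived sub-seed per generator component (kept well below 2^31)
.sub_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k

# gene IDs and disjoint signature assignment (deterministic in n_genes)
.sim_genes <- function(cfg) {
  ids <- sprintf("ENSGS%08d", seq_len(cfg$n_genes))
  idx <- 0L
  take <- function(n) {
    out <- ids[idx + seq_len(n)]
    idx <<- idx + n
    out
  }
  up <- take(cfg$n_up); down <- take(cfg$n_down)
  act <- lapply(cfg$activation_sizes, take)
  sigs <- c(list(repression = gene_signature("repression", up, down)),
            lapply(seq_along(act), function(i)
              gene_signature(names(cfg$activation_sizes)[i], act[[i]])))
  names(sigs) <- c("repression", names(cfg$activation_sizes))
  list(ids = ids, signatures = sigs, up = up, down = down, act = act)
}

#' Simulate a bulk expression study with planted programs
#'
#' Dense log2-scale expression for `n_cases + n_controls` samples. Each
#' gene has a fixed log2 baseline; every value adds independent Gaussian
#' noise. Case samples carry the repression program (up-set shifted down,
#' down-set shifted up, scaled by a per-sample dose ~ Unif(0.5, 1.5)) and,
#' with probability `burst_fraction`, the activation program on all
#' activation-signature genes. A per-sample severity measure is generated
#' from the true doses: `activity = a + b * rep_dose + c * act_dose +
#' noise`.
#'
#' @param cfg a [sim_config()] with `mode = "bulk"`.
#' @return List with `expr` (log-scale [expression_matrix()]), `labels`
#'   ([sample_labels()]; cases are the leading columns), `signatures`
#'   (named list of [gene_signature()]), `severity` (data.frame: sample,
#'   activity, active flag), `truth` (per-sample repression/activation
#'   doses and burst indicators) and `config`.
#' @export
simulate_bulk <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mode != "bulk") stop("config mode is not 'bulk'", call. = FALSE)
  n <- cfg$n_cases + cfg$n_controls
  g <- .sim_genes(cfg)
  set.seed(.sub_seed(cfg$seed, 1L))
  base <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  set.seed(.sub_seed(cfg$seed, 2L))
  rep_dose <- c(stats::runif(cfg$n_cases, 0.5, 1.5),
                numeric(cfg$n_controls))
  burst <- c(stats::runif(cfg$n_cases) < cfg$burst_fraction,
             rep(FALSE, cfg$n_controls))
  act_dose <- ifelse(burst, stats::runif(n, 0.5, 1.5), 0)
  set.seed(.sub_seed(cfg$seed, 3L))
  vals <- base + matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd),
                        cfg$n_genes, n)
  up_i <- match(g$up, g$ids); down_i <- match(g$down, g$ids)
  act_i <- match(unlist(g$act), g$ids)
  vals[up_i, ] <- vals[up_i, ] -
    matrix(cfg$delta_rep * rep_dose, length(up_i), n, byrow = TRUE)
  vals[down_i, ] <- vals[down_i, ] +
    matrix(cfg$delta_rep * rep_dose, length(down_i), n, byrow = TRUE)
  vals[act_i, ] <- vals[act_i, ] +
    matrix(cfg$delta_act * act_dose, length(act_i), n, byrow = TRUE)
  ids <- c(sprintf("case%03d", seq_len(cfg$n_cases)),
           sprintf("ctrl%03d", seq_len(cfg$n_controls)))
  dimnames(vals) <- list(g$ids, ids)
  set.seed(.sub_seed(cfg$seed, 5L))
  activity <- cfg$sev_intercept + cfg$sev_rep_coef * rep_dose +
    cfg$sev_act_coef * act_dose + stats::rnorm(n, 0, cfg$sev_noise_sd)
  severity <- data.frame(sample = ids, activity = activity,
                         active = as.integer(rep_dose > 0 | act_dose > 0),
                         stringsAsFactors = FALSE)
  list(expr = expression_matrix(vals, is_log = TRUE),
       labels = sample_labels(seq_len(cfg$n_cases), n),
       signatures = g$signatures,
       severity = severity,
       truth = list(rep_dose = rep_dose, act_dose = act_dose,
                    burst = burst),
       config = cfg)
}

#' Simulate sparse single-cell counts with planted programs
#'
#' Counts are Poisson draws from a latent log-normal expression level
#' (gene baseline + cell noise + planted shifts), thinned by Bernoulli
#' dropout. Every case cell carries the weak repression program; a
#' `burst_fraction` of case cells (and a `control_leak_fraction` of control
#' cells) carry a joint activation burst of `delta_act` log2 units on all
#' activation-signature genes, whose baseline is otherwise so low that the
#' program is essentially undetectable. Every cell is guaranteed at least
#' one nonzero gene.
#'
#' @param cfg a [sim_config()] with `mode = "single_cell"`.
#' @return List with `expr` (raw-count [expression_matrix()]), `labels`,
#'   `signatures`, `truth` (per-cell burst indicator) and `config`.
#' @export
simulate_single_cell <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mode != "single_cell")
    stop("config mode is not 'single_cell'", call. = FALSE)
  n <- cfg$n_cases + cfg$n_controls
  is_case <- c(rep(TRUE, cfg$n_cases), rep(FALSE, cfg$n_controls))
  g <- .sim_genes(cfg)
  set.seed(.sub_seed(cfg$seed, 1L))
  base <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  act_i <- match(unlist(g$act), g$ids)
  base[act_i] <- cfg$activation_baseline
  set.seed(.sub_seed(cfg$seed, 2L))
  burst <- ifelse(is_case,
                  stats::runif(n) < cfg$burst_fraction,
                  stats::runif(n) < cfg$control_leak_fraction)
  set.seed(.sub_seed(cfg$seed, 3L))
  latent <- base + matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd),
                          cfg$n_genes, n)
  up_i <- match(g$up, g$ids); down_i <- match(g$down, g$ids)
  latent[up_i, is_case] <- latent[up_i, is_case] - cfg$delta_rep
  latent[down_i, is_case] <- latent[down_i, is_case] + cfg$delta_rep
  if (any(burst))
    latent[act_i, burst] <- latent[act_i, burst] + cfg$delta_act
  set.seed(.sub_seed(cfg$seed, 4L))
  counts <- matrix(stats::rpois(length(latent), 2^latent),
                   cfg$n_genes, n)
  if (cfg$dropout_rate > 0)
    counts[stats::runif(length(counts)) < cfg$dropout_rate] <- 0L
  empty <- colSums(counts) == 0
  if (any(empty)) {  # zero-inflation must leave every cell detectable
    top <- apply(latent[, empty, drop = FALSE], 2L, which.max)
    counts[cbind(top, which(empty))] <- 1L
  }
  ids <- c(sprintf("case_cell%05d", seq_len(cfg$n_cases)),
           sprintf("ctrl_cell%05d", seq_len(cfg$n_controls)))
  dimnames(counts) <- list(g$ids, ids)
  storage.mode(counts) <- "double"
  list(expr = expression_matrix(counts, is_log = FALSE),
       labels = sample_labels(seq_len(cfg$n_cases), n),
       signatures = g$signatures,
       truth = list(burst = burst),
       config = cfg)
}

#' Write or read a simulation config as a flat key=value file
#'
#' Vector fields are comma-separated; the file round-trips through
#' [read_sim_config()].
#'
#' @param cfg a `sim_config`.
#' @param path file path.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  flat <- vapply(names(unclass(cfg)), function(nm) {
    v <- cfg[[nm]]
    if (nm == "activation_sizes")
      paste(paste0(names(v), ":", v), collapse = ",")
    else paste(format(v, digits = 17), collapse = ",")
  }, character(1))
  writeLines(paste0(names(flat), "=", flat), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(f) paste(f[-1L], collapse = "="), character(1))
  known <- names(formals(sim_config))
  known <- c(known, "delta_rep", "delta_act")
  bad <- setdiff(keys, known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- trimws(vals[i])
    args[[k]] <- if (k == "mode") {
      v
    } else if (k == "activation_sizes") {
      parts <- strsplit(v, ",", fixed = TRUE)[[1L]]
      if (all(grepl(":", parts, fixed = TRUE))) {
        nmv <- strsplit(parts, ":", fixed = TRUE)
        stats::setNames(as.integer(vapply(nmv, `[[`, character(1), 2L)),
                        vapply(nmv, `[[`, character(1), 1L))
      } else as.integer(parts)
    } else {
      num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1L]]))
      if (anyNA(num)) stop("non-numeric value for config key '", k, "': ",
                           v, call. = FALSE)
      num
    }
  }
  do.call(sim_config, args)
}
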