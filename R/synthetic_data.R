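# Generator for L1000-like level-5 datasets with known ground truth, plus
# calibration and recovery metrics for the screen. Level-5 values are
# z-score-like, so nulls are Normal(0, sigma) and a planted effect shifts
# the target gene's mean by delta for that compound's signatures.

# Gene-tier proportions of the real level-5 gene space: 978 landmark,
# 9,196 well-inferred and 2,154 less-well-inferred of 12,328 genes.
TIER_PROPORTIONS <- c(landmark = 978, well_inferred = 9196,
                      less_well_inferred = 2154) / 12328

#' Configure a synthetic signature dataset
#'
#' @param n_genes number of genes (rows); the target gene is one of them.
#' @param n_compounds number of perturbagens.
#' @param profiles_per_compound either a single integer (every compound gets
#'   exactly that many level-5 signatures) or a length-2 integer range
#'   `c(a, b)` sampled uniformly per compound.
#' @param frac_effect fraction in \[0, 1\] of compounds with a planted
#'   effect on the target gene (default 0, a pure null dataset).
#' @param delta planted mean shift for effect compounds, in z-units
#'   (default -0.6, a typical magnitude for a real suppressor hit).
#' @param sigma per-signature noise standard deviation in z-units
#'   (default 1, matching the z-score-like scale of level-5 data).
#' @param n_cell_lines number of cell-line labels cycled through the
#'   signature metadata (cosmetic: the screen pools across cell lines,
#'   but the labels exercise the metadata plumbing; default 5).
#' @param seed integer RNG seed; every random draw in the simulation flows
#'   from it, so a config is fully reproducible.
#' @param target_gene_id,target_gene_symbol identity given to the target
#'   gene row (defaults `"54677"` / `"CROT"`, the Entrez id and symbol of
#'   carnitine O-octanoyltransferase; the gene is tiered well-inferred as
#'   on the real platform).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 50L,
                              n_compounds = 200L,
                              profiles_per_compound = 10L,
                              frac_effect = 0,
                              delta = -0.6,
                              sigma = 1,
                              n_cell_lines = 5L,
                              seed = 1L,
                              target_gene_id = "54677",
                              target_gene_symbol = "CROT") {
  n_genes <- as.integer(n_genes)
  n_compounds <- as.integer(n_compounds)
  ppc <- as.integer(profiles_per_compound)
  if (is.na(n_genes) || n_genes < 1L) abort_args("'n_genes' must be >= 1")
  if (is.na(n_compounds) || n_compounds < 1L)
    abort_args("'n_compounds' must be >= 1")
  if (!length(ppc) %in% c(1L, 2L) || anyNA(ppc) || any(ppc < 1L))
    abort_args("'profiles_per_compound' must be a positive integer or range c(a, b)")
  if (length(ppc) == 2L && ppc[1L] > ppc[2L])
    abort_args("'profiles_per_compound' range must have a <= b")
  if (!is.numeric(frac_effect) || is.na(frac_effect) ||
      frac_effect < 0 || frac_effect > 1)
    abort_args("'frac_effect' must lie in [0, 1]")
  if (!is.numeric(sigma) || is.na(sigma) || sigma <= 0)
    abort_args("'sigma' must be > 0")
  structure(list(n_genes = n_genes, n_compounds = n_compounds,
                 profiles_per_compound = ppc, frac_effect = frac_effect,
                 delta = delta, sigma = sigma,
                 n_cell_lines = as.integer(n_cell_lines),
                 seed = as.integer(seed),
                 target_gene_id = as.character(target_gene_id),
                 target_gene_symbol = as.character(target_gene_symbol)),
            class = "simulation_config")
}

sim_gene_table <- function(config) {
  n <- config$n_genes
  # deterministic tier assignment at the platform's proportions
  n_lm <- round(TIER_PROPORTIONS[["landmark"]] * n)
  n_well <- round(TIER_PROPORTIONS[["well_inferred"]] * n)
  tier <- rep("less_well_inferred", n)
  tier[seq_len(min(n_lm, n))] <- "landmark"
  if (n_well > 0 && n_lm < n)
    tier[(n_lm + 1):min(n_lm + n_well, n)] <- "well_inferred"
  target_row <- (n + 1L) %/% 2L
  gene_id <- as.character(1000L + seq_len(n))
  symbol <- sprintf("GENE%04d", seq_len(n))
  gene_id[target_row] <- config$target_gene_id
  symbol[target_row] <- config$target_gene_symbol
  tier[target_row] <- "well_inferred"
  list(table = data.frame(
         gene_id = gene_id, symbol = symbol,
         tier = factor(tier, levels = names(TIER_PROPORTIONS)),
         stringsAsFactors = FALSE),
       target_row = target_row)
}

#' Simulate an L1000-like level-5 dataset with known ground truth
#'
#' Draws every matrix entry from Normal(0, `sigma`), then shifts the target
#' gene's row by `delta` in the signatures of the compounds chosen (at
#' random, fraction `frac_effect`) to carry a planted effect. All other
#' genes, and all signatures of null compounds, stay at mean zero —
#' mirroring the fact that the screen reads a single gene, so off-target
#' structure is irrelevant to it. Signature metadata rows carry
#' `pert_type = "trt_cp"` and round-robin cell-line labels.
#'
#' @param config a [simulation_config].
#' @return A list with elements `matrix` (a [sig_matrix]), `sig_meta` and
#'   `gene_meta` (data.frames in the dialects the readers return), and
#'   `truth` (data.frame `pert_id`, `effect`; effect is 0 for nulls and
#'   `delta` for planted compounds — one row per simulated compound).
#'   Bit-identical across runs with the same config.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    abort_args("'config' must come from simulation_config()")
  set.seed(config$seed)
  genes <- sim_gene_table(config)
  n_cmp <- config$n_compounds
  ppc <- config$profiles_per_compound
  n_prof <- if (length(ppc) == 1L) rep(ppc, n_cmp) else
    sample(seq(ppc[1L], ppc[2L]), n_cmp, replace = TRUE)
  pert_id <- sprintf("BRD-S%07d", seq_len(n_cmp))
  n_effect <- round(config$frac_effect * n_cmp)
  effect_idx <- if (n_effect > 0) sort(sample.int(n_cmp, n_effect)) else integer(0)
  effect <- numeric(n_cmp)
  effect[effect_idx] <- config$delta

  total <- sum(n_prof)
  cmp_of_sig <- rep(seq_len(n_cmp), n_prof)
  sig_id <- sprintf("SIM%03d:%s:%d", config$seed %% 1000L,
                    pert_id[cmp_of_sig],
                    sequence(n_prof))
  values <- matrix(stats::rnorm(config$n_genes * total, 0, config$sigma),
                   nrow = config$n_genes, ncol = total)
  values[genes$target_row, ] <- values[genes$target_row, ] + effect[cmp_of_sig]

  sig_meta <- data.frame(
    sig_id = sig_id,
    pert_id = pert_id[cmp_of_sig],
    pert_iname = sprintf("compound-%04d", cmp_of_sig),
    pert_type = "trt_cp",
    cell_id = sprintf("CL%02d", (seq_len(total) - 1L) %% config$n_cell_lines + 1L),
    dose = "10 uM",
    time = "24 h",
    stringsAsFactors = FALSE
  )
  list(matrix = sig_matrix(values, genes$table$gene_id, sig_meta$sig_id),
       sig_meta = sig_meta,
       gene_meta = genes$table,
       truth = data.frame(pert_id = pert_id, effect = effect,
                          stringsAsFactors = FALSE))
}

#' Write a simulated dataset as screen-ready files
#'
#' Emits the dataset in exactly the formats the readers consume — the matrix
#' as GCTX or GCT, signature metadata as a sig-info TSV, gene metadata as a
#' gene-info TSV (with `pr_*` columns and landmark/well-inferred flags) —
#' plus the ground truth as `truth.tsv`, so the whole pipeline is testable
#' file-to-file.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param format matrix format, `"gctx"` (default) or `"gct"`.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_simulated_dataset <- function(sim, dir, format = c("gctx", "gct")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  matrix_path <- file.path(dir, paste0("matrix.", format))
  write_signature_matrix(sim$matrix, matrix_path, format)
  sig_path <- file.path(dir, "sig_info.tsv")
  utils::write.table(sim$sig_meta, sig_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gm <- sim$gene_meta
  gene_tab <- data.frame(
    pr_gene_id = gm$gene_id,
    pr_gene_symbol = ifelse(is.na(gm$symbol), MISSING_SENTINEL, gm$symbol),
    pr_is_lm = as.integer(gm$tier == "landmark"),
    pr_is_bing = as.integer(gm$tier %in% c("landmark", "well_inferred")),
    stringsAsFactors = FALSE
  )
  gene_path <- file.path(dir, "gene_info.tsv")
  utils::write.table(gene_tab, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(matrix = matrix_path, sig_info = sig_path,
                 gene_info = gene_path, truth = truth_path))
}

# Per-compound summaries of the simulated target gene, bypassing selection.
compound_pvalues <- function(sim, test = "t_two_sided", direction = "down") {
  z <- gene_values(sim$matrix, target_gene_id_of(sim))
  groups <- group_by_perturbagen(sim$sig_meta)
  summarize_groups(z, groups, list(test = test, direction = direction))
}

# The generator plants effects on the middle row; recover its gene id.
target_gene_id_of <- function(sim) {
  rownames(sim$matrix)[(nrow(sim$matrix) + 1L) %/% 2L]
}

#' Empirical type-I-error calibration of the screen's test
#'
#' Simulates pure-null datasets (no planted effects) and measures the
#' fraction of compounds whose p-value falls below `alpha`. For a
#' well-calibrated test this empirical rejection rate matches `alpha`; the
#' result carries an exact binomial 95% confidence interval.
#'
#' Compounds with an undefined p-value (fewer than two profiles) are not
#' counted as tests.
#'
#' @param config a [simulation_config] with `frac_effect = 0`.
#' @param alpha nominal significance level in (0, 1).
#' @param reps number of independent simulated datasets (seeds
#'   `seed, seed + 1, ...`); default 1.
#' @return List with `rate`, `ci_lower`, `ci_upper` (95% exact binomial),
#'   `n_tests`, `n_rejections` and `alpha`.
#' @export
null_calibration <- function(config, alpha, reps = 1L) {
  if (!inherits(config, "simulation_config"))
    abort_args("'config' must come from simulation_config()")
  if (config$frac_effect != 0)
    abort_args("null calibration needs frac_effect = 0 (got %g)",
               config$frac_effect)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort_args("'alpha' must lie in (0, 1)")
  reps <- as.integer(reps)
  if (reps * config$n_compounds < 1 / alpha)
    warning(sprintf("only %d tests for alpha = %g; rate estimate cannot resolve the level",
                    reps * config$n_compounds, alpha), call. = FALSE)
  n_tests <- 0L
  n_rej <- 0L
  for (r in seq_len(reps)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r - 1L
    sim <- simulate_dataset(cfg_r)
    p <- compound_pvalues(sim)$p_value
    p <- p[!is.na(p)]
    n_tests <- n_tests + length(p)
    n_rej <- n_rej + sum(p < alpha)
  }
  ci <- stats::binom.test(n_rej, n_tests)$conf.int
  list(rate = n_rej / n_tests, ci_lower = ci[[1L]], ci_upper = ci[[2L]],
       n_tests = n_tests, n_rejections = n_rej, alpha = alpha)
}

#' Recovery metrics of a screen run against simulation ground truth
#'
#' Treats planted-effect compounds as positives and computes the standard
#' confusion-matrix rates for the set of compounds the screen selected.
#'
#' @param table the [candidate_table] produced from the simulated dataset.
#' @param truth the `truth` data.frame of [simulate_dataset()] (columns
#'   `pert_id`, `effect`); defines the full compound universe.
#' @return List with `sensitivity`, `specificity` and `precision` in
#'   \[0, 1\]; `precision` is `NA` when nothing was selected.
#' @export
recovery_evaluation <- function(table, truth) {
  table <- as_candidate_table(table)
  if (!is.data.frame(truth) || !all(c("pert_id", "effect") %in% names(truth)))
    abort_args("'truth' must have pert_id and effect columns")
  if (anyDuplicated(truth$pert_id))
    abort_integrity("duplicate pert_id in truth")
  stray <- setdiff(table$pert_id, truth$pert_id)
  if (length(stray) > 0)
    abort_integrity("candidate table contains compounds absent from truth: %s",
                    paste(stray, collapse = ", "))
  selected <- truth$pert_id %in% table$pert_id
  positive <- truth$effect != 0
  tp <- sum(selected & positive)
  list(
    sensitivity = if (sum(positive) == 0) NA_real_ else tp / sum(positive),
    specificity = if (sum(!positive) == 0) NA_real_ else
      sum(!selected & !positive) / sum(!positive),
    precision = if (sum(selected) == 0) NA_real_ else tp / sum(selected)
  )
}
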