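# The screening computation: filter level-5 signatures by perturbagen type,
# pool replicate signatures per compound, test the target gene's mean
# differential expression against the plate-control baseline of zero, then
# select, rank and curate candidates.

#' Configure a target-gene screen
#'
#' Bundles the target gene and every filter / test threshold of the screen.
#' The defaults are the published preset for the CROT query against the
#' GSE92742 level-5 data: small-molecule treatments (`pert_type` `"trt_cp"`),
#' compounds with at least five level-5 signatures, two-sided one-sample t
#' test of mean z-score = 0, and selection of compounds that push the target
#' gene down (negative mean) at p < 1e-6.
#'
#' @param target_gene gene id or symbol of the gene being queried
#'   (default `"CROT"`).
#' @param pert_type perturbagen-type filter, matched exactly and
#'   case-sensitively against the metadata (default `"trt_cp"`,
#'   small-molecule compound treatments).
#' @param min_profiles minimum number of level-5 signatures a compound must
#'   have to be tested; at least 2 so a dispersion estimate exists
#'   (default 5).
#' @param p_threshold selection threshold on the per-compound p-value, in
#'   the open interval (0, 1) (default 1e-6).
#' @param direction `"down"` (negative mean required, the default), `"up"`,
#'   or `"both"` (no sign constraint).
#' @param test `"t_two_sided"` (default) or `"t_one_sided"`; the one-sided
#'   variant tests in the configured direction and is unavailable with
#'   `direction = "both"`.
#' @param tie_break column order used to break ties among equal means when
#'   ranking (default p-value ascending, then pert_id lexicographic).
#' @return A `screen_config` list.
#' @export
screen_config <- function(target_gene = "CROT",
                          pert_type = "trt_cp",
                          min_profiles = 5L,
                          p_threshold = 1e-6,
                          direction = c("down", "up", "both"),
                          test = c("t_two_sided", "t_one_sided"),
                          tie_break = c("p_value", "pert_id")) {
  direction <- match.arg(direction)
  test <- match.arg(test)
  min_profiles <- as.integer(min_profiles)
  if (is.na(min_profiles) || min_profiles < 2L)
    abort_args("'min_profiles' must be an integer >= 2 (got %s), so a dispersion estimate exists",
               min_profiles)
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      is.na(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    abort_args("'p_threshold' must lie in the open interval (0, 1)")
  if (test == "t_one_sided" && direction == "both")
    abort_args("a one-sided test needs a direction ('down' or 'up')")
  if (!all(tie_break %in% c("p_value", "pert_id")))
    abort_args("'tie_break' fields must be among: p_value, pert_id")
  structure(list(target_gene = as.character(target_gene),
                 pert_type = as.character(pert_type),
                 min_profiles = min_profiles,
                 p_threshold = p_threshold,
                 direction = direction,
                 test = test,
                 tie_break = tie_break),
            class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("screen_config:\n")
  cat(sprintf("  target gene   : %s\n", x$target_gene))
  cat(sprintf("  pert_type     : %s\n", x$pert_type))
  cat(sprintf("  min profiles  : %d\n", x$min_profiles))
  cat(sprintf("  p threshold   : %g\n", x$p_threshold))
  cat(sprintf("  direction     : %s\n", x$direction))
  cat(sprintf("  test          : %s\n", x$test))
  invisible(x)
}

#' Filter signature metadata by perturbagen type
#'
#' Keeps exactly the rows whose `pert_type` equals the filter string
#' (exact, case-sensitive comparison), preserving row order. An empty
#' result is allowed.
#'
#' @param records signature metadata data.frame from
#'   [read_signature_metadata()].
#' @param pert_type type code to keep, e.g. `"trt_cp"` for small-molecule
#'   compound treatments.
#' @return The matching subset of `records`.
#' @export
filter_signatures <- function(records, pert_type) {
  if (!is.data.frame(records) || !all(c("sig_id", "pert_type") %in% names(records)))
    abort_args("'records' must be a signature metadata data.frame")
  keep <- !is.na(records$pert_type) & records$pert_type == pert_type
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group signatures by perturbagen
#'
#' Pools every signature of a perturbagen (across cell lines, doses and
#' times) into one group keyed by `pert_id`. Each `sig_id` lands in exactly
#' one group. Group order follows first appearance in `records`.
#'
#' @param records filtered signature metadata.
#' @return Named list mapping `pert_id` to a character vector of `sig_id`s.
#' @export
group_by_perturbagen <- function(records) {
  if (!is.data.frame(records) || !all(c("sig_id", "pert_id") %in% names(records)))
    abort_args("'records' must be a signature metadata data.frame")
  bad <- is.na(records$pert_id) | records$pert_id == ""
  if (any(bad))
    abort_integrity("%d signature record(s) have no pert_id (e.g. sig_id %s)",
                    sum(bad), records$sig_id[which(bad)[1L]])
  split(records$sig_id, factor(records$pert_id, levels = unique(records$pert_id)))
}

# One-sample t of H0: mean = 0, vectorised over groups. Returns two-sided or
# directional one-sided p; NA (undefined) when n < 2 or the sample has zero
# dispersion, so such groups can never be selected.
t_test_zero <- function(n, mean, sd, test = "t_two_sided", direction = "down") {
  p <- rep(NA_real_, length(n))
  ok <- !is.na(sd) & n >= 2L & sd > 0
  t_stat <- rep(NA_real_, length(n))
  t_stat[ok] <- mean[ok] / (sd[ok] / sqrt(n[ok]))
  df <- n - 1L
  if (test == "t_two_sided") {
    p[ok] <- 2 * stats::pt(abs(t_stat[ok]), df[ok], lower.tail = FALSE)
  } else if (direction == "down") {
    p[ok] <- stats::pt(t_stat[ok], df[ok], lower.tail = TRUE)
  } else {
    p[ok] <- stats::pt(t_stat[ok], df[ok], lower.tail = FALSE)
  }
  list(t = t_stat, p = p)
}

#' Summarise one perturbagen's target-gene values
#'
#' Computes the replicate count, arithmetic mean and the p-value of the
#' configured test of the null hypothesis that the mean level-5
#' differential expression equals 0 (the plate-control baseline). With
#' fewer than two values, or a sample of exactly zero dispersion, the
#' p-value is undefined (`NA`) rather than zero — such compounds are never
#' selected.
#'
#' @param z_values numeric vector of the target gene's level-5 values over
#'   the compound's signatures; must be non-empty and finite.
#' @param test `"t_two_sided"` (default) or `"t_one_sided"`.
#' @param direction direction of the one-sided alternative (`"down"` tests
#'   mean < 0); ignored for the two-sided test.
#' @return List with `n`, `mean` and `p`.
#' @export
summarize_perturbagen <- function(z_values, test = c("t_two_sided", "t_one_sided"),
                                  direction = c("down", "up")) {
  test <- match.arg(test)
  direction <- match.arg(direction)
  if (length(z_values) == 0L) abort_args("'z_values' must be non-empty")
  if (!is.numeric(z_values) || any(!is.finite(z_values)))
    abort_args("'z_values' must be finite numerics")
  n <- length(z_values)
  m <- mean(z_values)
  s <- if (n >= 2L) stats::sd(z_values) else NA_real_
  res <- t_test_zero(n, m, s, test, direction)
  list(n = n, mean = m, p = res$p[[1L]])
}

summarize_groups <- function(z, groups, config) {
  # z: named vector (names = sig_id) of the target gene's values.
  sizes <- lengths(groups)
  f <- rep(seq_along(groups), sizes)
  zz <- z[unlist(groups, use.names = FALSE)]
  sums <- rowsum(zz, f)[, 1L]
  means <- sums / sizes
  sq <- rowsum(zz^2, f)[, 1L]
  vars <- pmax(sq - sizes * means^2, 0) / (sizes - 1)
  vars[sizes < 2L] <- NA_real_
  sds <- sqrt(vars)
  res <- t_test_zero(sizes, means, sds, config$test,
                     if (config$direction == "both") "down" else config$direction)
  data.frame(pert_id = names(groups),
             n_profiles = as.integer(sizes),
             mean_expression = unname(means),
             p_value = unname(res$p),
             stringsAsFactors = FALSE)
}

#' Apply the selection rule to per-compound summaries
#'
#' Keeps compounds whose p-value is below the threshold AND whose mean
#' satisfies the direction constraint (for `"down"`, a negative mean). The
#' two conditions are a conjunction, so their order is immaterial.
#' Summaries with an undefined (`NA`) p-value are never selected.
#'
#' @param summaries data.frame with `mean_expression` and `p_value` columns
#'   (one row per compound, minimum-profile filtering already applied).
#' @param config a [screen_config].
#' @return The selected subset, original order preserved.
#' @export
select_candidates <- function(summaries, config) {
  if (!is.data.frame(summaries) ||
      !all(c("mean_expression", "p_value") %in% names(summaries)))
    abort_args("'summaries' must have mean_expression and p_value columns")
  dir_ok <- switch(config$direction,
                   down = summaries$mean_expression < 0,
                   up = summaries$mean_expression > 0,
                   both = rep(TRUE, nrow(summaries)))
  keep <- !is.na(summaries$p_value) &
    summaries$p_value < config$p_threshold & dir_ok
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank selected compounds into a candidate table
#'
#' Sorts by mean expression ascending, so the strongest suppressor of the
#' target gene gets rank 1, breaking ties by the configured fields
#' (default: p-value ascending, then pert_id lexicographic), and assigns
#' consecutive 1-based rankings.
#'
#' @param selected data.frame of selected per-compound summaries.
#' @param config a [screen_config] (supplies the tie-break order).
#' @return A [candidate_table].
#' @export
rank_candidates <- function(selected, config = screen_config()) {
  if (!is.data.frame(selected))
    abort_args("'selected' must be a data.frame of summaries")
  keys <- list(selected$mean_expression)
  for (field in config$tie_break) {
    keys <- c(keys, list(switch(field,
                                p_value = selected$p_value,
                                pert_id = selected$pert_id)))
  }
  ord <- do.call(order, c(keys, list(method = "radix")))
  out <- selected[ord, , drop = FALSE]
  out$ranking <- seq_len(nrow(out))
  as_candidate_table(out)
}

#' Remove curated exclusions from a candidate table
#'
#' Drops every row whose `pert_id` matches an exclusion exactly or whose
#' `pert_iname` matches case-insensitively, then re-ranks the survivors
#' consecutively. Exclusions that match no row raise a warning each, so a
#' misspelled curation entry is never silently ignored.
#'
#' @param table a [candidate_table].
#' @param exclusions character vector of pert_id or pert_iname strings (an
#'   empty vector returns the table unchanged).
#' @return The curated, re-ranked [candidate_table].
#' @export
apply_exclusions <- function(table, exclusions) {
  table <- as_candidate_table(table)
  exclusions <- as.character(exclusions)
  exclusions <- exclusions[nzchar(trimws(exclusions))]
  if (length(exclusions) == 0L) return(table)
  drop <- rep(FALSE, nrow(table))
  for (ex in exclusions) {
    hit <- table$pert_id == ex |
      tolower(table$pert_iname) == tolower(trimws(ex))
    hit[is.na(hit)] <- FALSE
    if (!any(hit))
      warning(sprintf("exclusion matched no candidate: %s", ex), call. = FALSE)
    drop <- drop | hit
  }
  out <- table[!drop, , drop = FALSE]
  out$ranking <- seq_len(nrow(out))
  as_candidate_table(out)
}

#' Read an exclusion list
#'
#' One identifier (pert_id or pert_iname) per line; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path path to the plain-text list.
#' @return Character vector of identifiers.
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) abort_args("file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

resolve_target_gene <- function(gene_meta, target) {
  target <- as.character(target)
  if (target %in% gene_meta$gene_id) return(target)
  hits <- gene_meta$gene_id[!is.na(gene_meta$symbol) &
                              gene_meta$symbol == target]
  if (length(hits) == 1L) return(hits)
  if (length(hits) > 1L)
    abort_lookup("gene symbol %s maps to multiple gene ids: %s",
                 target, paste(hits, collapse = ", "))
  abort_lookup("target gene not found as gene_id or symbol: %s", target)
}

#' Run the full target-gene screen
#'
#' The complete pipeline: resolve the target gene, extract its level-5
#' values (reading only that gene's row when `matrix_source` is a file
#' path), filter signatures by perturbagen type, pool replicates per
#' compound, drop compounds with fewer than `min_profiles` signatures, test
#' each compound's mean against the zero baseline, select by direction and
#' p-value, and rank. Deterministic for fixed inputs.
#'
#' Signatures present in the metadata but absent from the matrix (or vice
#' versa) are dropped with a warning; the screen runs on the intersection.
#'
#' @param matrix_source a [sig_matrix], or a path to a GCTX/GCT file.
#' @param sig_meta signature metadata ([read_signature_metadata()]).
#' @param gene_meta gene metadata ([read_gene_metadata()]).
#' @param config a [screen_config].
#' @return A [candidate_table]. The attribute `"n_tested"` records how many
#'   compounds survived the minimum-profile filter and were tested.
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 20, n_compounds = 50,
#'                                           profiles_per_compound = 8,
#'                                           frac_effect = 0.2, delta = -1.5,
#'                                           seed = 7))
#' run_screen(sim$matrix, sim$sig_meta, sim$gene_meta,
#'            screen_config(p_threshold = 1e-3))
#' @export
run_screen <- function(matrix_source, sig_meta, gene_meta, config = screen_config()) {
  if (!inherits(config, "screen_config"))
    abort_args("'config' must come from screen_config()")
  gene_id <- resolve_target_gene(gene_meta, config$target_gene)
  if (is_sig_matrix(matrix_source)) {
    z <- gene_values(matrix_source, gene_id)
  } else {
    slice <- read_signature_matrix(matrix_source, gene_subset = gene_id)
    z <- unclass(slice)[1L, ]
  }
  filtered <- filter_signatures(sig_meta, config$pert_type)
  in_matrix <- filtered$sig_id %in% names(z)
  if (!all(in_matrix))
    warning(sprintf("%d filtered signature(s) missing from the matrix; using the intersection",
                    sum(!in_matrix)), call. = FALSE)
  filtered <- filtered[in_matrix, , drop = FALSE]
  groups <- group_by_perturbagen(filtered)
  groups <- groups[lengths(groups) >= config$min_profiles]
  if (length(groups) == 0L) {
    warning("no perturbagen has enough profiles; candidate table is empty",
            call. = FALSE)
    empty <- empty_candidate_table()
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  summaries <- summarize_groups(z, groups, config)
  iname <- filtered$pert_iname[match(summaries$pert_id, filtered$pert_id)]
  summaries$pert_iname <- ifelse(is.na(iname), summaries$pert_id, iname)
  summaries$q_value <- stats::p.adjust(summaries$p_value, method = "BH")
  selected <- select_candidates(summaries, config)
  table <- rank_candidates(selected, config)
  attr(table, "n_tested") <- nrow(summaries)
  table
}
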