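# Fixtures are built in code at test time; nothing binary ships with the
# package.

write_gene_info_fixture <- function(path,
                                    ids = c("101", "102", "54677"),
                                    symbols = c("AAA1", "-666", "CROT"),
                                    is_lm = c(1, 0, 0),
                                    is_bing = c(1, 0, 1)) {
  tab <- data.frame(pr_gene_id = ids, pr_gene_symbol = symbols,
                    pr_gene_title = "t", pr_is_lm = is_lm,
                    pr_is_bing = is_bing)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_sig_info_fixture <- function(path,
                                   sig_id = paste0("sig", 1:5),
                                   pert_id = c("P1", "P1", "P2", "P3", "P3"),
                                   pert_type = c("trt_cp", "trt_cp", "trt_sh",
                                                 "trt_cp", "ctl_vehicle")) {
  tab <- data.frame(sig_id = sig_id, pert_id = pert_id,
                    pert_iname = tolower(pert_id), pert_type = pert_type,
                    cell_id = "A375", pert_idose = "10 uM",
                    pert_itime = "24 h", distil_ss = "7.5")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_sig_matrix <- function(n_genes, n_sigs, seed) {
  set.seed(seed)
  sig_matrix(matrix(rnorm(n_genes * n_sigs), n_genes, n_sigs),
             gene_ids = as.character(seq(101, length.out = n_genes)),
             sig_ids = sprintf("sig%03d", seq_len(n_sigs)))
}

# Independent re-implementation of the screen: explicit loop over
# compounds, stats::t.test for the p-value. Used only as an oracle.
naive_screen <- function(mat, sig_meta, gene_meta, config) {
  gid <- if (config$target_gene %in% gene_meta$gene_id) {
    config$target_gene
  } else {
    gene_meta$gene_id[match(config$target_gene, gene_meta$symbol)]
  }
  z <- unclass(mat)[gid, ]
  recs <- sig_meta[!is.na(sig_meta$pert_type) &
                     sig_meta$pert_type == config$pert_type &
                     sig_meta$sig_id %in% colnames(mat), , drop = FALSE]
  rows <- list()
  for (pid in unique(recs$pert_id)) {
    zz <- z[recs$sig_id[recs$pert_id == pid]]
    if (length(zz) < config$min_profiles) next
    p <- if (stats::sd(zz) == 0) NA_real_ else stats::t.test(zz, mu = 0)$p.value
    rows[[pid]] <- data.frame(pert_id = pid, n_profiles = length(zz),
                              mean_expression = mean(zz), p_value = p,
                              stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) return(df)
  keep <- !is.na(df$p_value) & df$p_value < config$p_threshold &
    df$mean_expression < 0
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$mean_expression, df$p_value, df$pert_id,
                 method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

published_candidates <- function() {
  read_candidate_table(system.file("extdata", "gse92742_crot_candidates.tsv",
                                   package = "cmapscreen"))
}

published_exclusions <- function() {
  read_exclusion_list(system.file("extdata", "gse92742_crot_exclusions.txt",
                                  package = "cmapscreen"))
}
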