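test_that("screen_config validates thresholds", {
  expect_error(screen_config(min_profiles = 1), class = "cmapscreen_argument_error")
  expect_error(screen_config(p_threshold = 0), class = "cmapscreen_argument_error")
  expect_error(screen_config(p_threshold = 1), class = "cmapscreen_argument_error")
  expect_error(screen_config(test = "t_one_sided", direction = "both"),
               class = "cmapscreen_argument_error")
  cfg <- screen_config()
  expect_equal(cfg$min_profiles, 5L)
  expect_equal(cfg$p_threshold, 1e-6)
  expect_equal(cfg$pert_type, "trt_cp")
})

test_that("perturbagen-type filtering is exact, case-sensitive and order-preserving", {
  recs <- data.frame(sig_id = paste0("s", 1:6),
                     pert_id = paste0("P", 1:6),
                     pert_type = c("trt_cp", "TRT_CP", "trt_sh", "trt_cp",
                                   NA, "trt_cp."),
                     stringsAsFactors = FALSE)
  kept <- filter_signatures(recs, "trt_cp")
  expect_equal(kept$sig_id, c("s1", "s4"))
  expect_equal(nrow(filter_signatures(recs, "nothing_matches")), 0L)
})

test_that("grouping by perturbagen conserves signatures and demands pert_id", {
  recs <- data.frame(sig_id = paste0("s", 1:6),
                     pert_id = c("A", "A", "B", "A", "B", "A"),
                     stringsAsFactors = FALSE)
  groups <- group_by_perturbagen(recs)
  expect_equal(lengths(groups), c(A = 4L, B = 2L))
  expect_equal(sum(lengths(groups)), nrow(recs))
  expect_setequal(unlist(groups), recs$sig_id)

  recs$pert_id[3] <- NA
  expect_error(group_by_perturbagen(recs), class = "cmapscreen_integrity_error")
})

test_that("per-compound summary matches the frozen one-sample t oracle", {
  # expected values computed beforehand with stats::t.test on this sample
  z <- c(-1.0, -0.5, -0.8, -0.3, -0.4)
  s <- summarize_perturbagen(z)
  expect_equal(s$n, 5L)
  expect_equal(s$mean, -0.6)
  expect_equal(s$p, 1.001737505278e-02, tolerance = 1e-10)

  one <- summarize_perturbagen(z, test = "t_one_sided", direction = "down")
  expect_equal(one$p, 5.008687526390e-03, tolerance = 1e-10)

  # degenerate groups: zero dispersion or a single value leave p undefined
  expect_true(is.na(summarize_perturbagen(c(0, 0, 0, 0, 0))$p))
  expect_true(is.na(summarize_perturbagen(-0.4)$p))
  expect_error(summarize_perturbagen(numeric(0)),
               class = "cmapscreen_argument_error")
  expect_error(summarize_perturbagen(c(1, NA)),
               class = "cmapscreen_argument_error")
})

test_that("p-values respond monotonically to effect size and replicate count", {
  tz <- cmapscreen:::t_test_zero
  means <- seq(0.1, 2, by = 0.1)
  p_by_mean <- tz(rep(10L, length(means)), -means, rep(1, length(means)))$p
  expect_true(all(diff(p_by_mean) <= 0))
  ns <- c(3L, 5L, 10L, 20L, 50L, 100L)
  p_by_n <- tz(ns, rep(-0.5, length(ns)), rep(1, length(ns)))$p
  expect_true(all(diff(p_by_n) <= 0))
})

test_that("selection keeps the conjunction of direction and significance", {
  toy <- data.frame(pert_id = c("a", "b", "c", "d"),
                    mean_expression = c(-0.5, -0.5, 0.5, -0.9),
                    p_value = c(1e-7, 1e-5, 1e-9, NA),
                    stringsAsFactors = FALSE)
  sel <- select_candidates(toy, screen_config())
  expect_equal(sel$pert_id, "a")          # b fails p, c fails sign, d has NA p
  expect_equal(nrow(select_candidates(toy[0, ], screen_config())), 0L)

  up <- select_candidates(toy, screen_config(direction = "up", p_threshold = 1e-6))
  expect_equal(up$pert_id, "c")
})

test_that("ranking orders by mean ascending with p then pert_id tie-breaks", {
  sel <- data.frame(pert_id = c("Z", "A", "M"),
                    pert_iname = c("z", "a", "m"),
                    n_profiles = c(5L, 5L, 5L),
                    mean_expression = c(-0.5, -0.5, -0.9),
                    p_value = c(1e-7, 1e-8, 1e-6),
                    stringsAsFactors = FALSE)
  tab <- rank_candidates(sel, screen_config())
  expect_equal(tab$pert_id, c("M", "A", "Z"))   # A beats Z on smaller p
  expect_equal(tab$ranking, 1:3)

  tie_p <- sel; tie_p$p_value <- 1e-7; tie_p$mean_expression <- -0.5
  expect_equal(rank_candidates(tie_p, screen_config())$pert_id,
               c("A", "M", "Z"))                # falls through to pert_id
})

test_that("exclusions match by id or case-insensitive name and warn on misses", {
  tab <- published_candidates()
  curated <- apply_exclusions(tab, c("ikk-2-INHIBITOR-v", "BRD-K77987382",
                                     "D-64131"))
  expect_equal(nrow(curated), 13L)
  expect_equal(curated$ranking, 1:13)
  expect_false(any(curated$pert_iname %in%
                     c("IKK-2-inhibitor-V", "mebendazole", "D-64131")))

  expect_identical(apply_exclusions(tab, character(0)), tab)
  expect_warning(out <- apply_exclusions(tab, "nonexistent-drug"),
                 "nonexistent-drug")
  expect_equal(nrow(out), nrow(tab))
})

test_that("run_screen equals an independent naive loop on a random instance", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 20, n_compounds = 60, profiles_per_compound = c(3L, 12L),
    frac_effect = 0.3, delta = -1.2, seed = 99))
  cfg <- screen_config(p_threshold = 1e-3)
  got <- run_screen(sim$matrix, sim$sig_meta, sim$gene_meta, cfg)
  want <- naive_screen(sim$matrix, sim$sig_meta, sim$gene_meta, cfg)
  expect_equal(got$pert_id, want$pert_id)
  expect_equal(got$n_profiles, want$n_profiles)
  expect_equal(got$mean_expression, want$mean_expression, tolerance = 1e-10)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
})

test_that("the candidate table is invariant to column and metadata row order", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 10, n_compounds = 40, profiles_per_compound = 8,
    frac_effect = 0.25, delta = -1.0, seed = 5))
  cfg <- screen_config(p_threshold = 1e-3)
  base <- run_screen(sim$matrix, sim$sig_meta, sim$gene_meta, cfg)

  set.seed(1)
  perm_cols <- sample(ncol(sim$matrix))
  shuffled <- sig_matrix(unclass(sim$matrix)[, perm_cols],
                         rownames(sim$matrix), colnames(sim$matrix)[perm_cols])
  perm_rows <- sample(nrow(sim$sig_meta))
  got <- run_screen(shuffled, sim$sig_meta[perm_rows, ], sim$gene_meta, cfg)
  expect_equal(got$pert_id, base$pert_id)
  expect_equal(got$mean_expression, base$mean_expression, tolerance = 1e-12)
  expect_equal(got$p_value, base$p_value, tolerance = 1e-12)
})

test_that("run_screen resolves targets by symbol, errors usefully, empties gracefully", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 9, n_compounds = 10, profiles_per_compound = 4, seed = 2))
  cfg_symbol <- screen_config(target_gene = "CROT", p_threshold = 0.5,
                              min_profiles = 4)
  cfg_id <- screen_config(target_gene = "54677", p_threshold = 0.5,
                          min_profiles = 4)
  by_symbol <- run_screen(sim$matrix, sim$sig_meta, sim$gene_meta, cfg_symbol)
  by_id <- run_screen(sim$matrix, sim$sig_meta, sim$gene_meta, cfg_id)
  expect_equal(by_symbol$pert_id, by_id$pert_id)

  expect_error(run_screen(sim$matrix, sim$sig_meta, sim$gene_meta,
                          screen_config(target_gene = "NOSUCHGENE")),
               class = "cmapscreen_lookup_error")

  expect_warning(
    empty <- run_screen(sim$matrix, sim$sig_meta, sim$gene_meta,
                        screen_config(min_profiles = 50)),
    "no perturbagen")
  expect_equal(nrow(empty), 0L)

  # path-based source must agree with the in-memory matrix
  dir <- withr::local_tempdir()
  paths <- write_simulated_dataset(sim, dir, format = "gctx")
  from_file <- run_screen(paths$matrix, sim$sig_meta, sim$gene_meta, cfg_id)
  expect_equal(from_file, by_id)
})

test_that("every emitted candidate satisfies the selection contract", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 10, n_compounds = 80, profiles_per_compound = c(2L, 15L),
    frac_effect = 0.4, delta = -1.5, seed = 13))
  cfg <- screen_config(p_threshold = 1e-3, min_profiles = 5)
  tab <- run_screen(sim$matrix, sim$sig_meta, sim$gene_meta, cfg)
  expect_true(all(tab$n_profiles >= cfg$min_profiles))
  expect_true(all(tab$p_value < cfg$p_threshold))
  expect_true(all(tab$mean_expression < 0))
  expect_equal(tab$ranking, seq_len(nrow(tab)))
  expect_true(!is.unsorted(tab$mean_expression))
})
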