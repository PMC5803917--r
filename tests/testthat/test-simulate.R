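test_that("simulation is deterministic under a fixed seed", {
  cfg <- fix_planted_config(n_genes = 200, n_patients = 3, seed = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$truth, s2$truth)

  s3 <- simulate_cohort(fix_planted_config(n_genes = 200, n_patients = 3,
                                           seed = 6))
  expect_false(identical(s1$values, s3$values))
})

test_that("the simulated knowledge base partitions all genes by default", {
  cfg <- simulation_config(n_genes = 500, pathway_size_range = c(20, 40),
                           n_patients = 2, arms = "BM", seed = 2)
  sim <- simulate_cohort(cfg)
  expect_length(kb_universe(sim$kb), 500L)
  expect_equal(nrow(kb_validate(sim$kb)$violations), 0L)
  sizes <- lengths(sim$kb$pathways$genes)
  expect_true(all(sizes >= 20 & sizes <= 40 + 19))  # tail merge may widen one
})

test_that("in the noiseless limit every planted gene is a DEG in every patient", {
  cfg <- simulation_config(
    n_genes = 120, pathway_size_range = c(20, 20), n_patients = 4,
    arms = "BM", probes_per_gene_range = c(1, 1), probe_jitter_sd = 0,
    noise_sd = 0, absent_call_rate = 0,
    planted_pathways = tibble::tibble(pathway = "PW001", delta = 2,
                                      responder_fraction = 1,
                                      affected_gene_fraction = 1),
    seed = 8)
  sim <- simulate_cohort(cfg)
  res <- analyze_cohort(sim)
  planted_genes <- sim$truth$planted$affected_genes[[1]]
  for (col in attr(res$degs, "columns")) {
    expect_setequal(deg_genes(res$degs, col, "up"), planted_genes)
  }
  expect_equal(res$summary$n_enriched[res$summary$pathway == "PW001"], 4L)
})

test_that("a null cohort has no planted truth and the expected DEG tail mass", {
  cfg <- simulation_config(
    n_genes = 2000, pathway_size_range = c(20, 40), n_patients = 5,
    arms = "BM", probes_per_gene_range = c(1, 1), probe_jitter_sd = 0,
    noise_sd = 0.3, absent_call_rate = 0, seed = 17)
  sim <- simulate_cohort(cfg)
  expect_null(sim$truth$planted)
  expect_equal(nrow(sim$truth$gene_effects), 0L)

  res <- analyze_cohort(sim, cutoff = 1.0)
  # an unperturbed log2 FC is Normal(0, sqrt(2) * 0.3); expected DEG rate
  # is its two-sided tail mass beyond 1
  expected <- 2 * pnorm(-1, sd = sqrt(2) * 0.3)
  observed <- nrow(res$degs) / (2000 * 5)
  expect_equal(observed, expected, tolerance = 0.25)
})

test_that("infeasible or inconsistent configurations are rejected", {
  expect_error(simulation_config(n_genes = 50, pathway_size_range = c(60, 80)),
               class = "skinora_config_error")
  expect_error(simulation_config(n_genes = 100, n_pathways = 10,
                                 pathway_size_range = c(20, 30)),
               "infeasible", class = "skinora_config_error")
  expect_error(simulation_config(absent_call_rate = 1.5),
               class = "skinora_config_error")
  expect_error(
    simulation_config(planted_pathways = tibble::tibble(
      pathway = "PW001", delta = 1, responder_fraction = 2,
      affected_gene_fraction = 1)),
    class = "skinora_config_error")
  cfg <- simulation_config(n_genes = 100, pathway_size_range = c(50, 50),
                           planted_pathways = tibble::tibble(
                             pathway = "PW099", delta = 1,
                             responder_fraction = 1,
                             affected_gene_fraction = 1))
  expect_error(simulate_cohort(cfg), "PW099", class = "skinora_config_error")
})

test_that("probes failing the detection rule never reach the gene matrix", {
  cfg <- simulation_config(n_genes = 150, pathway_size_range = c(25, 25),
                           n_patients = 6, arms = "BM",
                           absent_call_rate = 0.6, seed = 23)
  sim <- simulate_cohort(cfg)
  design_arm <- sim$design[sim$design$arm == "BM", ]
  kept <- filter_by_detection(median_normalize(sim$values), sim$calls,
                              design_arm, threshold = 0.7)
  # recompute the rule directly per group
  for (grp in split(design_arm$sample_id,
                    paste(design_arm$arm, design_arm$condition))) {
    pm <- rowMeans(as.matrix(sim$calls[match(kept$probe_id,
                                             sim$calls$probe_id),
                                       grp]) %in% c("P", "M") |>
                     matrix(nrow = nrow(kept)))
    expect_true(all(pm >= 0.7))
  }
  gm <- suppressMessages(collapse_probes(kept, sim$probe_map))
  surviving_genes <- unique(sim$probe_map$gene[sim$probe_map$probe_id %in%
                                                 kept$probe_id])
  expect_setequal(gm$gene, toupper(surviving_genes))
})

test_that("type-I estimation validates its inputs and returns a fraction", {
  null_cfg <- simulation_config(n_genes = 150, pathway_size_range = c(25, 25),
                                n_patients = 3, arms = "BM",
                                probes_per_gene_range = c(1, 1), seed = 3)
  expect_error(estimate_type1(null_cfg, n_reps = 0),
               class = "skinora_config_error")
  expect_error(estimate_type1(fix_planted_config(), n_reps = 2),
               class = "skinora_config_error")
  frac <- estimate_type1(null_cfg, n_reps = 2)
  expect_gte(as.numeric(frac), 0)
  expect_lte(as.numeric(frac), 1)
  expect_equal(attr(frac, "n_calls"), 2L * 6L * 3L)  # reps x pathways x samples

  frac_all <- estimate_type1(null_cfg, n_reps = 2, alpha = 1)
  expect_lte(as.numeric(frac_all), 1)
})

test_that("power estimation recovers a strong plant and rises with effect size", {
  expect_error(estimate_power(simulation_config(), n_reps = 2),
               class = "skinora_config_error")
  strong <- fix_planted_config(n_genes = 300, n_patients = 4, delta = 2,
                               seed = 19, probes_per_gene_range = c(1, 1))
  pw <- estimate_power(strong, n_reps = 3)
  expect_equal(pw$pathway, "PW001")
  expect_equal(pw$recovery, 1)
  expect_equal(pw$top_rank_fraction, 1)

  rec <- vapply(c(0.5, 1, 2), function(delta) {
    cfg <- fix_planted_config(n_genes = 300, n_patients = 4, delta = delta,
                              seed = 19, probes_per_gene_range = c(1, 1))
    mean(estimate_power(cfg, n_reps = 3)$recovery)
  }, numeric(1))
  expect_true(all(diff(rec) >= 0))
})
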