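#' Configuration for the paired-cohort simulator
#'
#' Describes a synthetic before/after treatment microarray cohort: a gene
#' universe partitioned into pathways (the simulated knowledge base),
#' patients measured at baseline and after treatment in one or more arms,
#' several probes per gene, Present/Marginal/Absent detection calls, and
#' optional planted pathway-level log2 shifts with known ground truth.
#'
#' The intensity model is log-normal: each (gene, patient, arm) draws a
#' baseline log2 level from `Normal(baseline_log2_mean, baseline_log2_sd)`;
#' baseline and treated samples add independent `Normal(0, noise_sd)` log2
#' measurement noise; treated samples of responder patients additionally
#' shift affected genes of planted pathways by `delta` log2 units. Probe
#' intensities jitter around their gene's sample value by
#' `Normal(0, probe_jitter_sd)` and are exponentiated to the linear scale.
#' Detection calls are drawn independently of intensity (Absent with rate
#' `absent_call_rate`, otherwise Marginal with rate `marginal_call_rate`).
#'
#' @param n_genes Number of genes in the simulated platform/knowledge base.
#' @param pathway_size_range Integer range (lo, hi) of pathway sizes.
#' @param n_pathways Number of pathways, or `NULL` (default) to partition
#'   all genes into pathways, making the knowledge-base universe equal the
#'   full gene set.
#' @param overlap_fraction Fraction of each pathway's size added as genes
#'   shared with other pathways. Default 0.
#' @param n_patients Patients per arm (paired baseline/treated samples).
#'   Default 10.
#' @param arms Character vector of treatment arm labels. Default
#'   `c("BM", "PC")`.
#' @param probes_per_gene_range Integer range of probes per gene.
#' @param probe_jitter_sd Log2 sd of probe-level jitter around the gene
#'   value.
#' @param baseline_log2_mean,baseline_log2_sd Log2 mean/sd of baseline
#'   gene levels.
#' @param noise_sd Log2 sd of per-sample measurement noise (a log2 fold
#'   change of an unperturbed gene then has sd `sqrt(2) * noise_sd`).
#' @param absent_call_rate Probability a (probe, sample) call is Absent.
#' @param marginal_call_rate Probability a detected call is Marginal
#'   rather than Present.
#' @param planted_pathways `NULL` (null cohort) or a data frame with
#'   columns `pathway`, `delta` (log2 shift), `responder_fraction`,
#'   `affected_gene_fraction`.
#' @param seed Integer seed; fixes all randomness end to end.
#' @return A validated list of class `skinora_sim_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              pathway_size_range = c(20, 40),
                              n_pathways = NULL,
                              overlap_fraction = 0,
                              n_patients = 10,
                              arms = c("BM", "PC"),
                              probes_per_gene_range = c(1, 3),
                              probe_jitter_sd = 0.1,
                              baseline_log2_mean = 6,
                              baseline_log2_sd = 1,
                              noise_sd = 0.3,
                              absent_call_rate = 0.05,
                              marginal_call_rate = 0.05,
                              planted_pathways = NULL,
                              seed = 1L) {
  stopifnot(length(pathway_size_range) == 2L,
            length(probes_per_gene_range) == 2L)
  pathway_size_range <- as.integer(round(pathway_size_range))
  probes_per_gene_range <- as.integer(round(probes_per_gene_range))
  if (pathway_size_range[1] < 1 ||
      pathway_size_range[2] < pathway_size_range[1]) {
    abort_config("`pathway_size_range` must be an increasing positive range")
  }
  if (probes_per_gene_range[1] < 1 ||
      probes_per_gene_range[2] < probes_per_gene_range[1]) {
    abort_config("`probes_per_gene_range` must be an increasing positive range")
  }
  if (n_genes < pathway_size_range[1]) {
    abort_config("`n_genes` is smaller than the minimum pathway size")
  }
  if (!is.null(n_pathways) &&
      n_pathways * pathway_size_range[1] > n_genes) {
    abort_config("infeasible: pathway sizes exceed the gene count")
  }
  assert_fraction(overlap_fraction, "overlap_fraction")
  assert_fraction(absent_call_rate, "absent_call_rate")
  assert_fraction(marginal_call_rate, "marginal_call_rate")
  for (nm in c("probe_jitter_sd", "baseline_log2_sd", "noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort_config(sprintf("`%s` must be a single non-negative number", nm))
    }
  }
  if (n_patients < 1) abort_config("`n_patients` must be >= 1")
  if (!is.null(planted_pathways)) {
    planted_pathways <- as_tibble(planted_pathways)
    need <- c("pathway", "delta", "responder_fraction",
              "affected_gene_fraction")
    miss <- setdiff(need, names(planted_pathways))
    if (length(miss)) {
      abort_config(sprintf("`planted_pathways` missing column(s): %s",
                           paste(miss, collapse = ", ")))
    }
    for (f in c("responder_fraction", "affected_gene_fraction")) {
      if (any(planted_pathways[[f]] < 0 | planted_pathways[[f]] > 1)) {
        abort_config(sprintf("`planted_pathways$%s` must lie in [0, 1]", f))
      }
    }
  }
  structure(list(
    n_genes = as.integer(n_genes),
    pathway_size_range = pathway_size_range,
    n_pathways = if (is.null(n_pathways)) NULL else as.integer(n_pathways),
    overlap_fraction = overlap_fraction,
    n_patients = as.integer(n_patients),
    arms = arms,
    probes_per_gene_range = probes_per_gene_range,
    probe_jitter_sd = probe_jitter_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    noise_sd = noise_sd,
    absent_call_rate = absent_call_rate,
    marginal_call_rate = marginal_call_rate,
    planted_pathways = planted_pathways,
    seed = as.integer(seed)
  ), class = "skinora_sim_config")
}

#' Simulate a paired treatment cohort with known ground truth
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `skinora_cohort` with elements `values` (wide
#'   probe x sample intensity tibble), `calls` (matching P/M/A tibble),
#'   `design` (sample design tibble), `probe_map` (probe to gene),
#'   `kb` (the simulated `skinora_kb`), `truth` (planted pathways with
#'   responder patients and affected genes; per-(gene, patient) true log2
#'   shifts) and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "skinora_sim_config"))
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  kb <- simulate_kb(cfg, genes)

  if (!is.null(cfg$planted_pathways)) {
    missing <- setdiff(cfg$planted_pathways$pathway, kb$pathways$pathway)
    if (length(missing)) {
      abort_config(sprintf(
        "planted pathway(s) not generated (have %d pathways): %s",
        nrow(kb$pathways), paste(missing, collapse = ", ")))
    }
  }

  patients <- sprintf("PT%02d", seq_len(cfg$n_patients))
  design <- tidyr::expand_grid(patient = patients, arm = cfg$arms,
                               condition = c("baseline", "treated"))
  design$sample_id <- paste(design$patient, design$arm, design$condition,
                            sep = "_")
  design <- design[, c("sample_id", "patient", "arm", "condition")]

  # planted ground truth
  planted <- NULL
  effect <- matrix(0, nrow = cfg$n_genes, ncol = cfg$n_patients,
                   dimnames = list(genes, patients))
  if (!is.null(cfg$planted_pathways) && nrow(cfg$planted_pathways)) {
    planted <- cfg$planted_pathways
    planted$responders <- vector("list", nrow(planted))
    planted$affected_genes <- vector("list", nrow(planted))
    for (i in seq_len(nrow(planted))) {
      pw_genes <- kb$pathways$genes[[match(planted$pathway[i],
                                           kb$pathways$pathway)]]
      n_resp <- round(planted$responder_fraction[i] * cfg$n_patients)
      n_aff <- round(planted$affected_gene_fraction[i] * length(pw_genes))
      resp <- sort(sample(patients, n_resp))
      aff <- sort(sample(pw_genes, n_aff))
      planted$responders[[i]] <- resp
      planted$affected_genes[[i]] <- aff
      effect[aff, resp] <- effect[aff, resp] + planted$delta[i]
    }
  }

  n_probes <- runif_int(cfg$probes_per_gene_range[1],
                        cfg$probes_per_gene_range[2], cfg$n_genes)
  probe_gene <- rep(genes, n_probes)
  probe_ids <- sprintf("%s_at%d", probe_gene,
                       unlist(lapply(n_probes, seq_len), use.names = FALSE))
  probe_row <- match(probe_gene, genes)

  samples <- design$sample_id
  vals <- matrix(NA_real_, nrow = length(probe_ids), ncol = length(samples),
                 dimnames = list(probe_ids, samples))
  for (arm in cfg$arms) {
    base_log2 <- matrix(
      stats::rnorm(cfg$n_genes * cfg$n_patients, cfg$baseline_log2_mean,
                   cfg$baseline_log2_sd),
      nrow = cfg$n_genes, dimnames = list(genes, patients))
    for (cond in c("baseline", "treated")) {
      gene_val <- base_log2 +
        matrix(stats::rnorm(length(base_log2), 0, cfg$noise_sd),
               nrow = cfg$n_genes)
      if (cond == "treated") gene_val <- gene_val + effect
      ids <- design$sample_id[design$arm == arm & design$condition == cond]
      pt <- design$patient[match(ids, design$sample_id)]
      probe_val <- gene_val[probe_row, match(pt, patients), drop = FALSE] +
        matrix(stats::rnorm(length(probe_ids) * length(ids), 0,
                            cfg$probe_jitter_sd),
               nrow = length(probe_ids))
      vals[, ids] <- 2^probe_val
    }
  }

  call_mat <- matrix(
    ifelse(stats::runif(length(vals)) < cfg$absent_call_rate, "A",
           ifelse(stats::runif(length(vals)) < cfg$marginal_call_rate,
                  "M", "P")),
    nrow = nrow(vals), dimnames = dimnames(vals))

  values <- dplyr::bind_cols(tibble(probe_id = probe_ids),
                             as_tibble(vals))
  calls <- dplyr::bind_cols(tibble(probe_id = probe_ids),
                            as_tibble(call_mat))

  truth <- list(
    planted = planted,
    gene_effects = as_tibble(as.table(effect), .name_repair = "minimal") |>
      stats::setNames(c("gene", "patient", "delta")) |>
      dplyr::filter(.data$delta != 0)
  )
  structure(list(values = values, calls = calls, design = design,
                 probe_map = tibble(probe_id = probe_ids, gene = probe_gene),
                 kb = kb, truth = truth, config = cfg),
            class = "skinora_cohort")
}

simulate_kb <- function(cfg, genes) {
  shuffled <- sample(genes)
  sizes <- integer(0)
  total <- 0L
  max_pw <- cfg$n_pathways %||% Inf
  lo <- cfg$pathway_size_range[1]; hi <- cfg$pathway_size_range[2]
  while (length(sizes) < max_pw && total + lo <= cfg$n_genes) {
    s <- runif_int(lo, hi, 1L)
    s <- min(s, cfg$n_genes - total)
    sizes <- c(sizes, s)
    total <- total + s
  }
  if (is.null(cfg$n_pathways) && total < cfg$n_genes) {
    # tail remainder too small for its own pathway: fold into the last one
    sizes[length(sizes)] <- sizes[length(sizes)] + (cfg$n_genes - total)
  }
  idx_end <- cumsum(sizes)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  gene_sets <- lapply(seq_along(sizes), function(i) {
    sort(shuffled[idx_start[i]:idx_end[i]])
  })
  if (cfg$overlap_fraction > 0 && length(sizes) > 1L) {
    gene_sets <- lapply(seq_along(gene_sets), function(i) {
      pool <- setdiff(shuffled, gene_sets[[i]])
      n_extra <- round(cfg$overlap_fraction * length(gene_sets[[i]]))
      sort(c(gene_sets[[i]], sample(pool, min(n_extra, length(pool)))))
    })
  }
  knowledge_base(tibble(
    pathway = sprintf("PW%03d", seq_along(gene_sets)),
    category = "simulated",
    genes = gene_sets
  ))
}

#' Run the standard analysis pipeline on a cohort
#'
#' Convenience wrapper chaining [median_normalize()],
#' [filter_by_detection()], [collapse_probes()], [fold_change()],
#' [call_degs()] and [enrich()] for one arm of a (simulated or real)
#' cohort.
#'
#' @param cohort A `skinora_cohort`, or any list with `values`, `calls`,
#'   `design`, `probe_map`, `kb`.
#' @param arm Arm to analyse; defaults to the first arm in the design.
#' @param cutoff DEG log2 fold-change cutoff. Default 1.0.
#' @param alpha Enrichment significance level. Default 0.05.
#' @param detection_threshold Present/Marginal rate threshold. Default 0.70.
#' @param mode Fold-change mode, `"per_sample"` or `"aggregate"`.
#' @param ... Passed on to [enrich()].
#' @return A list with `fc`, `degs`, `enrichment`, `summary`.
#' @export
analyze_cohort <- function(cohort, arm = NULL, cutoff = 1.0, alpha = 0.05,
                           detection_threshold = 0.70,
                           mode = c("per_sample", "aggregate"), ...) {
  mode <- match.arg(mode)
  arm <- arm %||% cohort$design$arm[1L]
  design_arm <- cohort$design[cohort$design$arm == arm, ]
  norm <- median_normalize(cohort$values)
  kept <- filter_by_detection(norm, cohort$calls, design_arm,
                              threshold = detection_threshold)
  gm <- suppressMessages(collapse_probes(kept, cohort$probe_map))
  fc <- fold_change(gm, design_arm, arm = arm, mode = mode)
  degs <- call_degs(fc, cutoff = cutoff)
  res <- enrich(degs, cohort$kb, alpha = alpha, ...)
  list(fc = fc, degs = degs, enrichment = res,
       summary = enrichment_summary(res))
}

#' Estimate the type-I error of the enrichment pipeline
#'
#' Repeatedly simulates null cohorts (no planted pathways), runs the full
#' pipeline (normalise, filter, collapse, per-sample fold change, DEG call,
#' enrichment) and returns the fraction of (pathway, sample, replicate)
#' results with p below `alpha`. The exact test is conservative, so this
#' fraction is expected at or below the nominal level.
#'
#' @param cfg A null [simulation_config()] (no planted pathways).
#' @param n_reps Number of replicate cohorts (>= 1).
#' @param alpha Nominal significance level. Default 0.05.
#' @param arm Arm to analyse; defaults to the first configured arm.
#' @param cutoff DEG cutoff used in the pipeline. Default 1.0.
#' @return The fraction of significant calls, with attributes
#'   `n_calls` (total tests) and `n_reps`.
#' @export
estimate_type1 <- function(cfg, n_reps, alpha = 0.05, arm = NULL,
                           cutoff = 1.0) {
  stopifnot(inherits(cfg, "skinora_sim_config"))
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1) {
    abort_config("`n_reps` must be a positive integer")
  }
  if (!is.null(cfg$planted_pathways) &&
      any(cfg$planted_pathways$delta != 0)) {
    abort_config("`cfg` must be a null configuration (no planted effects)")
  }
  hits <- 0L; total <- 0L
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg; cfg_r$seed <- cfg$seed + r
    sim <- simulate_cohort(cfg_r)
    res <- analyze_cohort(sim, arm = arm, cutoff = cutoff,
                          alpha = alpha)$enrichment
    hits <- hits + sum(res$p_value < alpha)
    total <- total + nrow(res)
  }
  structure(hits / total, n_calls = total, n_reps = n_reps)
}

#' Estimate recovery power for planted pathways
#'
#' Repeatedly simulates cohorts with the configured planted effects, runs
#' the full pipeline and scores, per planted pathway and replicate:
#' \describe{
#'   \item{recovered}{the pathway is enriched (p < alpha) in at least
#'     `responder_fraction * n_patients - 1` treated samples;}
#'   \item{top ranked}{the pathway has the smallest median p-value across
#'     treated samples among all pathways.}
#' }
#'
#' @param cfg A [simulation_config()] with at least one planted pathway.
#' @param n_reps Number of replicate cohorts (>= 1).
#' @inheritParams estimate_type1
#' @return A tibble: `pathway`, `recovery`, `top_rank_fraction`, `n_reps`.
#' @export
estimate_power <- function(cfg, n_reps, alpha = 0.05, arm = NULL,
                           cutoff = 1.0) {
  stopifnot(inherits(cfg, "skinora_sim_config"))
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1) {
    abort_config("`n_reps` must be a positive integer")
  }
  if (is.null(cfg$planted_pathways) || !nrow(cfg$planted_pathways)) {
    abort_config("`cfg` must plant at least one pathway")
  }
  planted <- cfg$planted_pathways
  recovered <- stats::setNames(numeric(nrow(planted)), planted$pathway)
  top <- recovered
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg; cfg_r$seed <- cfg$seed + r
    sim <- simulate_cohort(cfg_r)
    res <- analyze_cohort(sim, arm = arm, cutoff = cutoff,
                          alpha = alpha)$enrichment
    med_p <- as_tibble(res) |>
      dplyr::summarise(med = stats::median(.data$p_value), .by = "pathway")
    best <- med_p$pathway[which.min(med_p$med)]
    summ <- enrichment_summary(res)
    for (i in seq_len(nrow(planted))) {
      pw <- planted$pathway[i]
      need <- ceiling(planted$responder_fraction[i] * cfg$n_patients) - 1
      got <- summ$n_enriched[summ$pathway == pw]
      if (length(got) && got >= need) {
        recovered[pw] <- recovered[pw] + 1
      }
      if (identical(best, pw)) top[pw] <- top[pw] + 1
    }
  }
  tibble(pathway = planted$pathway,
         recovery = unname(recovered[planted$pathway]) / n_reps,
         top_rank_fraction = unname(top[planted$pathway]) / n_reps,
         n_reps = n_reps)
}
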