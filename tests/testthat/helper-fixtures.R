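# Shared fixtures, all built in code.

fix_design <- function(n_pat = 3, arm = "BM") {
  d <- tidyr::expand_grid(patient = sprintf("PT%d", seq_len(n_pat)),
                          arm = arm,
                          condition = c("baseline", "treated"))
  d$sample_id <- paste(d$patient, d$arm, d$condition, sep = "_")
  d[, c("sample_id", "patient", "arm", "condition")]
}

# wide probe matrix with uniform intensities, one probe per row
fix_values <- function(probes, samples, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(length(probes) * length(samples), 1, 100),
                nrow = length(probes),
                dimnames = list(NULL, samples))
    dplyr::bind_cols(tibble::tibble(probe_id = probes),
                     tibble::as_tibble(m))
  })
}

fix_calls <- function(values, call = "P") {
  calls <- values
  calls[setdiff(names(calls), "probe_id")] <- call
  calls
}

fix_kb <- function() {
  knowledge_base(tibble::tibble(
    pathway = c("P1", "P2", "P3"),
    category = c("catA", "catA", "catB"),
    genes = list(c("A", "B", "C"), c("C", "D"), c("E", "F", "G", "H"))
  ))
}

# long fold-change table with deterministic values (args recycled by tibble)
fix_fc <- function(genes, columns, values) {
  fc <- tibble::tibble(gene = genes, column_id = columns, log2fc = values)
  structure(fc, mode = "per_sample", arm = "BM",
            class = c("skinora_fc", class(fc)))
}

write_gmt_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# small planted-cohort config for end-to-end tests
fix_planted_config <- function(n_genes = 400, n_patients = 5, delta = 2,
                               seed = 11, ...) {
  simulation_config(
    n_genes = n_genes, pathway_size_range = c(20, 20),
    n_patients = n_patients, arms = "BM",
    planted_pathways = tibble::tibble(
      pathway = "PW001", delta = delta,
      responder_fraction = 1, affected_gene_fraction = 0.8),
    seed = seed, ...)
}
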