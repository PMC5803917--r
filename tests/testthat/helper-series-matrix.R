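# Synthetic GEO-style series-matrix fixture, generated in code.
# Gene identifiers are drawn from the demo knowledge base so that
# enrichment against it is meaningful.
write_series_matrix_fixture <- function(path, n_pat = 3, seed = 101) {
  kb <- demo_kb()
  genes <- kb_universe(kb)
  inflam <- kb$pathways$genes[[match("Inflammation", kb$pathways$pathway)]]
  design <- dplyr::bind_rows(
    fix_design(n_pat, arm = "BM"),
    fix_design(n_pat, arm = "PC"))
  titles <- sprintf(
    "AD lesional skin, patient %s, %s, %s treatment",
    sub("PT", "", design$patient),
    ifelse(design$arm == "BM", "betamethasone", "pimecrolimus"),
    ifelse(design$condition == "baseline", "before", "after"))
  gsm <- sprintf("GSM%05d", seq_len(nrow(design)))

  withr::with_seed(seed, {
    m <- matrix(2^rnorm(length(genes) * nrow(design), mean = 6, sd = 1),
                nrow = length(genes))
    # plant: inflammation genes strongly DOWN after BM treatment
    trt_bm <- which(design$arm == "BM" & design$condition == "treated")
    base_bm <- which(design$arm == "BM" & design$condition == "baseline")
    m[match(inflam, genes), trt_bm] <-
      m[match(inflam, genes), base_bm] / 8
  })
  lines <- c(
    "!Series_title\t\"synthetic paired treatment fixture\"",
    paste0("!Sample_title\t", paste(sprintf('"%s"', titles), collapse = "\t")),
    paste0("!Sample_geo_accession\t",
           paste(sprintf('"%s"', gsm), collapse = "\t")),
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", sprintf('"%s"', gsm)), collapse = "\t"),
    vapply(seq_along(genes), function(i) {
      paste(c(sprintf('"%s"', genes[i]),
              formatC(m[i, ], format = "f", digits = 4)), collapse = "\t")
    }, character(1)),
    "!series_matrix_table_end")
  writeLines(lines, path)
  list(path = path, genes = genes, design = design, gsm = gsm)
}
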