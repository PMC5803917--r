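#' Read a GEO series-matrix text file
#'
#' Parses the plain-text "series matrix" layout deposited by GEO:
#' `!`-prefixed metadata lines, then the expression table between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers with
#' one column per sample. Gzipped files are read transparently.
#'
#' @param path Path to the series-matrix file (`.txt` or `.txt.gz`).
#' @return A list with `values` (wide tibble, `probe_id` + sample columns)
#'   and `samples` (tibble of per-sample metadata: `sample_id` plus one
#'   column per `!Sample_*` field, e.g. `title`).
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) {
    abort_parse(sprintf("series-matrix file not found: %s", path))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    abort_parse(sprintf(
      "'%s' does not look like a series-matrix file (table markers missing)",
      path))
  }
  tbl_lines <- lines[(begin + 1L):(end - 1L)]
  values <- readr::read_tsv(I(tbl_lines), show_col_types = FALSE,
                            progress = FALSE)
  names(values)[1L] <- "probe_id"
  values$probe_id <- as.character(values$probe_id)

  meta_lines <- grep("^!Sample_", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    key <- sub("^!Sample_", "", parts[1L])
    vals <- gsub('^"|"$', "", parts[-1L])
    if (length(vals) == ncol(values) - 1L) {
      k <- key
      j <- 1L
      while (k %in% names(meta)) {
        j <- j + 1L
        k <- paste0(key, ".", j)
      }
      meta[[k]] <- vals
    }
  }
  samples <- dplyr::bind_cols(
    tibble(sample_id = names(values)[-1L]),
    as_tibble(meta))
  list(values = values, samples = samples)
}

#' Reproduce the paired-treatment analysis from a GEO series matrix
#'
#' Ingests a deposited series matrix (downloaded by accession, or read
#' from a local file), infers or accepts a baseline/treated design for the
#' treatment arms, and runs aggregate-mode DEG counting plus per-sample
#' enrichment against a knowledge base. Detection calls are not part of
#' the series-matrix layout, so the detection filter does not apply here.
#'
#' @param accession GEO series accession (default `"GSE32473"`, the
#'   deposited betamethasone/pimecrolimus atopic-dermatitis cohort).
#' @param series_matrix Optional path to an already-downloaded
#'   series-matrix file; when given, no network access is attempted.
#' @param kb Knowledge base to enrich against. Defaults to [demo_kb()];
#'   supply the platform's probe-level GMT for a full reproduction.
#' @param probe_map Optional probe-to-gene tibble. When `NULL`, probe
#'   identifiers are assumed to already be gene symbols.
#' @param design Optional design tibble (see [read_design()]). When
#'   `NULL`, arm and condition are inferred from sample titles (arm from
#'   "betamethasone"/"BM" vs "pimecrolimus"/"PC" matches, condition from
#'   "before/baseline/pre" vs "after/post/treated" matches); inference
#'   failure is an error listing the sample titles.
#' @param cutoff DEG log2 cutoff. Default 1.0.
#' @param alpha Enrichment significance level. Default 0.05.
#' @param timeout Download timeout in seconds. Default 120.
#' @return A list with `report` (tibble: `metric`, `arm`, `value`),
#'   `per_arm` (per-arm fold changes, DEG sets and enrichment) and
#'   `design`.
#' @export
reproduce_geo <- function(accession = "GSE32473", series_matrix = NULL,
                          kb = demo_kb(), probe_map = NULL, design = NULL,
                          cutoff = 1.0, alpha = 0.05, timeout = 120) {
  if (is.null(series_matrix)) {
    series_matrix <- download_series_matrix(accession, timeout = timeout)
  }
  sm <- read_series_matrix(series_matrix)
  if (is.null(design)) {
    design <- infer_design_from_titles(sm$samples)
  } else {
    design <- validate_design(design)
  }

  genes <- if (is.null(probe_map)) {
    gm <- sm$values
    names(gm)[1L] <- "gene"
    gm$gene <- toupper(gm$gene)
    gm[!duplicated(gm$gene), ]
  } else {
    suppressMessages(collapse_probes(sm$values, probe_map))
  }
  gm_norm <- gene_median_normalize(genes)

  per_arm <- list()
  report <- list()
  for (arm in unique(design$arm)) {
    design_arm <- design[design$arm == arm, ]
    fc_agg <- fold_change(gm_norm, design_arm, arm = arm, mode = "aggregate")
    degs_agg <- call_degs(fc_agg, cutoff = cutoff)
    fc_ps <- fold_change(gm_norm, design_arm, arm = arm, mode = "per_sample")
    degs_ps <- call_degs(fc_ps, cutoff = cutoff)
    res <- enrich(degs_ps, kb, alpha = alpha, universe = "kb_measured",
                  measured = gm_norm$gene)
    report <- c(report, list(tibble(
      metric = c(sprintf("DEG count, aggregate mode, cutoff %s",
                         format(cutoff)),
                 "DEG count per sample (mean)",
                 "pathway-sample pairs enriched"),
      arm = arm,
      value = c(nrow(degs_agg),
                nrow(degs_ps) / max(1L, length(attr(degs_ps, "columns"))),
                sum(res$enriched)))))
    per_arm[[arm]] <- list(fc_aggregate = fc_agg, degs_aggregate = degs_agg,
                           fc_per_sample = fc_ps, degs_per_sample = degs_ps,
                           enrichment = res)
  }
  list(report = dplyr::bind_rows(report), per_arm = per_arm, design = design)
}

gene_median_normalize <- function(genes) {
  out <- genes
  for (s in sample_columns(genes, "gene")) {
    med <- mid_median(out[[s]])
    if (!is.finite(med) || med <= 0) {
      abort_data(sprintf("sample '%s' has non-positive median", s))
    }
    out[[s]] <- out[[s]] / med
  }
  out
}

download_series_matrix <- function(accession, timeout = 120) {
  stub <- sub("\\d{1,3}$", "nnn", accession)
  url <- sprintf(
    "https://ftp.ncbi.nlm.nih.gov/geo/series/%s/%s/matrix/%s_series_matrix.txt.gz",
    stub, accession, accession)
  dest <- file.path(tempdir(), basename(url))
  ok <- tryCatch(
    withr::with_options(list(timeout = timeout), {
      utils::download.file(url, dest, mode = "wb", quiet = TRUE)
      TRUE
    }),
    error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok) || !file.exists(dest) || file.size(dest) == 0) {
    msg <- if (isTRUE(ok)) "empty download" else conditionMessage(ok)
    abort_network(sprintf(
      "could not download series matrix for %s from %s (%s); pass `series_matrix` to use a local copy",
      accession, url, msg))
  }
  dest
}

infer_design_from_titles <- function(samples) {
  if (!"title" %in% names(samples)) {
    abort_data("sample metadata has no 'title' field to infer the design from")
  }
  title <- samples$title
  arm <- dplyr::case_when(
    grepl("betamethasone|\\bBM\\b", title, ignore.case = TRUE) ~ "BM",
    grepl("pimecrolimus|\\bPC\\b", title, ignore.case = TRUE) ~ "PC",
    .default = NA_character_)
  condition <- dplyr::case_when(
    grepl("before|baseline|pre[- ]?treat|week[ _]?0|\\bday[ _]?0\\b", title,
          ignore.case = TRUE) ~ "baseline",
    grepl("after|post|treated|week[ _]?[1-9]", title,
          ignore.case = TRUE) ~ "treated",
    .default = NA_character_)
  patient <- sub(".*?(patient|subject|pat|pt)[ _#]*(\\d+).*", "\\2", title,
                 ignore.case = TRUE)
  patient[patient == title] <- NA_character_
  bad <- is.na(arm) | is.na(condition) | is.na(patient)
  if (any(bad)) {
    abort_data(paste0(
      "could not infer arm/condition/patient for sample title(s); ",
      "supply `design` explicitly:\n  ",
      paste(utils::head(title[bad], 10L), collapse = "\n  ")))
  }
  validate_design(tibble(sample_id = samples$sample_id,
                         patient = paste0("PT", patient),
                         arm = arm, condition = condition))
}
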