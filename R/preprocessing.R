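#' Read a wide expression (or detection-call) table
#'
#' Expects a tab-delimited file whose first column holds probe identifiers
#' and whose header row names the samples.
#'
#' @param path Path to the TSV file.
#' @param id_col Name to give the identifier column (default `"probe_id"`).
#' @return A tibble with the identifier column first.
#' @export
read_expression <- function(path, id_col = "probe_id") {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1L] <- id_col
  check_wide_matrix(df, id_col, path)
  df
}

#' Read a sample design table
#'
#' A design table has one row per array sample: `sample_id`, `patient`,
#' `arm` (treatment arm label) and `condition` (`"baseline"` or
#' `"treated"`). Every treated sample must have exactly one baseline sample
#' from the same patient and arm.
#'
#' @param path Path to the TSV file.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("design file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_design(df)
}

#' Validate a design table
#'
#' @param design Data frame with columns `sample_id`, `patient`, `arm`,
#'   `condition`.
#' @return The design as a tibble, invisibly checked.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "patient", "arm", "condition")
  missing <- setdiff(need, names(design))
  if (length(missing)) {
    abort_design(sprintf("design table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  design <- as_tibble(design)
  if (anyDuplicated(design$sample_id)) {
    abort_design("design table has duplicated sample_id values")
  }
  bad <- setdiff(unique(design$condition), c("baseline", "treated"))
  if (length(bad)) {
    abort_design(sprintf("condition must be 'baseline' or 'treated'; got: %s",
                         paste(bad, collapse = ", ")))
  }
  design
}

#' Read a probe-to-gene mapping table
#'
#' Two tab-separated columns, `probe_id` and `gene`. A probe may map to at
#' most one gene; probes without a mapping are dropped downstream.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `probe_id`, `gene`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("probe map not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1:2] <- c("probe_id", "gene")
  df[, c("probe_id", "gene")]
}

#' Median-scale each sample of an expression matrix
#'
#' Divides every sample (column) by that sample's median intensity, the
#' 50th-percentile scaling commonly applied to processed single-channel
#' microarray data. Scaling happens on the linear intensity scale; any log
#' transform is applied downstream. After scaling, every sample's median is
#' exactly 1, and the operation is idempotent.
#'
#' @param values Wide tibble: `probe_id` column plus one numeric column per
#'   sample.
#' @return The rescaled tibble, same shape.
#' @export
#' @examples
#' m <- tibble::tibble(probe_id = c("p1", "p2", "p3"), s1 = c(2, 4, 8))
#' median_normalize(m)
median_normalize <- function(values) {
  check_wide_matrix(values, "probe_id", "expression matrix")
  samples <- sample_columns(values, "probe_id")
  for (s in samples) {
    v <- values[[s]]
    if (any(v < 0, na.rm = TRUE)) {
      abort_data(sprintf("sample '%s' has negative intensities", s))
    }
    med <- mid_median(v)
    if (!is.finite(med) || med <= 0) {
      abort_data(sprintf(
        "sample '%s' has non-positive median intensity; cannot median-scale", s))
    }
    values[[s]] <- v / med
  }
  values
}

#' Filter probes by Present/Marginal detection-call rate
#'
#' Keeps a probe only if its fraction of Present-or-Marginal calls reaches
#' `threshold` within the analysis groups defined by the design's
#' (arm, condition) pairs. The boundary is inclusive: 7 P/M calls out of 10
#' at threshold 0.7 passes. By default (`group_rule = "every"`) a probe
#' must pass in every analysis group covered by `design`; `"any"` relaxes
#' this to at least one group.
#'
#' @param values Wide expression tibble (`probe_id` + sample columns).
#' @param calls Wide detection-call tibble of the same shape with entries
#'   `"P"`, `"M"` or `"A"`.
#' @param design Design table covering the samples under analysis (see
#'   [read_design()]); only samples present in both `values` and `design`
#'   enter the group rates, and the output is restricted to them.
#' @param threshold Minimum P/M fraction, in (0, 1]. Default 0.70.
#' @param group_rule `"every"` (default) or `"any"`.
#' @return The filtered `values` tibble (same sample columns, fewer rows).
#' @export
filter_by_detection <- function(values, calls, design, threshold = 0.70,
                                group_rule = c("every", "any")) {
  group_rule <- match.arg(group_rule)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold > 1) {
    abort_config("`threshold` must be a single value in (0, 1]")
  }
  check_wide_matrix(values, "probe_id", "expression matrix")
  check_wide_matrix(calls, "probe_id", "detection-call matrix")
  design <- validate_design(design)
  samples <- intersect(sample_columns(values, "probe_id"), design$sample_id)
  if (!length(samples)) abort_design("design covers none of the matrix samples")
  missing_calls <- setdiff(samples, sample_columns(calls, "probe_id"))
  if (length(missing_calls)) {
    abort_data(sprintf("detection calls missing for sample(s): %s",
                       paste(missing_calls, collapse = ", ")))
  }
  calls <- calls[match(values$probe_id, calls$probe_id), ]
  if (anyNA(calls$probe_id) || !identical(calls$probe_id, values$probe_id)) {
    abort_data("detection-call matrix does not cover all probes in `values`")
  }

  design <- design[design$sample_id %in% samples, ]
  groups <- split(design$sample_id, paste(design$arm, design$condition))
  pass <- lapply(groups, function(ids) {
    pm <- as.matrix(calls[, ids, drop = FALSE]) %in% c("P", "M")
    pm <- matrix(pm, nrow = nrow(calls))
    rowMeans(pm) >= threshold
  })
  keep <- if (group_rule == "every") {
    Reduce(`&`, pass)
  } else {
    Reduce(`|`, pass)
  }
  values[keep, c("probe_id", samples)]
}

#' Collapse probes to genes by the median
#'
#' Assigns to each gene, per sample, the median expression value across its
#' surviving probes (even counts: mean of the two central values). Probes
#' absent from the mapping are dropped with a message; a probe mapping to
#' more than one gene is an error.
#'
#' @param values Wide expression tibble (`probe_id` + sample columns).
#' @param probe_map Tibble with columns `probe_id`, `gene`.
#' @return Wide gene-level tibble: `gene` column plus the same sample
#'   columns.
#' @export
collapse_probes <- function(values, probe_map) {
  check_wide_matrix(values, "probe_id", "expression matrix")
  if (!all(c("probe_id", "gene") %in% names(probe_map))) {
    abort_data("`probe_map` needs columns `probe_id` and `gene`")
  }
  probe_map <- as_tibble(probe_map)
  probe_map$gene <- toupper(probe_map$gene)
  multi <- unique(probe_map$probe_id[duplicated(probe_map[, "probe_id"])])
  multi <- multi[vapply(multi, function(p) {
    length(unique(probe_map$gene[probe_map$probe_id == p])) > 1L
  }, logical(1))]
  if (length(multi)) {
    abort_data(sprintf(
      "probe(s) mapped to more than one gene (one gene per probe required): %s",
      paste(utils::head(multi, 5L), collapse = ", ")))
  }
  probe_map <- dplyr::distinct(probe_map)

  n_unmapped <- sum(!values$probe_id %in% probe_map$probe_id)
  if (n_unmapped > 0) {
    inform(sprintf("collapse_probes: dropping %d probe(s) with no gene mapping",
                   n_unmapped))
  }
  samples <- sample_columns(values, "probe_id")
  map_idx <- match(values$probe_id, probe_map$probe_id)
  keep <- !is.na(map_idx)
  if (!any(keep)) {
    out <- tibble(gene = character())
    for (s in samples) out[[s]] <- numeric()
    return(out)
  }
  mm <- as.matrix(values[keep, samples, drop = FALSE])
  # grouped median over (gene, sample); data.table's GForce median keeps
  # this fast for the probes-times-samples long form
  long <- data.table::data.table(
    gene = rep(probe_map$gene[map_idx[keep]], times = length(samples)),
    sample_id = rep(samples, each = sum(keep)),
    value = as.vector(mm))
  med <- long[, list(value = median(value)),
              by = c("gene", "sample_id")]
  out <- data.table::dcast(med, gene ~ sample_id, value.var = "value")
  out <- as_tibble(out)
  out[order(out$gene), c("gene", samples)]
}
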