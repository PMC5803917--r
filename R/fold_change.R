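#' Log2 fold changes versus baseline
#'
#' Computes log2 fold changes of treated samples against their baselines for
#' one treatment arm, either per sample (paired: each treated sample against
#' the same patient's baseline) or in aggregate (the median over treated
#' samples against the median over baselines, one column named
#' `"aggregate"`).
#'
#' A pseudo-value `eps` is added on the linear scale before taking logs so
#' that isolated zeros stay finite; gene/column pairs where both treated and
#' baseline intensities are exactly zero carry no fold-change information
#' and are excluded (with a message reporting the count).
#'
#' @param genes Wide gene-level tibble (`gene` column + sample columns),
#'   e.g. from [collapse_probes()]. Values are linear-scale intensities.
#' @param design Design table (see [read_design()]).
#' @param arm Which treatment arm of `design` to analyse.
#' @param mode `"per_sample"` (default) or `"aggregate"`.
#' @param baseline For `per_sample` mode: `"paired"` (default; each treated
#'   sample against its own patient's baseline) or `"pooled"` (against the
#'   median of all the arm's baseline samples).
#' @param eps Pseudo-value added on the linear scale. Default `1e-6`.
#' @return A tibble of class `skinora_fc` in long form: `gene`, `column_id`
#'   (treated sample id, or `"aggregate"`), `log2fc`; attributes `mode`,
#'   `arm`, `cutoff`-free.
#' @export
fold_change <- function(genes, design, arm,
                        mode = c("per_sample", "aggregate"),
                        baseline = c("paired", "pooled"),
                        eps = 1e-6) {
  mode <- match.arg(mode)
  baseline <- match.arg(baseline)
  check_wide_matrix(genes, "gene", "gene matrix")
  design <- validate_design(design)
  design <- design[design$arm == arm, ]
  if (!nrow(design)) abort_design(sprintf("no samples in arm '%s'", arm))
  samples <- sample_columns(genes, "gene")
  design <- design[design$sample_id %in% samples, ]
  base <- design[design$condition == "baseline", ]
  trt <- design[design$condition == "treated", ]
  if (!nrow(base) || !nrow(trt)) {
    abort_design(sprintf(
      "arm '%s' needs at least one baseline and one treated sample in the matrix",
      arm))
  }

  l2 <- function(x) log2(x + eps)
  if (mode == "aggregate") {
    t_med <- apply(as.matrix(genes[, trt$sample_id, drop = FALSE]), 1L, mid_median)
    b_med <- apply(as.matrix(genes[, base$sample_id, drop = FALSE]), 1L, mid_median)
    out <- tibble(gene = genes$gene, column_id = "aggregate",
                  log2fc = l2(t_med) - l2(b_med))
    drop <- t_med == 0 & b_med == 0
    out <- finalize_fc(out, drop, mode, arm)
    return(out)
  }

  cols <- lapply(seq_len(nrow(trt)), function(i) {
    t_id <- trt$sample_id[i]
    t_val <- genes[[t_id]]
    if (baseline == "paired") {
      b_id <- base$sample_id[base$patient == trt$patient[i]]
      if (length(b_id) != 1L) {
        abort_design(sprintf(
          "treated sample '%s' (patient %s, arm %s) has %d paired baseline sample(s); exactly one required",
          t_id, trt$patient[i], arm, length(b_id)))
      }
      b_val <- genes[[b_id]]
    } else {
      b_val <- apply(as.matrix(genes[, base$sample_id, drop = FALSE]), 1L,
                     mid_median)
    }
    tibble(gene = genes$gene, column_id = t_id,
           log2fc = l2(t_val) - l2(b_val),
           .drop = t_val == 0 & b_val == 0)
  })
  out <- dplyr::bind_rows(cols)
  finalize_fc(out[, c("gene", "column_id", "log2fc")], out$.drop, mode, arm)
}

finalize_fc <- function(out, drop, mode, arm) {
  if (any(drop)) {
    inform(sprintf(
      "fold_change: excluding %d gene/column value(s) with zero intensity in both conditions",
      sum(drop)))
    out <- out[!drop, ]
  }
  structure(out, mode = mode, arm = arm,
            class = c("skinora_fc", class(out)))
}

#' Pivot a fold-change table to wide form
#'
#' @param fc A `skinora_fc` long tibble.
#' @return Wide tibble: `gene` column plus one column per `column_id`.
#' @export
fc_wide <- function(fc) {
  tidyr::pivot_wider(as_tibble(fc), names_from = "column_id",
                     values_from = "log2fc")
}

#' Call differentially expressed genes at a log2 fold-change cutoff
#'
#' A gene is up-regulated in a column when its log2 fold change is greater
#' than or equal to `+cutoff`, and down-regulated when it is less than or
#' equal to `-cutoff` — boundary values are included on both sides. No
#' statistical test is involved: the call is purely threshold-based.
#'
#' @param fc A `skinora_fc` table (or any tibble with `gene`, `column_id`,
#'   `log2fc`).
#' @param cutoff Positive log2 fold-change threshold. Default 1.0
#'   (two-fold).
#' @return A tibble of class `skinora_degs`: `column_id`, `gene`,
#'   `direction` (`"up"`/`"down"`), `log2fc`; attribute `cutoff`, and
#'   attribute `columns` listing every column of `fc` (so columns with zero
#'   DEGs are not forgotten downstream).
#' @export
call_degs <- function(fc, cutoff = 1.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff <= 0) {
    abort_config("`cutoff` must be a single positive number of log2 units")
  }
  fc <- as_tibble(fc)
  hits <- fc[abs(fc$log2fc) >= cutoff, ]
  out <- tibble(column_id = hits$column_id,
                gene = hits$gene,
                direction = ifelse(hits$log2fc > 0, "up", "down"),
                log2fc = hits$log2fc)
  out <- out[order(out$column_id, out$direction, out$gene), ]
  structure(out, cutoff = cutoff,
            columns = unique(fc$column_id),
            class = c("skinora_degs", class(out)))
}

#' Genes of one DEG set
#'
#' @param degs A `skinora_degs` table.
#' @param column A `column_id` present in the table.
#' @param direction `"both"` (default), `"up"` or `"down"`.
#' @return Character vector of gene symbols.
#' @export
deg_genes <- function(degs, column, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  d <- degs[degs$column_id == column, ]
  if (direction != "both") d <- d[d$direction == direction, ]
  unique(d$gene)
}
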