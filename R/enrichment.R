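#' Per-sample pathway over-representation analysis
#'
#' Runs the exact over-representation test ([fisher_p()]) for every pathway
#' of the knowledge base against every DEG column (treated sample, or the
#' single `"aggregate"` column), so multiple samples are analysed
#' simultaneously instead of being averaged away. For each
#' (pathway, column) pair the 2x2 table counts unique genes within the
#' knowledge-base universe (up- and down-regulated genes pooled) and the
#' pathway is flagged enriched when its p-value is strictly below `alpha`.
#'
#' @param degs A `skinora_degs` table from [call_degs()] (or any tibble
#'   with `column_id`, `gene`; an attribute `columns` may list columns with
#'   zero DEGs).
#' @param kb A `skinora_kb` knowledge base.
#' @param alpha Significance level; a pathway is enriched iff p < alpha
#'   (strict). Default 0.05.
#' @param alternative Tail of the test: `"greater"` (over-representation,
#'   default) or `"two.sided"`.
#' @param universe `"kb"` (default): the population is the full
#'   knowledge-base universe. `"kb_measured"`: restrict the population to
#'   knowledge-base genes that were actually measured (requires
#'   `measured`).
#' @param measured Character vector of measured gene symbols; required for
#'   `universe = "kb_measured"`.
#' @param adjust `"none"` (default; the enriched flag uses the raw p) or
#'   `"BH"` (Benjamini-Hochberg across pathways within each column; the
#'   flag then uses the adjusted p).
#' @return A tibble of class `skinora_enrichment`, one row per
#'   (pathway, column): `pathway`, `column_id`, `a`, `b`, `c`, `d`, `n`,
#'   `p_value` (and `p_adjust` when `adjust = "BH"`), `enriched`. Rows are
#'   ordered by column, then p ascending with ties broken by pathway name.
#'   Attributes: `alpha`, `alternative`, `universe_size`.
#' @export
enrich <- function(degs, kb, alpha = 0.05,
                   alternative = c("greater", "two.sided"),
                   universe = c("kb", "kb_measured"),
                   measured = NULL,
                   adjust = c("none", "BH")) {
  alternative <- match.arg(alternative)
  universe <- match.arg(universe)
  adjust <- match.arg(adjust)
  stopifnot(inherits(kb, "skinora_kb"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    abort_config("`alpha` must be a single value in [0, 1]")
  }
  uni <- kb_universe(kb)
  if (!length(uni)) {
    abort_data("knowledge base has an empty universe; nothing to enrich against")
  }
  if (universe == "kb_measured") {
    if (is.null(measured)) {
      abort_config("universe = 'kb_measured' requires the `measured` gene vector")
    }
    uni <- intersect(uni, toupper(unique(measured)))
    if (!length(uni)) {
      abort_data("no overlap between the knowledge base and measured genes")
    }
  }

  degs_tbl <- as_tibble(degs)
  columns <- attr(degs, "columns") %||% unique(degs_tbl$column_id)
  if (!length(columns)) {
    abort_data("no DEG sets supplied: at least one column is required")
  }

  pw_names <- kb$pathways$pathway
  pw_genes <- lapply(kb$pathways$genes, intersect, y = uni)
  rows <- lapply(columns, function(col) {
    dg <- intersect(unique(degs_tbl$gene[degs_tbl$column_id == col]), uni)
    a <- vapply(pw_genes, function(g) length(intersect(dg, g)), integer(1))
    k_sz <- lengths(pw_genes)
    tibble(pathway = pw_names, column_id = col,
           a = a, b = length(dg) - a, c = k_sz - a,
           d = length(uni) - k_sz - length(dg) + a,
           n = length(uni))
  })
  out <- dplyr::bind_rows(rows)
  out$p_value <- fisher_p(out$a, out$b, out$c, out$d,
                          alternative = alternative)
  if (adjust == "BH") {
    out <- out |>
      dplyr::mutate(p_adjust = stats::p.adjust(.data$p_value, method = "BH"),
                    .by = "column_id")
    out$enriched <- out$p_adjust < alpha
  } else {
    out$enriched <- out$p_value < alpha
  }
  out <- out[order(match(out$column_id, columns), out$p_value, out$pathway), ]
  structure(out, alpha = alpha, alternative = alternative,
            universe_size = length(uni),
            columns = columns,
            class = c("skinora_enrichment", class(out)))
}

#' Summarise enrichment across samples
#'
#' Counts, for each pathway, the number of columns (samples) in which it is
#' enriched — the quantity shown as bar length in cross-sample enrichment
#' bar charts.
#'
#' @param result A `skinora_enrichment` table from [enrich()].
#' @return A tibble of class `skinora_enrichment_summary`: `pathway`,
#'   `n_enriched`, `n_columns`, ordered by `n_enriched` descending then
#'   pathway name.
#' @export
enrichment_summary <- function(result) {
  stopifnot(inherits(result, "skinora_enrichment"))
  columns <- attr(result, "columns")
  out <- as_tibble(result) |>
    dplyr::summarise(n_enriched = sum(.data$enriched),
                     n_columns = length(columns),
                     .by = "pathway")
  out <- out[order(-out$n_enriched, out$pathway), ]
  structure(out, alpha = attr(result, "alpha"),
            class = c("skinora_enrichment_summary", class(out)))
}

#' @rdname enrich
#' @param x A `skinora_enrichment` object.
#' @param ... Unused.
#' @method tidy skinora_enrichment
#' @export
tidy.skinora_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' @rdname enrich
#' @method glance skinora_enrichment
#' @export
glance.skinora_enrichment <- function(x, ...) {
  tibble(
    n_pathways = length(unique(x$pathway)),
    n_columns = length(attr(x, "columns")),
    n_enriched_calls = sum(x$enriched),
    universe_size = attr(x, "universe_size"),
    alpha = attr(x, "alpha"),
    alternative = attr(x, "alternative")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of enriched-sample counts per pathway
#'
#' @param object A `skinora_enrichment_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot skinora_enrichment_summary
#' @export
autoplot.skinora_enrichment_summary <- function(object, ...) {
  df <- as_tibble(object)
  df$pathway <- stats::reorder(df$pathway, df$n_enriched)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_enriched, y = .data$pathway)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(
      x = sprintf("samples enriched (p < %s) out of %d",
                  format(attr(object, "alpha")), df$n_columns[1L]),
      y = NULL, title = "Pathway enrichment across samples"
    ) +
    ggplot2::theme_minimal()
}

#' Write enrichment results and summaries as TSV
#'
#' @param result A `skinora_enrichment` or `skinora_enrichment_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  readr::write_tsv(as_tibble(result), path)
  invisible(path)
}
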