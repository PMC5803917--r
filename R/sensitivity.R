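#' Fold-change cutoff sensitivity analysis
#'
#' Re-runs DEG calling and pathway enrichment at several log2 fold-change
#' cutoffs (by default 0.5, 1.0 and 1.5 — the default cutoff plus one half
#' fold-change either side) and tabulates how the enriched-pathway
#' conclusions change. Because DEG sets are nested in the cutoff
#' (a gene passing 1.5 also passes 1.0 and 0.5), robust pathways are
#' expected to be recovered at every cutoff.
#'
#' @param fc A `skinora_fc` fold-change table.
#' @param kb A `skinora_kb` knowledge base.
#' @param cutoffs Numeric vector of at least two positive cutoffs.
#'   Default `c(0.5, 1.0, 1.5)`.
#' @param alpha Significance level passed to [enrich()]. Default 0.05.
#' @param ... Further arguments passed to [enrich()] (tail, universe
#'   policy, adjustment).
#' @return A list of class `skinora_sensitivity` with tibbles:
#'   \describe{
#'     \item{deg_counts}{`cutoff`, `column_id`, `n_up`, `n_down`, `n_deg`.}
#'     \item{summary}{per cutoff the cross-sample enrichment summary
#'       (`cutoff`, `pathway`, `n_enriched`, `n_columns`).}
#'     \item{overlap}{per pathway: in how many cutoffs it was enriched in
#'       at least one column (`n_cutoffs_enriched`), and whether it was
#'       enriched at every cutoff (`all_cutoffs`).}
#'   }
#' @export
sensitivity_analysis <- function(fc, kb, cutoffs = c(0.5, 1.0, 1.5),
                                 alpha = 0.05, ...) {
  if (length(cutoffs) < 2L) {
    abort_config("`cutoffs` must contain at least two cutoffs to compare")
  }
  if (any(cutoffs <= 0) || anyDuplicated(cutoffs)) {
    abort_config("`cutoffs` must be distinct positive log2 fold-change values")
  }
  cutoffs <- sort(cutoffs)
  per_cut <- lapply(cutoffs, function(ct) {
    degs <- call_degs(fc, cutoff = ct)
    res <- enrich(degs, kb, alpha = alpha, ...)
    counts <- tibble(column_id = attr(degs, "columns")) |>
      dplyr::left_join(
        as_tibble(degs) |>
          dplyr::summarise(n_up = sum(.data$direction == "up"),
                           n_down = sum(.data$direction == "down"),
                           .by = "column_id"),
        by = "column_id") |>
      dplyr::mutate(cutoff = ct,
                    n_up = dplyr::coalesce(.data$n_up, 0L),
                    n_down = dplyr::coalesce(.data$n_down, 0L),
                    n_deg = .data$n_up + .data$n_down)
    summ <- enrichment_summary(res) |>
      as_tibble() |>
      dplyr::mutate(cutoff = ct)
    list(counts = counts, summary = summ)
  })
  deg_counts <- dplyr::bind_rows(lapply(per_cut, `[[`, "counts"))
  summary <- dplyr::bind_rows(lapply(per_cut, `[[`, "summary"))
  overlap <- summary |>
    dplyr::summarise(
      n_cutoffs_enriched = sum(.data$n_enriched > 0),
      .by = "pathway") |>
    dplyr::mutate(all_cutoffs = .data$n_cutoffs_enriched == length(cutoffs)) |>
    dplyr::arrange(dplyr::desc(.data$n_cutoffs_enriched), .data$pathway)
  structure(list(
    deg_counts = deg_counts[, c("cutoff", "column_id", "n_up", "n_down", "n_deg")],
    summary = summary[, c("cutoff", "pathway", "n_enriched", "n_columns")],
    overlap = overlap,
    cutoffs = cutoffs, alpha = alpha
  ), class = "skinora_sensitivity")
}

#' @export
print.skinora_sensitivity <- function(x, ...) {
  cat(sprintf("<skinora_sensitivity> cutoffs: %s; alpha = %s\n",
              paste(x$cutoffs, collapse = ", "), format(x$alpha)))
  robust <- x$overlap$pathway[x$overlap$all_cutoffs]
  cat(sprintf("pathways enriched (>= 1 sample) at every cutoff: %s\n",
              if (length(robust)) paste(robust, collapse = ", ") else "none"))
  invisible(x)
}

#' @rdname sensitivity_analysis
#' @param x A `skinora_sensitivity` object.
#' @method tidy skinora_sensitivity
#' @export
tidy.skinora_sensitivity <- function(x, ...) {
  as_tibble(x$summary)
}

#' @rdname sensitivity_analysis
#' @param object A `skinora_sensitivity` object.
#' @method autoplot skinora_sensitivity
#' @export
autoplot.skinora_sensitivity <- function(object, ...) {
  df <- object$summary
  df$pathway <- stats::reorder(df$pathway, df$n_enriched, FUN = max)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_enriched, y = .data$pathway)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::facet_wrap(~cutoff, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "samples enriched", y = NULL,
                  title = "Enrichment across fold-change cutoffs") +
    ggplot2::theme_minimal()
}
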