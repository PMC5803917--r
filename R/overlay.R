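#' Overlay fold-change states on a pathway interaction graph
#'
#' Assigns every gene of a pathway, for every fold-change column, one of
#' four discrete expression states at a log2 cutoff:
#' `"up"` (log2fc >= +cutoff), `"down"` (log2fc <= -cutoff),
#' `"unchanged"` otherwise, and `"not_measured"` for pathway genes absent
#' from the fold-change table. The continuous log2 fold change is retained
#' alongside the state. The pathway's signed interaction edges travel with
#' the result, so it can be exported for graph viewers.
#'
#' Up/down states agree exactly with [call_degs()] membership at the same
#' cutoff.
#'
#' @param kb A `skinora_kb`.
#' @param pathway Name of a pathway in `kb`.
#' @param fc A `skinora_fc` fold-change table.
#' @param cutoff Log2 threshold for the up/down states. Default 1.0.
#' @return A tibble of class `skinora_overlay`: `gene`, `column_id`,
#'   `log2fc` (NA when not measured), `state`; attributes `pathway`,
#'   `edges` (tibble), `cutoff`.
#' @export
overlay <- function(kb, pathway, fc, cutoff = 1.0) {
  stopifnot(inherits(kb, "skinora_kb"))
  i <- match(pathway, kb$pathways$pathway)
  if (is.na(i)) {
    abort_data(sprintf("unknown pathway: '%s'", pathway))
  }
  genes <- kb$pathways$genes[[i]]
  fc <- as_tibble(fc)
  columns <- unique(fc$column_id)
  if (!length(columns)) columns <- "aggregate"
  grid <- tidyr::expand_grid(gene = genes, column_id = columns)
  out <- dplyr::left_join(grid, fc[, c("gene", "column_id", "log2fc")],
                          by = c("gene", "column_id"))
  out$state <- dplyr::case_when(
    is.na(out$log2fc) ~ "not_measured",
    out$log2fc >= cutoff ~ "up",
    out$log2fc <= -cutoff ~ "down",
    .default = "unchanged"
  )
  edges <- kb$edges[kb$edges$pathway == pathway, ]
  structure(out, pathway = pathway, edges = edges, cutoff = cutoff,
            class = c("skinora_overlay", class(out)))
}

#' Export an overlay for external graph viewers
#'
#' Writes three artifacts into `dir`:
#' \describe{
#'   \item{`<pathway>_nodes.tsv`}{gene, column_id, log2fc, state.}
#'   \item{`<pathway>_edges.tsv`}{source, sign, target.}
#'   \item{`<pathway>.graphml`}{GraphML with per-column `log2fc_*` and
#'     `state_*` node attributes and a `sign` edge attribute.}
#' }
#' Output is a pure function of the overlay: identical inputs give
#' byte-identical files.
#'
#' @param ov A `skinora_overlay`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_overlay <- function(ov, dir) {
  stopifnot(inherits(ov, "skinora_overlay"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pw <- attr(ov, "pathway")
  slug <- gsub("[^A-Za-z0-9._-]+", "_", pw)
  node_path <- file.path(dir, paste0(slug, "_nodes.tsv"))
  edge_path <- file.path(dir, paste0(slug, "_edges.tsv"))
  graph_path <- file.path(dir, paste0(slug, ".graphml"))

  nodes <- as_tibble(ov)
  ok <- tryCatch({
    readr::write_tsv(nodes, node_path)
    edges <- attr(ov, "edges")
    readr::write_tsv(edges[, c("source", "sign", "target")], edge_path)

    node_attrs <- nodes |>
      tidyr::pivot_wider(names_from = "column_id",
                         values_from = c("log2fc", "state"))
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "target", "sign")],
      directed = TRUE, vertices = node_attrs)
    igraph::write_graph(g, graph_path, format = "graphml")
    TRUE
  }, error = function(e) {
    abort_data(sprintf("failed to export overlay '%s' to '%s': %s",
                       pw, dir, conditionMessage(e)))
  })
  invisible(c(nodes = node_path, edges = edge_path, graphml = graph_path))
}

#' Heat-tile view of an overlay
#'
#' @param object A `skinora_overlay`.
#' @param ... Unused.
#' @return A ggplot showing gene x column expression states.
#' @method autoplot skinora_overlay
#' @export
autoplot.skinora_overlay <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column_id, y = .data$gene,
                                   fill = .data$state)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_manual(values = c(
      up = "#CC3311", down = "#0077BB",
      unchanged = "grey92", not_measured = "grey60")) +
    ggplot2::labs(title = attr(object, "pathway"), x = NULL, y = NULL,
                  fill = sprintf("state (|log2FC| >= %s)",
                                 format(attr(object, "cutoff")))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Expression profile table for a gene list
#'
#' Restricts a fold-change table to the requested genes, in wide
#' gene-by-column form — the machine-readable analogue of per-pathway
#' expression-profile figures. Genes not present in the table are reported
#' as rows of NA (state `not_measured` in overlays); duplicates in the
#' request are collapsed.
#'
#' @param fc A `skinora_fc` fold-change table.
#' @param genes Character vector of gene symbols.
#' @return A wide tibble: `gene` plus one column per fold-change column.
#' @export
profile_table <- function(fc, genes) {
  genes <- unique(toupper(genes))
  if (!length(genes)) {
    return(tibble(gene = character()))
  }
  fc <- as_tibble(fc)
  wide <- fc[fc$gene %in% genes, c("gene", "column_id", "log2fc")] |>
    tidyr::pivot_wider(names_from = "column_id", values_from = "log2fc")
  out <- dplyr::left_join(tibble(gene = genes), wide, by = "gene")
  out
}
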