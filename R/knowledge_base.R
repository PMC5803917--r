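#' Construct a pathway knowledge base
#'
#' A knowledge base couples a catalogue of named gene sets ("pathways") with
#' an optional set of signed, directed molecular-interaction edges. The union
#' of all pathway gene sets is the gene universe used as the population of
#' the enrichment test, and the edges drive expression overlays.
#'
#' @param pathways A data frame with columns `pathway` (unique name),
#'   `category` (free-text functional category) and `genes` (list column of
#'   character vectors). Gene symbols are upper-cased and deduplicated.
#' @param edges Optional data frame of interactions with columns `source`,
#'   `target`, `sign` (one of `"activation"`, `"inhibition"`,
#'   `"unspecified"`) and `pathway`. Endpoints must belong to the named
#'   pathway's gene set.
#'
#' @return An object of class `skinora_kb`: a list with tibbles `pathways`
#'   and `edges`.
#' @seealso [read_gmt()], [demo_kb()], [kb_universe()], [kb_validate()]
#' @export
#' @examples
#' kb <- knowledge_base(tibble::tibble(
#'   pathway = c("P1", "P2"), category = "demo",
#'   genes = list(c("A", "B", "C"), c("C", "D"))
#' ))
#' kb_universe(kb)
knowledge_base <- function(pathways, edges = NULL) {
  if (!is.data.frame(pathways) ||
      !all(c("pathway", "genes") %in% names(pathways))) {
    abort_validation("`pathways` needs columns `pathway` and `genes`")
  }
  pathways <- as_tibble(pathways)
  if (!"category" %in% names(pathways)) pathways$category <- NA_character_
  pathways <- pathways[, c("pathway", "category", "genes")]
  pathways$pathway <- as.character(pathways$pathway)
  dup <- unique(pathways$pathway[duplicated(pathways$pathway)])
  if (length(dup)) {
    abort_validation(sprintf("duplicate pathway name(s): %s",
                             paste(dup, collapse = ", ")))
  }
  pathways$genes <- lapply(pathways$genes, function(g) {
    unique(toupper(as.character(g)))
  })
  empty <- lengths(pathways$genes) == 0L
  if (any(empty)) {
    abort_validation(sprintf("pathway(s) with empty gene set: %s",
                             paste(pathways$pathway[empty], collapse = ", ")))
  }
  if (is.null(edges)) {
    edges <- tibble(source = character(), target = character(),
                    sign = character(), pathway = character())
  } else {
    edges <- as_tibble(edges)[, c("source", "target", "sign", "pathway")]
    edges$source <- toupper(edges$source)
    edges$target <- toupper(edges$target)
    check_edges_in_pathways(edges, pathways)
    edges <- dplyr::distinct(edges)
  }
  structure(list(pathways = pathways, edges = edges), class = "skinora_kb")
}

check_edges_in_pathways <- function(edges, pathways) {
  sets <- stats::setNames(pathways$genes, pathways$pathway)
  bad <- vapply(seq_len(nrow(edges)), function(i) {
    pw <- edges$pathway[i]
    if (!pw %in% names(sets)) return(TRUE)
    !(edges$source[i] %in% sets[[pw]]) || !(edges$target[i] %in% sets[[pw]])
  }, logical(1))
  if (any(bad)) {
    lines <- paste(edges$source[bad], edges$target[bad], edges$pathway[bad],
                   sep = " -> ")
    abort_validation(paste0(
      "interaction edge endpoint(s) outside the named pathway's gene set:\n  ",
      paste(lines, collapse = "\n  ")))
  }
  invisible(edges)
}

#' @export
print.skinora_kb <- function(x, ...) {
  cat(sprintf("<skinora_kb> %d pathways, %d genes in universe, %d edges\n",
              nrow(x$pathways), length(kb_universe(x)), nrow(x$edges)))
  invisible(x)
}

#' Gene universe of a knowledge base
#'
#' The universe is the set of unique genes appearing in any pathway; it is
#' the population `n` of the enrichment contingency table. Genes shared by
#' several pathways are counted once.
#'
#' @param kb A `skinora_kb`.
#' @return Sorted character vector of gene symbols.
#' @export
kb_universe <- function(kb) {
  stopifnot(inherits(kb, "skinora_kb"))
  sort(unique(unlist(kb$pathways$genes, use.names = FALSE)))
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>category<TAB>gene1<TAB>gene2...`. Gene symbols are
#' upper-cased and deduplicated within a line. An empty file yields an empty
#' knowledge base (which the enrichment step refuses to use).
#'
#' @param path Path to the GMT file.
#' @return A [knowledge_base()] with no edges.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(knowledge_base(tibble(pathway = character(),
                                 category = character(),
                                 genes = list())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort_parse(sprintf(
      "malformed GMT line(s) with fewer than 3 tab-separated fields: line %s",
      paste(short, collapse = ", ")))
  }
  knowledge_base(tibble(
    pathway  = vapply(fields, `[[`, "", 1L),
    category = vapply(fields, `[[`, "", 2L),
    genes    = lapply(fields, function(f) f[-(1:2)])
  ))
}

#' Write gene sets to a GMT file
#'
#' Inverse of [read_gmt()]: the pathway-to-gene-set mapping round-trips
#' (order-insensitively).
#'
#' @param kb A `skinora_kb`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(kb, path) {
  stopifnot(inherits(kb, "skinora_kb"))
  lines <- vapply(seq_len(nrow(kb$pathways)), function(i) {
    paste(c(kb$pathways$pathway[i],
            kb$pathways$category[i] %||% ".",
            kb$pathways$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read signed interaction edges into a knowledge base
#'
#' The file format is SIF-like with an explicit pathway column:
#' `source<TAB>relation<TAB>target<TAB>pathway`, one edge per line.
#' Relations `activates` and `inhibits` map to signs `activation` and
#' `inhibition`; any other relation maps to `unspecified` with a warning.
#' Both endpoints must belong to the named pathway's gene set.
#'
#' @param path Path to the edge file.
#' @param kb The `skinora_kb` to attach edges to.
#' @return The knowledge base with edges attached.
#' @export
read_interactions <- function(path, kb) {
  stopifnot(inherits(kb, "skinora_kb"))
  if (!file.exists(path)) {
    abort_parse(sprintf("interaction file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(kb)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    abort_parse(sprintf(
      "malformed interaction line(s), expected 4 tab-separated fields: line %s",
      paste(bad, collapse = ", ")))
  }
  relation <- vapply(fields, `[[`, "", 2L)
  sign <- dplyr::case_match(relation,
                            "activates" ~ "activation",
                            "inhibits"  ~ "inhibition",
                            "interacts" ~ "unspecified",
                            .default = NA_character_)
  unknown <- is.na(sign)
  if (any(unknown)) {
    warn(sprintf("unknown relation(s) %s mapped to sign 'unspecified'",
                 paste(unique(relation[unknown]), collapse = ", ")))
    sign[unknown] <- "unspecified"
  }
  edges <- tibble(
    source  = vapply(fields, `[[`, "", 1L),
    target  = vapply(fields, `[[`, "", 3L),
    sign    = sign,
    pathway = vapply(fields, `[[`, "", 4L)
  )
  knowledge_base(kb$pathways, edges = dplyr::bind_rows(kb$edges, edges))
}

#' Validate a knowledge base
#'
#' Reports (without failing) duplicate pathway names, empty pathways and
#' edges whose endpoints fall outside their pathway's gene set, together
#' with universe and per-pathway sizes.
#'
#' @param kb A `skinora_kb` (or a plain list with `pathways`/`edges`
#'   tibbles, so that deliberately broken inputs can be audited).
#' @return A list of class `skinora_kb_report` with tibbles `violations`
#'   (`kind`, `detail`) and `sizes` (`pathway`, `n_genes`), and
#'   `universe_size`.
#' @export
kb_validate <- function(kb) {
  pathways <- as_tibble(kb$pathways)
  edges <- as_tibble(kb$edges)
  violations <- list()
  dup <- unique(pathways$pathway[duplicated(pathways$pathway)])
  if (length(dup)) {
    violations <- c(violations, list(tibble(kind = "duplicate_pathway",
                                            detail = dup)))
  }
  empty <- pathways$pathway[lengths(pathways$genes) == 0L]
  if (length(empty)) {
    violations <- c(violations, list(tibble(kind = "empty_pathway",
                                            detail = empty)))
  }
  if (nrow(edges)) {
    sets <- stats::setNames(pathways$genes, pathways$pathway)
    dangling <- vapply(seq_len(nrow(edges)), function(i) {
      pw <- edges$pathway[i]
      if (!pw %in% names(sets)) return(TRUE)
      !(edges$source[i] %in% sets[[pw]]) || !(edges$target[i] %in% sets[[pw]])
    }, logical(1))
    if (any(dangling)) {
      violations <- c(violations, list(tibble(
        kind = "dangling_edge",
        detail = paste(edges$source[dangling], edges$target[dangling],
                       edges$pathway[dangling], sep = " -> "))))
    }
  }
  violations <- if (length(violations)) {
    dplyr::bind_rows(violations)
  } else {
    tibble(kind = character(), detail = character())
  }
  structure(list(
    violations = violations,
    sizes = tibble(pathway = pathways$pathway,
                   n_genes = lengths(lapply(pathways$genes, unique))),
    universe_size = length(unique(unlist(pathways$genes, use.names = FALSE)))
  ), class = "skinora_kb_report")
}

#' @export
print.skinora_kb_report <- function(x, ...) {
  cat(sprintf("<skinora_kb_report> universe %d genes, %d pathway(s), %d violation(s)\n",
              x$universe_size, nrow(x$sizes), nrow(x$violations)))
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}

#' Write a validation report as TSV
#'
#' @param report A `skinora_kb_report` from [kb_validate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kb_report <- function(report, path) {
  stopifnot(inherits(report, "skinora_kb_report"))
  readr::write_tsv(report$violations, path)
  invisible(path)
}

#' Built-in demonstration knowledge base
#'
#' A small skin-biology knowledge base assembled from genes repeatedly
#' implicated in atopic-dermatitis treatment response: inflammatory
#' signalling around TNF/NF-kB, keratinocyte differentiation and cornified-
#' envelope proteins, wound-healing growth factors, tight-junction barrier
#' genes, epidermal lipid synthesis, and DNA-damage repair. It is a
#' synthetic stand-in for proprietary curated pathway content: gene
#' membership is indicative, not exhaustive, and the signed edges cover a
#' few canonical relations (e.g. glucocorticoid-receptor inhibition of TNF,
#' the TNF receptor cascade into NF-kB).
#'
#' @return A `skinora_kb` with 8 pathways and signed edges.
#' @export
#' @examples
#' demo_kb()
demo_kb <- function() {
  pathways <- tibble(
    pathway = c("Inflammation", "Keratinocyte Differentiation",
                "Wound Healing", "Barrier Formation", "Lipid Synthesis",
                "DNA Damage and Repair", "Immune Response",
                "Chemokine Signaling"),
    category = c("Basic skin physiology", "Epidermal formation",
                 "Basic skin physiology", "Epidermal formation",
                 "Basic skin physiology", "Stress response",
                 "Basic skin physiology", "Basic skin physiology"),
    genes = list(
      c("TNF", "TNFRSF1A", "TRADD", "NFKB1", "NR3C1", "CXCL1", "CXCL9",
        "CXCL10", "IL18", "CCL2", "CCL5", "CCL13", "CD86", "ICAM1", "VCAM1",
        "MMP9", "SELE", "TLR1", "TLR2", "IRAK4", "IKBKB", "SMAD4", "IL4",
        "IL4R", "IFNG", "IL1B", "IL11", "EDN1", "PLCB2"),
      c("LOR", "FLG", "TGM5", "CDSN", "IVL", "LCE3D", "TGM1", "TGM3",
        "DSG3", "KRT1", "KRT10", "DSC1", "CD44", "AKT1", "PKN2", "PLCG1",
        "PRKCD", "HRAS", "MAP2K3", "JUN", "FOS", "JUND", "FOSL1", "CEBPA",
        "CEBPB", "SP1", "HSPB1", "S100A7", "S100A8", "S100A9", "STAT3",
        "TGFA", "MYC", "MAPK1"),
      c("VEGFA", "FN1", "PIK3CA", "PLCG1", "MAPK1", "MAPK3", "HBEGF",
        "AREG", "EGFR", "PDGFB"),
      c("CTTN", "CDC42", "GRHL3", "AHR", "CLDN1", "OCLN", "TJP1",
        "LAMA5", "COL4A1", "ITGB1"),
      c("LDLR", "ABCA12", "SPTLC2", "SGMS2", "SMPD2", "NR1H2", "SCD",
        "FASN", "HMGCR", "LPL", "APOC1"),
      c("H2AFX", "RAD51", "BRCA2", "MCM3", "DHFR", "HMOX1", "GINS1",
        "PCNA", "CDK1", "CDKN1A", "CCNB1", "E2F1"),
      c("IL6", "IL6R", "IL13", "IL13RA2", "IL12RB1", "IL27RA", "IL2",
        "JAK1", "JAK2", "STAT6", "SOCS1", "SOCS3", "NFATC1", "TGFB1",
        "CCL4", "CXCL2", "MMP2"),
      c("CXCL6", "CXCL16", "CCL8", "CCL24", "CCL25", "CCL26", "CCR3",
        "CXCR2", "GNAI2", "RAF1")
    )
  )
  edges_raw <- tibble::tribble(
    ~source,     ~relation,   ~target,     ~pathway,
    "NR3C1",     "inhibits",  "TNF",       "Inflammation",
    "TNF",       "activates", "TNFRSF1A",  "Inflammation",
    "TNFRSF1A",  "activates", "TRADD",     "Inflammation",
    "TRADD",     "activates", "NFKB1",     "Inflammation",
    "NFKB1",     "activates", "CXCL1",     "Inflammation",
    "NFKB1",     "activates", "CXCL9",     "Inflammation",
    "NFKB1",     "activates", "CXCL10",    "Inflammation",
    "NFKB1",     "activates", "IL18",      "Inflammation",
    "NFKB1",     "activates", "CCL2",      "Inflammation",
    "NFKB1",     "activates", "CCL5",      "Inflammation",
    "NFKB1",     "activates", "ICAM1",     "Inflammation",
    "NFKB1",     "activates", "VCAM1",     "Inflammation",
    "NFKB1",     "activates", "MMP9",      "Inflammation",
    "NFKB1",     "activates", "SELE",      "Inflammation",
    "NFKB1",     "activates", "TNF",       "Inflammation",
    "TLR1",      "activates", "IRAK4",     "Inflammation",
    "TLR2",      "activates", "IRAK4",     "Inflammation",
    "IRAK4",     "activates", "NFKB1",     "Inflammation",
    "NR3C1",     "activates", "IKBKB",     "Inflammation",
    "IKBKB",     "inhibits",  "NFKB1",     "Inflammation",
    "CD44",      "activates", "AKT1",      "Keratinocyte Differentiation",
    "AKT1",      "activates", "PKN2",      "Keratinocyte Differentiation",
    "PKN2",      "activates", "PLCG1",     "Keratinocyte Differentiation",
    "PLCG1",     "activates", "JUN",       "Keratinocyte Differentiation",
    "PLCG1",     "activates", "CEBPB",     "Keratinocyte Differentiation",
    "JUN",       "activates", "LOR",       "Keratinocyte Differentiation",
    "JUN",       "activates", "S100A7",    "Keratinocyte Differentiation",
    "CEBPA",     "activates", "IVL",       "Keratinocyte Differentiation",
    "TGFA",      "activates", "CEBPA",     "Keratinocyte Differentiation",
    "VEGFA",     "activates", "PIK3CA",    "Wound Healing",
    "VEGFA",     "activates", "PLCG1",     "Wound Healing",
    "VEGFA",     "activates", "MAPK1",     "Wound Healing"
  )
  kb <- knowledge_base(pathways)
  knowledge_base(kb$pathways, edges = tibble(
    source = edges_raw$source,
    target = edges_raw$target,
    sign = ifelse(edges_raw$relation == "inhibits", "inhibition", "activation"),
    pathway = edges_raw$pathway
  ))
}
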