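#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates preprocessing, fold-change computation, DEG calling,
#' per-sample pathway enrichment, the cutoff sensitivity analysis and
#' overlay exports, writing every artifact plus an md5 manifest and a run
#' log into the output directory. Arms are always processed independently:
#' no statistic is shared across arms.
#'
#' @param config Either a path to a YAML file or a named list with
#'   entries:
#'   \describe{
#'     \item{matrix}{path to the wide probe x sample intensity TSV
#'       (required).}
#'     \item{calls}{path to the matching detection-call TSV (optional; when
#'       absent every call is treated as Present, i.e. no filtering
#'       bites).}
#'     \item{probe_map}{path to the probe-to-gene TSV (required).}
#'     \item{design}{path to the sample design TSV (required).}
#'     \item{gene_sets}{path to the knowledge-base GMT (required).}
#'     \item{interactions}{path to the signed edge file (optional).}
#'     \item{arms}{arms to analyse (default: all arms in the design).}
#'     \item{mode}{`"per_sample"` (default) or `"aggregate"`.}
#'     \item{cutoff}{DEG log2 cutoff, default 1.0.}
#'     \item{sensitivity_cutoffs}{default `c(0.5, 1.0, 1.5)`.}
#'     \item{alpha}{default 0.05.}
#'     \item{detection_threshold}{default 0.70.}
#'     \item{universe}{`"kb"` (default) or `"kb_measured"`.}
#'     \item{tail}{`"greater"` (default) or `"two.sided"`.}
#'     \item{out_dir}{output directory (required).}
#'   }
#' @return Invisibly, a list with the per-arm results and the manifest
#'   tibble (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- c("# skinora pipeline run",
                 paste0("# config: ", yaml::as.yaml(
                   cfg[setdiff(names(cfg), "out_dir")])))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_data(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)))
    })
  }

  design <- stage("design", read_design(cfg$design))
  values <- stage("matrix", read_expression(cfg$matrix))
  calls <- stage("calls", {
    if (is.null(cfg$calls)) {
      all_p <- values
      all_p[setdiff(names(all_p), "probe_id")] <- "P"
      all_p
    } else {
      read_expression(cfg$calls)
    }
  })
  probe_map <- stage("probe_map", read_probe_map(cfg$probe_map))
  kb <- stage("gene_sets", read_gmt(cfg$gene_sets))
  if (!is.null(cfg$interactions)) {
    kb <- stage("interactions", read_interactions(cfg$interactions, kb))
  }
  arms <- cfg$arms %||% unique(design$arm)

  outputs <- character(0)
  results <- list()
  for (arm in arms) {
    design_arm <- design[design$arm == arm, ]
    norm <- stage("normalize", median_normalize(values))
    kept <- stage("detection_filter",
                  filter_by_detection(norm, calls, design_arm,
                                      threshold = cfg$detection_threshold))
    log_lines <- c(log_lines, sprintf(
      "[%s] detection filter: kept %d of %d probes", arm, nrow(kept),
      nrow(values)))
    gm <- stage("collapse", withCallingHandlers(
      collapse_probes(kept, probe_map),
      message = function(m) {
        log_lines <<- c(log_lines, sprintf("[%s] %s", arm,
                                           trimws(conditionMessage(m))))
        invokeRestart("muffleMessage")
      }))
    fc <- stage("fold_change",
                fold_change(gm, design_arm, arm = arm, mode = cfg$mode))
    degs <- stage("deg_call", call_degs(fc, cutoff = cfg$cutoff))
    res <- stage("enrichment",
                 enrich(degs, kb, alpha = cfg$alpha,
                        alternative = cfg$tail, universe = cfg$universe,
                        measured = gm$gene))
    summ <- enrichment_summary(res)
    sens <- stage("sensitivity",
                  sensitivity_analysis(fc, kb,
                                       cutoffs = cfg$sensitivity_cutoffs,
                                       alpha = cfg$alpha,
                                       alternative = cfg$tail,
                                       universe = cfg$universe,
                                       measured = gm$gene))
    prefix <- function(x) file.path(cfg$out_dir, paste0(arm, "_", x))
    readr::write_tsv(fc_wide(fc), prefix("log2fc.tsv"))
    readr::write_tsv(as_tibble(degs), prefix("degs.tsv"))
    write_enrichment(res, prefix("enrichment.tsv"))
    write_enrichment(summ, prefix("enrichment_summary.tsv"))
    readr::write_tsv(sens$summary, prefix("sensitivity.tsv"))
    outputs <- c(outputs, prefix(c("log2fc.tsv", "degs.tsv",
                                   "enrichment.tsv",
                                   "enrichment_summary.tsv",
                                   "sensitivity.tsv")))
    top <- summ$pathway[summ$n_enriched > 0]
    if (!length(top)) top <- summ$pathway[1L]
    for (pw in utils::head(top, 5L)) {
      ov <- stage("overlay", overlay(kb, pw, fc, cutoff = cfg$cutoff))
      paths <- export_overlay(ov, file.path(cfg$out_dir,
                                            paste0(arm, "_overlays")))
      outputs <- c(outputs, paths)
    }
    log_lines <- c(log_lines, sprintf(
      "[%s] %d DEG calls; %d/%d pathway-sample pairs enriched at alpha %s",
      arm, nrow(degs), sum(res$enriched), nrow(res), format(cfg$alpha)))
    results[[arm]] <- list(fc = fc, degs = degs, enrichment = res,
                           summary = summ, sensitivity = sens)
  }

  manifest <- tibble(
    file = sub(paste0("^", cfg$out_dir, "/?"), "", unname(outputs)),
    md5 = unname(tools::md5sum(outputs))
  )
  readr::write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  writeLines(log_lines, log_path)
  invisible(list(results = results, manifest = manifest,
                 out_dir = cfg$out_dir))
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort_config(sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_config("`config` must be a list or a YAML path")
  defaults <- list(mode = "per_sample", cutoff = 1.0,
                   sensitivity_cutoffs = c(0.5, 1.0, 1.5), alpha = 0.05,
                   detection_threshold = 0.70, universe = "kb",
                   tail = "greater", calls = NULL, interactions = NULL,
                   arms = NULL)
  cfg <- utils::modifyList(defaults, config)
  required <- c("matrix", "probe_map", "design", "gene_sets", "out_dir")
  miss <- setdiff(required, names(cfg))
  if (length(miss)) {
    abort_config(sprintf("run config is missing required field(s): %s",
                         paste(miss, collapse = ", ")))
  }
  cfg$sensitivity_cutoffs <- as.numeric(cfg$sensitivity_cutoffs)
  cfg
}
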