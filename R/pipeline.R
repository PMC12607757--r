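## End-to-end orchestration: read inputs, derive the marked set, score
## induction, classify DIGs, summarize stages, run morphometry statistics,
## and write plain TSV outputs plus a JSON run manifest.

default_pipeline_params <- function() {
  list(expressed_tpm_threshold = 1, z_threshold = 0.5,
       l2fc_min = 2, fdr_max = 0.05, aggregate = "any",
       min_overlap = 1, dev_group_regex = "^perithecium")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' A configuration has a `paths` block (annotation, peaks_rep1, peaks_rep2,
#' compendium_tpm, compendium_metadata, morphometry, optional `de_tables`)
#' and an optional `params` block overriding the defaults
#' (expressed_tpm_threshold, z_threshold, l2fc_min, fdr_max, aggregate,
#' min_overlap, dev_group_regex). Relative paths are resolved against the
#' configuration file's directory.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Configuration list with `paths` and `params`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$paths)) stop_config("config lacks a 'paths' block")
  base <- dirname(normalizePath(path))
  cfg$paths <- lapply(cfg$paths, function(p) {
    ifelse(grepl("^/", p), p, file.path(base, p))
  })
  cfg$params <- utils::modifyList(default_pipeline_params(),
                                  as.list(cfg$params %||% list()))
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

write_output_tsv <- function(df, path, params) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(params),
                     vapply(params, function(x) paste(format(x), collapse = ","),
                            character(1))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the complete analysis pipeline
#'
#' Executes every stage over the configured inputs and writes, under
#' `outdir`: the marked-set provenance table, the induction-score table
#' (sorted by rank), the DIG classification, the marked/DIG overlap
#' summary, stage-wise expression summaries, the morphometry statistics,
#' and a machine-readable JSON manifest (parameters, input checksums,
#' package version). Reruns with identical inputs are bit-identical. Each
#' output table carries the parameter block as leading `#` comment lines.
#'
#' @param config Configuration list (see [read_pipeline_config()]) or a
#'   path to a YAML/JSON configuration file.
#' @param outdir Output directory (created if needed).
#' @return The result bundle, invisibly: `marked_set`, `scores`, `ranking`,
#'   `de`, `classification`, `overlap`, `stages`, `morphometry`,
#'   `manifest`.
#' @export
run_all <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  params <- utils::modifyList(default_pipeline_params(),
                              as.list(config$params %||% list()))
  paths <- config$paths
  need <- c("annotation", "peaks_rep1", "peaks_rep2", "compendium_tpm",
            "compendium_metadata", "morphometry")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop_config("config paths block lacks: %s",
                                paste(miss, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  annotation <- run_stage("read_annotation", read_annotation(paths$annotation))
  peaks1 <- run_stage("read_peaks", read_peaks_bed(paths$peaks_rep1))
  peaks2 <- run_stage("read_peaks", read_peaks_bed(paths$peaks_rep2))
  compendium <- run_stage("read_compendium",
                          read_compendium_tsv(paths$compendium_tpm,
                                              paths$compendium_metadata))
  morphometry <- run_stage("read_morphometry",
                           read_morphometry_tsv(paths$morphometry))

  marked <- run_stage("derive_marked_set",
    derive_marked_set(annotation, peaks1, peaks2, compendium,
                      expressed_tpm_threshold = params$expressed_tpm_threshold,
                      min_overlap = params$min_overlap))
  marked_ids <- marked$gene_id[marked$passed]

  scores <- run_stage("induction_score",
                      induction_score(compendium, marked_ids,
                                      z_threshold = params$z_threshold))
  ranking <- rank_conditions(scores)
  scores_sorted <- scores[match(ranking, scores$experiment_id), , drop = FALSE]
  scores_sorted$rank <- seq_len(nrow(scores_sorted))

  de <- run_stage("differential_expression", {
    if (!is.null(paths$de_tables)) {
      do.call(rbind, lapply(unlist(paths$de_tables), read_de_tsv))
    } else {
      md <- compendium$metadata
      dev <- md$experiment_id[grepl(params$dev_group_regex, md$group)]
      ctrl <- md$experiment_id[md$is_mycelial_control]
      call_de(compendium, dev, ctrl, contrast_label = "development_vs_mycelium")
    }
  })

  classification <- run_stage("classify_digs",
    classify_digs(de, marked_ids, l2fc_min = params$l2fc_min,
                  fdr_max = params$fdr_max, aggregate = params$aggregate))
  universe <- intersect(annotation$gene_id, rownames(compendium$tpm))
  digs <- classification$gene_id[classification$is_dig]
  overlap <- run_stage("overlap_stats",
                       overlap_stats(marked_ids, digs, universe))

  stages <- run_stage("stage_summary",
                      stage_summary(compendium, classification))
  morph <- run_stage("morphometry", kw_dunn(morphometry))

  run_stage("write_outputs", {
    write_output_tsv(marked, file.path(outdir, "marked_set.tsv"), params)
    write_output_tsv(scores_sorted, file.path(outdir, "induction_scores.tsv"), params)
    write_output_tsv(de, file.path(outdir, "de_results.tsv"), params)
    write_output_tsv(classification, file.path(outdir, "dig_classification.tsv"), params)
    write_output_tsv(as.data.frame(overlap), file.path(outdir, "overlap_summary.tsv"), params)
    write_output_tsv(stages$summary, file.path(outdir, "stage_summary.tsv"), params)
    omnibus <- data.frame(statistic = "kruskal_wallis_H", value = morph$H,
                          df = morph$df, p = morph$p_omnibus)
    write_output_tsv(omnibus, file.path(outdir, "morphometry_omnibus.tsv"), params)
    write_output_tsv(morph$pairwise, file.path(outdir, "morphometry_pairwise.tsv"), params)
  })

  manifest <- list(
    package = "prc2induction",
    version = as.character(utils::packageVersion("prc2induction")),
    parameters = params,
    inputs = as.list(tools::md5sum(unlist(paths[need]))),
    n_genes_universe = length(universe),
    n_marked_passed = length(marked_ids),
    n_digs = length(digs),
    pct_marked_in_digs = overlap$pct_a_in_b,
    top_experiment = ranking[1]
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(marked_set = marked, scores = scores_sorted,
                 ranking = ranking, de = de, classification = classification,
                 overlap = overlap, stages = stages, morphometry = morph,
                 manifest = manifest))
}
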