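## Per-gene z-scores across the compendium, the per-experiment induction
## score of a gene set, condition ranking, and relative-expression matrices.

#' Per-gene expression z-scores across experiments
#'
#' For each gene, z-scores are computed across experiments on the
#' log2(TPM+1) scale (optionally raw TPM) using the sample (n-1) standard
#' deviation. Genes with zero variance get z = 0 in every experiment.
#'
#' @param compendium Expression compendium (list of `tpm`, `metadata`).
#' @param genes Gene identifiers (rows) to include; default all.
#' @param scale `"log2"` (default, log2(TPM+1)) or `"tpm"` (raw).
#' @return Numeric matrix of z-scores (genes x experiments); every
#'   nondegenerate row has mean 0 and sample SD 1.
#' @examples
#' study <- simulate_study(sim_config(n_genes = 20, n_marked = 2,
#'   n_boundary_expressed = 0, n_decoy = 0, n_experiments = 6, seed = 2))
#' z <- zscore_matrix(study$compendium)
#' @export
zscore_matrix <- function(compendium, genes = NULL, scale = c("log2", "tpm")) {
  validate_compendium(compendium)
  scale <- match.arg(scale)
  tpm <- compendium$tpm
  if (ncol(tpm) < 2) stop_config("z-scores need at least 2 experiments")
  if (!is.null(genes)) {
    missing_ids <- setdiff(genes, rownames(tpm))
    if (length(missing_ids))
      stop_config("genes absent from compendium: %s",
                  paste(utils::head(missing_ids, 5), collapse = ", "))
    tpm <- tpm[genes, , drop = FALSE]
  }
  x <- if (scale == "log2") log2_tpm1(tpm) else tpm
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  z <- (x - mu) / sdv
  z[sdv == 0, ] <- 0
  z
}

#' Per-experiment induction score of a gene set
#'
#' For each experiment, the induction score of the gene set is the product
#' of the mean over the set of (TPM + 1) and the percentage of set genes
#' whose expression z-score exceeds `z_threshold`.
#'
#' @param compendium Expression compendium.
#' @param genes Non-empty character vector of gene identifiers (e.g. the
#'   marked set), all present in the compendium.
#' @param z_threshold z-score above which a gene counts as expressed in an
#'   experiment (default 0.5, strict inequality).
#' @param pct_scale `"percent"` (0-100, default) or `"fraction"` (0-1;
#'   scores shrink by 100x, for cross-checking).
#' @param zscore_scale Scale on which z-scores are computed; see
#'   [zscore_matrix()].
#' @return Data frame with one row per experiment: `experiment_id`,
#'   `mean_expr` (mean of TPM+1 over the set), `pct_above`, `score`.
#' @examples
#' tpm <- rbind(g1 = c(0, 0, 0, 10), g2 = c(0, 0, 0, 20))
#' colnames(tpm) <- paste0("e", 1:4)
#' md <- data.frame(experiment_id = colnames(tpm), condition_label = "c",
#'                  group = "g", is_mycelial_control = FALSE)
#' induction_score(list(tpm = tpm, metadata = md), c("g1", "g2"))$score
#' @export
induction_score <- function(compendium, genes, z_threshold = 0.5,
                            pct_scale = c("percent", "fraction"),
                            zscore_scale = c("log2", "tpm")) {
  validate_compendium(compendium)
  pct_scale <- match.arg(pct_scale)
  if (length(genes) == 0) stop_config("induction_score: gene set is empty")
  z <- zscore_matrix(compendium, genes = genes, scale = match.arg(zscore_scale))
  tpm <- compendium$tpm[genes, , drop = FALSE]
  mean_expr <- colMeans(tpm + 1)
  denom <- if (pct_scale == "percent") 100 else 1
  pct_above <- denom * colMeans(z > z_threshold)
  data.frame(
    experiment_id = colnames(tpm),
    mean_expr = unname(mean_expr),
    pct_above = unname(pct_above),
    score = unname(mean_expr * pct_above),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Rank experiments by induction score
#'
#' @param table Output of [induction_score()].
#' @return Character vector of experiment ids sorted by decreasing score;
#'   ties broken by lexicographic experiment id (deterministic).
#' @export
rank_conditions <- function(table) {
  if (!nrow(table)) stop_config("rank_conditions: empty score table")
  table$experiment_id[order(-table$score, table$experiment_id)]
}

#' Relative expression (log2 fold change versus reference experiments)
#'
#' value(g, e) = log2( (TPM(g,e) + 1) / (mean over reference of TPM(g,.) + 1) ).
#'
#' @param compendium Expression compendium.
#' @param genes Gene identifiers (rows); default all.
#' @param reference Non-empty character vector of reference experiment ids
#'   (e.g. the mycelial controls).
#' @return Numeric matrix of log2 fold changes (genes x experiments).
#' @export
relative_expression <- function(compendium, genes = NULL, reference) {
  validate_compendium(compendium)
  tpm <- compendium$tpm
  if (!is.null(genes)) tpm <- tpm[genes, , drop = FALSE]
  ref <- intersect(reference, colnames(tpm))
  if (!length(ref)) stop_config("reference experiments not found in compendium")
  ref_mean <- rowMeans(tpm[, ref, drop = FALSE]) + 1
  log2((tpm + 1) / ref_mean)
}
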