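## Developmentally induced genes (DIGs): built-in differential-expression
## contrast, threshold classification against the marked set, set-overlap
## statistics with hypergeometric enrichment, and stage-wise summaries.

#' Differential expression between two experiment groups
#'
#' Built-in contrast engine: per gene, l2fc is the difference of group
#' means of log2(TPM+1); the p-value comes from a two-sample Welch
#' (unequal-variance) t test on the same scale; FDR is Benjamini-Hochberg
#' across all genes of the contrast. Externally produced tables (gene_id,
#' l2fc, p_value, fdr) can be substituted anywhere a DE result is consumed.
#'
#' @param compendium Expression compendium.
#' @param group_a,group_b Disjoint character vectors of experiment ids
#'   (>= 2 each); l2fc is a minus b (e.g. perithecia vs mycelium).
#' @param contrast_label Label recorded in the result.
#' @return Data frame with `gene_id`, `l2fc`, `p_value`, `fdr`,
#'   `contrast_label`.
#' @export
call_de <- function(compendium, group_a, group_b,
                    contrast_label = "group_a_vs_group_b") {
  validate_compendium(compendium)
  ids <- colnames(compendium$tpm)
  missing_ids <- setdiff(c(group_a, group_b), ids)
  if (length(missing_ids))
    stop_config("experiments absent from compendium: %s",
                paste(missing_ids, collapse = ", "))
  if (length(intersect(group_a, group_b)))
    stop_config("group_a and group_b overlap")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_config("each group needs >= 2 experiments")
  xa <- log2_tpm1(compendium$tpm[, group_a, drop = FALSE])
  xb <- log2_tpm1(compendium$tpm[, group_b, drop = FALSE])
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  l2fc <- ma - mb
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, l2fc / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               1)
  p <- 2 * stats::pt(-abs(tstat), df)
  # both groups constant: no sampling variance; p degenerates on the sign
  # of the difference
  p[se2 == 0] <- ifelse(l2fc[se2 == 0] == 0, 1, 0)
  data.frame(
    gene_id = rownames(compendium$tpm),
    l2fc = unname(l2fc),
    p_value = unname(p),
    fdr = stats::p.adjust(unname(p), method = "BH"),
    contrast_label = contrast_label,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Classify genes as developmentally induced (DIG) and by marked status
#'
#' A gene is a DIG when l2fc > `l2fc_min` AND fdr < `fdr_max` (both strict).
#' With multiple contrasts in `de` (e.g. one per perithecial timepoint vs
#' mycelium), `aggregate = "any"` (default) calls a DIG when the thresholds
#' pass in any contrast; `"all"` requires every contrast.
#'
#' @param de DE result table (`gene_id`, `l2fc`, `p_value`, `fdr`,
#'   optionally `contrast_label`), from [call_de()] or an external tool.
#' @param marked Marked gene set: provenance table from
#'   [derive_marked_set()] or a character vector; all its genes must be
#'   covered by `de`.
#' @param l2fc_min Log2 fold-change threshold (default 2, strict >).
#' @param fdr_max FDR threshold (default 0.05, strict <).
#' @param aggregate `"any"` or `"all"` across contrasts.
#' @return Data frame with `gene_id`, `is_dig`, `is_marked`, and `class`
#'   in {"marked DIG", "unmarked DIG", "marked non-DIG",
#'   "unmarked non-DIG"}.
#' @export
classify_digs <- function(de, marked, l2fc_min = 2, fdr_max = 0.05,
                          aggregate = c("any", "all")) {
  aggregate <- match.arg(aggregate)
  need <- c("gene_id", "l2fc", "fdr")
  miss <- setdiff(need, names(de))
  if (length(miss)) stop_config("DE table lacks columns: %s",
                                paste(miss, collapse = ", "))
  marked_ids <- marked_gene_ids(marked)
  absent <- setdiff(marked_ids, de$gene_id)
  if (length(absent))
    stop_config("marked genes absent from DE table: %s",
                paste(utils::head(absent, 5), collapse = ", "))
  pass <- de$l2fc > l2fc_min & de$fdr < fdr_max
  agg <- tapply(pass, de$gene_id, if (aggregate == "any") any else all)
  gene_id <- sort(names(agg))
  is_dig <- unname(agg[gene_id])
  is_marked <- gene_id %in% marked_ids
  cls <- ifelse(is_marked,
                ifelse(is_dig, "marked DIG", "marked non-DIG"),
                ifelse(is_dig, "unmarked DIG", "unmarked non-DIG"))
  data.frame(gene_id = gene_id, is_dig = is_dig, is_marked = is_marked,
             class = cls, stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap statistics between two gene sets
#'
#' Counts, the percentage of set A found in set B, and the upper-tail
#' hypergeometric enrichment probability P(X >= overlap) given the
#' universe.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector: the gene universe (e.g. all annotated
#'   genes present in the compendium).
#' @return List with `n_set_a`, `n_set_b`, `n_overlap`, `pct_a_in_b`,
#'   `enrichment_p`, `universe_size`.
#' @examples
#' overlap_stats(letters[1:5], letters[3:6], letters[1:10])
#' @export
overlap_stats <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe)))
    stop_config("sets must be contained in the universe")
  n_a <- length(set_a); n_b <- length(set_b)
  n_ov <- length(intersect(set_a, set_b))
  list(
    n_set_a = n_a,
    n_set_b = n_b,
    n_overlap = n_ov,
    pct_a_in_b = if (n_a) 100 * n_ov / n_a else NA_real_,
    enrichment_p = stats::phyper(n_ov - 1, n_b, length(universe) - n_b, n_a,
                                 lower.tail = FALSE),
    universe_size = length(universe)
  )
}

#' Stage-wise expression summaries of DIG classes
#'
#' For each stage (a metadata `group` label) and each DIG class
#' ("marked DIG", "unmarked DIG"), returns the per-gene mean log2(TPM+1)
#' across the stage's experiments plus median/quartile summaries, suitable
#' for violin plots of expression across development.
#'
#' @param compendium Expression compendium.
#' @param classification Output of [classify_digs()].
#' @param stages Ordered character vector of metadata `group` labels.
#' @return List with `values` (stage, class, gene_id, mean_log2_tpm1) and
#'   `summary` (stage, class, n, median, q1, q3; empty classes have n = 0
#'   and NA quantiles).
#' @export
stage_summary <- function(compendium, classification,
                          stages = unique(compendium$metadata$group)) {
  validate_compendium(compendium)
  md <- compendium$metadata
  absent <- setdiff(stages, md$group)
  if (length(absent))
    stop_config("stage label(s) absent from metadata: %s",
                paste(absent, collapse = ", "))
  classes <- c("marked DIG", "unmarked DIG")
  logx <- log2_tpm1(compendium$tpm)
  values <- list(); summaries <- list()
  for (st in stages) {
    cols <- md$experiment_id[md$group == st]
    stage_mean <- rowMeans(logx[, cols, drop = FALSE])
    for (cl in classes) {
      ids <- intersect(classification$gene_id[classification$class == cl],
                       rownames(logx))
      v <- unname(stage_mean[ids])
      values[[paste(st, cl)]] <- data.frame(
        stage = rep(st, length(ids)), class = rep(cl, length(ids)),
        gene_id = ids, mean_log2_tpm1 = v, stringsAsFactors = FALSE)
      q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
           else rep(NA_real_, 3)
      summaries[[paste(st, cl)]] <- data.frame(
        stage = st, class = cl, n = length(v),
        median = q[2], q1 = q[1], q3 = q[3], stringsAsFactors = FALSE)
    }
  }
  list(values = do.call(rbind, c(values, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))))
}
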