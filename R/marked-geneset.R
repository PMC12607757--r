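## Derivation of the PRC2/H3K27me3-marked gene set: genes under peaks in
## two independent ChIP replicates, minus expressed peak-boundary genes.
## All internal coordinates are 0-based half-open; GFF3 is converted on read.

#' Normalize an interval table
#'
#' Converts coordinates to the internal 0-based half-open convention
#' (GFF3 records are 1-based closed and have 1 subtracted from `start`),
#' optionally merges overlapping intervals (for peak sets), and sorts
#' stably by (chrom, start).
#'
#' @param raw Data frame with `chrom`, `start`, `end` and optional extra
#'   columns (kept unless `merge = TRUE`).
#' @param dialect `"bed"` (0-based half-open, kept as is) or `"gff3"`
#'   (1-based closed, converted).
#' @param merge Merge overlapping intervals per chromosome (use for peak
#'   sets, not annotations).
#' @return The normalized data frame.
#' @examples
#' normalize_intervals(data.frame(chrom = "chr1", start = 101, end = 200),
#'                     dialect = "gff3")
#' @export
normalize_intervals <- function(raw, dialect = c("bed", "gff3"), merge = FALSE) {
  dialect <- match.arg(dialect)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop_config("interval table lacks columns: %s",
                                paste(miss, collapse = ", "))
  df <- raw
  if (dialect == "gff3") df$start <- df$start - 1L
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop_config("interval start >= end after conversion at line(s): %s",
                paste(utils::head(bad, 5), collapse = ", "))
  if (any(df$start < 0)) stop_config("negative interval coordinates")
  if (merge && nrow(df)) {
    red <- GenomicRanges::reduce(df_to_granges(df))
    df <- granges_to_df(red)
  }
  df[order(df$chrom, df$start, df$end), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Genes under peaks
#'
#' Returns the identifiers of genes whose body overlaps any peak by at
#' least `min_overlap` bp (strand-ignorant). Peaks on chromosomes absent
#' from the annotation contribute nothing (with a warning).
#'
#' @param annotation Normalized gene annotation (0-based half-open).
#' @param peaks Normalized peak table.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Sorted character vector of gene identifiers.
#' @examples
#' ann <- data.frame(gene_id = "g1", chrom = "chr1", start = 100, end = 200)
#' genes_under_peaks(ann, data.frame(chrom = "chr1", start = 199, end = 300))
#' @export
genes_under_peaks <- function(annotation, peaks, min_overlap = 1L) {
  validate_annotation(annotation)
  validate_peaks(peaks)
  if (!nrow(peaks)) return(character(0))
  orphan <- setdiff(unique(peaks$chrom), unique(annotation$chrom))
  if (length(orphan))
    warning(sprintf("peaks on chromosome(s) absent from annotation: %s",
                    paste(orphan, collapse = ", ")))
  gr_genes <- df_to_granges(annotation)
  gr_peaks <- df_to_granges(peaks)
  # orphan chromosomes are reported above; silence the duplicate seqlevel
  # notice from findOverlaps
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_genes, gr_peaks,
                                minoverlap = as.integer(min_overlap),
                                ignore.strand = TRUE)
  )
  sort(unique(annotation$gene_id[S4Vectors::queryHits(hits)]))
}

# TRUE for genes whose body is fully contained in a single merged peak
contained_in_peaks <- function(annotation, peaks) {
  if (!nrow(peaks)) return(stats::setNames(rep(FALSE, nrow(annotation)), annotation$gene_id))
  merged <- normalize_intervals(peaks, dialect = "bed", merge = TRUE)
  hits <- GenomicRanges::findOverlaps(df_to_granges(annotation),
                                      df_to_granges(merged),
                                      type = "within", ignore.strand = TRUE)
  out <- rep(FALSE, nrow(annotation))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  stats::setNames(out, annotation$gene_id)
}

#' Boundary-expression filter for marked-set candidates
#'
#' A candidate gene is flagged `is_boundary` when its body is not fully
#' contained within a single merged peak in at least one replicate, i.e. it
#' overlaps a peak edge. A boundary gene whose mean TPM over the designated
#' mycelial/control experiments reaches `expressed_tpm_threshold` is
#' excluded (`passed = FALSE`); genes contained in both replicates are
#' exempt from the filter regardless of expression.
#'
#' @param candidates Character vector of gene ids under peaks in both
#'   replicates.
#' @param annotation Normalized gene annotation.
#' @param peaks_1,peaks_2 Normalized peak tables of the two replicates.
#' @param compendium Expression compendium (list of `tpm`, `metadata`);
#'   must designate at least one mycelial control experiment.
#' @param expressed_tpm_threshold Mean control TPM at or above which a
#'   boundary gene counts as expressed (default 1).
#' @return A marked-gene-set provenance data frame with columns `gene_id`,
#'   `in_replicate_1`, `in_replicate_2`, `is_boundary`, `control_tpm`,
#'   `passed`.
#' @export
boundary_expression_filter <- function(candidates, annotation, peaks_1, peaks_2,
                                       compendium, expressed_tpm_threshold = 1) {
  validate_annotation(annotation)
  validate_compendium(compendium)
  ctrl <- control_experiments(compendium)
  if (!length(ctrl))
    stop_config("no mycelial/control experiments designated in compendium metadata")
  missing_ids <- setdiff(candidates, annotation$gene_id)
  if (length(missing_ids))
    stop_config("candidate genes absent from annotation: %s",
                paste(utils::head(missing_ids, 5), collapse = ", "))
  sub <- annotation[annotation$gene_id %in% candidates, , drop = FALSE]
  cont1 <- contained_in_peaks(sub, peaks_1)
  cont2 <- contained_in_peaks(sub, peaks_2)
  is_boundary <- !(cont1[sub$gene_id] & cont2[sub$gene_id])
  ctrl_tpm <- if (nrow(sub)) {
    rowMeans(compendium$tpm[sub$gene_id, ctrl, drop = FALSE])
  } else numeric(0)
  out <- data.frame(
    gene_id = sub$gene_id,
    in_replicate_1 = rep(TRUE, nrow(sub)),
    in_replicate_2 = rep(TRUE, nrow(sub)),
    is_boundary = unname(is_boundary),
    control_tpm = unname(ctrl_tpm),
    passed = unname(!(is_boundary & ctrl_tpm >= expressed_tpm_threshold)),
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Derive the PRC2/H3K27me3-marked gene set
#'
#' Full derivation: genes under peaks in each replicate, intersection of
#' the two identifier sets, then the boundary-expression filter. Emits a
#' provenance table over the union of genes hit in either replicate; genes
#' present in only one replicate have `passed = FALSE`.
#'
#' @param annotation Normalized gene annotation.
#' @param peaks_1,peaks_2 Normalized peak tables of the two ChIP replicates.
#' @param compendium Expression compendium with designated mycelial
#'   controls.
#' @param expressed_tpm_threshold Control-TPM cutoff for the boundary
#'   filter (default 1).
#' @param min_overlap Minimum gene/peak overlap in bp (default 1).
#' @return Provenance data frame (see [boundary_expression_filter()]);
#'   the marked set is `gene_id[passed]`.
#' @examples
#' study <- simulate_study(sim_config(n_genes = 60, n_marked = 6,
#'   n_boundary_expressed = 2, n_decoy = 2, n_experiments = 10, seed = 3))
#' ms <- derive_marked_set(study$annotation, study$peaks$rep1,
#'                         study$peaks$rep2, study$compendium)
#' setequal(ms$gene_id[ms$passed], study$truth$marked_gene_ids)
#' @export
derive_marked_set <- function(annotation, peaks_1, peaks_2, compendium,
                              expressed_tpm_threshold = 1, min_overlap = 1L) {
  hits1 <- genes_under_peaks(annotation, peaks_1, min_overlap = min_overlap)
  hits2 <- genes_under_peaks(annotation, peaks_2, min_overlap = min_overlap)
  both <- intersect(hits1, hits2)
  tab <- boundary_expression_filter(both, annotation, peaks_1, peaks_2,
                                    compendium, expressed_tpm_threshold)
  only <- setdiff(union(hits1, hits2), both)
  if (length(only)) {
    sub <- annotation[annotation$gene_id %in% only, , drop = FALSE]
    ctrl <- control_experiments(compendium)
    extra <- data.frame(
      gene_id = sub$gene_id,
      in_replicate_1 = sub$gene_id %in% hits1,
      in_replicate_2 = sub$gene_id %in% hits2,
      is_boundary = NA,
      control_tpm = unname(rowMeans(compendium$tpm[sub$gene_id, ctrl, drop = FALSE])),
      passed = FALSE,
      stringsAsFactors = FALSE
    )
    tab <- rbind(tab, extra)
  }
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Extract the passed marked-gene identifiers from a provenance table
#'
#' @param marked Provenance data frame from [derive_marked_set()], or a
#'   plain character vector (returned unchanged).
#' @return Character vector of marked gene ids.
#' @export
marked_gene_ids <- function(marked) {
  if (is.character(marked)) return(marked)
  if (is.data.frame(marked) && all(c("gene_id", "passed") %in% names(marked)))
    return(marked$gene_id[marked$passed])
  stop_config("'marked' must be a character vector or a marked-set provenance table")
}
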