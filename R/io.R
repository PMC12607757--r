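## Readers and writers for the pipeline's plain-text formats: BED3/BED6 and
## GFF3 through rtracklayer, TSV matrices and metadata, JSON ground truth.

#' Write a gene annotation as BED6
#'
#' @param annotation Annotation data frame (0-based half-open).
#' @param path Output file.
#' @export
write_annotation_bed <- function(annotation, path) {
  validate_annotation(annotation)
  gr <- df_to_granges(annotation)
  S4Vectors::mcols(gr)$name <- annotation$gene_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a gene annotation as GFF3
#'
#' @inheritParams write_annotation_bed
#' @export
write_annotation_gff3 <- function(annotation, path) {
  validate_annotation(annotation)
  gr <- df_to_granges(annotation)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$source <- "prc2induction"
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write a peak table as BED3
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param path Output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  validate_peaks(peaks)
  rtracklayer::export(df_to_granges(peaks), path, format = "BED")
  invisible(path)
}

#' Read a gene annotation from BED or GFF3
#'
#' Coordinates are converted to the internal 0-based half-open convention.
#' Gene identifiers come from the BED name column or the GFF3
#' ID/Name/gene_id attribute.
#'
#' @param path Input file; format from the extension unless given.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return Annotation data frame.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("annotation file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "GFF3" else "BED")
  mc <- S4Vectors::mcols(gr)
  id <- mc$name %||% mc$ID %||% mc$Name %||% mc$gene_id
  if (is.null(id)) stop_config("no gene identifiers found in %s", path)
  ann <- data.frame(
    gene_id = as.character(id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)
  ann[order(ann$chrom, ann$start), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Read a peak table from BED
#'
#' @param path BED file.
#' @param merge Merge overlapping peaks (default TRUE).
#' @return Normalized peak data frame.
#' @export
read_peaks_bed <- function(path, merge = TRUE) {
  if (!file.exists(path)) stop_config("peaks file not found: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  normalize_intervals(granges_to_df(gr), dialect = "bed", merge = merge)
}

#' Write an expression compendium as two TSV files
#'
#' The matrix TSV has `gene_id` as its first column and one column per
#' experiment; the metadata TSV has `experiment_id`, `condition_label`,
#' `group`, `is_mycelial_control`.
#'
#' @param compendium Compendium list (`tpm`, `metadata`).
#' @param tpm_path,metadata_path Output files.
#' @export
write_compendium_tsv <- function(compendium, tpm_path, metadata_path) {
  validate_compendium(compendium)
  df <- data.frame(gene_id = rownames(compendium$tpm),
                   compendium$tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, tpm_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(compendium$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(tpm_path, metadata_path))
}

#' Read an expression compendium from TSV files
#'
#' @param tpm_path,metadata_path Files written by [write_compendium_tsv()]
#'   or equivalent.
#' @return Compendium list (`tpm`, `metadata`).
#' @export
read_compendium_tsv <- function(tpm_path, metadata_path) {
  for (p in c(tpm_path, metadata_path))
    if (!file.exists(p)) stop_config("compendium file not found: %s", p)
  df <- utils::read.delim(tpm_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop_config("first column of %s must be gene_id", tpm_path)
  tpm <- as.matrix(df[, -1, drop = FALSE])
  rownames(tpm) <- df$gene_id
  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  md$is_mycelial_control <- as.logical(md$is_mycelial_control)
  compendium <- list(tpm = tpm, metadata = md)
  validate_compendium(compendium)
  compendium
}

#' Write/read morphometry measurements as TSV
#'
#' @param morphometry Data frame with `group`, `diameter_um`.
#' @param path File path.
#' @export
write_morphometry_tsv <- function(morphometry, path) {
  utils::write.table(morphometry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_morphometry_tsv
#' @export
read_morphometry_tsv <- function(path) {
  if (!file.exists(path)) stop_config("morphometry file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read an externally produced differential-expression table
#'
#' Expects TSV columns `gene_id`, `l2fc`, `p_value`, `fdr`, optionally
#' `contrast_label`.
#'
#' @param path TSV file.
#' @return DE result data frame.
#' @export
read_de_tsv <- function(path) {
  if (!file.exists(path)) stop_config("DE table not found: %s", path)
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "l2fc", "p_value", "fdr")
  miss <- setdiff(need, names(de))
  if (length(miss)) stop_config("DE table %s lacks columns: %s", path,
                                paste(miss, collapse = ", "))
  if (is.null(de$contrast_label)) de$contrast_label <- basename(path)
  de
}

#' Write/read planted ground truth as JSON
#'
#' @param truth `ground_truth` object from [plant_ground_truth()].
#' @param path JSON file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) stop_config("ground-truth file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("marked_gene_ids", "boundary_expressed_gene_ids",
              "decoy_gene_ids", "induced_experiment_ids"))
    x[[f]] <- as.character(x[[f]] %||% character(0))
  structure(x, class = "ground_truth")
}

#' Write a simulated study to an output directory
#'
#' Emits the annotation (BED6 and GFF3), the two peak replicates (BED3),
#' the compendium (matrix + metadata TSV), the morphometry table (TSV) and
#' the planted ground truth (JSON).
#'
#' @param study Output of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotation_bed = file.path(outdir, "annotation.bed"),
    annotation_gff3 = file.path(outdir, "annotation.gff3"),
    peaks_rep1 = file.path(outdir, "peaks_rep1.bed"),
    peaks_rep2 = file.path(outdir, "peaks_rep2.bed"),
    tpm = file.path(outdir, "compendium_tpm.tsv"),
    metadata = file.path(outdir, "compendium_metadata.tsv"),
    morphometry = file.path(outdir, "morphometry.tsv"),
    truth = file.path(outdir, "ground_truth.json")
  )
  write_annotation_bed(study$annotation, paths[["annotation_bed"]])
  write_annotation_gff3(study$annotation, paths[["annotation_gff3"]])
  write_peaks_bed(study$peaks$rep1, paths[["peaks_rep1"]])
  write_peaks_bed(study$peaks$rep2, paths[["peaks_rep2"]])
  write_compendium_tsv(study$compendium, paths[["tpm"]], paths[["metadata"]])
  write_morphometry_tsv(study$morphometry, paths[["morphometry"]])
  write_truth_json(study$truth, paths[["truth"]])
  invisible(paths)
}
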