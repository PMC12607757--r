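## Internal helpers: validation and interval-container conversion.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Convert an interval data frame to GRanges
#'
#' Interval tables in this package are 0-based half-open (BED convention):
#' columns `chrom`, `start`, `end`, optionally `gene_id` and `strand`.
#' GRanges is 1-based closed, so `start` is shifted by one on the way in.
#'
#' @param df data frame with `chrom`, `start`, `end` (0-based half-open).
#' @return A [GenomicRanges::GRanges] object.
#' @keywords internal
#' @noRd
df_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (!is.null(df$gene_id)) S4Vectors::mcols(gr)$gene_id <- df$gene_id
  if (!is.null(df$strand)) {
    s <- df$strand
    s[!s %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- s
  }
  gr
}

granges_to_df <- function(gr, id_col = NULL) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(id_col)) df[[id_col]] <- S4Vectors::mcols(gr)[[id_col]]
  df
}

#' Validate a gene annotation table
#'
#' @param annotation data frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), optionally `strand`.
#' @keywords internal
#' @noRd
validate_annotation <- function(annotation) {
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop_config("annotation lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$gene_id))
    stop_config("annotation gene_id values are not unique")
  if (any(annotation$start < 0)) stop_config("annotation has negative coordinates")
  bad <- which(annotation$start >= annotation$end)
  if (length(bad))
    stop_config("annotation has start >= end at row(s): %s",
                paste(utils::head(bad, 5), collapse = ", "))
  invisible(annotation)
}

validate_peaks <- function(peaks) {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop_config("peak table lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(peaks) && any(peaks$start >= peaks$end))
    stop_config("peak table has start >= end")
  invisible(peaks)
}

#' Validate an expression compendium
#'
#' A compendium is a list with `tpm` (numeric matrix, rows = genes,
#' columns = experiments, rownames/colnames set) and `metadata` (data frame
#' with `experiment_id`, `condition_label`, `group`, `is_mycelial_control`).
#'
#' @keywords internal
#' @noRd
validate_compendium <- function(compendium) {
  if (!is.list(compendium) || is.null(compendium$tpm) || is.null(compendium$metadata))
    stop_config("compendium must be a list with elements 'tpm' and 'metadata'")
  tpm <- compendium$tpm
  md <- compendium$metadata
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop_config("compendium tpm matrix needs gene rownames and experiment colnames")
  if (anyDuplicated(colnames(tpm))) stop_config("experiment ids are not unique")
  if (any(tpm < 0)) stop_config("TPM values must be non-negative")
  if (anyNA(tpm)) stop_config("TPM matrix contains missing values")
  need <- c("experiment_id", "condition_label", "group", "is_mycelial_control")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop_config("compendium metadata lacks columns: %s",
                                paste(miss, collapse = ", "))
  if (!setequal(md$experiment_id, colnames(tpm)))
    stop_config("metadata experiment ids do not match tpm matrix columns")
  invisible(compendium)
}

control_experiments <- function(compendium) {
  md <- compendium$metadata
  md$experiment_id[md$is_mycelial_control]
}

log2_tpm1 <- function(tpm) log2(tpm + 1)
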