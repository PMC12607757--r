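## Synthetic-data generators: annotation, planted truth, peak replicates,
## expression compendium, morphometry. All are deterministic given the
## configuration seed; each generator reseeds from a fixed offset of
## config$seed so the pieces can also be regenerated independently.

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes sequentially along `n_chromosomes` synthetic
#' chromosomes with random lengths and intergenic gaps. Coordinates are
#' 0-based half-open.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @examples
#' ann <- generate_annotation(sim_config(n_genes = 10, seed = 1))
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 11L)
  n <- config$n_genes
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), n))
  len <- round(stats::runif(n, config$gene_length_range[1], config$gene_length_range[2]))
  gap <- round(stats::runif(n, config$intergenic_gap_range[1], config$intergenic_gap_range[2]))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- integer(n); end <- integer(n)
  pos <- 0
  for (i in seq_len(n)) {
    if (i > 1 && chrom_of[i] != chrom_of[i - 1]) pos <- 0
    start[i] <- pos + gap[i]
    end[i] <- start[i] + len[i]
    pos <- end[i]
  }
  ann <- data.frame(
    gene_id = sprintf("NCS%05d", seq_len(n)),
    chrom = sprintf("chr%d", chrom_of),
    start = start,
    end = end,
    strand = strand,
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)
  ann
}

#' Plant ground truth over an annotation
#'
#' Assigns genes to the marked, boundary-expressed and single-replicate
#' decoy classes. Planted genes are never adjacent to one another along a
#' chromosome, so the peak domain of one planted gene can never merge with
#' or contain a neighbouring planted gene.
#'
#' @param config A [sim_config()] object.
#' @param annotation Output of [generate_annotation()].
#' @return A list of class `ground_truth` with `marked_gene_ids`,
#'   `boundary_expressed_gene_ids`, `decoy_gene_ids`,
#'   `induced_experiment_ids`, and `group_diameter_params`.
#' @export
plant_ground_truth <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  validate_annotation(annotation)
  set.seed(config$seed + 13L)
  ord <- order(annotation$chrom, annotation$start)
  n_need <- config$n_marked + config$n_boundary_expressed + config$n_decoy
  picked <- integer(0)
  for (i in sample(seq_along(ord))) {
    if (length(picked) >= n_need) break
    if (!any(abs(picked - i) <= 1L)) picked <- c(picked, i)
  }
  if (length(picked) < n_need)
    stop_config("cannot plant %d non-adjacent special genes among %d genes",
                n_need, config$n_genes)
  ids <- annotation$gene_id[ord][picked]
  marked <- ids[seq_len(config$n_marked)]
  boundary <- ids[config$n_marked + seq_len(config$n_boundary_expressed)]
  decoy <- ids[config$n_marked + config$n_boundary_expressed + seq_len(config$n_decoy)]
  design <- experiment_design(config)
  structure(list(
    marked_gene_ids = sort(marked),
    boundary_expressed_gene_ids = sort(boundary),
    decoy_gene_ids = sort(decoy),
    induced_experiment_ids = design$experiment_id[design$is_induced],
    group_diameter_params = list(
      wt_protoperithecia = list(dist = "normal", mean = 100, sd = 8),
      set7_false_perithecia = list(dist = "uniform", min = 100, max = 600),
      wt_perithecia = list(dist = "uniform", min = 400, max = 600)
    )
  ), class = "ground_truth")
}

#' Generate two replicate ChIP peak sets over planted genes
#'
#' Each replicate covers every marked gene's body entirely (peak edges
#' jittered independently per replicate within the intergenic margin) and
#' every boundary-expressed gene partially (the peak ends inside the gene
#' body, so the gene overlaps a peak edge in both replicates). Decoy genes
#' are fully covered in only one replicate, alternating between the two.
#'
#' @param config A [sim_config()] object.
#' @param annotation Output of [generate_annotation()].
#' @param truth Output of [plant_ground_truth()].
#' @return List of two data frames (`rep1`, `rep2`) with `chrom`, `start`,
#'   `end`, sorted and non-overlapping within each replicate.
#' @export
generate_peak_replicates <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  validate_annotation(annotation)
  if (length(truth$marked_gene_ids) == 0)
    stop_config("generate_peak_replicates: truth.marked_gene_ids is empty")
  all_planted <- c(truth$marked_gene_ids, truth$boundary_expressed_gene_ids,
                   truth$decoy_gene_ids)
  missing_ids <- setdiff(all_planted, annotation$gene_id)
  if (length(missing_ids))
    stop_config("planted genes absent from annotation: %s",
                paste(utils::head(missing_ids, 5), collapse = ", "))
  set.seed(config$seed + 17L)

  rows <- function(ids) annotation[match(ids, annotation$gene_id), , drop = FALSE]
  # margins stay below half the minimal intergenic gap: peaks of neighbouring
  # genes can never merge
  mmax <- min(100, floor(config$intergenic_gap_range[1] / 2) - 1)
  margin <- function(k) round(stats::runif(k, 20, mmax))

  full_cover <- function(g) {
    if (!nrow(g)) return(g[, c("chrom", "start", "end")])
    data.frame(chrom = g$chrom,
               start = pmax(0, g$start - margin(nrow(g))),
               end = g$end + margin(nrow(g)))
  }
  edge_cover <- function(g) {
    if (!nrow(g)) return(g[, c("chrom", "start", "end")])
    # peak stops inside the gene body: the gene overlaps the peak edge
    data.frame(chrom = g$chrom,
               start = pmax(0, g$start - margin(nrow(g))),
               end = g$start + pmax(1, floor((g$end - g$start) / 2)))
  }

  marked <- rows(truth$marked_gene_ids)
  boundary <- rows(truth$boundary_expressed_gene_ids)
  decoys <- rows(truth$decoy_gene_ids)
  in_rep1 <- seq_len(nrow(decoys)) %% 2L == 1L

  rep1 <- rbind(full_cover(marked), edge_cover(boundary),
                full_cover(decoys[in_rep1, , drop = FALSE]))
  rep2 <- rbind(full_cover(marked), edge_cover(boundary),
                full_cover(decoys[!in_rep1, , drop = FALSE]))
  list(rep1 = normalize_intervals(rep1, dialect = "bed", merge = TRUE),
       rep2 = normalize_intervals(rep2, dialect = "bed", merge = TRUE))
}

#' Generate a synthetic expression compendium
#'
#' Per-gene baseline means are drawn on the log2(TPM+1) scale: unmarked and
#' boundary-expressed genes from
#' Normal(`baseline_log_expr_mean`, `baseline_log_expr_sd`), marked genes
#' pinned at `log2(marked_silent_tpm + 1)`. Marked genes are shifted by
#' `induction_log2fc` in the induced experiments. Cell-level Gaussian noise
#' (`noise_sd`) is added, and values are back-transformed to TPM (>= 0).
#'
#' @inheritParams generate_peak_replicates
#' @return A compendium: list with `tpm` (gene x experiment matrix) and
#'   `metadata` (see [experiment_design()]).
#' @export
generate_compendium <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  validate_annotation(annotation)
  if (config$n_experiments < 2)
    stop_config("generate_compendium: n_experiments must be >= 2")
  set.seed(config$seed + 19L)
  design <- experiment_design(config)
  n_g <- config$n_genes
  n_e <- config$n_experiments
  is_marked <- annotation$gene_id %in% truth$marked_gene_ids
  is_boundary <- annotation$gene_id %in% truth$boundary_expressed_gene_ids

  mu <- stats::rnorm(n_g, config$baseline_log_expr_mean, config$baseline_log_expr_sd)
  mu <- pmax(mu, 0)
  # boundary genes are planted *expressed*: floor their baseline well above
  # the conventional TPM >= 1 expressed cutoff
  mu[is_boundary] <- pmax(mu[is_boundary], 3)
  mu[is_marked] <- log2(config$marked_silent_tpm + 1)

  x <- matrix(mu, nrow = n_g, ncol = n_e)
  induced_col <- design$experiment_id %in% truth$induced_experiment_ids
  x[is_marked, induced_col] <- x[is_marked, induced_col] + config$induction_log2fc
  if (config$noise_sd > 0)
    x <- x + matrix(stats::rnorm(n_g * n_e, 0, config$noise_sd), n_g, n_e)

  tpm <- pmax(2^x - 1, 0)
  dimnames(tpm) <- list(annotation$gene_id, design$experiment_id)
  compendium <- list(tpm = tpm,
                     metadata = design[, c("experiment_id", "condition_label",
                                           "group", "is_mycelial_control")])
  validate_compendium(compendium)
  compendium
}

#' Generate synthetic fruiting-body diameter measurements
#'
#' Emulates the three morphological groups: wild-type protoperithecia
#' (tight unimodal, ~100 um), wild-type perithecia (400-600 um), and
#' PRC2-deficient (delta set-7) false perithecia spanning ~100-600 um.
#'
#' @param truth Output of [plant_ground_truth()] (carries the per-group
#'   diameter distributions).
#' @param n_per_group Observations per group (>= 2).
#' @param seed Integer seed.
#' @return Data frame with `group` and `diameter_um` (> 0).
#' @export
generate_morphometry <- function(truth, n_per_group = 30, seed) {
  stopifnot(inherits(truth, "ground_truth"))
  if (missing(seed)) stop_config("generate_morphometry: 'seed' is mandatory")
  if (n_per_group < 2) stop_config("generate_morphometry: n_per_group must be >= 2")
  set.seed(as.integer(seed))
  params <- truth$group_diameter_params
  out <- lapply(names(params), function(g) {
    p <- params[[g]]
    d <- switch(p$dist,
      normal = stats::rnorm(n_per_group, p$mean, p$sd),
      uniform = stats::runif(n_per_group, p$min, p$max),
      stop_config("unknown diameter distribution '%s'", p$dist)
    )
    data.frame(group = g, diameter_um = pmax(d, 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate the complete synthetic study
#'
#' Convenience wrapper running all four generators under one configuration.
#'
#' @param config A [sim_config()] object.
#' @param n_per_group Morphometry observations per group.
#' @return List with `annotation`, `truth`, `peaks` (list of `rep1`,
#'   `rep2`), `compendium`, and `morphometry`.
#' @examples
#' study <- simulate_study(sim_config(n_genes = 50, n_marked = 5,
#'   n_boundary_expressed = 2, n_decoy = 2, n_experiments = 10, seed = 7))
#' @export
simulate_study <- function(config, n_per_group = 30) {
  annotation <- generate_annotation(config)
  truth <- plant_ground_truth(config, annotation)
  peaks <- generate_peak_replicates(config, annotation, truth)
  compendium <- generate_compendium(config, annotation, truth)
  morphometry <- generate_morphometry(truth, n_per_group = n_per_group,
                                      seed = config$seed + 23L)
  list(annotation = annotation, truth = truth, peaks = peaks,
       compendium = compendium, morphometry = morphometry)
}
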