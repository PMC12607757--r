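#' Simulation configuration for the synthetic study
#'
#' Bundles every tunable of the synthetic-data module. The defaults describe
#' the packaged study conditions: a genome of 1,000 genes of which 80 lie
#' fully inside replicated H3K27me3 peak domains (the planted marked set),
#' 15 expressed genes straddle peak boundaries, and 20 decoy genes sit under
#' a peak in only one of the two ChIP replicates. The expression compendium
#' holds 60 experiments: 6 mycelial controls, 6 perithecial-development
#' experiments in which the marked set is coordinately induced, and 48 other
#' vegetative conditions.
#'
#' Expression is generated on the log2(TPM+1) scale: each gene draws a
#' class-specific baseline mean, condition effects are added on that scale,
#' Gaussian noise with `noise_sd` is added per cell, and values are
#' back-transformed to TPM (floored at 0). Marked genes sit at
#' `log2(marked_silent_tpm + 1)` outside induced experiments and are shifted
#' by `induction_log2fc` inside them.
#'
#' @param n_genes Number of genes in the synthetic genome.
#' @param n_marked Number of planted PRC2/H3K27me3-marked genes; defaults
#'   to 8% of the genome, close to the ~7% marked in *N. crassa*.
#' @param n_boundary_expressed Number of expressed genes overlapping peak
#'   boundaries (planted to exercise the boundary filter); default 1.5%.
#' @param n_decoy Number of decoy genes covered by a peak in only one
#'   replicate (exercises the two-replicate requirement); default 2%.
#' @param n_experiments Number of expression experiments (>= 2).
#' @param n_mycelial_control Number of mycelial control experiments.
#' @param n_induced Number of induced (perithecial-development) experiments.
#' @param baseline_log_expr_mean,baseline_log_expr_sd Mean and SD (log2-TPM
#'   units) of the per-gene baseline expression for unmarked genes.
#' @param marked_silent_tpm Baseline TPM of marked genes outside induced
#'   conditions (~0: Polycomb-silenced).
#' @param induction_log2fc Shift (log2 units) applied to marked genes in
#'   induced experiments.
#' @param noise_sd Per-cell Gaussian noise SD on the log2(TPM+1) scale.
#' @param n_chromosomes Number of synthetic chromosomes.
#' @param gene_length_range,intergenic_gap_range Ranges (bp) for gene
#'   lengths and intergenic gaps. The minimum gap must exceed twice the
#'   maximal peak margin so that peak domains of neighbouring genes never
#'   merge into one another.
#' @param seed Integer seed; mandatory. Identical configurations produce
#'   bit-identical outputs from every generator.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 100, n_marked = 10, n_boundary_expressed = 2,
#'                   n_decoy = 2, n_experiments = 12, seed = 1)
#' @export
sim_config <- function(n_genes = 1000,
                       n_marked = round(0.08 * n_genes),
                       n_boundary_expressed = round(0.015 * n_genes),
                       n_decoy = round(0.02 * n_genes),
                       n_experiments = 60,
                       n_mycelial_control = 6,
                       n_induced = 6,
                       baseline_log_expr_mean = 5,
                       baseline_log_expr_sd = 1.5,
                       marked_silent_tpm = 0,
                       induction_log2fc = 4,
                       noise_sd = 0.25,
                       n_chromosomes = 7,
                       gene_length_range = c(500, 3000),
                       intergenic_gap_range = c(300, 2000),
                       seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop_config("sim_config: 'seed' is mandatory")
  seed <- as.integer(seed)
  counts <- c(n_genes = n_genes, n_marked = n_marked,
              n_boundary_expressed = n_boundary_expressed, n_decoy = n_decoy,
              n_experiments = n_experiments,
              n_mycelial_control = n_mycelial_control, n_induced = n_induced)
  if (any(counts < 0)) stop_config("sim_config: counts must be non-negative")
  if (n_genes < 1) stop_config("sim_config: n_genes must be >= 1")
  if (n_marked + n_boundary_expressed + n_decoy > n_genes)
    stop_config("sim_config: n_marked + n_boundary_expressed + n_decoy exceeds n_genes")
  if (n_experiments >= 1 && n_mycelial_control + n_induced > n_experiments)
    stop_config("sim_config: control + induced experiments exceed n_experiments")
  if (noise_sd < 0 || baseline_log_expr_sd < 0)
    stop_config("sim_config: standard deviations must be non-negative")
  if (marked_silent_tpm < 0) stop_config("sim_config: marked_silent_tpm must be >= 0")
  structure(list(
    n_genes = as.integer(n_genes),
    n_marked = as.integer(n_marked),
    n_boundary_expressed = as.integer(n_boundary_expressed),
    n_decoy = as.integer(n_decoy),
    n_experiments = as.integer(n_experiments),
    n_mycelial_control = as.integer(n_mycelial_control),
    n_induced = as.integer(n_induced),
    baseline_log_expr_mean = baseline_log_expr_mean,
    baseline_log_expr_sd = baseline_log_expr_sd,
    marked_silent_tpm = marked_silent_tpm,
    induction_log2fc = induction_log2fc,
    noise_sd = noise_sd,
    n_chromosomes = as.integer(max(1, n_chromosomes)),
    gene_length_range = as.numeric(gene_length_range),
    intergenic_gap_range = as.numeric(intergenic_gap_range),
    seed = seed
  ), class = "sim_config")
}

#' Experiment design table implied by a simulation configuration
#'
#' Deterministically lays out experiment identifiers, condition labels and
#' groups: first the mycelial controls, then the induced perithecial
#' experiments (stage labels cycling over 3-6 days post-fertilization), then
#' the remaining vegetative conditions.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with `experiment_id`, `condition_label`, `group`,
#'   `is_mycelial_control`, `is_induced`.
#' @export
experiment_design <- function(config) {
  n <- config$n_experiments
  ids <- sprintf("exp%03d", seq_len(n))
  group <- rep("vegetative_other", n)
  label <- rep("other_condition", n)
  ctrl <- seq_len(config$n_mycelial_control)
  group[ctrl] <- "mycelium"
  label[ctrl] <- "mycelium_minimal_medium"
  ind <- config$n_mycelial_control + seq_len(config$n_induced)
  dpf <- 3 + (seq_len(config$n_induced) - 1) %% 4
  group[ind] <- sprintf("perithecium_%ddpf", dpf)
  label[ind] <- sprintf("perithecia_%ddpf", dpf)
  other <- setdiff(seq_len(n), c(ctrl, ind))
  if (length(other))
    label[other] <- sprintf("vegetative_condition_%02d", seq_along(other))
  data.frame(
    experiment_id = ids,
    condition_label = label,
    group = group,
    is_mycelial_control = seq_len(n) %in% ctrl,
    is_induced = seq_len(n) %in% ind,
    stringsAsFactors = FALSE
  )
}
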