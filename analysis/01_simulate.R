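#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study.
#
# Generates the full set of pipeline inputs with planted ground truth:
# a 1,000-gene annotation over 7 chromosomes, two replicate H3K27me3 peak
# sets covering 80 marked genes (plus 15 expressed boundary genes and 20
# single-replicate decoys), a 60-experiment TPM compendium in which the
# marked set is induced only in the 6 perithecial experiments, and diameter
# measurements for the three fruiting-body groups. Run from the repository
# root; later stages read results/simulated_study/.

suppressPackageStartupMessages(library(prc2induction))

seed <- 2025
cfg <- sim_config(seed = seed)
study <- simulate_study(cfg)
paths <- write_simulated_study(study, "results/simulated_study")

cat(sprintf("genome: %d genes on %d chromosomes\n",
            nrow(study$annotation), length(unique(study$annotation$chrom))))
cat(sprintf("planted: %d marked, %d boundary-expressed, %d decoys\n",
            length(study$truth$marked_gene_ids),
            length(study$truth$boundary_expressed_gene_ids),
            length(study$truth$decoy_gene_ids)))
cat(sprintf("compendium: %d experiments (%d mycelial controls, %d induced)\n",
            ncol(study$compendium$tpm),
            sum(study$compendium$metadata$is_mycelial_control),
            length(study$truth$induced_experiment_ids)))
cat("wrote:\n"); cat(sprintf("  %s\n", paths))
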