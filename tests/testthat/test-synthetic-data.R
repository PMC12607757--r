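# Synthetic-data generators: determinism, planted structure, generative
# closed forms.

test_that("generators are deterministic given the seed", {
  cfg <- sim_config(n_genes = 100, n_marked = 10, n_boundary_expressed = 3,
                    n_decoy = 3, n_experiments = 12, n_mycelial_control = 3,
                    n_induced = 3, seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$compendium, s2$compendium)
  expect_identical(s1$morphometry, s2$morphometry)
  expect_identical(s1$truth, s2$truth)
})

test_that("annotation intervals are valid and pairwise non-overlapping", {
  ann1 <- generate_annotation(sim_config(n_genes = 1, seed = 3))
  expect_equal(nrow(ann1), 1)
  expect_gt(ann1$end - ann1$start, 0)

  ann <- generate_annotation(sim_config(n_genes = 50, seed = 3))
  expect_equal(anyDuplicated(ann$gene_id), 0)
  # brute-force all-pairs overlap count
  n_overlapping <- 0
  for (i in seq_len(nrow(ann) - 1)) {
    for (j in (i + 1):nrow(ann)) {
      if (ann$chrom[i] != ann$chrom[j]) next
      if (min(ann$end[i], ann$end[j]) > max(ann$start[i], ann$start[j]))
        n_overlapping <- n_overlapping + 1
    }
  }
  expect_equal(n_overlapping, 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 100, seed = NULL), "seed")
  expect_error(sim_config(n_genes = 100, n_marked = -1, seed = 1), "non-negative")
  expect_error(sim_config(n_genes = 10, n_marked = 8, n_boundary_expressed = 5,
                          seed = 1), "exceeds")
})

test_that("peak replicates cover exactly the planted genes", {
  cfg <- sim_config(n_genes = 80, n_marked = 8, n_boundary_expressed = 0,
                    n_decoy = 0, n_experiments = 8, n_mycelial_control = 2,
                    n_induced = 2, seed = 11)
  ann <- generate_annotation(cfg)
  truth <- plant_ground_truth(cfg, ann)
  pks <- generate_peak_replicates(cfg, ann, truth)
  for (rep in pks) {
    expect_setequal(oracle_genes_under_peaks(ann, rep), truth$marked_gene_ids)
  }

  # with 5 decoys, genes hit in BOTH replicates are exactly marked + boundary
  cfg2 <- sim_config(n_genes = 80, n_marked = 8, n_boundary_expressed = 3,
                     n_decoy = 5, n_experiments = 8, n_mycelial_control = 2,
                     n_induced = 2, seed = 11)
  ann2 <- generate_annotation(cfg2)
  truth2 <- plant_ground_truth(cfg2, ann2)
  pks2 <- generate_peak_replicates(cfg2, ann2, truth2)
  both <- intersect(oracle_genes_under_peaks(ann2, pks2$rep1),
                    oracle_genes_under_peaks(ann2, pks2$rep2))
  expect_setequal(both, c(truth2$marked_gene_ids,
                          truth2$boundary_expressed_gene_ids))
  # each decoy is hit in exactly one replicate
  in1 <- truth2$decoy_gene_ids %in% oracle_genes_under_peaks(ann2, pks2$rep1)
  in2 <- truth2$decoy_gene_ids %in% oracle_genes_under_peaks(ann2, pks2$rep2)
  expect_true(all(xor(in1, in2)))
})

test_that("compendium follows the generative model exactly when noiseless", {
  cfg <- sim_config(n_genes = 40, n_marked = 5, n_boundary_expressed = 2,
                    n_decoy = 0, n_experiments = 10, n_mycelial_control = 3,
                    n_induced = 3, marked_silent_tpm = 0, induction_log2fc = 5,
                    noise_sd = 0, seed = 9)
  study <- simulate_study(cfg)
  tpm <- study$compendium$tpm
  induced <- study$truth$induced_experiment_ids
  other <- setdiff(colnames(tpm), induced)
  marked <- study$truth$marked_gene_ids
  expect_equal(unname(tpm[marked, other]),
               matrix(0, length(marked), length(other)))
  expect_equal(unname(tpm[marked, induced]),
               matrix(2^5 - 1, length(marked), length(induced)))
  expect_true(all(tpm >= 0))
})

test_that("null induction leaves marked genes flat across condition groups", {
  cfg <- sim_config(n_genes = 200, n_marked = 40, n_boundary_expressed = 0,
                    n_decoy = 0, n_experiments = 30, n_mycelial_control = 5,
                    n_induced = 10, marked_silent_tpm = 20,
                    induction_log2fc = 0, noise_sd = 0.2, seed = 13)
  study <- simulate_study(cfg)
  tpm <- study$compendium$tpm
  induced <- study$truth$induced_experiment_ids
  other <- setdiff(colnames(tpm), induced)
  m_ind <- mean(log2(tpm[study$truth$marked_gene_ids, induced] + 1))
  m_oth <- mean(log2(tpm[study$truth$marked_gene_ids, other] + 1))
  expect_lt(abs(m_ind - m_oth), 3 * 0.2 / sqrt(40 * 10))
})

test_that("morphometry groups have the planted size ordering", {
  cfg <- sim_config(n_genes = 10, seed = 5)
  truth <- plant_ground_truth(cfg, generate_annotation(cfg))

  d2 <- generate_morphometry(truth, n_per_group = 2, seed = 5)
  expect_equal(nrow(d2), 6)
  expect_true(all(d2$diameter_um > 0))
  expect_identical(d2, generate_morphometry(truth, n_per_group = 2, seed = 5))
  expect_error(generate_morphometry(truth, n_per_group = 1, seed = 5), ">= 2")

  big <- generate_morphometry(truth, n_per_group = 2000, seed = 5)
  med <- tapply(big$diameter_um, big$group, stats::median)
  expect_lt(med[["wt_protoperithecia"]], med[["set7_false_perithecia"]])
  expect_lt(med[["set7_false_perithecia"]], med[["wt_perithecia"]])

  # zero-variance variant flows through the omnibus test gracefully
  truth0 <- truth
  truth0$group_diameter_params <- lapply(truth0$group_diameter_params,
    function(p) list(dist = "normal", mean = 100, sd = 0))
  flat <- generate_morphometry(truth0, n_per_group = 5, seed = 5)
  res <- kruskal_wallis(flat$diameter_um, flat$group)
  expect_equal(res$H, 0)
  expect_equal(res$p_omnibus, 1)
})
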