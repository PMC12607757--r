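# Marked-gene-set derivation: coordinate conventions, peak overlap against
# a brute-force oracle, the boundary-expression filter, and full recovery
# of the planted set.

test_that("normalize_intervals converts dialects and merges peaks", {
  gff <- data.frame(chrom = "chr1", start = 101, end = 200)
  expect_equal(normalize_intervals(gff, dialect = "gff3")$start, 100)
  expect_equal(normalize_intervals(gff, dialect = "gff3")$end, 200)

  bed <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_equal(normalize_intervals(bed, dialect = "bed"), bed)

  merged <- normalize_intervals(
    data.frame(chrom = c("chr1", "chr1"), start = c(0, 5), end = c(10, 20)),
    dialect = "bed", merge = TRUE)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 0)
  expect_equal(merged$end, 20)
  # merged set covers exactly the union of bases
  expect_equal(sum(merged$end - merged$start), oracle_union_bases(c(0, 5), c(10, 20)))

  expect_error(normalize_intervals(data.frame(chrom = "chr1", start = 5, end = 5),
                                   dialect = "bed"), "line")
})

test_that("genes_under_peaks applies the >= 1 bp rule and matches brute force", {
  ann <- data.frame(gene_id = "g1", chrom = "chr1", start = 100, end = 200)
  expect_identical(genes_under_peaks(ann, data.frame(chrom = character(0),
                                                     start = numeric(0),
                                                     end = numeric(0))),
                   character(0))
  expect_equal(genes_under_peaks(ann, data.frame(chrom = "chr1", start = 199,
                                                 end = 300)), "g1")
  expect_identical(genes_under_peaks(ann, data.frame(chrom = "chr1", start = 200,
                                                     end = 300)), character(0))
  expect_warning(genes_under_peaks(ann, data.frame(chrom = "chr9", start = 0,
                                                   end = 10)), "chr9")

  set.seed(101)
  for (i in 1:25) {
    inst <- random_instance()
    expect_identical(genes_under_peaks(inst$annotation, inst$peaks),
                     oracle_genes_under_peaks(inst$annotation, inst$peaks))
  }
})

test_that("genes_under_peaks is monotone under added peaks", {
  set.seed(202)
  inst <- random_instance(n_genes = 40, n_peaks = 15)
  base <- genes_under_peaks(inst$annotation, inst$peaks[1:8, ])
  more <- genes_under_peaks(inst$annotation, inst$peaks)
  expect_true(all(base %in% more))
})

test_that("boundary filter: containment exempts, silent boundary genes stay", {
  ann <- data.frame(gene_id = c("inside", "edge_silent", "edge_expressed"),
                    chrom = "chr1",
                    start = c(100, 1000, 2000), end = c(200, 1100, 2100))
  # peaks fully contain "inside"; stop mid-body for the two edge genes
  pk <- data.frame(chrom = "chr1", start = c(50, 950, 1950),
                   end = c(250, 1050, 2050))
  tpm <- rbind(inside = c(500, 500), edge_silent = c(0, 0),
               edge_expressed = c(30, 50))
  colnames(tpm) <- c("ctrl1", "ctrl2")
  comp <- make_compendium(tpm, controls = c("ctrl1", "ctrl2"))

  res <- boundary_expression_filter(ann$gene_id, ann, pk, pk, comp,
                                    expressed_tpm_threshold = 1)
  res <- res[match(ann$gene_id, res$gene_id), ]
  expect_equal(res$is_boundary, c(FALSE, TRUE, TRUE))
  expect_equal(res$passed, c(TRUE, TRUE, FALSE))
  expect_equal(res$control_tpm, c(500, 0, 40))

  no_ctrl <- make_compendium(tpm)
  expect_error(boundary_expression_filter(ann$gene_id, ann, pk, pk, no_ctrl),
               "control")
})

test_that("derive_marked_set recovers the planted set exactly", {
  study <- tiny_study()
  tab <- derive_marked_set(study$annotation, study$peaks$rep1,
                           study$peaks$rep2, study$compendium)
  passed <- tab$gene_id[tab$passed]
  expect_setequal(passed, study$truth$marked_gene_ids)
  expect_equal(length(passed), 12)

  # decoys appear in exactly one replicate and never pass
  dec <- tab[tab$gene_id %in% study$truth$decoy_gene_ids, ]
  expect_equal(nrow(dec), 4)
  expect_true(all(xor(dec$in_replicate_1, dec$in_replicate_2)))
  expect_false(any(dec$passed))

  # boundary-expressed genes are flagged and filtered
  bnd <- tab[tab$gene_id %in% study$truth$boundary_expressed_gene_ids, ]
  expect_true(all(bnd$is_boundary))
  expect_false(any(bnd$passed))

  # empty replicate 2 empties the passed set
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  tab0 <- derive_marked_set(study$annotation, study$peaks$rep1, empty,
                            study$compendium)
  expect_equal(sum(tab0$passed), 0)
})

test_that("derivation properties: containment and threshold monotonicity", {
  study <- tiny_study()
  tab <- derive_marked_set(study$annotation, study$peaks$rep1,
                           study$peaks$rep2, study$compendium)
  both <- intersect(genes_under_peaks(study$annotation, study$peaks$rep1),
                    genes_under_peaks(study$annotation, study$peaks$rep2))
  expect_true(all(tab$gene_id[tab$passed] %in% both))

  loose <- derive_marked_set(study$annotation, study$peaks$rep1,
                             study$peaks$rep2, study$compendium,
                             expressed_tpm_threshold = 1e6)
  expect_true(all(tab$gene_id[tab$passed] %in% loose$gene_id[loose$passed]))
})
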