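# DIG calling and classification, set-overlap statistics with
# hypergeometric enrichment, stage-wise summaries.

test_that("call_de computes l2fc arithmetic and matches BH and Welch oracles", {
  set.seed(51)
  tpm <- matrix(rexp(200 * 8, 0.05), 200, 8,
                dimnames = list(sprintf("g%03d", 1:200), paste0("e", 1:8)))
  comp <- make_compendium(tpm)
  de <- call_de(comp, paste0("e", 1:4), paste0("e", 5:8))

  # independent step-up BH reproduces the fdr column exactly
  expect_equal(de$fdr, oracle_bh(de$p_value))
  # spot-check Welch p-values against stats::t.test
  for (g in c("g001", "g050", "g123")) {
    tt <- t.test(log2(tpm[g, 1:4] + 1), log2(tpm[g, 5:8] + 1))
    expect_equal(de$p_value[de$gene_id == g], unname(tt$p.value))
    expect_equal(de$l2fc[de$gene_id == g],
                 unname(tt$estimate[1] - tt$estimate[2]))
  }

  # duplicated columns give a null contrast
  tpm2 <- cbind(tpm[, 1:2], tpm[, 1:2])
  colnames(tpm2) <- paste0("e", 1:4)
  de0 <- call_de(make_compendium(tpm2), c("e1", "e2"), c("e3", "e4"))
  expect_equal(de0$l2fc, rep(0, 200))

  # stated arithmetic: log2(TPM+1) means [6,6] vs [2,2] -> l2fc = 4
  tpm3 <- rbind(g1 = c(63, 63, 3, 3))
  colnames(tpm3) <- paste0("e", 1:4)
  de4 <- call_de(make_compendium(tpm3), c("e1", "e2"), c("e3", "e4"))
  expect_equal(de4$l2fc, 4)

  expect_error(call_de(comp, paste0("e", 1:4), paste0("e", 4:8)), "overlap")
  expect_error(call_de(comp, "e1", paste0("e", 5:8)), ">= 2")
})

test_that("DIG classification uses strict thresholds and labels classes", {
  de <- data.frame(
    gene_id = c("exact", "dig_marked", "dig_unmarked", "weak"),
    l2fc = c(2, 3, 5, 0.5),
    p_value = c(0.001, 0.001, 0.001, 0.5),
    fdr = c(0.01, 0.01, 0.001, 0.9),
    contrast_label = "c1"
  )
  cls <- classify_digs(de, marked = c("exact", "dig_marked"))
  cls <- cls[match(de$gene_id, cls$gene_id), ]
  expect_equal(cls$is_dig, c(FALSE, TRUE, TRUE, FALSE))   # l2fc = 2 is not > 2
  expect_equal(cls$class, c("marked non-DIG", "marked DIG", "unmarked DIG",
                            "unmarked non-DIG"))
  expect_error(classify_digs(de, marked = "missing_gene"), "missing_gene")

  # threshold monotonicity: loosening thresholds never drops a DIG
  set.seed(61)
  de_r <- data.frame(gene_id = sprintf("g%02d", 1:50),
                     l2fc = rnorm(50, 1, 2), p_value = runif(50),
                     fdr = runif(50))
  strict <- classify_digs(de_r, marked = character(0))
  loose <- classify_digs(de_r, marked = character(0), l2fc_min = 1,
                         fdr_max = 0.2)
  expect_true(all(strict$gene_id[strict$is_dig] %in%
                    loose$gene_id[loose$is_dig]))
})

test_that("multi-contrast aggregation follows the any/all rule", {
  de <- rbind(
    data.frame(gene_id = c("g1", "g2"), l2fc = c(3, 3), p_value = 0.001,
               fdr = 0.01, contrast_label = "t3"),
    data.frame(gene_id = c("g1", "g2"), l2fc = c(3, 0), p_value = 0.001,
               fdr = 0.01, contrast_label = "t4")
  )
  any_cls <- classify_digs(de, marked = character(0))
  all_cls <- classify_digs(de, marked = character(0), aggregate = "all")
  expect_equal(any_cls$is_dig[any_cls$gene_id == "g2"], TRUE)
  expect_equal(all_cls$is_dig[all_cls$gene_id == "g2"], FALSE)
  expect_equal(all_cls$is_dig[all_cls$gene_id == "g1"], TRUE)
})

test_that("planted marked genes come out as marked DIGs end to end", {
  study <- tiny_study()
  md <- study$compendium$metadata
  dev <- md$experiment_id[grepl("^perithecium", md$group)]
  ctrl <- md$experiment_id[md$is_mycelial_control]
  de <- call_de(study$compendium, dev, ctrl)
  cls <- classify_digs(de, marked = study$truth$marked_gene_ids)
  marked_cls <- cls$class[cls$gene_id %in% study$truth$marked_gene_ids]
  expect_true(all(marked_cls == "marked DIG"))
})

test_that("overlap statistics match printed-count arithmetic and enumeration", {
  u <- sprintf("g%04d", 1:6000)
  a <- u[1:516]
  b <- c(u[1:440], u[4000:6000])
  os <- overlap_stats(a, b, u)
  expect_equal(os$n_overlap, 440)
  expect_equal(round(os$pct_a_in_b), 85)

  os_id <- overlap_stats(a, a, u)
  expect_equal(os_id$pct_a_in_b, 100)
  expect_lt(os_id$enrichment_p, 1e-200)

  # exhaustive enumeration for small universes
  expect_equal(overlap_stats(letters[1:5], letters[1:4], letters[1:10])$enrichment_p,
               5 / 210)
  set.seed(71)
  for (i in 1:12) {
    N <- sample(6:15, 1)
    na <- sample(1:(N - 1), 1); nb <- sample(1:(N - 1), 1)
    u_i <- letters[1:N]
    a_i <- sample(u_i, na); b_i <- sample(u_i, nb)
    os_i <- overlap_stats(a_i, b_i, u_i)
    expect_equal(os_i$enrichment_p,
                 oracle_hyper_enum(N, na, nb, os_i$n_overlap))
    # overlap count is symmetric; percentages rescale exactly
    os_s <- overlap_stats(b_i, a_i, u_i)
    expect_equal(os_s$n_overlap, os_i$n_overlap)
    expect_equal(os_s$pct_a_in_b, 100 * os_i$n_overlap / nb)
  }
  expect_error(overlap_stats(c("zz"), letters[1:3], letters[1:10]), "universe")
})

test_that("stage summaries separate silenced and constitutive DIGs", {
  study <- tiny_study()
  md <- study$compendium$metadata
  dev <- md$experiment_id[grepl("^perithecium", md$group)]
  ctrl <- md$experiment_id[md$is_mycelial_control]
  de <- call_de(study$compendium, dev, ctrl)
  cls <- classify_digs(de, marked = study$truth$marked_gene_ids)
  st <- stage_summary(study$compendium, cls,
                      stages = c("mycelium", unique(md$group[grepl("^perithecium",
                                                                   md$group)])))
  smry <- st$summary
  myc <- smry[smry$stage == "mycelium" & smry$class == "marked DIG", ]
  expect_lt(myc$median, 0.5)         # silenced in mycelium
  peri <- smry[smry$stage != "mycelium" & smry$class == "marked DIG", ]
  expect_true(all(peri$median > 2))  # strongly induced in perithecia

  # empty class: present with n = 0, no crash
  empty <- smry[smry$class == "unmarked DIG", ]
  expect_true(all(empty$n == 0) || all(empty$n > 0))
  expect_equal(nrow(smry), 2 * length(unique(smry$stage)))

  # single-gene class: median equals that gene's value
  one_cls <- data.frame(gene_id = rownames(study$compendium$tpm)[1],
                        is_dig = TRUE, is_marked = TRUE, class = "marked DIG")
  st1 <- stage_summary(study$compendium, one_cls, stages = "mycelium")
  expect_equal(st1$summary$median[st1$summary$class == "marked DIG"],
               st1$values$mean_log2_tpm1[1])

  expect_error(stage_summary(study$compendium, cls, stages = "no_such_stage"),
               "no_such_stage")
})
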