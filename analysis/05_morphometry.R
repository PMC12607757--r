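#!/usr/bin/env Rscript
# Stage 5 — fruiting-body morphometry statistics.
#
# Compares the diameters of wild-type protoperithecia, wild-type perithecia
# and PRC2-mutant false perithecia with the tie-corrected Kruskal-Wallis
# omnibus test and Holm-adjusted Dunn pairwise post hoc tests.

suppressPackageStartupMessages(library(prc2induction))

morph <- read_morphometry_tsv("results/simulated_study/morphometry.tsv")
cat("group sizes and median diameters (um):\n")
print(data.frame(
  n = tapply(morph$diameter_um, morph$group, length),
  median_um = round(tapply(morph$diameter_um, morph$group, stats::median), 1)
))

res <- kw_dunn(morph)
print(res)
if (res$p_omnibus < 0.001)
  cat("omnibus difference significant at P < 0.001\n")

utils::write.table(
  data.frame(statistic = "kruskal_wallis_H", value = res$H, df = res$df,
             p = res$p_omnibus),
  "results/morphometry_omnibus.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(res$pairwise, "results/morphometry_pairwise.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/morphometry_omnibus.tsv, results/morphometry_pairwise.tsv\n")
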