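# Independent oracles used across the suite. These are deliberately naive
# (all-pairs loops, full enumeration, step-up written out) and share no code
# with the implementation paths they check.

# O(n*m) all-pairs interval overlap: gene ids overlapping any peak by
# >= min_overlap bp (0-based half-open intervals)
oracle_genes_under_peaks <- function(annotation, peaks, min_overlap = 1) {
  hit <- character(0)
  for (i in seq_len(nrow(annotation))) {
    for (j in seq_len(nrow(peaks))) {
      if (annotation$chrom[i] != peaks$chrom[j]) next
      ov <- min(annotation$end[i], peaks$end[j]) -
        max(annotation$start[i], peaks$start[j])
      if (ov >= min_overlap) { hit <- c(hit, annotation$gene_id[i]); break }
    }
  }
  sort(unique(hit))
}

# covered-base union of a set of intervals on one chromosome
oracle_union_bases <- function(starts, ends) {
  covered <- logical(max(ends))
  for (k in seq_along(starts)) covered[(starts[k] + 1):ends[k]] <- TRUE
  sum(covered)
}

# Benjamini-Hochberg step-up, written out
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- 1
  for (idx in seq_along(o)) {
    i <- o[idx]
    rank_i <- m - idx + 1
    running <- min(running, p[i] * m / rank_i)
    adj[i] <- running
  }
  adj
}

# exhaustive hypergeometric upper tail: over all C(N, n_a) draws of set A
# from the universe, the fraction with >= n_overlap members of set B
oracle_hyper_enum <- function(universe_size, n_a, n_b, n_overlap) {
  universe <- seq_len(universe_size)
  in_b <- universe <= n_b
  draws <- utils::combn(universe, n_a)
  mean(colSums(matrix(in_b[draws], nrow = n_a)) >= n_overlap)
}

# small deterministic study shared by several files (built once per run)
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 120, n_marked = 12, n_boundary_expressed = 4,
                        n_decoy = 4, n_experiments = 16,
                        n_mycelial_control = 4, n_induced = 4, seed = 42)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})

random_instance <- function(n_genes = 50, n_peaks = 20) {
  len <- sample(50:500, n_genes, replace = TRUE)
  gap <- sample(1:400, n_genes, replace = TRUE)
  chrom <- sort(sample(c("chr1", "chr2"), n_genes, replace = TRUE))
  start <- integer(n_genes); pos <- 0
  for (i in seq_len(n_genes)) {
    if (i > 1 && chrom[i] != chrom[i - 1]) pos <- 0
    start[i] <- pos + gap[i]
    pos <- start[i] + len[i]
  }
  ann <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                    chrom = chrom, start = start, end = start + len,
                    stringsAsFactors = FALSE)
  pk_start <- sample(0:max(ann$end), n_peaks, replace = TRUE)
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), n_peaks, replace = TRUE),
                      start = pk_start,
                      end = pk_start + sample(20:800, n_peaks, replace = TRUE),
                      stringsAsFactors = FALSE)
  list(annotation = ann, peaks = peaks)
}

make_compendium <- function(tpm, controls = character(0), groups = NULL) {
  md <- data.frame(
    experiment_id = colnames(tpm),
    condition_label = colnames(tpm),
    group = groups %||% rep("g", ncol(tpm)),
    is_mycelial_control = colnames(tpm) %in% controls,
    stringsAsFactors = FALSE
  )
  list(tpm = tpm, metadata = md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
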