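---
title: "Methods: deriving and scoring PRC2-marked gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and scoring PRC2-marked gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prc2induction)
```

## The scientific setting

PRC2-deposited H3K27me3 silences a few hundred genes in *Neurospora
crassa* mycelium. This package operationalizes the question "under which
conditions does that gene set turn on?" as a pipeline over four
ingredients: a gene annotation, two replicate H3K27me3 ChIP-seq peak sets,
a multi-condition TPM expression compendium with designated mycelial
controls, and (for the mutant phenotype) diameter measurements of
fruiting-body structures. Everything runs equally on real files (BED,
GFF3, TSV) and on the package's synthetic data with planted ground truth.

## Marked-set derivation

A gene is a candidate when its body overlaps a peak by at least 1 bp
(strand-ignorant) in **both** replicates. The 1 bp rule is the simplest
defensible choice — no minimum-overlap fraction is biologically motivated
here — and `min_overlap` is exposed for stricter analyses. Replicate
consistency is enforced as the *set intersection of per-replicate gene
hits*, not as geometric intersection of the peak intervals themselves:
two replicates may disagree on exact peak edges while agreeing that a
gene is covered, and it is the gene call that matters downstream.

The boundary filter then removes genes that straddle a peak edge and are
expressed. "Straddles an edge" is made precise as: the gene body is not
fully contained in a single merged peak in at least one replicate.
Containment in both replicates exempts a gene from the filter no matter
how highly it is expressed — such genes are inside the domain, and marked
domains are precisely what the set should contain. "Expressed" means mean
TPM ≥ 1 over the mycelial control experiments; the TPM ≥ 1 convention is
the default and the threshold is a parameter
(`expressed_tpm_threshold`). Raising it can only enlarge the passed set
(a weaker filter), which the test suite checks as an invariant.

Coordinates are 0-based half-open everywhere internally; GFF3 input is
converted on read (1-based closed → half-open) and interval work is
delegated to GenomicRanges/IRanges. The test suite holds the overlap
machinery to an all-pairs brute-force oracle on hundreds of random
instances.

## The induction score

For gene set $G$ and experiment $e$:

$$\mathrm{score}(e) = \underbrace{\frac{1}{|G|}\sum_{g \in G}
(\mathrm{TPM}_{g,e} + 1)}_{\text{mean expression}} \times
\underbrace{\frac{100}{|G|}\,\bigl|\{g : z_{g,e} > 0.5\}\bigr|}_{\text{\% of set genes on}}$$

Two numerical choices deserve comment:

* **z-scores are computed on log2(TPM+1)**, using the sample (n−1)
  standard deviation per gene across experiments. The log scale keeps a
  single enormous TPM value from dominating a gene's variance; raw-TPM
  z-scores are available via `zscore_scale = "tpm"`. Genes with zero
  variance (all-silent rows are common in a Polycomb-marked set) get
  z = 0 everywhere rather than 0/0.
* **The percentage is on the 0–100 scale**; `pct_scale = "fraction"`
  divides scores by exactly 100 for cross-checking against plots drawn on
  the other convention.

The product structure means the score is zero unless *some* genes clear
the z-threshold, and grows with both the breadth (percentage) and the
magnitude (mean TPM+1) of induction. It is invariant to gene and
experiment ordering and monotone in the set's TPM values, both tested.
Condition ranking breaks score ties by experiment identifier so that
reruns are deterministic.

A hand-checkable example, used verbatim in the tests: two genes with TPM
rows (0,0,0,10) and (0,0,0,20) over four experiments give z-rows
(−0.5, −0.5, −0.5, 1.5) — for values $\{0,0,0,v\}$ the mean is $v/4$ and
the sample SD $v/2$ — so experiment 4 scores
$\frac{11 + 21}{2} \times 100 = 1600$ and the rest score 0.

## DIG classification and overlap

Developmentally induced genes pass l2fc > 2 **and** FDR < 0.05, both
strict, in a development-vs-mycelium contrast. The package ships a
deliberately plain DE engine — per-gene Welch t test on log2(TPM+1) with
Benjamini–Hochberg correction — because DE methodology is routine and
interchangeable here; externally produced tables (`read_de_tsv()`) drop
in wherever a DE result is consumed. With several perithecial timepoints,
a gene is a DIG when it passes in *any* contrast (`aggregate = "any"`);
requiring *all* contrasts is a flag. Overlap enrichment uses the
upper-tail hypergeometric probability with the universe set to all
annotated genes present in the compendium, which is what a genome-scale
Venn diagram implicitly assumes. The enrichment is checked against
exhaustive enumeration for small universes, and the BH column against an
independent step-up implementation.

## Morphometry statistics

The diameter comparison uses the tie-corrected Kruskal–Wallis statistic

$$H = \frac{12}{N(N+1)}\sum_i n_i\left(\bar R_i - \frac{N+1}{2}\right)^2
\bigg/ \left(1 - \frac{\sum_t (t^3 - t)}{N^3 - N}\right)$$

with mid-ranks for ties and a $\chi^2_{k-1}$ upper-tail p-value, Dunn's
pairwise z

$$z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left[\frac{N(N+1)}{12} -
\frac{\sum_t (t^3-t)}{12(N-1)}\right]\left(\frac{1}{n_i} +
\frac{1}{n_j}\right)}}$$

with two-sided normal p-values (sidedness is a convention; two-sided is
the default of common implementations), and Holm's step-down adjustment.
These are written out from first principles — the point is an
implementation whose every term is inspectable — and validated three
ways: hand-derived closed forms (groups 1–3/4–6/7–9 give exactly
H = 7.2; groups 1–3 vs 7–9 give Dunn z = −3/√(7/3) ≈ −1.964; Holm on
(0.01, 0.04, 0.03) gives (0.03, 0.06, 0.06)), agreement with the standard
library routines on random tied data, and an exact-permutation option
(`exact = TRUE`, full enumeration, practical to N ≈ 8–10) whose p-value
is compared against a full-enumeration oracle. Degenerate inputs are
defined rather than errors: all-tied data give H = 0, p = 1 and z = 0,
p = 1. A Monte-Carlo calibration check (2,000 null datasets, 3 × 10
observations) verifies the omnibus rejection rate at α = 0.05 stays in
[0.03, 0.07] — the chi-square approximation runs slightly conservative at
these group sizes, which is the expected direction.

## What the synthetic generator emulates — and what it does not

The generator plants a genome of non-overlapping genes (defaults: 1,000
genes, 7 chromosomes, lengths 0.5–3 kb, gaps 0.3–2 kb), a marked subset
(8%, close to the ~7% marked in the organism), expressed boundary genes,
and decoy genes covered in only one replicate; peak margins stay below
half the minimal intergenic gap so neighbouring domains never merge.
Expression is log2(TPM+1)-normal per gene class with additive condition
effects — the scale every downstream figure uses — with defaults of
baseline mean 5 and SD 1.5 log2 units, marked-gene silence at 0 TPM, a
4-log2-unit induction in 6 of 60 experiments, and cell-level noise SD
0.25. Morphometry draws protoperithecia from Normal(100, 8) µm,
perithecia from Uniform(400, 600) µm and mutant false perithecia from
Uniform(100, 600) µm, matching the reported ranges of the three
structures. Seeds are mandatory and every generator is bit-reproducible.

What passing recovery tests does **not** show: the generator treats all
experiments as directly comparable TPM with homogeneous noise. Real
compendia aggregated from hundreds of public runs carry batch effects,
library-preparation biases and annotation-version mismatches, none of
which are simulated; nor are coverage-level ChIP artefacts (peak calling
is consumed, not performed), nor unmarked genes with genuine
developmental induction — in the clean synthetic study every DIG is a
marked gene, so the "unmarked DIG" class is exercised only through
hand-built fixtures in the tests. Perfect precision/recall on synthetic
data therefore validates the *logic* of the derivation, not its
robustness to real-data noise.

## Problem sizes and defaults

The packaged study conditions are 1,000 genes / 80 marked / 15
boundary-expressed / 20 decoys / 60 experiments, and the induction-recovery
condition is 500 genes / 60 experiments / 6 induced at log2 fold change 4,
noise SD 0.25 — small enough that the whole suite, including 200
brute-force oracle instances and the 2,000-replicate calibration, runs in
well under a minute, and large enough that recovery is not trivially
forced. Pipeline outputs are plain TSV with the parameter block as
leading `#` comments, plus one JSON manifest with input checksums, so any
run is diffable against any other.
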