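# mifishr

Single-cell copy-number analysis for multiplex interphase FISH (miFISH)
profiling of tumors. miFISH counts hybridization signals for a panel of
locus-specific probes — here eight breast-cancer genes (COX2, DBC2, MYC,
CCND1, CDH1, TP53, HER2, ZNF217) plus two centromere references (CCP4,
CCP10) — in hundreds of individual nuclei per sample. From those
per-nucleus integer count vectors, `mifishr` quantifies intratumor
heterogeneity and reconstructs clonal evolution:

* **Clones and instability.** Nuclei sharing a signal pattern form a
  clone; the instability index *I = N·100/n* (distinct patterns *N* per
  100 of *n* nuclei) measures intratumor heterogeneity.
* **Ploidy.** Per-nucleus ploidy is anchored on centromere counts with an
  amplification-robust gene average; a sample is aneuploid iff its
  one-decimal average ploidy is ≥ 2.2.
* **CNA calls.** Gains/losses relative to each nucleus's own ploidy,
  called at ≥ 15% of nuclei and graded major at ≥ 85%; amplification when
  a gene's mean count exceeds twice the sample ploidy.
* **Clone graphs.** Clones keyed by gain/loss pattern, connected when one
  single gain-or-loss change apart — a DAG read outward from the most
  balanced clone.
* **Minimal-event phylogenies.** Rooted trees from the diploid (2,…,2)
  state whose edges each change one probe by one copy or duplicate the
  whole genome (WGD), with inferred transit nodes, greedy event-count
  minimization, and an exact Steiner-arborescence oracle for small
  instances.
* **Mutual exclusivity / co-occurrence.** Margin-preserving edge-switching
  permutation tests on binary alteration matrices with Benjamini–Hochberg
  q-values.
* **Variant hard-filtering.** An auditable 11-criterion cascade on
  annotated somatic variant calls (caller status, depths, QUAL, MAPQ
  tiers, dbNSFP impact, dbSNP, population frequencies, COSMIC support,
  recurrence).
* **DNA image cytometry.** Histogram classification as diploid vs
  aneuploid from stem-line structure (2c/4c windows) and the
  more-than-10-cells-above-5c rule.
* **Synthetic data.** Generators for nucleus tables, variant tables and
  histograms with known ground truth, so every stage is testable without
  external data.

## Worked example

The package ships a synthetic reconstruction of a published
low-instability diploid case, built from its two printed clone patterns
(217 and 29 of 250 nuclei) plus three minor patterns:

```r
library(mifishr)
panel <- default_panel()
rec <- read_signal_table(system.file("extdata",
        "case7L_reconstruction_synthetic.tsv", package = "mifishr"), panel)

sample_summary(rec, panel)
#> <sample_summary> n = 250 nuclei, N = 5 patterns
#>   instability index I = 2.0
#>   average ploidy 2.0 (diploid), sample ploidy 2
#>   major clone 2-1-3-2-1-2-2-2-2-2 (86.8% of nuclei)
#>   CNA calls:
#>     DBC2    loss_major (gain 0%, loss 100%)
#>     MYC     gain_major (gain 100%, loss 0%)
#>     CDH1    loss_major (gain 0%, loss 100%)

build_clone_graph(rec, panel)
#> <clone_graph> 4 clones, 3 single-step edges
#>   DBC2-,MYC+,CDH1-                98.4%
#>   DBC2-,MYC+,CDH1-,ZNF217+         0.8%
#>   DBC2-,MYC+                       0.4%
#>   MYC+,CDH1-                       0.4%
```

The sample resolves to 5 signal patterns over 250 nuclei (instability
index 2 — the printed value), classifies as diploid, and its two major
signal-level clones collapse under ploidy-relative gain/loss annotation
into one clone carrying 98% of cells with loss of DBC2 and CDH1 and gain
of MYC. A minimal-event phylogeny of the same sample:

```r
pats <- aggregate_patterns(rec, panel)
build_fish_tree(pats[, gene_probes(panel)],
                multiplicity = pats$multiplicity,
                probe_names = gene_probes(panel))
#> <fish_tree> 7 nodes (5 observed, 2 transit), depth 4, 6 events
```

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write their tables under `results/`: `01_simulate.R` (cohort
generation), `02_clonal_metrics.R` (summaries, CNA calls, clone graphs via
`run_pipeline()`), `03_trees.R` (phylogenies and oracle agreement),
`04_exclusivity.R` (pair tests and empirical size), `05_variants.R`
(filter audit), `06_cytometry.R` (histogram classification). Each script
prints what it found; all are deterministic.

## The methods vignette

`vignettes/mifishr-methods.Rmd` documents the models and every numeric
convention (rounding, thresholds, tie-breaks, the tree event model, the
permutation null and its discreteness, filter-wording interpretations),
what the synthetic generators emulate, and known limitations.
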