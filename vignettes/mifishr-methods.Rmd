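---
title: "Methods: single-cell miFISH copy-number analysis with mifishr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell miFISH copy-number analysis with mifishr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifishr)
```

## The data and the model

Multiplex interphase FISH (miFISH) enumerates integer hybridization signal
counts for a panel of locus-specific probes in hundreds of individual tumor
nuclei. The default panel carries eight breast-cancer genes — COX2 (1q31.1),
DBC2 (8p21.3), MYC (8q24.21), CCND1 (11q13.3), CDH1 (16q22.1), TP53
(17p13.1), HER2 (17q12), ZNF217 (20q13.2) — and two centromere reference
probes (CCP4, CCP10). A nucleus's count vector over the panel is its
*signal pattern*; nuclei sharing a pattern form a clone, and the most
frequent pattern is the *major clone*. The input contract assumes
completely scored nuclei (every probe visible); a sample is expected to
carry at least 250 of them, and shortfalls are flagged at warning level
rather than rejected.

### Ploidy annotation

Per nucleus, the baseline copy number is anchored on the centromere probes
and an amplification-robust gene average:

1. candidate ploidy `p0` = median centromere count (median gene count for
   centromere-free panels);
2. gene probes counting more than `2 * p0` are set aside as amplified;
3. the nucleus ploidy is the pooled mean of centromere and retained gene
   counts, rounded half-up to an integer.

The published account states which signals are assessed and that amplified
markers are left out of the average, but not the pooling or the rounding;
this rule is our choice, fixed because it is deterministic and reproduces
both printed worked examples (the tetraploid `8-4-4-4-3-2-4-5` major clone
and flat diploid patterns). Rounding of exact halves is *half-up* (2.5
becomes 3) — a convention, applied consistently and guarded against
floating-point representation of rational means. Whether the sample-level
average ploidy should include centromere counts is ambiguous in the source
("average of all FISH probes"); the per-nucleus rule above pools both, and
the sample average is the mean of per-nucleus ploidies rounded half-up to
one decimal. A sample is **aneuploid** iff that one-decimal average is
`>= 2.2` (2.0 and 2.1 read as diploid) — the cutoff calibrated against DNA
image cytometry in the source study.

### Gains, losses, CNA calls, instability

Each gene probe is trichotomized against its own nucleus's ploidy (gain
above, loss below, neutral at). Sample-level copy-number-alteration (CNA)
calls use the fraction of nuclei carrying the aberration: called at
`>= 15%`, graded *major* at `>= 85%` (both inclusive, per the figure-legend
wording); when a gene crosses 15% in both directions, both fractions are
reported and the larger wins the single call (gain on an exact tie — a
tie-break the source never needs). A gene is *amplified* when its mean
count strictly exceeds twice the sample ploidy ("more than two times"),
the sample ploidy for this test being the rounded modal nucleus ploidy.

The instability index is `I = N * 100 / n` — distinct signal patterns per
100 nuclei. By default the pattern universe is the full probe vector
(including centromeres), with a switch for gene-probes-only; the source
counts "signal patterns observed" without restriction. `I` ranges from
`100/n` (monoclonal) to 100 (all distinct).

### Clone graphs

The imbalance clone plot groups nuclei by gain/loss pattern (not raw
counts), so ploidy-shifted clones with the same relative imbalances merge:
in the reconstructed low-instability case, the `2-1-3-2-1-2-2-2` and
`2-1-4-2-1-2-2-2` clones (217 + 29 of 250 nuclei) collapse into one
`DBC2-,MYC+,CDH1-` clone covering 98% of cells. Directed edges connect
clones exactly one single-step state change apart (neutral↔gain or
neutral↔loss); a loss↔gain flip in one gene passes through neutral and is
*two* changes, so it draws no edge. Edges point toward the clone with more
aberrant genes, which makes the graph a DAG. Unobserved intermediates are
never interpolated here — that is the tree model's job.

## Minimal-event phylogenies

Trees start from the all-2s diploid root. Each edge is one event: a single
probe changing by one copy, or a whole-genome duplication (WGD) doubling
every probe. Unobserved intermediates are materialized as *transit nodes*.
Under the *absorbing-zero* rule (default on, switchable) a fully lost
probe cannot be regained. Choices the source leaves open, fixed here:

* every event costs 1, so minimizing total alterations is minimizing edge
  count; a WGD counts as **one** event toward the total;
* WGD edges are allowed from any node, so doubling can be an initiating or
  a late event; default `allow_wgd = TRUE`;
* transit paths step coordinates in panel order — this changes node
  identity but never the event count.

The builder is a greedy agglomeration: repeatedly attach the unattached
pattern with the cheapest feasible connection (L1 distance, or 1 + L1 from
the doubled anchor when a WGD jump helps) to *any* node already in the
tree, transit nodes included; ties break deterministically (distance, then
lexicographically smallest pattern, then earliest-inserted anchor). A
transit node whose pattern matches a still-unattached observed pattern is
promoted in place. Tree depth is the maximum root-to-leaf edge count;
total events is the edge count.

### The exact oracle

`steiner_oracle()` computes the true minimum event count on small
instances (≤ 4 probes, counts ≤ 6, ≤ 4 patterns) as a directed Steiner
arborescence on the bounded copy-number lattice, via a Dreyfus–Wagner
dynamic program over terminal subsets with igraph shortest paths. With WGD
enabled the lattice cap is twice the largest terminal coordinate, because
an optimal route may double past a target and step back down; this is why
the bounds are enforced rather than advisory. The greedy builder can never
beat the oracle (its tree is valid), and on instances drawn from the
domain's own generative model — patterns accumulated by 1–4 unit events
along a random clone genealogy from the diploid root — it attains the
exact minimum in roughly 90% of 3-pattern instances. On uniform random
lattice points (which no FISH sample resembles) agreement drops to roughly
half: the greedy trunk-sharing heuristic is tuned to clonally structured
data, and we state its guarantee only there.

## Exclusivity and co-occurrence tests

Cohort-level alteration events (per-gene CNA calls, per-gene mutations)
form a binary samples × events matrix. For every event pair, the observed
overlap is compared against a null that preserves every sample's
alteration burden and every event's prevalence: edge-switching
randomization (repeatedly rotating 2×2 submatrices `10/01 ↔ 01/10`), with
`10 ×` (number of 1s) switch attempts between successive sampled matrices
— a standard mixing heuristic. P-values use the add-one estimator
`(1 + #extreme)/(1 + n_perm)` (default `n_perm = 10000`), upper tail for
co-occurrence, lower tail for exclusivity, each direction
Benjamini–Hochberg adjusted across all tested pairs. Events altered in no
or every sample carry no information under fixed margins and are excluded
and reported. Module-finding over interaction networks is not
re-implemented; the source uses the approach only for pairwise statements,
and the margin-preserving pairwise permutation test is the faithful
reduction.

Two mathematical properties of this null are worth knowing. A matrix
containing *only* two events is degenerate: fixed row and column sums pin
the overlap exactly, so every p-value is 1 — pairs must be tested inside
the full event matrix. And because the overlap statistic is discrete, the
test is conservative: at 40 samples its true size at `alpha = 0.05` is
about 0.025 whatever the margins (the exact hypergeometric tail shows the
same), so nominal-level rejections are trustworthy but the test does not
spend the full error budget.

## Variant filter cascade

Eleven hard-filter criteria are applied to fully annotated variant records
(caller status, allele fractions and depths, QUAL, MAPQ, dbNSFP impact,
dbSNP membership, population allele frequencies, COSMIC case counts,
cross-sample recurrence). All criteria are evaluated exhaustively — every
violated rule is recorded, not just the first — so the audit table shows
which rule removed each record. Absent annotations are an error, never a
silent pass. Readings fixed where the printed wording is ambiguous:

* the two-tier MAPQ rule: records with ≥ 100 COSMIC cases or on the
  breast-cancer hotspot genes (TP53, PIK3CA, GATA3, MAP3K1, KMT2C) face
  only the lenient `MAPQ >= 40` bar and are exempt from the strict 55
  tier, which applies to all other genes;
* recurrence (rule 10) removes variants seen in more than one sample
  *with* fewer than 100 COSMIC cases, recomputed table-globally so
  verdicts are order-independent;
* rule 11 removes variants with zero COSMIC cases whose impact is only
  "moderate";
* the 5% allele-fraction bound (rule 2) is inclusive, as printed.

## DNA image cytometry

A DNA-content histogram (c-value, cell-count pairs) is classified
aneuploid iff a stem line sits outside the `2c ± 0.25` and `4c ± 0.25`
windows, or strictly more than 10 cells measure above 5c; otherwise
diploid (the source pools Auer types I and III and does not restate the
full type system, so only this operational rule is implemented). The
source classifies histograms by eye; the numeric detector is ours:
Gaussian-kernel smoothing at bandwidth 0.1c, stem lines = local maxima
whose topographic prominence reaches what a co-located cluster of 2.5% of
all cells would produce. The window half-width covers staining variation
while still separating a 3c stem line; all three constants are exposed as
arguments. The recommended minimum of 1214 cells (the smallest analyzed in
the source) warns rather than rejects.

## Synthetic data: what it emulates, what it does not

`simulate_sample()` draws 250 nuclei (default) from a clone structure with
a forced ≥ 0.3 major clone (symmetric Dirichlet(1) frequencies otherwise),
clones grown from a diploid, WGD-tetraploid or hypodiploid founder by
single-probe unit events under absorbing zero, centromeres tracking the
founder ploidy, and independent per-probe miscount noise (±1 with equal
probability, floored at 0) at 2% — a rate at which monoclonal simulations
land in the instability range printed for stable tumors (≈ 2–8). The
hypodiploid founder mirrors the published severely hypodiploid case
(single copies of DBC2, MYC, CDH1, TP53, HER2). There is no spatial
structure, no selection model, and the noise is symmetric and
probe-independent — real FISH miscounts are none of these — so passing
recovery tests demonstrate correctness of the estimators under the stated
statistical model, not robustness to every real-data pathology.

One consequence of the noise model worth stating: per-probe miscounts
fragment exact signal patterns, so the *observed* major-clone multiplicity
is biased below the generating frequency by a factor of about
`(1 - rate)^P` for `P` probes (≈ 0.82 at defaults). Major-clone recovery
is therefore a binomial-error statement only at zero miscount noise, and
that is how it is tested; at default noise the bias is real, expected, and
not a defect of the estimator. Ploidy-class recovery, by contrast, is
insensitive to the noise and is tested at defaults.

`simulate_variant_table()` engineers records so that an exact, known
subset passes the cascade, cycling every failing record through the 11
criteria; `simulate_histogram()` mixes Gaussian stem lines with a uniform
debris floor. All generators are deterministic given their seed.

## Problem sizes and runtime

The shipped analyses and tests use: 9 simulated samples of 250 nuclei
across the three founder scenarios; 200 samples for ploidy-class recovery
and 100 noiseless samples for major-clone recovery; 100 oracle-checked
tree instances (3 patterns, 4 probes); 1000 null matrices of 40 × 6 events
at 2000 permutations for the size estimate; a 100-record engineered
variant table; 100 simulated histograms of 5000 cells. These sizes keep
every script in the minutes range on one CPU while leaving Monte-Carlo
error well below the margins being asserted.

## Known limitations

* The greedy tree builder is a heuristic; its optimality statement is
  empirical and distribution-dependent, and the oracle only certifies
  small instances. Reproducing any specific published tree node-for-node
  is out of scope (the upstream tool's exact heuristic is not public).
* Cohort-level printed frequencies (e.g. gene-wise CNA rates) require the
  study's raw nuclei, which were never deposited; they are covered by
  parameter recovery on synthetic data instead.
* The permutation test's conservatism at small cohorts is inherent to
  discrete exact tests; users wanting tighter calibration need larger
  cohorts, not a different `n_perm`.
* Whether single-chromosome duplications (as opposed to WGD) should be
  single events is not modeled; only unit steps and WGD are.
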