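---
title: "Gene set regularity profiling: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene set regularity profiling: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsrome)
```

## The model

`gsrome` quantifies the *dysregulation* of a biological function — a gene
set — in a single sample, relative to a reference phenotype, using only the
ordering of expression values. For a gene set with $m$ measured genes there
are $\binom{m}{2}$ unordered gene pairs. From the control samples we learn a
**rank template**: for each pair $(i, j)$, the direction $d_{ij} = 1$ if
strictly more than half the controls express gene $i$ below gene $j$, else
$d_{ij} = 0$. A sample's **gene set regularity (GSR) index** is the fraction
of pairs whose ordering in that sample agrees with the template:

$$\mathrm{GSR} = \frac{1}{\binom{m}{2}} \sum_{i<j}
  \mathbf{1}\!\left[\,\mathbf{1}(x_i < x_j) = d_{ij}\,\right] \in [0, 1],$$

so 1 means the sample's within-set ordering matches the most common control
ordering exactly, and 0 means every pairwise ordering is reversed — the most
dysregulated state. This is a rank-matching variant in the DIRAC family:
because only orderings enter, the index is invariant under any strictly
increasing transform of a sample's values (log scale, quantile scaling,
platform-monotone distortions), which is what makes merging heterogeneous
expression sources defensible at all.

The **functionome** of a sample is its vector of GSR indices over a whole
gene set collection (one column per GMT set, in GMT order). The
**immunofunctionome** is its restriction to the sets whose GO terms are
offspring of chosen immune ancestors — by default the two progenitors
"immune system process" (`GO:0002376`) and "inflammatory response"
(`GO:0006954`) when working with real GO data; offspring are collected by
following both `is_a` and `part_of` edges child-to-parent.

Downstream, each case group's GSR indices are compared to the controls per
term with a two-sided Mann–Whitney test, corrected within each group's
family of terms by Benjamini–Hochberg. Term clusters (subtrees under the
ancestors' direct children) are ranked by the **cluster weight index**

$$\mathrm{CWI}_c = \frac{\sum_{t \in c} -\log p_t}
                        {\sum_{c'} \sum_{t \in c'} -\log p_t},$$

a share of total evidence that lies in $[0,1]$, sums to 1 and is invariant
to the logarithm base (natural log used; $p$ clamped below at $10^{-300}$).
Terms are ordered by (cluster CWI desc, own $p$ asc, name asc) — a fully
deterministic "relevance" order — and the top-$k$ ($k = 30$ by default)
lists of the stage groups are intersected to find the functions
commonly dysregulated across disease progression. An exploratory-factor-
analysis step sometimes used for such rankings is deliberately *not*
implemented — no loadings/rotation/retention rule could be pinned down —
so the CWI-then-p order is the package's ranking, and users should read
"relevance" as exactly that quantity.

## Tie and tie-break conventions

Every convention that could make results run-dependent is fixed:

* Within a sample, the pair indicator is $\mathbf{1}(x_i < x_j)$; equality
  counts as 0 on both the template and the sample side.
* A template pair tied at exactly half the controls resolves to
  $d_{ij} = 0$. Results are bit-reproducible; no randomized tie-breaking.
* Mann–Whitney: $U$ counts pairs $x < y$ plus half-ties; the p-value is
  exact by enumeration when $n_x n_y \le 400$ with no ties, otherwise a
  tie-corrected normal approximation with continuity correction.
* Cutoff-scan ties in the minimum log-rank p resolve to the lower cutoff.
* Cluster-assignment ties in ancestor distance resolve by head order.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_genes` | 2 | A set needs ≥ 2 measured genes to define a pair; smaller sets are dropped and reported, never silently skipped. |
| `alpha`, `rule` | 0.05, `"q"` | Significance level; applied to BH q by default (the conservative reading of "p < 0.05 after FDR correction"), switchable to raw p. |
| `correction_mode` | `"none"` | Group-mean correction: raw case mean (consistent with published group tables, whose "corrected" values equal the raw case means), `"difference"` (case − control + grand control mean) or `"ratio"`. |
| `top_k` | 30 | Top-of-ranking size per group before cross-group intersection. |
| `roots` | config | Ancestor GO ids defining the immunofunctionome. |
| SVM | linear, C = 1 | No kernel/cost was specified upstream; a linear maximum-margin classifier with unit cost and per-training-fold standardization (no leakage) is the explicit default. |
| `min_group` | 5 | Smallest allowed side of a survival split, avoiding degenerate cutoffs. |
| quartiles | type 8 | Median-unbiased quantile convention; stated because the convention changes the admissible cutoff range. |

The survival scan deliberately reports `n_candidates`: selecting the
minimum p over a scan is anti-conservative by construction, and the scan
size is the quantity a reader needs to judge that.

The hazard ratio is the Peto (log-rank) estimator
$\exp\{(O - E)/V\}$ with CI $\exp\{(O-E)/V \pm 1.96/\sqrt V\}$, computed
from the log-rank observed/expected tables of the high- vs low-expression
groups. It is self-contained and deterministic but approximate: it can
differ slightly from a Cox partial-likelihood HR, and its CI coverage is
a little below nominal for strong effects.

## The synthetic study generator

`synthetic_spec()` defines the reference simulated study used throughout
the tests: 200 disjoint gene sets of 5–10 genes; within each set the genes
get strictly increasing baseline means with spacing 1.0; 30 controls and
two case groups of 30 draw values as baseline plus Gaussian noise with SD
0.5 (in spacing units — chosen so that roughly a quarter of adjacent-gene
comparisons flip per sample, a realistic amount of rank noise for
microarray-scale data); 20 sets are planted as dysregulated by reversing
(or deranging) their *baseline* order in cases. Disruption acts on the
population baselines, not per-sample shuffles, matching the GSR model's
assumption of a phenotype-level ordering change. The ontology generator
plants exactly `round(immune_fraction * n_sets)` sets under a synthetic
immune progenitor via a layer of cluster-head children; survival times are
exponential with hazard $h_0 \cdot \mathrm{HR}^{\mathbf 1(x > \tilde x)}$
($h_0 = 0.05$/month, HR = 2) and independent uniform censoring whose upper
bound is solved numerically to hit the 30% target rate.

Everything is reproducible from `(spec, seed)`; the three generators use
the derived sub-seeds `seed + 1` (expression), `seed + 2` (ontology) and
`seed + 3` (survival), so any artifact can be regenerated independently.
The generator never calls the GSR scoring code, keeping generator and
pipeline adversarially independent.

What the generator does **not** emulate: platform/batch effects, probe-level
noise, correlated genes shared between sets, non-Gaussian heavy tails, or
confounded cellular composition. Passing the planted-recovery tests
therefore shows the machinery is correct and calibrated under the model's
own assumptions — not that real tumor-versus-normal compendia are free of
the usual caveats (set overlap inflating false positives, mixture-of-cell
effects, undetected expression leaving ranks unchanged).

## Problem sizes and verification

The test suite and the acceptance script work at desk scale, chosen to
exercise every code path with tight statistical checks: 200 sets ×
60 samples for recovery (20 replicates; sensitivity ≥ 0.90, empirical FDR
≤ 0.10 at q < 0.05) and calibration (50 null replicates; raw p < 0.05 rate
in [0.03, 0.07]); 100 random DAGs (≤ 50 nodes) against a matrix-power
closure oracle; 200 random sets against an all-pairs GSR enumeration
oracle; 20 replicates of n = 300 survival cohorts for HR = 2 recovery.
Exact oracles are compared exactly; stochastic checks use the stated
bands. Counts reported by real-data analyses of this design (thousands of
GO sets, hundreds of immune offspring) depend on the specific MSigDB/GO
releases and expression compendia and are treated as version-dependent
integration facts, not test targets.

## Known limitations

* Pooled-control templates assume the control compendium is homogeneous
  enough for a single majority ordering; strongly stratified controls
  would argue for per-stratum templates (not implemented).
* GSR is blind to expression changes that do not alter within-set
  orderings, and duplicated genes across sets induce dependence between
  term tests that BH within-family correction does not remove.
* The feature filter occasionally applied before classification upstream
  of this package had no stated rule; `feature_filter` (top-N by variance)
  is provided but off by default rather than guessing.
* The cutoff scan's minimum p is reported as-is (with the scan size);
  no scan-wise multiplicity correction is applied, mirroring the common
  web-tool procedure it reproduces.
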