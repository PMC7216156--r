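# gsrome

Rank-based profiling of dysregulated biological functions from gene
expression data, for transcriptomics analysts who want to compare disease
and control cohorts at the level of GO-defined *functions* rather than
individual genes — e.g. locating which immune processes deteriorate as a
carcinoma progresses from early to advanced stage.

## The statistic at the core

For a gene set with $m$ measured genes, a **rank template** learned from
control samples records, for each of the $\binom{m}{2}$ gene pairs
$(i,j)$, whether the majority of controls express gene $i$ below gene $j$
($d_{ij} \in \{0,1\}$). The **gene set regularity (GSR) index** of a
sample is its fraction of concordant pairs,

$$\mathrm{GSR} = \tbinom{m}{2}^{-1} \textstyle\sum_{i<j}
  \mathbf{1}\left[\mathbf{1}(x_i < x_j) = d_{ij}\right] \in [0,1],$$

with 1 = the sample's within-set ordering matches the most common control
ordering, 0 = every pairwise ordering reversed (the most dysregulated
state). A rank-matching index in the DIRAC family, it depends only on
orderings and is therefore invariant to any strictly increasing transform
of a sample's values. The samples × sets matrix of GSR indices is the
**functionome**; restricted to GO offspring of immune ancestor terms
("immune system process", "inflammatory response") it is the
**immunofunctionome**.

On top of this the package provides: Mann–Whitney + Benjamini–Hochberg
screening of dysregulated terms per disease-stage group; cluster weight
index (CWI) ranking — each GO-subtree cluster's share of the summed
$-\log p$ evidence; top-k cross-group intersection with Venn region
counts; linear-SVM cross-validation of functionome informativeness;
immune-list-filtered differentially expressed genes; and a KM-plotter
style survival cutoff scan between the expression quartiles with log-rank
tests and Peto hazard ratios. A synthetic study generator with planted
ground truth (reversed gene orderings, a two-progenitor ontology,
expression-linked survival) makes the whole pipeline testable offline.

## Worked example

```r
library(gsrome)

spec  <- synthetic_spec(n_sets = 100, n_dysregulated = 10,
                        n_controls = 20, n_cases = c(early = 20, advanced = 20),
                        immune_fraction = 0.3)
study <- simulate_gsr_study(spec, seed = 1)

f  <- functionome(study$expression, study$groups, study$sets)
fi <- extract_immunofunctionome(f, study$ontology, study$mapping,
                                study$roots["immune"])
print(fi)
#> Functionome: 60 samples x 30 gene sets (0 dropped)
#> Mean GSR by group:
#> advanced  control    early
#>   0.9133   0.9752   0.9124
```

Controls self-fit near 1; both case groups sit visibly lower because 10
planted sets had their orderings reversed. The group summary makes the
comparison formal (per-group mean/SD of immunofunctionome GSR indices and
a Mann–Whitney p against controls):

```r
summary(fi)
#>      group  n case_mean  case_sd control_mean control_sd corrected_mean        p
#> 1    early 20    0.9124   0.2417       0.9752     0.0374         0.9124  6.8e-08
#> 2 advanced 20    0.9133   0.2417       0.9752     0.0374         0.9133  6.8e-08
```

Term-level screening recovers exactly the planted immune sets
(BH q < 0.05):

```r
tt <- test_all_terms(fi)
tt[tt$significant, c("set_name", "group", "case_mean", "control_mean", "q")]
#>             set_name    group case_mean control_mean        q
#> 12 GO_SYNTH_SET_0037    early    0.0232       0.9857  4.1e-07
#> 14 GO_SYNTH_SET_0048    early    0.0143       0.9750  4.1e-07
#> 42 GO_SYNTH_SET_0037 advanced    0.0232       0.9857  4.2e-07
#> 44 GO_SYNTH_SET_0048 advanced    0.0161       0.9750  4.2e-07
```

(`GO_SYNTH_SET_0037` and `0048` are precisely the planted dysregulated
sets under the immune root: `study$truth`.) Survival follow-up for the
planted outcome-linked gene scans all cutoffs between the quartiles:

```r
sv <- study$survival
x  <- study$expression[study$truth$linked_gene, sv$sample_id]
best_cutoff_scan(x, sv$time, sv$event, gene = study$truth$linked_gene)
#> G00089 [PFS]: cutoff 6.954 (n_low 15 / n_high 25, scanned 21)
#>   log-rank p = 0.0882, HR = 1.983 (0.903-4.357)
```

The Peto HR ≈ 2 matches the generator's true hazard ratio; the reported
scan size (21 candidate cutoffs) is a reminder that the minimum-p cutoff
is anti-conservative. `run_pipeline(pipeline_config(...))` chains all
stages — ingest, functionome, immunofunctionome, classification, term
tests, CWI ranking, top-k cross-comparison, immune DEGs, survival scan —
writing one plain TSV/JSON artifact per stage plus a manifest
(`inst/scripts/run-pipeline.R` is a shell wrapper over the same call).

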