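---
title: "Predicting per-cell drug sensitivity from transcriptomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting per-cell drug sensitivity from transcriptomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Tumours are pharmacologically heterogeneous: transcriptionally distinct
subpopulations of cells within one sample can respond differently to the
same compound, and bulk assays average this structure away. `scdrugsea`
predicts drug sensitivity one cell at a time, by transferring knowledge
from large pharmacogenomic screens (hundreds of cell lines with both
bulk RNA-seq and dose–response viability measurements) onto single-cell
transcriptomes.

The transfer works in two stages.

**Stage 1 — GPDS construction.** For each drug we build a Genomic
Profile of Drug Sensitivity (GPDS): every gene in the expression matrix
is scored by the Pearson correlation coefficient $r_g$ between its
log10(CPM + 1) expression and the drug's potency (area under the
dose–response curve, AUC) across the cell lines where the drug was
measured. Because a *low* AUC means the drug inhibits growth (the line
is sensitive), genes with $r_g > 0$ are resistance biomarkers and genes
with $r_g < 0$ are sensitivity biomarkers. Sorting by $r_g$ gives a
ranked list with resistance biomarkers at the top and sensitivity
biomarkers at the bottom.

**Stage 2 — per-cell enrichment.** Each cell is reduced to its most
*relevant* genes by gf-icf (gene frequency – inverse cell frequency), a
TF-IDF-style score
$s(g, c) = \frac{n_{gc}}{N_c}\,\ln\frac{n}{n_g}$,
where $n_{gc}$ is the UMI count of gene $g$ in cell $c$, $N_c$ the
cell's total, $n$ the number of cells and $n_g$ the number of cells in
which $g$ is detected. The cell's top $N$ genes (default $N = 500$) are
then tested for enrichment against every GPDS with the classic weighted
Kolmogorov–Smirnov running sum (pre-ranked GSEA): walking the ranked
list, a hit increments the sum by $|r_g|^p / \sum_{hits}|r|^p$
(default exponent $p = 1$), a miss decrements it by $1/(L - k)$, and
the enrichment score ES is the signed maximum deviation. A positive ES
means the cell's relevant genes concentrate among resistance
biomarkers (predicted tolerant); a negative ES predicts sensitivity.

Monte-Carlo p-values (random same-size gene sets from the universe) are
corrected per drug across cells with Benjamini–Hochberg, and the
cell × drug matrix $E$ keeps the ES wherever FDR < 0.1 and is 0
elsewhere — 0 is the explicit "no supporting evidence" state.

Downstream, the package aggregates cells to populations (median ES,
fraction of significant sensitive calls), evaluates predictions against
a viability gold standard (the 5% lowest z-scored AUCs per drug),
reconstructs a binarized therapeutic landscape (fractions ≥ 0.9 →
1, Jaccard-distance hierarchical clustering of lines and drugs), embeds
cells by their predicted response profiles (Fuzzy Jaccard Distance),
and tests differential sensitivity between subpopulations
(Mann–Whitney + BH, with a specificity rule).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_lines` | 100 | lines with measured potency required per drug; screens below this give unstable correlations |
| `entropy_percentile` | 0.05 | genes whose 10-bin expression entropy is in this lower tail are discarded as uninformative |
| `min_umi` / `max_mito_frac` | 5000 / 0.10 | single-cell QC: total UMI at least 5000 (inclusive) and mitochondrial fraction strictly below 10% |
| `N` (top relevant genes) | 500 | the GSEA query size per cell |
| `weight_exponent` | 1 | 1 = canonical weighted GSEA with the GPDS correlation magnitude as gene statistic; 0 = unweighted KS |
| `fdr_threshold` | 0.1 | significance cutoff (strict `<`) for a prediction to enter `E` |
| `sens_threshold` | 0.9 | landscape binarization, inclusive at 0.9 |
| `percentile` (gold standard) | 0.05 | z-score tail defining "sensitive" line/drug pairs |

Significance rules: the landscape intentionally uses the raw
`p < 0.05` rule for counting sensitive cells, everything else the
per-drug `FDR < 0.1` rule; both are exposed because both are needed in
practice, and `percent_sensitive()` forces the caller to pick one.

## Numerical and procedural choices

* **CPM, not TMM.** Bulk counts are normalized by plain library-size
  CPM. TMM-style scaling (edgeR) changes per-line scale factors only
  mildly, and the method consumes only correlations of logged values;
  users with TMM-normalized matrices can pass them directly to
  `bulk_expression()`.
* **Entropy bins.** The expression entropy of a gene is computed from a
  10-bin equal-width histogram over that gene's own range (per-gene
  bins; the global-bin alternative is not distinguishable from the
  method description, and per-gene bins make the score scale-free).
  All-zero genes are removed before the entropy step. With
  `entropy_percentile = 0` the entropy step is skipped entirely —
  the quantile at 0 is the minimum and the threshold is inclusive, so
  applying it would always remove the lowest-entropy gene.
* **Zero-variance genes** have undefined Pearson correlation and get
  $r = 0$; ties in $r$ are broken by lexicographic gene id so rankings
  are reproducible.
* **gf-icf variant.** ICF uses the natural log without smoothing:
  genes detected in *every* cell get ICF = 0 and can never be
  "relevant". This is the canonical TF-IDF convention; a smoothed
  variant (`icf_smooth = 1`) is available and documented because the
  upstream implementations differ in this detail.
* **ES tie rule.** When the running sum's positive and negative
  extrema tie in magnitude (this happens for symmetric hit
  configurations), the positive extremum is returned; the comparison
  uses a 1e-9 tolerance so the outcome is not decided by accumulated
  floating-point rounding. The C++ kernel, the plain-R reference and
  the brute-force test oracle all apply the identical rule.
* **p-values.** Plain adaptive Monte-Carlo over random same-size gene
  sets, estimator $(x+1)/(n+1)$, one-sided in the observed sign,
  doubled and capped at 1; sampling stops early once the tail count
  reaches `early_stop_tail`, which only abandons pairs that are
  already clearly non-significant. The adaptive multilevel-split
  estimators found in fast GSEA libraries are *not* reimplemented;
  instead an exact full-enumeration backend (`method = "exact"`)
  provides ground truth for small universes and serves as the oracle
  in the test suite.
* **Mann–Whitney.** Exact enumeration of all labelings for pooled
  sizes ≤ 8 (correct under ties), normal approximation with tie
  correction above; `stats::wilcox.test` cannot enumerate under ties,
  which is why the test is implemented here.
* **Gold-standard quantile** uses the type-7 (linear interpolation)
  convention on z-scores with an inclusive threshold; z-scoring is
  order-preserving, so this equals the same quantile taken on raw AUC.
* **Landscape clustering** uses complete linkage by default (the
  linkage was left open in the method description); the Jaccard
  distance of two all-zero binary profiles is undefined and is treated
  as 0 (identical).
* **Embedding backend.** UMAP on a precomputed distance matrix (e.g.
  via uwot) would be the obvious backend, but it is not part of this
  package's dependency envelope, so `run_drug_reduction()` uses
  non-metric MDS (`vegan::monoMDS`) on the same precomputed distances,
  with classical MDS as an alternative backend. Both honour the
  contract that matters downstream: 2-D coordinates from the FJD
  matrix, deterministic under a fixed seed.
* **FJD is implemented exactly as defined**,
  $\mathrm{FJD}_{x,y} = 1 - \sum_j |\mathrm{sign}(E_{x,j}) +
  \mathrm{sign}(E_{y,j})| / (2m)$. A known consequence: the
  self-distance is $1 - \mathrm{nnz}(x)/m > 0$ whenever a cell has
  zero ("no evidence") entries, so identity of indiscernibles fails in
  the presence of zeros and the "true metric" claim only holds on
  zero-free matrices (where FJD reduces to the Hamming disagreement
  rate; the test suite verifies the metric axioms exhaustively there).
  No normalized variant is silently substituted.

## What the synthetic generator emulates — and what it does not

`generate_pharmacogenomic_fixture()` plants, for each drug, disjoint
sets of biomarker genes whose latent log10 expression follows
`±effect · AUC + N(0, noise_sd)` over AUCs drawn uniformly on [0, 1],
on top of background genes with independent noise; integer counts come
from multinomial sampling of each line's library (1–2 million reads).
Defaults (200 lines, 2000 genes, 20 drugs, 20 biomarkers/drug,
effect 1, noise 0.5) are the stated recovery regime: with them ≥ 90%
of planted biomarkers land in the extreme decile of their GPDS.
Because counts are sampled and log10(CPM + 1) involves rounding, the
noiseless limit reaches $|r| \approx 0.999$, not exactly 1; the tests
assert the extreme ranks and $|r| > 0.99$.

`generate_single_cell_fixture()` gives each subpopulation a program of
GPDS-extreme genes (sensitivity biomarkers for planted-sensitive
populations, resistance biomarkers for tolerant ones). Program genes
are *marker-like*: up-weighted (`signal_strength`, default 5× — a
strong but realistic program shift) in their own population and
down-weighted (factor 0.05) elsewhere. The down-weighting is not
cosmetic: gf-icf assigns zero relevance to genes detected in every
cell, so a ubiquitously expressed program would be invisible to the
method by construction, most visibly at `dropout_rate = 0`. Dropout is
a Bernoulli mask applied to the expected-expression weights *before*
multinomial sampling at the drawn library size (5000–20000 UMI), so
every simulated cell passes QC by construction. A 10-gene `MT-` block
carries ~3% of the library to exercise the mitochondrial filter.

The generator does **not** model empirical zero-inflated negative
binomial noise, batch effects, doublets, or ambient RNA. A green
end-to-end test therefore establishes that the pipeline recovers
planted signal under idealized marker structure — not that it matches
the published performance on real cohorts, which requires the external
datasets and is out of scope here.

## Known limitations

* GPDS quality degrades for drugs measured on few lines; the
  `min_lines = 100` default mirrors the screens this method was
  designed for and should be lowered only deliberately.
* The Monte-Carlo p-value resolution is bounded by `n_perm`; per-drug
  BH across many cells partially compensates, but very small FDRs are
  not meaningful at the default budget.
* The NMDS embedding preserves rank-order dissimilarity, not UMAP's
  local-neighbourhood geometry; cluster separation conclusions
  transfer, exact layouts do not.
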