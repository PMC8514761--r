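# thymoflow

Identification and quantitation of human thymic stromal cell populations
from multi-parameter flow cytometry — with synthetic ground-truth data for
every analysis stage.

## The problem

Thymic epithelial cells (TECs) orchestrate T-cell selection but make up
only ~0.01–0.1 % of a human thymus cell suspension, and EpCAM — the
canonical murine TEC marker — misses human TECs with low surface EpCAM.
This package implements a gating strategy that captures all TECs as
pdpn^high/int^ EpCAM^high/int/low^ (with CD31⁺ lymphatic endothelium
excluded upstream) and splits them into cortical (CD49f⁺CD200⁻) and
medullary (CD49f^low^CD200⁺) subsets, alongside accessory gates for
fibroblasts (CD45⁻EpCAM⁻HLA-DR⁻pdpn^int^), vascular endothelium
(CD45⁻CD31⁺pdpn⁻), lymphatic endothelium (CD45⁻CD31⁺pdpn⁺CD49f^hi^CD200^hi^),
dendritic cells (CD45⁺HLA-DR⁺CD11c⁺CD11b⁺), macrophages
(CD45⁺HLA-DR⁺CD11c⁻CD11b⁺), thymocytes (CD3⁺ and/or CD1a⁺) and mature
single-positive thymocytes (CD3^high^CD1a^int/low^, split CD4SP/CD8SP).

It is intended for cytometrists and computational immunologists who want
this gating scheme as reproducible, scriptable code rather than manual
FlowJo sessions, plus the analytics around it:

* **Gating** — an executable gate tree with automatic, per-sample
  kernel-density threshold placement on asinh-transformed intensities
  (`asinh(x/150)`), and precision/recall/F1 evaluation against ground truth.
* **Marker screen** — per-population MFI, MFI-ratio ranking
  (MFI~A~/MFI~B~, sorted with deterministic tie handling), top-N candidate
  selection with an absolute-MFI floor, and inter-donor reproducibility
  (CV = sd/mean) scoring, as used for 332-marker antibody screens.
* **Cohort quantitation** — per-donor frequencies (percent of total live
  single events), cTEC/mTEC and mature CD4SP/CD8SP ratios, two-sided
  Mann–Whitney group comparisons, OLS correlations (R², F-test p), and
  qPCR relative quantification by 2^−ΔΔCt^ against a reference-gene mean
  and calibrator sample.
* **Exclusive transcripts** — on an FPKM matrix of sorted populations,
  calls a gene expressed at > 0.5 FPKM in ≥ 3/6 (cTEC, mTEC) or ≥ 2/4
  (FB, EC) samples, extracts population-exclusive genes, removes
  housekeeping genes, and tallies tissue-specificity categories from a
  user-supplied annotation table.
* **Synthetic data** — generators for labelled cytometry samples,
  stepwise stromal enrichment (~200-fold TEC enrichment at realistic
  frequencies), screen plates with planted discriminatory markers, FPKM
  matrices with planted exclusive genes, and donor cohorts with a planted
  male-infant cTEC deficit and an inversely coupled CD4/CD8 shift.

File formats: FCS 3.1 (float list-mode, read/write) and CSV for events,
YAML for panels and gate trees, TSV for plates, matrices and reports.

## Worked example

Simulate a 50,000-event sample from the default 12-population mixture, gate
it, and score the recovery:

```r
library(thymoflow)

sim <- simulate_sample(sample_spec(default_population_models(), 50000, seed = 1))
res <- apply_gating(transform_events(sim$table), build_thymic_gating_tree())
res$stats
#>       population        parent count freq_of_parent freq_of_total
#> 1  hematopoietic          root 39498         0.7900        0.7900
#> 2            TEC          root  5059         0.1012        0.1012
#> 3             EC          root  1953         0.0391        0.0391
#> 4            LEC          root   516         0.0103        0.0103
#> 5             FB          root  1990         0.0398        0.0398
#> 6             DC hematopoietic  1512         0.0383        0.0302
#> 7             MP hematopoietic  1461         0.0370        0.0292
#> 8      thymocyte hematopoietic 35511         0.8991        0.7102
#> 9           cTEC           TEC  2056         0.4064        0.0411
#> 10          mTEC           TEC  2998         0.5926        0.0600
#> 11      matureSP     thymocyte  4513         0.1271        0.0903
#> 12         CD4SP      matureSP  2981         0.6605        0.0596
#> 13         CD8SP      matureSP  1532         0.3395        0.0306
```

`count` is the number of events inside each gate, `freq_of_parent` the
fraction of its parent gate, and `freq_of_total` the fraction of all
acquired events — e.g. TECs are 10.1 % of this (stroma-rich, enriched-like)
mixture, 40.6 % of them cortical. Against the simulator's ground-truth
labels:

```r
evaluate_gating(res$assignment, sim$labels)[, c("truth_class", "node", "f1")]
#>           truth_class          node    f1
#> 1                cTEC          cTEC 1.000
#> 2                mTEC          mTEC 1.000
#> 3                  FB            FB 0.999
#> ...                                 (every population >= 0.999)
```

Rank a simulated 332-marker screen plate between the EpCAM-high and
EpCAM-low reference populations (five markers planted at fold 8, five at
fold 0.125):

```r
pl <- simulate_screen_plate(default_screen_spec(seed = 1))
head(rank_markers(pl, "EpCAMhigh", "EpCAMlow"), 5)
#>      marker mfi_a mfi_b  ratio infinite rank
#> M050   M050  7545 747.1 10.099    FALSE    1
#> M200   M200  3558 383.8  9.271    FALSE    2
#> M100   M100  3150 369.9  8.515    FALSE    3
#> M010   M010  2980 358.2  8.320    FALSE    4
#> M300   M300  3148 516.3  6.098    FALSE    5
```

All five planted high-fold markers occupy the top five ranks;
`select_candidates(rk, 30, mfi_floor)` then applies the top-30-per-end rule
with an absolute-MFI floor.

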