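---
title: "Identifying and quantifying human thymic stromal cells: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and quantifying human thymic stromal cells: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymoflow)
```

## The problem

Human thymic epithelial cells (TECs) are rare (on the order of 0.01–0.1 % of
a thymic cell suspension) and, unlike their murine counterparts, cannot be
captured by EpCAM alone: a subset of cytokeratin-positive TECs expresses
very low surface EpCAM. The pipeline in this package implements a
flow-cytometry strategy built around that observation:

* **TEC gate** — podoplanin (pdpn) high/intermediate with *all* EpCAM levels
  admitted; CD31+ (lymphatic) endothelium, which co-expresses pdpn, is
  excluded upstream.
* **cTEC / mTEC split** — CD49f+CD200− for cortical, CD49f-low CD200+ for
  medullary TECs. Events high for both markers match the lymphatic
  endothelial phenotype (CD49f-hi CD200-hi CD31+ pdpn+) and are deliberately
  assigned to neither subset.
* **Accessory gates** — vascular endothelium (CD45−CD31+pdpn−), lymphatic
  endothelium (CD45−CD31+pdpn+CD49f-hi CD200-hi), fibroblasts
  (CD45−EpCAM−HLA-DR−pdpn-int), dendritic cells (CD45+HLA-DR+CD11c+CD11b+),
  macrophages (CD45+HLA-DR+CD11c−CD11b+), thymocytes (CD3+ and/or CD1a+),
  mature single-positives (CD3-high CD1a-int/low) split into CD4SP/CD8SP.
* CD45 is dispensable for the TEC path itself and is only used in the
  accessory gates.

Around the gating core sit three analysis stages: MFI-ratio ranking for
antibody screens, cohort-level quantitation (group comparisons,
correlations, 2^−ΔΔCt qPCR quantification), and a population-exclusive
transcript filter for FPKM matrices. Every stage has a synthetic-data
generator with known ground truth, so the full pipeline is testable without
tissue or sequencing data.

## Intensity model and transform

Gating operates on asinh-transformed intensities, `asinh(x / c)` with
cofactor `c = 150` (arbitrary fluorescence units). The cofactor is a
convention for conventional-cytometer ranges, not a measured value: it sets
the scale below which the transform is effectively linear (autofluorescence
and negatives) and above which it is logarithmic. Screen MFIs, by contrast,
are always computed on the **raw** scale, because MFI ratios are reported on
instrument scale; the default statistic is the arithmetic mean (the
expansion of "mean fluorescence intensity"), with median and geometric mean
available for robustness checks. Negative raw intensities are clipped to 0
on read with a counted warning, since the ratio statistics downstream assume
non-negative signals.

## Automatic threshold placement

The published gates are drawn manually; automatic placement is this
package's own construction. Each gate clause is fitted on its *node scope* —
the events passing all ancestor gates — mirroring how a manual gater draws
each gate inside its parent. Three kernel-density-based placements cover the
scheme (plus `quantile(q)` and `fixed(v)`):

* `valley` — the KDE minimum between the two largest density modes. Used for
  markers that are bimodal within their scope (CD45, CD31, CD200, CD49f and
  CD3/CD1a inside the thymocyte gate).
* `valley_pos` — the KDE minimum between the two *lowest-lying* modes, i.e.
  the negative/positive boundary of a multimodal marker. Used where "any
  positivity" is meant (CD3/CD1a for the thymocyte gate, EpCAM and HLA-DR
  negativity for fibroblasts).
* `valley_hi` — a positivity cut first, then the valley separating the
  dimmest positive mode from the dominant brighter mode. This is the upper
  of the "up to two thresholds" a tri-level marker needs: on pdpn it places
  the boundary between the fibroblast (intermediate) and TEC (high) modes,
  which is exactly the boundary the published scheme leaves unspecified.

The simple "two largest modes" rule alone would be ambiguous on pdpn, whose
distribution has a dominant negative mode plus intermediate (fibroblast) and
high (TEC) modes; the staged variants make the intended cut deterministic.
Mode detection keeps local maxima of a 512-point Gaussian KDE whose height
is at least 1 % of the global maximum; valley placement on effectively
unimodal data falls back to the 0.99 quantile with a warning, and fitting a
scope with fewer than 50 events is an error naming the node. Sibling gates
that cut the same marker with the same method in the same scope receive
bit-identical thresholds, which makes complementary gates (cTEC vs mTEC)
exactly disjoint. Events exactly on a cut follow the clause operator;
positive gates default to `>=`, so a tied event goes to the positive side.
Thresholds are fitted per sample by default (matching per-donor manual
practice); fixed cohort-wide thresholds can be supplied as overrides.

Assignment is "deepest gate wins": an event is labelled with the deepest
node whose full ancestor chain it satisfies, `ungated` otherwise. If an
event ever satisfied two branches at equal depth, the first-declared branch
wins; with the default tree and phenotypes this does not occur.

## What the synthetic data emulates — and what it does not

`simulate_sample()` draws each event's population from the mixture weights
and its intensities i.i.d. log-normal per marker per population. Phenotype
levels (neg/low/int/high ≈ raw medians 50 / 300 / 1 500–2 000 / 12 000–25 000)
are spaced so that every *decision boundary* used by the default tree is at
least 3 standard deviations wide in asinh space at the default `sigma =
0.35`; the dimmest boundary (negative vs low) is ~3.2 sd, all others ≥ 5 sd.
An optional `truncate_sigma` bounds the draws; validation uses `sigma =
0.15` with 3-sigma truncation to build samples with strictly zero
between-population overlap, for which gate recovery must be *exact*.

The generator deliberately omits doublets, debris, dead cells (inputs are
assumed pre-cleaned live singlets), spectral spillover, acquisition drift,
and the skewed/heavy-tailed populations real cytometry shows. Passing tests
therefore demonstrate that the gating logic is correct *given* unimodal
log-normal populations with resolvable modes — not that the thresholds
would land correctly on arbitrary real data, where manual review of the
fitted cuts remains advisable.

`simulate_enrichment()` models stepwise stromal enrichment (density gradient
plus CD45 depletion) as class-specific Bernoulli retention; with the default
retentions (CD45+ 0.004, CD45− 0.9) and realistic TEC frequencies the
expected TEC enrichment is on the order of 200-fold, and the closed form
`p' = p r_s / Σ p_i r_i` is exact in expectation. Intensities of retained
events are untouched.

`simulate_screen_plate()` gives every marker a log-normal baseline MFI
shared across reference populations, multiplied by planted fold changes and
mean-one log-normal well noise. `simulate_expression_matrix()` plants
population-exclusive genes, ubiquitous housekeeping genes, shared-on genes
(always in ≥ 2 populations, so they can never be accidentally exclusive)
and silent background bounded below the calling threshold; per-sample
dropout can push an "on" observation into the background range.

## Cohort model

`simulate_cohort()` draws per-donor age group, sex and log-normal
frequency noise around baselines that default to the reported cohort
medians: TEC 0.067 % in the 0–3-month group, scaled by 0.033/0.067 and
0.016/0.067 for the older bins; MP 0.044 %, DC 0.057 %, FB 0.06 %, EC
0.061 %, LEC 0.0013 %. The cTEC/mTEC split of the TEC baseline is 50:50.
Two effects are planted:

* male donors in the 0–3-month bin have their cTEC frequency multiplied by
  `male_0_3m_ctec_multiplier` (default 0.5), producing the decreased
  cTEC/mTEC ratio;
* the CD8 share of mature single-positive thymocytes follows
  `plogis(qlogis(1/3) + slope · log(cTEC/mTEC))` with a positive slope, so
  the mature CD4/CD8 ratio is inversely coupled to the cTEC/mTEC ratio. The
  logistic link is this package's choice — only a correlation is reported,
  not a functional form.

Only medians are published, not inter-donor dispersion, so `donor_cv = 0.5`
is a modelling default (effect-recovery validation uses 0.2, the value its
property states). Because the donor noise is applied independently to cTEC
and mTEC, the ratio's CV is √2 times the per-population CV. A finite
acquisition can be emulated by multinomial counting at `n_events` per donor
(default 5 × 10⁵); the ground-truth cohort table is returned alongside and
is what the effect-recovery property evaluates, since gating thousands of
full event tables is outside any reasonable validation budget.

Age bins use month = 30.44 days. The significance test for group
comparisons is the two-sided Mann–Whitney test — exact when both groups have
≤ 8 observations and no ties, the tie-corrected normal approximation
otherwise. The original analysis does not name its test, so exact p-value
agreement with the published figures is not expected; Mann–Whitney was
chosen for robustness to the strongly skewed frequency distributions.
Benjamini–Hochberg adjustment is available via `p.adjust` on the emitted
family but off by default, matching single planned comparisons.

## Exclusive-transcript filter

A gene is *expressed* in a population when strictly more than 0.5 FPKM is
observed in at least 3 of 6 samples (cTEC, mTEC) or 2 of 4 (FB, EC); it is
*exclusive* when expressed in exactly one population. The strict `>` follows
the printed rule; a flag switches to `>=` for sensitivity analysis. Whether
housekeeping exclusion preceded or followed the exclusivity step is
ambiguous in the source; the default order here is mask → exclusivity →
housekeeping removal, with `housekeeping_first = TRUE` available. Both the
housekeeping list and the tissue-specificity annotation are user-supplied
tables (gene, category, tissue) rather than live database dependencies,
because the published counts depend on a specific protein-atlas snapshot
that cannot be pinned; gene identifiers are treated as opaque,
case-sensitive strings.

## Numerical and validation choices

* All generators restore the caller's RNG state and are bit-reproducible
  given their seed.
* The FCS 3.1 reader/writer covers the primary TEXT and DATA segments with
  `$DATATYPE F` (single-precision float) list-mode data only; spillover
  keywords are ignored, and round-trip equality holds to float32 precision.
  CSV files carry the transform state in a leading `#` comment line.
* Degenerate inputs: empty event tables gate to all-zero counts with an
  emptiness flag; an empty gate selection is an error for MFI computation
  (no silent NaN); a zero mTEC count flags the donor's ratio as undefined
  while keeping the row for frequency analyses; a zero screen denominator
  yields an ordinal +Inf ratio (flagged) and double-zero wells are excluded.
* Validation problem sizes, chosen to make every stochastic property
  decisive at interactive runtimes: 100,000-event samples for gate recovery
  (each of the 12 populations ≥ 200 events), 10 plates × 332 markers for
  screen capture, 100 replicate 31-donor cohorts for effect detection
  (measured true detection rate ≈ 0.85 under the stated conditions), and
  20 replicate 2,000-gene × 20-sample matrices for the exclusive filter.

## Known limitations

Axis-aligned rectangular gates only (the published scheme needs nothing
more); no compensation/spillover handling, logicle/biexponential
transforms, GatingML interchange, or clustering-based discovery. The
automatic thresholds assume resolvable KDE modes; sparse scopes fall back
to quantile cuts with warnings rather than failing silently. The screen
module stops at ranked candidates plus reproducibility CVs — the published
follow-up steps (visual inspection of subpopulation uniformity, exclusion
of glycolipid epitopes) are judgement calls that are not algorithmized.
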