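---
title: "Methods: dual-luciferase screen analysis, evidence integration and validation assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-luciferase screen analysis, evidence integration and validation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wntscreen)
```

# The measurement model

A dual-luciferase reporter screen reads out a pathway-responsive firefly
luciferase and a constitutively expressed *Renilla* luciferase from the same
well. Both channels are multiplied by the same nuisance factors — how many
cells are in the well, how well they were transfected — while only the
firefly channel carries the biological signal. The package's entire screen
model is therefore built on the per-well ratio $F_i/R_i$, which cancels the
shared factors exactly. The synthetic generator encodes this explicitly:

$$F = F_0 \cdot 2^{\beta} \cdot c \cdot \epsilon_F,\qquad
  R = R_0 \cdot c \cdot \epsilon_R,$$

where $\beta$ is the planted log2 knockdown effect (0 for non-regulators and
negative controls), $c$ is a shared log-normal "cell number" factor and
$\epsilon_F,\epsilon_R$ are independent log-normal channel noises. In the
ratio, $c$ drops out; this is precisely the rationale for Renilla
normalization, and a unit test verifies that inflating the cell-number CV
leaves the ratio's spread unchanged.

Plate effects dominate high-throughput screening noise, so every quantity is
plate-matched: a pool's wells are referenced to the negative-control median
of the plate they sit on, never to a global median. Cross-plate control
pooling is deliberately not a default.

## Pool summaries

For each siRNA pool, with plate-normalized ratios
$z_{ij} = (F_{ij}/R_{ij}) / \tilde{m}_{p(ij)}$ (where $\tilde m_p$ is plate
$p$'s negative-control median ratio):

* **Effect**: `percent_of_control` $= 100\cdot\mathrm{median}_j(z_{ij})$,
  and `log2_effect` its log2. "Two-fold" maps to $|\text{log2 effect}|\ge 1$.
* **Significance**: a two-group test of $\log_2 z_{ij}$ against the
  plate-normalized control log2 ratios of the same plates.

### Choice of the default test

The default is the pooled-variance (Student) unpaired two-tailed t-test,
with Welch and an exact/Monte-Carlo permutation test available via `test=`.
This was a genuinely open design point, and the decision is driven by the
replicate structure of the data: with the field-typical 3 replicate wells
per pool, Welch's degrees of freedom collapse to ~2 and its detection power
for a 4-fold effect at $\alpha = 0.01$ drops to roughly 75%, whereas the
pooled test borrows the (well-estimated) control variance and detects the
same effect essentially always, at a negligible joint false-positive rate
(the fold filter already removes nearly all null pools). Pooled variance is
also the assay convention — the validation assays in this workflow
("unpaired, two-tailed t-test") use it — and the homoscedasticity assumption
is reasonable here because pool and control wells share the same noise
process on the same plate. Users with strongly heteroscedastic data should
pass `test = "welch"`; small-sample purists can pay the granularity price of
`test = "permutation"`.

### Degenerate inputs

To keep p-values total and `NaN`-free: if every observation in both groups
is identical the groups are indistinguishable and $p = 1$; if both groups
have zero variance but different means, $p$ is the smallest positive double.
Zero-Renilla wells are flagged and excluded at parse time (never divided);
pools with no usable wells keep a row with `NA` p-value and a warning.

## Hit calling

A pool is a hit iff it passes **both** thresholds: at least
`fold_threshold`-fold change in either direction (boundary inclusive, so
exactly 2-fold passes) and $p < \alpha$ (strict, so $p = \alpha$ fails). A
gene is a consensus hit iff *every* pool targeting it is a hit. Direction
agreement across a gene's pools is recorded (`direction_mix`) but not
required by default, because the magnitude-and-significance rule is the
published convention; `require_direction_consensus = TRUE` tightens it, and
a property test verifies this can only shrink the hit set. Raw p-values are
the default (matching the workflow being reproduced); Benjamini–Hochberg is
available via `adjust = "BH"` for reuse beyond reproduction.

# Evidence integration

Symbols are the join key (evidence lists are symbol-based); harmonization
uppercases, trims, alias-resolves and deduplicates, keeping unresolvable
entries verbatim so nothing silently disappears. The disease-gene query runs
against a serialized JSON-lines gene-record dump rather than a live
database: published match counts (e.g. "745 disease-associated genes")
depend on the database snapshot of the day and are not reproducible from a
live query, so the package treats the dump as the citable input. Whole-word
matching is the default — "melanoma" should not match "melanomagenesis" —
with substring mode available.

`venn3()` reports *both* the seven exclusive regions and the three pairwise
totals, because published overlap figures are often ambiguous about which
they print; the identity pairwise = exclusive-pair + triple is asserted
property-style on every input.

# AP-MS background subtraction

Subtraction is presence/absence by prey label against the control-prey and
contaminant lists, as in classic AP-MS practice when no quantitative control
model is fitted; no spectral-count ratio filtering is applied by default (a
`min_count` option exists). Every input row is preserved with a
`removal_reason`, subtraction is idempotent, and a bait recovered as its own
prey is retained and tagged as the purification's positive control.

# Validation assays

* **Reporter**: per-replicate $F/R$ ratios; group mean, SEM, and the
  unpaired two-tailed t-test (Student default, as above).
* **qPCR**: $\Delta Ct = Ct_{target} - Ct_{reference}$ per sample;
  $\Delta\Delta Ct$ against the calibrator condition's mean;
  $RQ = E^{-\Delta\Delta Ct}$ with amplification efficiency $E = 2$ by
  default (uncalibrated SYBR assays assume perfect doubling; `efficiency`
  is exposed). Adding a constant to every Ct leaves RQ unchanged.
* **TUNEL**: percent positive $= 100\sum t_f / \sum d_f$, counts summed
  across fields *before* dividing. Mean-of-field-percentages would weight a
  10-cell field like a 1000-cell field; the summed form is invariant to how
  the same cells are partitioned into fields.
* **Densitometry**: band density / loading-control density, scaled to the
  maximum condition (= 100); invariant to rescaling all loading densities.

# The synthetic world

Defaults are fixed once and state a realistic desk-scale screen: 500 genes,
1 pool/gene, 3 replicate wells per pool, 384-well plates with 16 negative
controls each (the screening-scale format is 1536-well; set
`wells_per_plate = 1536` to emulate it), 10% true regulators with
$|\beta| \sim U(1,3)$ and random sign, channel and cell-number CVs of 0.2,
baselines of 1000 RLU. Replicates are laid out as plate copies, each with
its own controls — the layout real screens use. Assay generators default to
6 replicates, 0.15-cycle Ct scatter, 5 microscopy fields of ~200 nuclei,
and effect sizes typical of the validated biology (4-fold target induction,
2% vs 20% apoptosis rates).

What a green recovery test establishes: that the pipeline detects planted
multiplicative knockdown effects of the stated size under log-normal well
noise with plate-matched controls. What it does not establish: robustness
to spatial plate artifacts (edge effects), siRNA off-target structure,
non-log-normal outliers, or control reagents with real residual activity —
none of which the generator emulates.

All generators are pure functions of (config, seed): they restore the
caller's RNG state, identical seeds give byte-identical outputs, and the
pipeline derives fixed per-stage seed offsets from one master seed so one
stage's configuration never perturbs another stage's draws.

# Numerical and procedural choices

* Volcano tables sort by ascending p with a stable lexicographic `pool_id`
  tie-break; all set operations and exports are sorted, making every stage
  invariant to input row order and reports byte-identical across reruns.
* The exact permutation test enumerates group assignments when
  $\binom{n}{n_1}$ is within budget, otherwise Monte-Carlo with an
  add-one-count correction so $p > 0$. Its two-sided granularity floor
  ($2/\binom{n}{n_1}$) bounds how closely any t-test can agree with it at
  tiny $n$ — the oracle-agreement tests are phrased accordingly.
* A deliberately synthetic stand-in (`synthetic_fam129b_example()`)
  reproduces the published three-way overlap structure (17/1/119 pairwise,
  one triple-overlap gene, 18 retained AP-MS preys including KEAP1) with
  placeholder symbols, so the integration code paths can be exercised
  end-to-end offline. It is not the original supplementary data, and the
  original per-pool screen counts (10,215 regulating pools, 5,189 consensus
  genes) can only be recomputed from those download-only files.

# Known limitations

No B-score or spatial plate-effect correction (the simulator does not plant
spatial artifacts either); no SAINT/CompPASS-style probabilistic AP-MS
scoring; no qPCR efficiency calibration from dilution series; no
dose–response curve fitting. Gene-set enrichment statistics for the overlaps
are intentionally absent: the integration reports counts, not hypergeometric
p-values, mirroring the workflow it reproduces.
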