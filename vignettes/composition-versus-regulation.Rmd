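---
title: "Composition versus regulation: attributing bulk CNS expression changes to cell types"
author: "triCell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition versus regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triCell)
```

# The problem

Differential expression measured in bulk central-nervous-system tissue
confounds two biologically distinct processes. A gene's bulk abundance is
a proportion-weighted mixture over cell types,

$$ E[\text{bulk}_g] \;\propto\; \sum_c \pi_c\, \theta_{gc}, $$

where $\pi_c$ is the tissue fraction of cell type $c$ and $\theta_{gc}$
the gene's expression within that type. A treatment or disease contrast
can therefore change bulk abundance by changing $\theta$ (transcriptional
regulation within a cell type) or by changing $\pi$ (gliosis, microglial
proliferation, neuronal loss) with every $\theta$ untouched. The two are
indistinguishable from bulk data alone: a microglia-specific gene doubles
in bulk tissue whenever the microglial fraction doubles.

triCell implements the analysis framework that separates the two using
sorted-cell reference profiles for microglia, astrocytes and neurons
measured alongside the bulk samples: nRPKM normalization, marker-gene
specificity scoring, ternary-simplex attribution of bulk changes,
composition/regulation classification against the sorted contrasts,
fold-change distribution-shift diagnostics, differential splice-variant
usage, and qPCR ΔΔCt validation — together with a negative binomial
simulator that generates all of these data types with ground truth.

# Normalization: nRPKM

RPKM divides a gene's count by gene length (kb) and by total uniquely
aligned reads (millions). nRPKM replaces the per-sample "M" term with the
*adjusted total*: a quantity proportional to the sample's median-of-ratios
size factor, rescaled so the adjusted totals sum to the observed totals.
Consequences worth knowing:

* For a fixed gene, nRPKM across samples is **exactly proportional to
  count / size factor** (the "normalized count" statistic); the gene
  length and the calibration constant only set the gene-specific scale.
* Size factors are computed with genes having nonzero counts in every
  sample as the reference set, and are anchored to geometric mean 1, so a
  single sample gets factor 1 and nRPKM then equals RPKM.
* The calibration constant $C = \sum_j M_j / \sum_j s_j$ is a free choice
  (any positive constant preserves proportionality); conserving the
  project-wide read total keeps values on a familiar scale. Totals are
  taken from the sample sheet, never recomputed from exonic counts,
  because amplified CNS libraries carry substantial intronic read mass.

Zero counts give zero expression — no pseudocount enters at this stage.
A pseudocount of 1 is applied only at log-transform points (differential
testing, variable-gene selection), bounding fold changes for weakly
expressed genes.

# Differential expression

The attribution machinery consumes a per-gene table of log2 fold change,
p, BH-adjusted p, and a pre-filter flag. Genes with fewer than 10 counts
in fewer than 3 samples are excluded *before* testing: they are reported
with p = 1 and log2 fold change 0 for plotting, and they do not enter the
BH family, so the correction denominator is the number of tested genes.

The default test is a Welch t on log2(size-factor-normalized counts + 1).
This is a deliberate, desk-scale substitute for a negative binomial Wald
GLM: it is deterministic, assumption-light and adequate for pipeline
validation, but it has less power at n = 5 than a dispersion-shrinking
NB engine, and real analyses should import an externally computed table
(`readDeTable()` accepts the same layout) when one is available. The
substitution matters mainly as reduced detection counts; the downstream
classification logic is unchanged.

# Reference profiles, markers, and the ternary simplex

Reference profiles are per-gene mean nRPKM in each of the three sorted
cell types from the control condition. Two derived objects drive the
analysis:

* **Markers** — genes whose pseudocounted reference expression is at
  least 20-fold that of each other type (pseudocount 0.1 nRPKM). For a
  marker, bulk abundance tracks its cell type's tissue fraction, so the
  bulk fold-change distribution of a type's markers, compared against all
  non-marker genes (rank-sum test), diagnoses composition shifts: a
  doubling of the microglial fraction shifts microglial-marker log2 fold
  changes by about +1.
* **Simplex coordinates** — each gene's three-type mean vector normalized
  to sum 1 (the plane $x+y+z=1$) and mapped to the page by
  $\bigl[\begin{smallmatrix}-1&1&0\\0&0&\sqrt3\end{smallmatrix}\bigr]$,
  an equilateral triangle with corners $(-1,0)$, $(1,0)$, $(0,\sqrt3)$
  for the first, second and third listed type. The cell-type order is
  explicit metadata because the projection depends on it; the default is
  (microglia, astrocyte, neuron). Genes with zero expression in all three
  types cannot be placed and are excluded with a recorded reason.

# Attribution and classification

For each bulk gene passing the significance cutoffs (default 2-fold,
adjusted p ≤ 0.05), the simplex fractions become contribution shares and
the gene is assigned to the type holding at least half the total
(`shareCut = 0.5`), otherwise called "mixed". Share ties resolve to the
type with higher absolute reference expression and then to cell-type
order; since shares are normalized this makes the rule deterministic.
The threshold makes testable what is otherwise a visual judgement of
corner proximity.

Classification then consults the assigned type's own sorted-cell
contrast:

| sorted change (same direction, significant) | composition prior on the type | change_mode |
|---|---|---|
| yes | no | regulation |
| yes | yes | both |
| no (not significant) | yes | composition |
| otherwise | | unassigned |

The *composition prior* — whether a cell type's tissue fraction is known
to differ between conditions — is supplied by the caller (histology,
sorting yields) or by simulation truth; the expression data alone cannot
certify an unchanged $\theta$ plus changed $\pi$ without it, so an
unchanged sorted contrast with no prior stays "unassigned" rather than
being over-interpreted. A sorted change significant in the *opposite*
direction also stays unassigned.

# Splicing

Splicing events are sets of (usually two) variants — e.g. the inclusion
and skipping isoforms of a cassette exon. Each variant's per-sample count
is the sum of its 5′ and 3′ feature counts, or the single unique value
when both measure identical features. Its `vfreq` is the share of the
event total (0 = fully skipped, 1 = fully included; undefined at total
0). The filtering cascade is order-dependent and idempotent:

1. keep variants with ≥ 5 counts in ≥ 3 samples of any condition;
2. drop events left with one variant (effectively constitutive);
3. drop retained-intron events (artefact-prone with intron-rich
   libraries);
4. exclude each event's first remaining variant (input order, generally
   the skipping variant) from testing, limiting the number of tests.

BH correction is applied across the variants that are actually tested,
i.e. after step 4. Differential usage is a Welch t on logit(vfreq) with
vfreq clamped to [0.01, 0.99]; this replaces an exon-usage NB GLM with a
replicate-aware test monotone in the same signal, and external per-variant
results can be substituted. At depth 60 and 5 vs 5 the test holds its
nominal size and has essentially full power at a logit shift of 2.

# qPCR ΔΔCt

Technical replicates are averaged omitting fail calls; a sample whose
assay fails on all replicates is imputed at $C_t^{max}+1$, one cycle past
the assay's worst passing value in any sample (across all samples, not
per condition), and flagged — the flag propagates through every derived
quantity. $-\Delta C_t$ subtracts the (averaged) housekeeping $C_t$;
the housekeeping set is configurable — a single loading control (Actb)
for splicing assays, an averaged pair (Gapdh, Rpl37a) for gene-level
work. For splicing, $\Delta\Delta C_t = (-\Delta C_t^{incl}) -
(-\Delta C_t^{skip})$, lower meaning more skipping, tested per cell type
with an equal-variance Student t (the conventional choice for such
designs; Welch is an option), imputed values included, BH within each
cell type's events. For treatment contrasts, ΔΔCt is the group-mean
difference of $-\Delta C_t$, which equals the target's log2 fold change
under amplification efficiency exactly 2 (efficiency is not modelled; it
affects interpretation, not the arithmetic).

# The simulator

`simulationConfig()` fixes the study conditions the package is validated
under; they mirror a sorted-cell CNS study design and are not tuned per
run:

* 2,000 genes; baseline $\theta$ log-normal (meanlog log 10, sdlog 1.5);
  200 markers per type drawn brighter (meanlog log 50, sdlog 1) with
  non-target expression zeroed to a pseudo-floor of 0.05 — markers are
  *pure*, as the marker concept requires; their realized specificity far
  exceeds the 20-fold selection threshold.
* Negative binomial counts with Var $= \mu + \phi\mu^2$, $\phi = 0.1$
  (moderate biological dispersion for inbred animals); library sizes
  log-uniform in [5e5, 2e6] to exercise the size-factor machinery; total
  uniquely aligned reads exceed exonic counts by 1.3× (intron-rich
  amplified libraries).
* n = 5 animals per condition; bulk proportions (microglia, astrocyte,
  neuron) = (0.10, 0.30, 0.60) in control versus (0.20, 0.30, 0.50) in
  disease — the headline composition contrast (microglial proliferation,
  mild relative neuronal dilution, astrocytes unchanged). The regulation
  scenario instead holds π fixed and multiplies 100 random genes by 4 in
  microglia; regulated cells contribute to the bulk mixture too.
* Cassette splicing events: inclusion counts binomial at the event's
  inclusion frequency (uniform in [0.2, 0.8] at baseline), depth 60,
  treated condition shifted on the logit scale; the skipping variant is
  listed first, as in discovery order.
* qPCR: $C_t = a - \log_2 q + \mathcal N(0, \sigma)$ per replicate with
  $a = 35$, $\sigma = 0.15$, fail above $C_t$ 33, three technical
  replicates.

Every generator takes an explicit seed and is fully deterministic given
it. What the simulator does *not* emulate: amplification (e.g. ribosomal
or 3′) bias, batch effects, cell-type contamination of sorted
populations, correlated animal-level responses, or overdispersion of
splicing counts beyond binomial. Passing recovery tests therefore shows
the machinery is correct under its stated model, not that real tissue
meets these assumptions; in particular the contamination-driven sample
exclusions a real study needs are out of scope and left to the caller.

# Numerical choices and degenerate inputs

* Size factors: natural-scale median of ratios (even-sized reference
  sets average the two central ratios arithmetically); anchored to
  geometric mean 1; absence of any gene observed in all samples is an
  error, a single sample returns factor 1.
* Two-group tests fall back to p = 1 (equal means) or p = 0 (unequal)
  when both groups have zero variance, rather than returning NaN.
* Heat-map matrices: log2 values floored at −4 (log2(0) = −∞ included),
  Z-scored per gene within each dataset with the sample (n−1) standard
  deviation, zero-variance rows set to Z = 0, Z above 4 capped at 4.
* Variable-gene selection takes the top ⌈fraction × n⌉ by SD with ties
  broken by gene identifier; probe collapse takes the highest-IQR probe
  (linear-interpolation quantiles) with ties to the lexicographically
  smallest probe id — both fully deterministic.
* Four-way plots: a gene below 1 nRPKM in both conditions of a contrast
  is displayed as unchanged (FC = 1) there; the threshold is a
  conservative background floor, chosen once.
* Attribution of a gene absent from the profile, or expressed in no
  type, is "unassigned"; a missing sorted table for an assigned type
  warns and leaves its genes unassigned.

# Validation scale

The test suite validates parameter recovery at the design scale above
(2,000 genes, 20 simulation seeds per scenario, ~10 s per scenario):
composition-only runs classify ≥ 90% of microglia-attributed significant
bulk genes as composition-driven with a microglial marker shift of
1.0 ± 0.15 log2 units; regulation-only runs classify ≥ 80% of
bulk-detected regulated genes as regulation/both with off-target marker
shifts centred at 0. Splicing power/size and qPCR recovery are validated
over 20 seeds each, and the simplex projection, flooring, BH and
size-factor computations against closed forms and brute-force oracles.

# A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig()
sim <- simulateStudy(cfg, seed = 1)
res <- attributionPipeline(sim$sorted, sim$bulk,
                           control = "control", treated = "disease",
                           compositionTypes = "microglia")
table(res$calls$assigned, res$calls$change_mode)
res$shift
```

# Known limitations

* Exactly three cell types; other populations (endothelia, interneuron
  subtypes) fold into whichever of the three they resemble.
* The composition prior must come from outside the expression data.
* The Welch-t engines trade power for simplicity (see above); absolute
  detection counts are not comparable to NB-GLM analyses.
* nRPKM values are comparable within, not between, normalization groups;
  library chemistry differences shift the M term.
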