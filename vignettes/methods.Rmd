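---
title: "Models and methods behind lungdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lungdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungdx)
```

`lungdx` models the computational chain of a combined DNA-panel / RNA
fusion-assay NSCLC diagnostic service. This vignette documents the
statistical choices, tunable parameters and known limitations; the README
shows the user-facing workflow.

## The probe-count fusion caller

### Normalization

Raw probe counts from one hybridization are processed in two steps.

1. **Background correction.** The negative controls are probes with no
   biological target; their counts estimate nonspecific binding. We
   subtract `mean(neg) + k * sd(neg)` (default `k = 2`, the usual
   "mean plus two standard deviations" convention for this assay family)
   from every non-control probe, flooring at zero. The paper trail for
   this step in the source method names only the step, not the constant;
   `k` is therefore a parameter of `caller_thresholds()`.
2. **Positive-control scaling.** The positive controls are spiked
   synthetic targets at a fixed titration (128 down to 0.125 fM). Each
   profile's non-control counts are multiplied by
   `reference_factor / geomean(pos controls)` (default reference 1000,
   the expected geometric mean of the titration at typical counting
   depth). The geometric mean is robust to a single outlying control,
   and the construction makes every downstream statistic exactly
   invariant under a global multiplicative factor on the raw counts —
   a property the test suite asserts.

### QC failure rule

RNA from formalin-fixed tissue degrades; the symptom is collapsed
housekeeping counts. The QC statistic is the ratio `H / H_i` where `H_i`
is the profile's housekeeping geometric mean (raw counts) and `H` a
reference housekeeping level; a hybridization fails iff the ratio is
**strictly greater than 8**. The exact construction of `H` is a
calibration choice the method literature delegates to reference
hybridizations, so we expose it two ways:

* default: a fixed calibrated level (`reference_hk = 1500` in
  `caller_thresholds()`, the nominal intact-RNA housekeeping geometric
  mean of the shipped probe set) — this detects absolute degradation and
  correctly fails a batch in which *every* profile is degraded;
* `batch_reference_hk()`: the median across the batch of per-profile
  housekeeping geometric means, for labs that prefer a batch-relative
  check (blind to batch-wide degradation by construction).

### Classification

Per gene, the caller computes the 3'/5' imbalance ratio
`(mean 3' + c) / (mean 5' + c)` with pseudocount `c = 1` (avoiding
division by zero when background subtraction empties the 5' side) and
the maximum fusion-specific junction signal (ties broken to the
lexicographically smaller fusion id, so results are order-independent).
The two cuts — `ratio_threshold` (default 2) and
`specific_signal_threshold` (default 50 normalized counts) — partition
the plane into the four quadrants described in the README. Only three
quadrants are interpretable as calls; the upper-left pattern (junction
signal without imbalance) is reported `NEGATIVE` with a
`specific_signal_without_imbalance` flag rather than invented as a
fourth call class. The numeric cut values are laboratory calibration
parameters: the source method publishes them only as plot guide lines,
so the defaults here are chosen to cleanly separate the synthetic
classes and can be overridden globally or per gene (`gene_overrides`).

Joint 3'+5' overexpression — seen in vivo in, e.g., neuroendocrine
tumors with positive ALK IHC but no rearrangement — leaves the ratio
near 1 and is correctly negative; the generator has an explicit mode for
this pattern and the suite asserts the behavior.

## Variant filtering and the rule engine

Retention requires presence in both library pools of the bidirectional
amplicon assay, coverage strictly above 1000×, and VAF at or above 4%.
The boundary conventions (inclusive VAF, strict coverage) mirror how the
two thresholds are stated in the clinical validation they come from: a
*limit of detection of 4%* versus *coverage >1000X*. Rejection reasons
are recorded in the fixed order pool → coverage → VAF.

Protein changes are parsed from a tolerant HGVS-like dialect (one- and
three-letter codes, optional `p.`, deletion/insertion/duplication/
frameshift forms, `exon19del`-style aliases) by a total function —
unparseable input yields class `other`, never an error, because clinical
variant tables mix notations. Actionability rules are data
(`inst/extdata/actionability_rules.yaml`), matched first-rule-wins; the
loader enforces panel membership and per-gene codon-set disjointness so
every variant receives exactly one verdict. Two judgment calls are
exposed as flags: EGFR T790M counts as actionable by default
(`t790m_actionable`), and KRAS counts toward the headline ≥1-actionable
percentage by default (`kras_in_actionable`), with the KRAS-excluded
figure always reported alongside. The PIK3CA rule encodes codons
{542, 545, 1047}; the source listing repeats 1047, which we treat as a
typographical duplication (the rule file carries a comment and accepts
overrides).

## Concordance evaluation

Paired calls agree when both methods give the same mutation/no-mutation
verdict; when both report a mutation, variant identity is compared on
the protein change if both provide one, else on the coding change —
the convention matters because real discordances can hinge on two
methods reporting *different* variants at the same hotspot. Calls where
the panel found a variant at a locus the single-gene reference assay
never interrogates are flagged `in_scope = FALSE`; excluding them
removes them from numerator and denominator. Headline percentages are
rendered to the nearest integer, with one decimal kept internally.

## Stratification

Eligibility categories follow a fixed precedence: `EGFR+` (actionable
EGFR mutation, irrespective of other alterations), then `ALK+` (fusion),
then one per-gene emerging category (RET+/ROS1+ fusions, then BRAF+,
PIK3CA+, ERBB2+, NRAS+, MAP2K1+, AKT1+ mutations), then `KRAS_only`,
then `none` — a partition by construction. The EGFR-before-ALK order for
the rare double-positive is not dictated by the underlying method
description; it is configurable (`precedence`) and defaults to the order
in which standard-therapy categories are conventionally listed. The
variant-count histogram (0 / 1–2 / >2 per sample) uses all retained
non-synonymous variants including non-actionable genes such as TP53.
Samples never assayed for fusions stay in all cohort denominators but
not in fusion-positivity denominators; QC-failed hybridizations count as
tested but not analyzable. Triple-negative status (no retained EGFR,
KRAS or BRAF mutation — the subset forwarded to fusion screening) is a
pure function of the mutation data; fusion results cannot alter it.

## The synthetic-data generator

The generator exists so the pipeline's logic is testable end to end
without patient-level data, which are not publicly available for this
kind of clinical cohort.

* **Counts** are negative-binomial around probe-role-specific means
  (housekeeping 800–3000, endogenous flanks 400, fused 3' flanks 5000,
  junction probes 1200 when the event's fusion is on the panel, positive
  controls 250 counts/fM), times a per-profile lognormal lane factor
  (σ = 0.15) applied to every probe including controls. The NB size
  default of 100 corresponds to ~10% technical CV at high expression,
  consistent with replicate hybridizations of intact RNA. No
  distributional information is published for this assay's counts; this
  model is a documented stand-in, and the means are set so that every
  synthetic class sits at least fivefold from the default thresholds —
  the suite tests classification logic, not borderline calibration.
* **Degradation** multiplies endogenous and housekeeping means by 0.005
  while leaving the spiked controls untouched, so only the housekeeping
  QC ratio — not the positive controls — reveals the failure, as in real
  formalin-degraded samples.
* **Cohorts** draw histology from a configurable mix (default 65/17/15/3%
  adenocarcinoma/SqCC/NSCLC-NOS/other, the approximate composition of a
  consecutive single-region testing year), per-gene mutation presence as
  independent Bernoulli draws, and variant identity from a curated
  catalogue of recurrent panel variants in mixed notation. Ground truth
  (actionability, fusion status, QC failures) is written to a sidecar
  table only, never into primary inputs, and recovery must be exact.
* **Fixture specs.** `prospective_fusion_batch_spec()` encodes the
  screening batch this package's headline figures are computed on: 169
  hybridizations, 34 degraded, ten fusion events (4+1 ALK, 2+1-novel
  RET, 2 ROS1) among 135 analyzable profiles of which the first 67 —
  including all events — are adenocarcinomas.
  `validation_paired_call_spec()` encodes the 92-call validation table
  (29 mutation / 63 no-mutation calls; 4 discordant, 3 of them
  out-of-scope). `cell_line_control_batch_spec()` encodes the four
  fusion-positive control cell lines.

What passing tests on these fixtures shows: the arithmetic, thresholds,
bookkeeping and denominators of the pipeline are correct. What it does
not show: performance on real hybridization noise (correlated probe
effects, partial degradation, borderline tumor content), calibration of
the numeric cuts for a specific lab, or detection limits near 5% tumor
cell content — those require real reference material.

## Problem sizes and determinism

All simulations are seeded and byte-reproducible; identical seeds give
identical tables and different seeds differ. The shipped analyses run at
desk scale — the 169-profile batch, the 92-call validation table,
cohorts of a few hundred samples, a 5000-sample cohort only for the
binomial-convergence check — and the full suite completes in well under
a minute.

## Known limitations

* The caller consumes count tables, not the vendor's binary output, and
  models no probe-sequence thermodynamics.
* Codon numbering is taken at face value from the input notation against
  the canonical protein; no transcript mapping or genomic liftover is
  performed, and exon numbering follows the panel definition verbatim.
* MET exon-14 skipping, copy-number events and resistance mechanisms
  beyond T790M labeling are out of scope.
* The eligibility partition reports one category per sample; co-occurring
  drivers are visible in the co-occurrence matrix, not the pie.
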