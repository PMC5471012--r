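# lungdx

Multiplexed mutation and gene fusion diagnostics for non-small cell lung
cancer (NSCLC) panels.

Modern NSCLC care hinges on finding the driver alteration a tumor carries:
activating EGFR mutations and ALK/RET/ROS1 gene fusions route patients to
targeted inhibitors, KRAS and a tail of rarer oncogene mutations define
emerging-therapy populations. Clinical labs increasingly replace iterative
single-gene assays (real-time PCR, pyrosequencing, IHC/FISH) with one
DNA amplicon panel plus one multiplexed RNA fusion assay. `lungdx`
implements the computational side of that workflow for analysts validating
or operating such a service:

* **RNA probe-count fusion calling** for ALK, RET and ROS1 from
  NanoString-style hybridization counts;
* **panel variant filtering and actionability annotation** for a 26-gene
  exon-focused amplicon panel;
* **concordance accounting** between the panel and legacy single-gene
  assays on a paired validation cohort;
* **cohort stratification** by actionable drivers and treatment
  eligibility;
* a **seeded synthetic-data generator** emulating the statistical
  structure of a one-year consecutive testing cohort, so every stage is
  testable without patient data.

## The fusion caller

Each target gene carries capture/reporter probes 5' and 3' of its
tyrosine-kinase exons plus toehold-style probes spanning known fusion
junctions. After subtracting the negative-control background
(mean + 2·SD) and scaling each profile so its positive-control geometric
mean hits a fixed reference, the caller computes per gene

```
ratio_3'5' = (mean 3'-flank counts + 1) / (mean 5'-flank counts + 1)
specific   = max over the gene's junction probes
```

A rearrangement that puts the kinase domain under a foreign promoter
elevates 3' over 5'; whole-gene overexpression elevates both and leaves
the ratio near 1. On the (ratio, specific) plane:

| quadrant | ratio ≥ cut | specific ≥ cut | call |
|---|---|---|---|
| upper right | yes | yes | `KNOWN_FUSION` (junction identified) |
| lower right | yes | no  | `NOVEL_FUSION` (not covered by a junction probe) |
| lower left  | no  | no  | `NEGATIVE` |
| upper left  | no  | yes | `NEGATIVE`, flagged |

Hybridizations whose housekeeping geometric mean Hᵢ falls more than
8-fold below the calibrated reference H (ratio H/Hᵢ > 8) are QC failures —
the signature of formalin-degraded RNA — and are excluded from every
positivity denominator.

## Variant filtering and actionability

A variant is retained iff it was detected in **both** library pools of the
bidirectional assay, coverage is **> 1000×**, and VAF is **≥ 4%**
(inclusive limit of detection). Retained variants are parsed from
HGVS-like notation (`p.L858R`, `p.Glu746_Ala750del`, `exon19del`, …) and
matched, first rule wins, against a curated YAML rule set: KRAS codons
12/13/61, EGFR exon 19 deletions / exon 20 insertions / T790M / codons
719, 858, 861, BRAF codon 600, PIK3CA codons 542/545/1047, NRAS codons
12/13/61, ERBB2 exon 20 insertions, MAP2K1 codons 56/57, AKT1 L52R, with
ALK/RET/ROS1 fusions handled by the RNA caller.

## Worked example

```r
library(lungdx)

probes <- default_probe_set()
batch  <- generate_nanostring_batch(prospective_fusion_batch_spec(seed = 1), probes)
call_batch(batch$profiles, probes)
#> <fusion_batch> 169 profiles: 34 failed QC (20.1%), 10/135 analyzable positive (7.4%)
#>   gene  n_analyzed n_positive pct_positive
#> 1 ALK          135          5          3.7
#> 2 RET          135          3          2.2
#> 3 ROS1         135          2          1.5

calls <- generate_paired_calls(validation_paired_call_spec(seed = 1))
evaluate_concordance(calls)
#> <concordance_report> 88/92 concordant (96%)
evaluate_concordance(calls, exclude_out_of_scope = TRUE)
#> <concordance_report> 88/89 concordant (99%) after excluding 3 out-of-scope call(s)
```

The batch summary reads: of 169 simulated hybridizations, 34 (20.1%) fail
housekeeping QC (degraded RNA); among the 135 analyzable profiles the
caller finds five ALK, three RET (one via the ratio-only novel-fusion
path) and two ROS1 fusions — 7.4% positivity overall. The concordance
report counts 88 of 92 paired calls agreeing between the panel and prior
single-gene assays (96%), rising to 99% once the three calls at loci the
single-gene assays never interrogate are excluded.

`run_pipeline(list(seed = 1), "out/")` chains simulation, annotation,
fusion calling, concordance and stratification and writes TSV/JSON
artifacts with a provenance manifest.

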