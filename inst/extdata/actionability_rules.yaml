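# Curated actionable-alteration rules for the 26-gene NSCLC panel.
# First matching rule wins; codon sets within one gene must be disjoint.
- id: KRAS_codon_12_13_61
  gene: KRAS
  kind: codon_set
  codons: [12, 13, 61]
  tier: emerging
- id: EGFR_exon19_deletion
  gene: EGFR
  kind: exon_event
  event_exon: 19
  event_class: inframe_del
  tier: standard
- id: EGFR_exon20_insertion
  gene: EGFR
  kind: exon_event
  event_exon: 20
  event_class: inframe_ins
  tier: standard
- id: EGFR_T790M
  gene: EGFR
  kind: named_protein_change
  protein_change: T790M
  tier: standard
- id: EGFR_codon_719_858_861
  gene: EGFR
  kind: codon_set
  codons: [719, 858, 861]
  tier: standard
- id: BRAF_codon_600
  gene: BRAF
  kind: codon_set
  codons: [600]
  tier: emerging
# The fourth listed PIK3CA codon duplicates 1047 in the source material;
# treated as a typographical repetition. Override via a custom rule file
# if another codon was intended.
- id: PIK3CA_codon_542_545_1047
  gene: PIK3CA
  kind: codon_set
  codons: [542, 545, 1047]
  tier: emerging
- id: NRAS_codon_12_13_61
  gene: NRAS
  kind: codon_set
  codons: [12, 13, 61]
  tier: emerging
- id: ERBB2_exon20_insertion
  gene: ERBB2
  kind: exon_event
  event_exon: 20
  event_class: inframe_ins
  tier: emerging
- id: MAP2K1_codon_56_57
  gene: MAP2K1
  kind: codon_set
  codons: [56, 57]
  tier: emerging
- id: AKT1_L52R
  gene: AKT1
  kind: named_protein_change
  protein_change: L52R
  tier: emerging
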