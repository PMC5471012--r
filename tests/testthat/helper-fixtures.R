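# Hand-built single-gene probe set for arithmetic-level tests.
tiny_probe_set <- function() {
  probe_set(tibble::tribble(
    ~probe_id, ~gene, ~role,             ~fusion_id, ~nominal_amount,
    "A5a",     "ALK", "five_prime",       NA,        NA,
    "A5b",     "ALK", "five_prime",       NA,        NA,
    "A3a",     "ALK", "three_prime",      NA,        NA,
    "A3b",     "ALK", "three_prime",      NA,        NA,
    "FS_AX",   "ALK", "fusion_specific",  "AX",      NA,
    "FS_AY",   "ALK", "fusion_specific",  "AY",      NA,
    "HK1",     NA,    "housekeeping",     NA,        NA,
    "HK2",     NA,    "housekeeping",     NA,        NA,
    "HK3",     NA,    "housekeeping",     NA,        NA,
    "POS1",    NA,    "pos_control",      NA,        100,
    "POS2",    NA,    "pos_control",      NA,        400,
    "NEG1",    NA,    "neg_control",      NA,        NA,
    "NEG2",    NA,    "neg_control",      NA,        NA,
    "NEG3",    NA,    "neg_control",      NA,        NA))
}

# Profile over tiny_probe_set(); defaults are a balanced fusion-negative
# profile with clean controls.
tiny_profile <- function(five = c(50, 50), three = c(50, 50),
                         fs = c(0, 0), hk = c(100, 100, 100),
                         pos = c(100, 400), neg = c(0, 0, 0),
                         sample_id = "S1") {
  count_profile(sample_id, c(
    A5a = five[1], A5b = five[2], A3a = three[1], A3b = three[2],
    FS_AX = fs[1], FS_AY = fs[2], HK1 = hk[1], HK2 = hk[2], HK3 = hk[3],
    POS1 = pos[1], POS2 = pos[2], NEG1 = neg[1], NEG2 = neg[2],
    NEG3 = neg[3]))
}

# thresholds with no background subtraction / pseudocount, so hand
# arithmetic is exact; positive-control geomean of tiny_profile is 200
exact_thresholds <- function(background_sd_multiplier = 0, pseudocount = 0,
                             reference_factor = 200, ...) {
  caller_thresholds(background_sd_multiplier = background_sd_multiplier,
                    pseudocount = pseudocount,
                    reference_factor = reference_factor, ...)
}

make_variant <- function(sample_id = "S1", gene = "KRAS",
                         coding_change = "c.34G>T", protein_change = "p.G12C",
                         exon = 2L, vaf = 0.3, pool_a = TRUE, pool_b = TRUE,
                         coverage = 2000) {
  tibble::tibble(sample_id = sample_id, gene = gene,
                 coding_change = coding_change, protein_change = protein_change,
                 exon = exon, vaf = vaf, detected_in_pool_a = pool_a,
                 detected_in_pool_b = pool_b, coverage = coverage)
}

# independent brute-force rule matcher used as the oracle for the rule
# engine; re-implements matching from the rule definitions directly
brute_force_actionable <- function(variants, rules) {
  vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (!isTRUE(v$retained)) return(NA_character_)
    p <- lungdx::parse_protein_change(v$protein_change)
    norm <- sub("^p\\.", "", v$protein_change)
    for (j in seq_len(nrow(rules))) {
      r <- rules[j, ]
      if (r$gene != v$gene) next
      hit <- switch(r$kind,
        codon_set = !is.na(p$codon) && p$codon %in% r$codons[[1]] &&
          p$variant_class %in% c("missense", "inframe_del", "inframe_ins"),
        named_protein_change = !is.na(norm) && norm == r$protein_change,
        exon_event = !is.na(v$exon) && v$exon == r$event_exon &&
          p$variant_class == r$event_class)
      if (isTRUE(hit)) return(r$rule_id)
    }
    NA_character_
  }, character(1))
}

# 200-variant fixture mixing actionable, near-miss and off-target records
rule_engine_fixture <- function(seed = 42) {
  set.seed(seed)
  cat <- lungdx::variant_catalogue()
  idx <- sample(nrow(cat), 200, replace = TRUE)
  v <- cat[idx, ]
  tibble::tibble(
    sample_id = sprintf("RF%03d", seq_len(200)),
    gene = v$gene, coding_change = v$coding_change,
    protein_change = v$protein_change, exon = v$exon,
    vaf = round(runif(200, 0.04, 0.9), 3),
    detected_in_pool_a = TRUE, detected_in_pool_b = TRUE,
    coverage = 2000)
}
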