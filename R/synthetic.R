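HISTOLOGIES <- c("adenocarcinoma", "SqCC", "NSCLC-NOS", "other")

#' Curated per-gene variant catalogue used by the cohort simulator
#'
#' Recurrent NSCLC panel variants in mixed HGVS-like notation (the dialect
#' the annotation parser accepts), each tagged with its exon, variant class
#' and whether it matches the shipped actionability rules. The actionable
#' flag is the generator's ground truth; the rule engine must recover it
#' independently.
#'
#' @return Tibble with columns `gene`, `protein_change`, `coding_change`,
#'   `exon`, `variant_class`, `truth_actionable`.
#' @export
variant_catalogue <- function() {
  tibble::tribble(
    ~gene,     ~protein_change,        ~coding_change,       ~exon, ~variant_class, ~truth_actionable,
    "KRAS",    "p.G12C",               "c.34G>T",            2L,    "missense",     TRUE,
    "KRAS",    "p.G12D",               "c.35G>A",            2L,    "missense",     TRUE,
    "KRAS",    "p.G12V",               "c.35G>T",            2L,    "missense",     TRUE,
    "KRAS",    "p.G13D",               "c.38G>A",            2L,    "missense",     TRUE,
    "KRAS",    "p.Q61H",               "c.183A>C",           3L,    "missense",     TRUE,
    "KRAS",    "p.A146T",              "c.436G>A",           4L,    "missense",     FALSE,
    "EGFR",    "p.E746_A750del",       "c.2235_2249del",     19L,   "inframe_del",  TRUE,
    "EGFR",    "exon19del",            "c.2236_2250del",     19L,   "inframe_del",  TRUE,
    "EGFR",    "p.L858R",              "c.2573T>G",          21L,   "missense",     TRUE,
    "EGFR",    "p.T790M",              "c.2369C>T",          20L,   "missense",     TRUE,
    "EGFR",    "p.G719A",              "c.2156G>C",          18L,   "missense",     TRUE,
    "EGFR",    "p.L861Q",              "c.2582T>A",          21L,   "missense",     TRUE,
    "EGFR",    "p.A767_V769dup",       "c.2300_2308dup",     20L,   "inframe_ins",  TRUE,
    "BRAF",    "p.V600E",              "c.1799T>A",          15L,   "missense",     TRUE,
    "BRAF",    "p.D594N",              "c.1780G>A",          15L,   "missense",     FALSE,
    "BRAF",    "p.G466V",              "c.1397G>T",          11L,   "missense",     FALSE,
    "BRAF",    "p.K601E",              "c.1801A>G",          15L,   "missense",     FALSE,
    "TP53",    "p.R175H",              "c.524G>A",           5L,    "missense",     FALSE,
    "TP53",    "p.Y220C",              "c.659A>G",           6L,    "missense",     FALSE,
    "TP53",    "p.R248Q",              "c.743G>A",           7L,    "missense",     FALSE,
    "TP53",    "p.R273H",              "c.818G>A",           8L,    "missense",     FALSE,
    "TP53",    "p.R342*",              "c.1024C>T",          10L,   "nonsense",     FALSE,
    "PIK3CA",  "p.E542K",              "c.1624G>A",          9L,    "missense",     TRUE,
    "PIK3CA",  "p.E545K",              "c.1633G>A",          9L,    "missense",     TRUE,
    "PIK3CA",  "p.H1047R",             "c.3140A>G",          20L,   "missense",     TRUE,
    "NRAS",    "p.Q61K",               "c.181C>A",           3L,    "missense",     TRUE,
    "NRAS",    "p.G12D",               "c.35G>A",            2L,    "missense",     TRUE,
    "ERBB2",   "p.A775_G776insYVMA",   "c.2324_2325ins12",   20L,   "inframe_ins",  TRUE,
    "MAP2K1",  "p.K57N",               "c.171G>T",           2L,    "missense",     TRUE,
    "AKT1",    "p.L52R",               "c.155T>G",           2L,    "missense",     TRUE,
    "STK11",   "p.F354L",              "c.1062C>G",          8L,    "missense",     FALSE,
    "STK11",   "p.Q37*",               "c.109C>T",           1L,    "nonsense",     FALSE,
    "PTEN",    "p.R130G",              "c.388C>G",           5L,    "missense",     FALSE,
    "CTNNB1",  "p.S37F",               "c.110C>T",           2L,    "missense",     FALSE,
    "MET",     "p.T1010I",             "c.3029C>T",          15L,   "missense",     FALSE
  )
}

default_mutation_rates <- function() {
  c(TP53 = 0.40, KRAS = 0.30, EGFR = 0.12, BRAF = 0.06, PIK3CA = 0.05,
    STK11 = 0.05, PTEN = 0.03, CTNNB1 = 0.02, MET = 0.02, ERBB2 = 0.02,
    NRAS = 0.01, MAP2K1 = 0.01, AKT1 = 0.005)
}

#' Specification of a synthetic mutation-testing cohort
#'
#' @param n_samples Number of tumors.
#' @param histology_mix Named proportions over
#'   `adenocarcinoma`, `SqCC`, `NSCLC-NOS`, `other`; must sum to 1.
#' @param per_gene_mutation_rates Named per-gene per-sample mutation
#'   probabilities in `[0, 1]`.
#' @param vaf_range VAF interval within (0, 1].
#' @param seed Integer seed making generation reproducible.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples,
                        histology_mix = c(adenocarcinoma = 0.65, SqCC = 0.17,
                                          `NSCLC-NOS` = 0.15, other = 0.03),
                        per_gene_mutation_rates = default_mutation_rates(),
                        vaf_range = c(0.04, 0.9),
                        seed = 1L) {
  if (n_samples < 1) abort("cohort must contain at least one sample")
  if (!setequal(names(histology_mix), HISTOLOGIES)) {
    abort("histology_mix must name exactly adenocarcinoma, SqCC, NSCLC-NOS, other")
  }
  if (abs(sum(histology_mix) - 1) > 1e-9) {
    abort("histology proportions must sum to 1")
  }
  if (any(per_gene_mutation_rates < 0 | per_gene_mutation_rates > 1)) {
    abort("mutation rates must lie in [0, 1]")
  }
  if (vaf_range[1] <= 0 || vaf_range[2] > 1 || vaf_range[1] > vaf_range[2]) {
    abort("vaf_range must be an interval within (0, 1]")
  }
  structure(list(n_samples = as.integer(n_samples),
                 histology_mix = histology_mix[HISTOLOGIES],
                 per_gene_mutation_rates = per_gene_mutation_rates,
                 vaf_range = vaf_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic variant cohort
#'
#' Draws per-sample histology from the spec's mix, per-gene mutation
#' presence as independent Bernoulli events at the spec's rates, and the
#' variant identity uniformly from the gene's [variant_catalogue()]
#' entries. VAFs are uniform in `vaf_range`; coverage and dual-pool flags
#' are drawn so that generated variants pass the default retention
#' filters. Ground truth (which samples carry an actionable alteration)
#' goes to a sidecar table, never into the primary outputs.
#'
#' @param spec A [cohort_spec()].
#' @return List with `samples` (metadata tibble), `variants` (variant
#'   tibble) and `truth` (sidecar tibble: `sample_id`, `truth_actionable`,
#'   `truth_actionable_genes`).
#' @export
generate_variant_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  ids <- sprintf("LC%05d", seq_len(n))
  samples <- tibble::tibble(
    sample_id = ids,
    histology = sample(HISTOLOGIES, n, replace = TRUE,
                       prob = spec$histology_mix),
    specimen_type = sample(c("FFPE", "cytology"), n, replace = TRUE,
                           prob = c(0.745, 0.255)),
    tumor_cell_content = round(runif(n, 10, 95))
  )
  cat_by_gene <- split(variant_catalogue(), variant_catalogue()$gene)
  rows <- list()
  for (g in names(spec$per_gene_mutation_rates)) {
    rate <- spec$per_gene_mutation_rates[[g]]
    if (rate == 0) next
    if (!g %in% names(cat_by_gene)) {
      abort(sprintf("no catalogue variants for gene %s", g))
    }
    hit <- runif(n) < rate
    if (!any(hit)) next
    pick <- sample(nrow(cat_by_gene[[g]]), sum(hit), replace = TRUE)
    chosen <- cat_by_gene[[g]][pick, ]
    rows[[g]] <- tibble::tibble(
      sample_id = ids[hit],
      gene = g,
      coding_change = chosen$coding_change,
      protein_change = chosen$protein_change,
      exon = chosen$exon,
      vaf = round(runif(sum(hit), spec$vaf_range[1], spec$vaf_range[2]), 3),
      detected_in_pool_a = TRUE,
      detected_in_pool_b = TRUE,
      coverage = round(runif(sum(hit), 1200, 4000)),
      truth_actionable = chosen$truth_actionable
    )
  }
  variants <- if (length(rows) > 0) {
    dplyr::arrange(dplyr::bind_rows(rows), .data$sample_id, .data$gene)
  } else {
    tibble::tibble(sample_id = character(0), gene = character(0),
                   coding_change = character(0), protein_change = character(0),
                   exon = integer(0), vaf = numeric(0),
                   detected_in_pool_a = logical(0),
                   detected_in_pool_b = logical(0), coverage = numeric(0),
                   truth_actionable = logical(0))
  }
  act <- variants |>
    dplyr::filter(.data$truth_actionable) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(genes = paste(sort(unique(.data$gene)), collapse = ","),
                     .groups = "drop")
  truth <- tibble::tibble(
    sample_id = ids,
    truth_actionable = ids %in% act$sample_id,
    truth_actionable_genes = act$genes[match(ids, act$sample_id)]
  )
  variants$truth_actionable <- NULL
  list(samples = samples, variants = variants, truth = truth)
}

#' Specification of a synthetic hybridization batch
#'
#' @param n_profiles Number of hybridizations.
#' @param events Tibble of fusion events: columns `profile` (index),
#'   `gene`, `fusion_id` (a fusion id present on the probe set, or
#'   `"NOVEL"` for a junction not covered by any specific probe).
#' @param n_degraded Number of degraded-RNA profiles (QC failures);
#'   placed on the last indices not carrying an event.
#' @param overexpression Optional tibble (`profile`, `gene`) of profiles
#'   with joint 3' + 5' overexpression of a gene without rearrangement.
#' @param histology Optional character vector (length `n_profiles`) of
#'   histology labels; defaults to `adenocarcinoma` everywhere.
#' @param baseline_count_scale Multiplier on all expected counts.
#' @param noise_dispersion Negative-binomial size parameter (larger =
#'   tighter counts). Default 100, i.e. ~10% technical CV at high
#'   expression, matching replicate hybridizations of intact RNA.
#' @param seed Integer seed.
#' @return List of class `nanostring_batch_spec`.
#' @export
nanostring_batch_spec <- function(n_profiles, events = NULL, n_degraded = 0,
                                  overexpression = NULL, histology = NULL,
                                  baseline_count_scale = 1,
                                  noise_dispersion = 100, seed = 1L) {
  if (n_profiles < 1) abort("batch must contain at least one profile")
  events <- events %||% tibble::tibble(profile = integer(0),
                                       gene = character(0),
                                       fusion_id = character(0))
  events <- tibble::as_tibble(events)
  stopifnot_cols(events, c("profile", "gene", "fusion_id"), "event table")
  if (anyDuplicated(events$profile)) abort("event profile indices must be distinct")
  if (any(events$profile < 1 | events$profile > n_profiles)) {
    abort("event profile indices out of range")
  }
  if (n_degraded > n_profiles) abort("n_degraded exceeds n_profiles")
  if (n_degraded > n_profiles - nrow(events)) {
    abort("not enough event-free profiles to degrade")
  }
  if (!is.null(histology) && length(histology) != n_profiles) {
    abort("histology must have one label per profile")
  }
  if (baseline_count_scale <= 0 || noise_dispersion <= 0) {
    abort("baseline_count_scale and noise_dispersion must be positive")
  }
  structure(list(n_profiles = as.integer(n_profiles), events = events,
                 n_degraded = as.integer(n_degraded),
                 overexpression = overexpression,
                 histology = histology %||% rep("adenocarcinoma", n_profiles),
                 baseline_count_scale = baseline_count_scale,
                 noise_dispersion = noise_dispersion,
                 seed = as.integer(seed)),
            class = "nanostring_batch_spec")
}

# expected (pre-noise) counts per probe role, at baseline_count_scale = 1
BATCH_MEANS <- list(housekeeping = c(800, 1200, 2000, 3000, 1500, 1000, 2500),
                    neg_control = 15, flank = 400, fused_3p = 5000,
                    specific = 1200, pos_per_fm = 250, degraded_factor = 0.005)

#' Generate a synthetic hybridization batch of probe-count profiles
#'
#' Counts are negative-binomial around probe-role-specific means, times a
#' per-profile lognormal lane factor applied to every probe (controls
#' included; positive-control scaling must remove it). Fusion events
#' elevate the 3'-flank probes of their gene ~20-fold and, unless
#' `"NOVEL"`, the matching junction probe; overexpression events elevate
#' 3' and 5' jointly; degraded profiles have endogenous and housekeeping
#' signal suppressed ~200-fold while the spiked controls are untouched,
#' so only the housekeeping QC ratio reveals them. Separation from the
#' default thresholds is at least fivefold in all directions.
#'
#' @param spec A [nanostring_batch_spec()].
#' @param probe_set A [probe_set()] covering the event genes.
#' @return List with `profiles` (list of [count_profile()]) and `truth`
#'   (sidecar tibble: `sample_id`, `histology`, `qc_fail`, per-event
#'   `gene`/`fusion_id`, `true_status`, and the brute-force
#'   `truth_ratio_3p5p` recomputed from the raw generated counts).
#' @export
generate_nanostring_batch <- function(spec, probe_set = default_probe_set()) {
  stopifnot(inherits(spec, "nanostring_batch_spec"))
  bad <- setdiff(spec$events$gene, unique(probe_set$gene))
  if (length(bad) > 0) {
    abort(sprintf("event gene(s) absent from probe set: %s",
                  paste(bad, collapse = ", ")))
  }
  for (k in seq_len(nrow(spec$events))) {
    fid <- spec$events$fusion_id[k]
    g <- spec$events$gene[k]
    if (fid != "NOVEL" &&
        !fid %in% probe_set$fusion_id[probe_set$gene %inn% g]) {
      abort(sprintf("fusion id %s not on the probe set for gene %s", fid, g))
    }
  }
  set.seed(spec$seed)
  n <- spec$n_profiles
  free <- setdiff(seq_len(n), spec$events$profile)
  degraded_idx <- utils::tail(free, spec$n_degraded)
  genes <- sort(unique(probe_set$gene[probe_set$role == "five_prime"]))

  mu_base <- numeric(nrow(probe_set))
  names(mu_base) <- probe_set$probe_id
  mu_base[probe_set$role == "housekeeping"] <-
    rep_len(BATCH_MEANS$housekeeping, sum(probe_set$role == "housekeeping"))
  mu_base[probe_set$role == "neg_control"] <- BATCH_MEANS$neg_control
  mu_base[probe_set$role %in% c("five_prime", "three_prime")] <- BATCH_MEANS$flank
  mu_base[probe_set$role == "fusion_specific"] <- BATCH_MEANS$neg_control
  pos <- probe_set$role == "pos_control"
  mu_base[pos] <- BATCH_MEANS$pos_per_fm * as.numeric(probe_set$nominal_amount[pos])

  profiles <- vector("list", n)
  truth_rows <- vector("list", n)
  endo <- !probe_set$role %in% c("pos_control", "neg_control")
  for (j in seq_len(n)) {
    mu <- mu_base * spec$baseline_count_scale
    ev <- spec$events[spec$events$profile == j, ]
    if (nrow(ev) == 1) {
      mu[probes_for(probe_set, ev$gene, "three_prime")] <- BATCH_MEANS$fused_3p *
        spec$baseline_count_scale
      if (ev$fusion_id != "NOVEL") {
        fp <- probe_set$probe_id[probe_set$fusion_id %inn% ev$fusion_id]
        mu[fp] <- BATCH_MEANS$specific * spec$baseline_count_scale
      }
    }
    if (!is.null(spec$overexpression)) {
      ov <- spec$overexpression[spec$overexpression$profile == j, ]
      for (g in ov$gene) {
        mu[c(probes_for(probe_set, g, "five_prime"),
             probes_for(probe_set, g, "three_prime"))] <-
          BATCH_MEANS$fused_3p * spec$baseline_count_scale
      }
    }
    degraded <- j %in% degraded_idx
    if (degraded) mu[endo] <- mu[endo] * BATCH_MEANS$degraded_factor
    lane <- exp(rnorm(1, 0, 0.15))
    counts <- rnbinom(length(mu), size = spec$noise_dispersion, mu = mu * lane)
    names(counts) <- names(mu)
    sid <- sprintf("NS%04d", j)
    profiles[[j]] <- count_profile(sid, counts, batch_id = "synthetic")

    ratio <- vapply(genes, function(g) {
      mean(counts[probes_for(probe_set, g, "three_prime")]) /
        mean(counts[probes_for(probe_set, g, "five_prime")])
    }, numeric(1))
    ev_gene <- if (nrow(ev) == 1) ev$gene else NA_character_
    ev_fid <- if (nrow(ev) == 1) ev$fusion_id else NA_character_
    truth_rows[[j]] <- tibble::tibble(
      sample_id = sid, gene = genes,
      histology = spec$histology[j],
      qc_fail = degraded,
      true_status = dplyr::case_when(
        degraded ~ "QC_FAIL",
        gene == ev_gene & ev_fid == "NOVEL" ~ "NOVEL_FUSION",
        gene == ev_gene ~ "KNOWN_FUSION",
        TRUE ~ "NEGATIVE"),
      fusion_id = ifelse(gene == ev_gene & ev_fid != "NOVEL" & !degraded,
                         ev_fid, NA_character_),
      truth_ratio_3p5p = unname(ratio))
  }
  list(profiles = profiles, truth = dplyr::bind_rows(truth_rows))
}

#' Batch spec emulating the prospective triple-negative fusion screen
#'
#' 169 hybridizations of which 34 are degraded-RNA failures, leaving 135
#' analyzable profiles that carry ten fusion events: four EML4-ALK_E13:A20
#' and one EML4-ALK_E6ab:A20, two CCDC6-RET_C1:R12 and one novel RET
#' junction, and one SLC34A2-ROS1_S4:R32 plus one SDC4-ROS1_S2:R32. The
#' first 67 analyzable profiles (including all ten events) are
#' adenocarcinomas; the remainder split across the other histologies.
#'
#' @param seed Integer seed forwarded to the batch spec.
#' @return A [nanostring_batch_spec()].
#' @export
prospective_fusion_batch_spec <- function(seed = 1L) {
  events <- tibble::tibble(
    profile = 1:10,
    gene = c(rep("ALK", 5), rep("RET", 3), rep("ROS1", 2)),
    fusion_id = c(rep("EML4-ALK_E13:A20", 4), "EML4-ALK_E6ab:A20",
                  rep("CCDC6-RET_C1:R12", 2), "NOVEL",
                  "SLC34A2-ROS1_S4:R32", "SDC4-ROS1_S2:R32"))
  histology <- c(rep("adenocarcinoma", 67), rep("SqCC", 40),
                 rep("NSCLC-NOS", 20), rep("other", 8),
                 # degraded tail: histology of failed hybridizations
                 rep("adenocarcinoma", 20), rep("SqCC", 10),
                 rep("NSCLC-NOS", 4))
  nanostring_batch_spec(n_profiles = 169, events = events, n_degraded = 34,
                        histology = histology, seed = seed)
}

#' Batch spec emulating the four fusion-positive control cell lines
#'
#' HCC78 (SLC34A2-ROS1), KARPAS-299 (NPM1-ALK), LC-2/ad (CCDC6-RET) and
#' H2228 (EML4-ALK), each a QC-passing profile carrying its known fusion.
#'
#' @param seed Integer seed.
#' @return A [nanostring_batch_spec()].
#' @export
cell_line_control_batch_spec <- function(seed = 1L) {
  events <- tibble::tibble(
    profile = 1:4,
    gene = c("ROS1", "ALK", "RET", "ALK"),
    fusion_id = c("SLC34A2-ROS1_S4:R32", "NPM1-ALK_N4:A20",
                  "CCDC6-RET_C1:R12", "EML4-ALK_E13:A20"))
  nanostring_batch_spec(n_profiles = 4, events = events, n_degraded = 0,
                        histology = rep("cell_line", 4), seed = seed)
}

#' Specification of a paired-call validation fixture
#'
#' Per gene-within-cohort counts of concordant and discordant calls, split
#' by the reference method's verdict (mutation vs no mutation).
#' `out_of_scope_discordant` counts the subset of no-mutation discordant
#' rows where the test panel found a variant at a locus the single-gene
#' reference assay does not interrogate.
#'
#' @param counts Tibble with columns `gene`, `cohort`, `mut_concordant`,
#'   `mut_discordant`, `nomut_concordant`, `nomut_discordant`,
#'   `out_of_scope_discordant`.
#' @param seed Integer seed (used for variant identity draws).
#' @return List of class `paired_call_spec`.
#' @export
paired_call_spec <- function(counts, seed = 1L) {
  counts <- tibble::as_tibble(counts)
  stopifnot_cols(counts, c("gene", "cohort", "mut_concordant",
                           "mut_discordant", "nomut_concordant",
                           "nomut_discordant", "out_of_scope_discordant"),
                 "paired-call spec")
  num <- counts[, c("mut_concordant", "mut_discordant", "nomut_concordant",
                    "nomut_discordant", "out_of_scope_discordant")]
  if (any(as.matrix(num) < 0)) abort("paired-call counts must be non-negative")
  if (any(counts$out_of_scope_discordant > counts$nomut_discordant)) {
    abort("out-of-scope rows cannot exceed no-mutation discordant rows")
  }
  structure(list(counts = counts, seed = as.integer(seed)),
            class = "paired_call_spec")
}

#' Generate a paired-call table from a spec
#'
#' Expands the spec's per-gene counts into one row per call: concordant
#' mutation rows share a catalogue variant between methods; discordant
#' mutation rows have the reference variant unconfirmed by the test panel;
#' out-of-scope rows carry a test-only variant with `in_scope = FALSE`.
#'
#' @param spec A [paired_call_spec()].
#' @return Tibble with columns `sample_id`, `cohort`, `gene`, `ref_call`,
#'   `test_call`, `ref_protein_change`, `ref_coding_change`,
#'   `test_protein_change`, `test_coding_change`, `in_scope`.
#' @export
generate_paired_calls <- function(spec) {
  stopifnot(inherits(spec, "paired_call_spec"))
  set.seed(spec$seed)
  cat_by_gene <- split(variant_catalogue(), variant_catalogue()$gene)
  rows <- list()
  k <- 0L
  next_id <- function() {
    k <<- k + 1L
    sprintf("VAL%03d", k)
  }
  pick_variant <- function(gene) {
    cat <- cat_by_gene[[gene]]
    if (is.null(cat)) {
      return(tibble::tibble(protein_change = "p.?", coding_change = "c.?"))
    }
    cat[sample(nrow(cat), 1), c("protein_change", "coding_change")]
  }
  for (i in seq_len(nrow(spec$counts))) {
    row <- spec$counts[i, ]
    add <- function(nrep, ref_call, test_call, in_scope, which_variant) {
      purrr::map_dfr(seq_len(nrep), function(.) {
        v <- pick_variant(row$gene)
        tibble::tibble(
          sample_id = next_id(), cohort = row$cohort, gene = row$gene,
          ref_call = ref_call, test_call = test_call,
          ref_protein_change = if (ref_call == "mutation") v$protein_change
                               else NA_character_,
          ref_coding_change = if (ref_call == "mutation") v$coding_change
                              else NA_character_,
          test_protein_change = if (test_call == "mutation") v$protein_change
                                else NA_character_,
          test_coding_change = if (test_call == "mutation") v$coding_change
                               else NA_character_,
          in_scope = in_scope)
      })
    }
    n_oos <- row$out_of_scope_discordant
    rows[[length(rows) + 1]] <- dplyr::bind_rows(
      add(row$mut_concordant, "mutation", "mutation", TRUE),
      add(row$mut_discordant, "mutation", "no_mutation", TRUE),
      add(row$nomut_concordant, "no_mutation", "no_mutation", TRUE),
      add(row$nomut_discordant - n_oos, "no_mutation", "mutation", TRUE),
      add(n_oos, "no_mutation", "mutation", FALSE))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(sample_id = character(0), cohort = character(0),
                          gene = character(0), ref_call = character(0),
                          test_call = character(0),
                          ref_protein_change = character(0),
                          ref_coding_change = character(0),
                          test_protein_change = character(0),
                          test_coding_change = character(0),
                          in_scope = logical(0))
  }
  out
}

#' Paired-call spec encoding the clinical validation cohort
#'
#' 92 calls over 81 tumors (lung, cutaneous melanoma, colon): 29 known
#' hotspot mutation calls and 63 calls of no mutation, with four
#' discordant calls of which three are out-of-scope (panel-only variants
#' at loci the single-gene assay does not read) and one is an unconfirmed
#' reference KRAS call.
#'
#' @param seed Integer seed.
#' @return A [paired_call_spec()].
#' @export
validation_paired_call_spec <- function(seed = 1L) {
  counts <- tibble::tribble(
    ~gene,  ~cohort,       ~mut_concordant, ~mut_discordant,
      ~nomut_concordant, ~nomut_discordant, ~out_of_scope_discordant,
    "EGFR", "lung",        8L, 0L, 31L, 1L, 1L,
    "BRAF", "melanoma",    9L, 0L, 11L, 1L, 1L,
    "NRAS", "melanoma",    0L, 0L,  1L, 0L, 0L,
    "KRAS", "colon",       9L, 1L,  8L, 0L, 0L,
    "NRAS", "colon",       1L, 0L,  4L, 1L, 1L,
    "BRAF", "colon",       1L, 0L,  5L, 0L, 0L)
  paired_call_spec(counts, seed = seed)
}
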