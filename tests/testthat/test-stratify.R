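samples3 <- tibble::tibble(
  sample_id = c("S1", "S2", "S3"),
  histology = c("adenocarcinoma", "SqCC", "adenocarcinoma"))

test_that("triple-negative status depends only on retained EGFR/KRAS/BRAF mutations", {
  v <- annotate_variants(dplyr::bind_rows(
    make_variant("S1", "TP53", "c.524G>A", "p.R175H", 5L),
    make_variant("S2", "KRAS", "c.35G>T", "p.G12V", 2L),
    make_variant("S3", "EGFR", "c.2573T>G", "p.L858R", 21L,
                 pool_b = FALSE)))  # rejected -> does not count
  expect_equal(is_triple_negative(samples3, v), c(TRUE, FALSE, TRUE))
  # no variants at all: every sample is triple-negative
  expect_true(all(is_triple_negative(samples3, v[0, ])))
  # fusion results must not change the computation (no fusion argument exists)
  expect_identical(is_triple_negative(samples3, v),
                   is_triple_negative(samples3[, c("sample_id", "histology")], v))
})

test_that("eligibility categories follow the stated precedence", {
  v <- annotate_variants(dplyr::bind_rows(
    make_variant("S1", "EGFR", "c.2573T>G", "p.L858R", 21L),
    make_variant("S1", "KRAS", "c.34G>T", "p.G12C", 2L),
    make_variant("S2", "BRAF", "c.1799T>A", "p.V600E", 15L),
    make_variant("S3", "KRAS", "c.34G>T", "p.G12C", 2L)))
  fus <- tibble::tibble(sample_id = "S2", gene = "ALK",
                        status = "KNOWN_FUSION")
  cats <- eligibility_category(samples3, v, fus)
  expect_equal(cats, c("EGFR+", "ALK+", "KRAS_only"))  # ALK beats BRAF
  # with no fusion data S2 falls to its emerging mutation
  expect_equal(eligibility_category(samples3, v)[2], "BRAF+")
  # no actionable alterations at all
  expect_equal(eligibility_category(samples3, v[0, ]), rep("none", 3))
  # configurable precedence flips the rare double-positive
  v2 <- dplyr::bind_rows(v, annotate_variants(
    make_variant("S2", "EGFR", "c.2369C>T", "p.T790M", 20L)))
  expect_equal(eligibility_category(samples3, v2, fus,
                                    precedence = c("ALK+", "EGFR+"))[2], "ALK+")
})

test_that("eligibility categories partition every cohort and percentages are consistent", {
  co <- generate_variant_cohort(cohort_spec(250, seed = 31))
  ann <- annotate_variants(co$variants)
  st <- stratify(co$samples, ann)
  # partition: per-histology category counts sum to group sizes
  sums <- tapply(st$eligibility$n, st$eligibility$histology, sum)
  sizes <- table(co$samples$histology)
  expect_equal(as.integer(sums[names(sizes)]), as.integer(sizes))
  # percent >=1 actionable equals 100 - percent(none) per group
  for (h in unique(co$samples$histology)) {
    none <- st$eligibility$n[st$eligibility$histology == h &
                               st$eligibility$category == "none"]
    none <- if (length(none) == 0) 0 else none
    g <- st$groups[st$groups$group == h, ]
    expect_equal(g$pct_actionable, round(100 * (g$n - none) / g$n, 1))
  }
})

test_that("stratification counts recover the generator's ground truth exactly", {
  co <- generate_variant_cohort(cohort_spec(400, seed = 17))
  ann <- annotate_variants(co$variants)
  st <- stratify(co$samples, ann)
  truth_n <- sum(co$truth$truth_actionable)
  expect_equal(st$groups$n_actionable[st$groups$group == "overall"], truth_n)
  expect_equal(st$groups$pct_actionable[st$groups$group == "overall"],
               round(100 * truth_n / nrow(co$samples), 1))
  # determinism: same inputs, same report
  expect_identical(unclass(stratify(co$samples, ann))[1:4], unclass(st)[1:4])
})

test_that("trivial cohorts stratify as expected", {
  v <- annotate_variants(dplyr::bind_rows(
    make_variant("S1", "KRAS", "c.34G>T", "p.G12C", 2L),
    make_variant("S2", "KRAS", "c.35G>A", "p.G12D", 2L),
    make_variant("S3", "KRAS", "c.35G>T", "p.G12V", 2L)))
  st <- stratify(samples3, v)
  overall <- st$groups[st$groups$group == "overall", ]
  expect_equal(overall$pct_actionable, 100)
  expect_true(all(st$eligibility$category == "KRAS_only"))
  # two-sample cohort with one EGFR+ AC and one silent SqCC
  two <- tibble::tibble(sample_id = c("A", "B"),
                        histology = c("adenocarcinoma", "SqCC"))
  v2 <- annotate_variants(make_variant("A", "EGFR", "c.2573T>G", "p.L858R", 21L))
  st2 <- stratify(two, v2)
  expect_equal(st2$groups$pct_actionable[st2$groups$group == "adenocarcinoma"], 100)
  expect_equal(st2$groups$pct_actionable[st2$groups$group == "SqCC"], 0)
  expect_error(stratify(samples3[0, ], v), "empty cohort")
})

test_that("variant histogram uses retained non-synonymous variants incl. TP53", {
  v <- annotate_variants(dplyr::bind_rows(
    make_variant("S1", "TP53", "c.524G>A", "p.R175H", 5L),
    make_variant("S1", "KRAS", "c.34G>T", "p.G12C", 2L),
    make_variant("S2", "TP53", "c.659A>G", "p.Y220C", 6L),
    make_variant("S2", "TP53", "c.743G>A", "p.R248Q", 7L),
    make_variant("S2", "STK11", "c.109C>T", "p.Q37*", 1L)))
  st <- stratify(samples3, v)
  h <- st$variant_histogram
  expect_equal(h$n[h$histology == "adenocarcinoma" & h$bin == "1-2"], 1)  # S1
  expect_equal(h$n[h$histology == "adenocarcinoma" & h$bin == "0"], 1)    # S3
  expect_equal(h$n[h$histology == "SqCC" & h$bin == ">2"], 1)             # S2
})

test_that("co-occurrence matrix equals a brute-force pairwise recount", {
  co <- generate_variant_cohort(cohort_spec(50, seed = 23))
  ann <- annotate_variants(co$variants)
  m <- cooccurrence_matrix(ann)
  genes <- rownames(m)
  for (g1 in genes) for (g2 in genes) {
    s1 <- unique(ann$sample_id[ann$retained & ann$gene == g1])
    s2 <- unique(ann$sample_id[ann$retained & ann$gene == g2])
    expect_equal(unname(m[g1, g2]), length(intersect(s1, s2)))
  }
  # single sample with KRAS + PIK3CA puts a 1 off-diagonal
  v <- annotate_variants(dplyr::bind_rows(
    make_variant("S1", "KRAS", "c.34G>T", "p.G12C", 2L),
    make_variant("S1", "PIK3CA", "c.1633G>A", "p.E545K", 9L)))
  m2 <- cooccurrence_matrix(v)
  expect_equal(unname(m2["KRAS", "PIK3CA"]), 1)
  # mutually exclusive drivers leave off-diagonals at zero
  v3 <- annotate_variants(dplyr::bind_rows(
    make_variant("S1", "KRAS", "c.34G>T", "p.G12C", 2L),
    make_variant("S2", "EGFR", "c.2573T>G", "p.L858R", 21L)))
  m3 <- cooccurrence_matrix(v3)
  expect_equal(unname(m3["KRAS", "EGFR"]), 0)
})

test_that("fusion-untested samples stay in cohort denominators but not fusion ones", {
  fus <- tibble::tibble(sample_id = c("S1", "S2"), gene = "ALK",
                        status = c("KNOWN_FUSION", "QC_FAIL"))
  st <- stratify(samples3, variants = NULL, fusions = fus)
  overall <- st$groups[st$groups$group == "overall", ]
  expect_equal(overall$n, 3)
  expect_equal(overall$n_fusion_tested, 2)
  expect_equal(overall$n_fusion_analyzable, 1)
  expect_equal(overall$n_fusion_positive, 1)
  expect_equal(overall$pct_fusion_positive, 100)
})
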