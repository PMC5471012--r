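EMERGING_FUSION_GENES <- c("RET", "ROS1")
EMERGING_MUT_GENES <- c("BRAF", "PIK3CA", "ERBB2", "NRAS", "MAP2K1", "AKT1")

# per-sample sets of actionable mutation genes and fusion-positive genes
actionable_sets <- function(sample_ids, variants = NULL, fusions = NULL) {
  mut <- if (!is.null(variants) && nrow(variants) > 0) {
    v <- variants[variants$actionable %in% TRUE, c("sample_id", "gene")]
    split(v$gene, factor(v$sample_id, levels = sample_ids))
  } else {
    split(character(0), factor(character(0), levels = sample_ids))
  }
  fus <- if (!is.null(fusions) && nrow(fusions) > 0) {
    f <- fusions[fusions$status %in% c("KNOWN_FUSION", "NOVEL_FUSION"),
                 c("sample_id", "gene")]
    split(f$gene, factor(f$sample_id, levels = sample_ids))
  } else {
    split(character(0), factor(character(0), levels = sample_ids))
  }
  list(mut = mut, fus = fus)
}

#' Triple-negative status: no retained EGFR, KRAS or BRAF mutation
#'
#' The triple-negative subset (no retained variant in EGFR, KRAS or BRAF)
#' is the population forwarded to RNA fusion screening. The computation
#' uses only the mutation data; fusion results never alter it.
#'
#' @param samples Sample metadata tibble with `sample_id`.
#' @param variants Annotated variant tibble (needs `retained`; all
#'   variants are treated as retained if the column is absent).
#' @return Logical vector along the rows of `samples`.
#' @export
is_triple_negative <- function(samples, variants) {
  variants <- tibble::as_tibble(variants)
  if (!"retained" %in% names(variants)) variants$retained <- TRUE
  hit <- variants$retained & variants$gene %in% c("EGFR", "KRAS", "BRAF")
  !(samples$sample_id %in% variants$sample_id[hit])
}

#' Treatment-eligibility category of each sample
#'
#' Categories, in precedence order: `EGFR+` (actionable EGFR mutation,
#' irrespective of other alterations), `ALK+` (ALK fusion, irrespective of
#' other alterations), one per-gene emerging category (`RET+`, `ROS1+`
#' fusions; `BRAF+`, `PIK3CA+`, `ERBB2+`, `NRAS+`, `MAP2K1+`, `AKT1+`
#' mutations), `KRAS_only` (the only actionable alteration(s) are KRAS),
#' and `none`. Categories partition every cohort.
#'
#' @param samples Sample metadata tibble with `sample_id`.
#' @param variants Annotated variant tibble (needs `actionable`); may be
#'   NULL.
#' @param fusions Fusion-call tibble from [call_batch()]; may be NULL
#'   (not assayed).
#' @param precedence Character vector ordering the first two categories;
#'   default `c("EGFR+", "ALK+")`.
#' @return Character vector of categories along the rows of `samples`.
#' @export
eligibility_category <- function(samples, variants = NULL, fusions = NULL,
                                 precedence = c("EGFR+", "ALK+")) {
  sets <- actionable_sets(samples$sample_id, variants, fusions)
  vapply(samples$sample_id, function(s) {
    mg <- sets$mut[[s]] %||% character(0)
    fg <- sets$fus[[s]] %||% character(0)
    has <- c(`EGFR+` = "EGFR" %in% mg, `ALK+` = "ALK" %in% fg)
    for (cat in precedence) if (has[[cat]]) return(cat)
    for (g in EMERGING_FUSION_GENES) if (g %in% fg) return(paste0(g, "+"))
    for (g in EMERGING_MUT_GENES) if (g %in% mg) return(paste0(g, "+"))
    if ("KRAS" %in% mg) return("KRAS_only")
    "none"
  }, character(1), USE.NAMES = FALSE)
}

#' Gene-by-gene co-occurrence matrix of retained alterations
#'
#' Symmetric matrix counting samples that carry retained alterations in
#' both genes of a pair; the diagonal holds per-gene totals. Fusion calls
#' contribute their gene when positive.
#'
#' @param variants Annotated variant tibble (`retained` assumed TRUE when
#'   absent); may be NULL.
#' @param fusions Fusion-call tibble; may be NULL.
#' @param genes Genes to include; defaults to every gene observed.
#' @return Integer matrix with gene dimnames.
#' @export
cooccurrence_matrix <- function(variants = NULL, fusions = NULL, genes = NULL) {
  pairs <- list()
  if (!is.null(variants) && nrow(variants) > 0) {
    v <- tibble::as_tibble(variants)
    if (!"retained" %in% names(v)) v$retained <- TRUE
    v <- v[v$retained, c("sample_id", "gene")]
    pairs <- c(pairs, list(v))
  }
  if (!is.null(fusions) && nrow(fusions) > 0) {
    f <- fusions[fusions$status %in% c("KNOWN_FUSION", "NOVEL_FUSION"),
                 c("sample_id", "gene")]
    pairs <- c(pairs, list(f))
  }
  alt <- if (length(pairs) > 0) dplyr::distinct(dplyr::bind_rows(pairs))
         else tibble::tibble(sample_id = character(0), gene = character(0))
  genes <- genes %||% sort(unique(alt$gene))
  m <- matrix(0L, length(genes), length(genes), dimnames = list(genes, genes))
  for (s in unique(alt$sample_id)) {
    gs <- intersect(alt$gene[alt$sample_id == s], genes)
    m[gs, gs] <- m[gs, gs] + 1L
  }
  m
}

#' Stratify a cohort by actionable alterations
#'
#' Joins annotated variants, fusion calls and sample metadata and
#' summarizes, per histology group and overall: sample counts, the
#' proportion with at least one actionable alteration (with and without
#' KRAS), the retained non-synonymous variant-count histogram (0 / 1-2 /
#' >2), the treatment-eligibility partition, fusion-assay coverage and
#' positivity, the per-gene actionable-variant distribution, and the
#' gene-by-gene co-occurrence matrix. Samples never assayed for fusions
#' stay in all denominators except the fusion-positivity one; samples
#' whose hybridization failed QC are counted as tested but not analyzable.
#'
#' @param samples Sample metadata tibble (`sample_id`, `histology`).
#' @param variants Annotated variant tibble from [annotate_variants()];
#'   may be NULL or empty.
#' @param fusions Fusion-call tibble from [call_batch()]; may be NULL.
#' @param kras_in_actionable Count actionable KRAS variants toward the
#'   headline ≥1-actionable percentage? Default TRUE (the complement is
#'   always reported alongside).
#' @return List of class `stratification_report`: `groups` tibble,
#'   `eligibility` tibble, `variant_histogram` tibble, `gene_distribution`
#'   tibble, `cooccurrence` matrix.
#' @export
stratify <- function(samples, variants = NULL, fusions = NULL,
                     kras_in_actionable = TRUE) {
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0) abort("empty cohort")
  stopifnot_cols(samples, c("sample_id", "histology"), "sample table")
  if (!is.null(variants) && nrow(variants) > 0) {
    variants <- tibble::as_tibble(variants)
    if (!"retained" %in% names(variants)) variants$retained <- TRUE
    if (!"actionable" %in% names(variants)) {
      abort("variants must be annotated (see annotate_variants)")
    }
  }
  sets <- actionable_sets(samples$sample_id, variants, fusions)
  per_sample <- tibble::tibble(
    sample_id = samples$sample_id,
    histology = samples$histology,
    n_actionable_mut = lengths(sets$mut)[samples$sample_id],
    fusion_positive_genes = lengths(sets$fus)[samples$sample_id],
    category = eligibility_category(samples, variants, fusions))
  kras_only_mut <- vapply(samples$sample_id, function(s) {
    mg <- sets$mut[[s]] %||% character(0)
    length(mg) > 0 && all(mg == "KRAS") &&
      length(sets$fus[[s]] %||% character(0)) == 0
  }, logical(1), USE.NAMES = FALSE)
  per_sample$any_actionable <- per_sample$n_actionable_mut > 0 |
    per_sample$fusion_positive_genes > 0
  per_sample$any_actionable_excl_kras <- per_sample$any_actionable &
    !kras_only_mut
  if (!kras_in_actionable) {
    per_sample$any_actionable <- per_sample$any_actionable_excl_kras
  }

  # retained non-synonymous variant counts per sample (includes
  # non-actionable genes such as TP53)
  nonsyn <- if (!is.null(variants) && nrow(variants) > 0) {
    cls <- if ("variant_class" %in% names(variants)) variants$variant_class
           else "missense"
    v <- variants[variants$retained & !cls %in% c("synonymous"), ]
    table(factor(v$sample_id, levels = samples$sample_id))
  } else {
    table(factor(character(0), levels = samples$sample_id))
  }
  per_sample$n_variants <- as.integer(nonsyn[samples$sample_id])

  # fusion assay coverage
  if (!is.null(fusions) && nrow(fusions) > 0) {
    tested <- unique(fusions$sample_id)
    failed <- unique(fusions$sample_id[fusions$status == "QC_FAIL"])
    per_sample$fusion_tested <- per_sample$sample_id %in% tested
    per_sample$fusion_analyzable <- per_sample$fusion_tested &
      !per_sample$sample_id %in% failed
  } else {
    per_sample$fusion_tested <- FALSE
    per_sample$fusion_analyzable <- FALSE
  }

  summarize_group <- function(df, label) {
    n <- nrow(df)
    n_act <- sum(df$any_actionable)
    n_fa <- sum(df$fusion_analyzable)
    n_fp <- sum(df$fusion_analyzable & df$fusion_positive_genes > 0)
    tibble::tibble(
      group = label, n = n,
      n_actionable = n_act,
      pct_actionable = round1(100 * n_act / n),
      n_actionable_excl_kras = sum(df$any_actionable_excl_kras),
      pct_actionable_excl_kras = round1(100 * sum(df$any_actionable_excl_kras) / n),
      n_fusion_tested = sum(df$fusion_tested),
      n_fusion_analyzable = n_fa,
      n_fusion_positive = n_fp,
      pct_fusion_positive = if (n_fa > 0) round1(100 * n_fp / n_fa) else NA_real_)
  }
  group_labels <- c("overall", intersect(HISTOLOGIES,
                                         unique(per_sample$histology)),
                    setdiff(unique(per_sample$histology), HISTOLOGIES))
  groups <- purrr::map_dfr(group_labels, function(g) {
    df <- if (g == "overall") per_sample
          else per_sample[per_sample$histology == g, ]
    summarize_group(df, g)
  })

  eligibility <- per_sample |>
    dplyr::count(.data$histology, .data$category, name = "n") |>
    dplyr::group_by(.data$histology) |>
    dplyr::mutate(pct = round1(100 * .data$n / sum(.data$n))) |>
    dplyr::ungroup()

  histogram <- per_sample |>
    dplyr::mutate(bin = dplyr::case_when(.data$n_variants == 0 ~ "0",
                                         .data$n_variants <= 2 ~ "1-2",
                                         TRUE ~ ">2")) |>
    dplyr::count(.data$histology, .data$bin, name = "n")

  gene_distribution <- if (!is.null(variants) && nrow(variants) > 0) {
    variants |>
      dplyr::filter(.data$actionable) |>
      dplyr::left_join(samples[, c("sample_id", "histology")], by = "sample_id") |>
      dplyr::count(.data$histology, .data$gene, name = "n_actionable_variants")
  } else {
    tibble::tibble(histology = character(0), gene = character(0),
                   n_actionable_variants = integer(0))
  }

  structure(list(groups = groups, eligibility = eligibility,
                 variant_histogram = histogram,
                 gene_distribution = gene_distribution,
                 cooccurrence = cooccurrence_matrix(variants, fusions),
                 per_sample = per_sample),
            class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, ...) {
  cat("<stratification_report>\n")
  print(x$groups)
  invisible(x)
}
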