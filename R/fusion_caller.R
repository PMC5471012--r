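FUSION_STATUSES <- c("KNOWN_FUSION", "NOVEL_FUSION", "NEGATIVE", "QC_FAIL")

#' Caller thresholds for the probe-count fusion assay
#'
#' The assay plots, per gene, the maximum fusion-specific junction signal
#' against the 3'/5' expression ratio of probes flanking the tyrosine-kinase
#' exons. The two cut lines partition that plane into quadrants; the
#' housekeeping QC ratio gates which hybridizations are interpretable at
#' all. Numeric cut values are laboratory calibration parameters, not
#' constants of the method; the defaults separate the synthetic classes
#' generated by [generate_nanostring_batch()] with a wide margin.
#'
#' @param ratio_threshold 3'/5' imbalance ratio at or above which a gene is
#'   ratio-positive. Default 2.
#' @param specific_signal_threshold Normalized fusion-specific count at or
#'   above which the junction signal is positive. Default 50.
#' @param qc_ratio_threshold Housekeeping H/Hi ratio strictly above which a
#'   hybridization is a failure. Default 8.
#' @param background_sd_multiplier Multiplier k in the background estimate
#'   mean(neg) + k * sd(neg). Default 2.
#' @param pseudocount Added to both numerator and denominator means of the
#'   3'/5' ratio to avoid division by zero. Default 1.
#' @param reference_factor Target value for the geometric mean of the
#'   positive-control counts after scaling. Default 1000 (the expected
#'   geometric mean of the standard six-point titration).
#' @param reference_hk Calibrated housekeeping reference level H for the
#'   QC ratio, i.e. the geometric-mean housekeeping count expected from an
#'   intact-RNA hybridization. Default 1500. Set to `NULL` to fall back to
#'   the batch median ([batch_reference_hk()]), which detects relative
#'   degradation only.
#' @param gene_overrides Optional named list (by gene) of lists overriding
#'   `ratio_threshold` and/or `specific_signal_threshold` per gene.
#' @return A list of class `caller_thresholds`.
#' @export
caller_thresholds <- function(ratio_threshold = 2,
                              specific_signal_threshold = 50,
                              qc_ratio_threshold = 8,
                              background_sd_multiplier = 2,
                              pseudocount = 1,
                              reference_factor = 1000,
                              reference_hk = 1500,
                              gene_overrides = list()) {
  for (v in c(ratio_threshold, specific_signal_threshold, qc_ratio_threshold,
              reference_factor)) {
    if (!is.numeric(v) || v <= 0) abort("thresholds must be strictly positive")
  }
  if (background_sd_multiplier < 0) {
    abort("background_sd_multiplier must be >= 0")
  }
  structure(list(ratio_threshold = ratio_threshold,
                 specific_signal_threshold = specific_signal_threshold,
                 qc_ratio_threshold = qc_ratio_threshold,
                 background_sd_multiplier = background_sd_multiplier,
                 pseudocount = pseudocount,
                 reference_factor = reference_factor,
                 reference_hk = reference_hk,
                 gene_overrides = gene_overrides),
            class = "caller_thresholds")
}

threshold_for <- function(thresholds, gene, what) {
  ov <- thresholds$gene_overrides[[gene]]
  if (!is.null(ov) && !is.null(ov[[what]])) ov[[what]] else thresholds[[what]]
}

#' Subtract the negative-control background from a count profile
#'
#' The background estimate is mean(negative controls) +
#' `background_sd_multiplier` * sd(negative controls). It is subtracted from
#' every non-control probe (endogenous flank, fusion-specific and
#' housekeeping probes), flooring at zero; control counts are preserved for
#' downstream scaling and QC.
#'
#' @param profile A [count_profile()].
#' @param probe_set A [probe_set()].
#' @param thresholds A [caller_thresholds()].
#' @return The background-corrected `count_profile`.
#' @export
background_correct <- function(profile, probe_set,
                               thresholds = caller_thresholds()) {
  check_profile_complete(profile, probe_set)
  neg <- probes_role(probe_set, "neg_control")
  if (length(neg) == 0) {
    abort("probe set has no negative-control probes")
  }
  missing_neg <- neg[is.na(profile$counts[neg])]
  if (length(missing_neg) > 0) {
    abort(sprintf("negative-control counts missing for: %s",
                  paste(missing_neg, collapse = ", ")))
  }
  negc <- profile$counts[neg]
  bg <- mean(negc) + thresholds$background_sd_multiplier * sd(negc)
  ctrl <- probe_set$probe_id[probe_set$role %in% c("pos_control", "neg_control")]
  target <- setdiff(probe_set$probe_id, ctrl)
  profile$counts[target] <- pmax(profile$counts[target] - bg, 0)
  profile
}

#' Scale a profile against its positive controls
#'
#' Multiplies all non-control counts by `reference_factor` divided by the
#' geometric mean of the profile's positive-control counts, making every
#' downstream statistic invariant to global multiplicative factors on the
#' raw counts (lane/hybridization efficiency).
#'
#' @inheritParams background_correct
#' @param reference_factor Target positive-control geometric mean; defaults
#'   to the value in `thresholds`.
#' @return The scaled `count_profile`.
#' @export
scale_by_positive_controls <- function(profile, probe_set,
                                       thresholds = caller_thresholds(),
                                       reference_factor = thresholds$reference_factor) {
  check_profile_complete(profile, probe_set)
  pos <- probes_role(probe_set, "pos_control")
  posc <- profile$counts[pos]
  if (any(posc == 0)) {
    abort(sprintf("degenerate hybridization for %s: positive control(s) at zero count",
                  profile$sample_id))
  }
  f <- reference_factor / geomean(posc)
  ctrl <- probe_set$probe_id[probe_set$role %in% c("pos_control", "neg_control")]
  target <- setdiff(probe_set$probe_id, ctrl)
  profile$counts[target] <- profile$counts[target] * f
  profile
}

#' Housekeeping reference level of a batch
#'
#' The batch reference H is the median across profiles of each profile's
#' housekeeping-probe geometric mean, computed on raw (pre-scaling) counts.
#' The median keeps degraded profiles from dragging the reference down.
#'
#' @param profiles List of raw [count_profile()] objects.
#' @inheritParams background_correct
#' @return A single positive number.
#' @export
batch_reference_hk <- function(profiles, probe_set) {
  median(vapply(profiles, profile_hk_level, numeric(1), probe_set = probe_set))
}

profile_hk_level <- function(profile, probe_set) {
  hk <- probes_role(probe_set, "housekeeping")
  if (length(hk) == 0) abort("probe set has no housekeeping probes")
  geomean(pmax(profile$counts[hk], 0.5))  # guard log(0) on collapsed profiles
}

#' Housekeeping QC check for one hybridization
#'
#' Computes the QC ratio H / Hi, where H is the batch (or other reference)
#' housekeeping level and Hi the profile's own housekeeping geometric mean,
#' both on raw counts. Degraded RNA collapses housekeeping signal, inflating
#' the ratio; the hybridization fails iff the ratio strictly exceeds
#' `qc_ratio_threshold` (default 8).
#'
#' @inheritParams background_correct
#' @param reference_hk Reference housekeeping level H; defaults to the
#'   calibrated level in `thresholds`, or supply [batch_reference_hk()]
#'   for a batch-relative check.
#' @return A list with `pass` (logical) and `qc_ratio`.
#' @export
qc_check <- function(profile, probe_set, thresholds = caller_thresholds(),
                     reference_hk = thresholds$reference_hk) {
  if (is.null(reference_hk)) {
    abort("qc_check needs a reference housekeeping level")
  }
  check_profile_complete(profile, probe_set)
  ratio <- reference_hk / profile_hk_level(profile, probe_set)
  list(pass = !(ratio > thresholds$qc_ratio_threshold), qc_ratio = ratio)
}

#' 3'/5' imbalance ratio for one gene
#'
#' A fusion placing the kinase domain under a foreign promoter elevates the
#' probes 3' of the breakpoint relative to the 5' probes; whole-gene
#' overexpression elevates both and leaves the ratio near 1. Returns
#' (mean 3' counts + pseudocount) / (mean 5' counts + pseudocount) on the
#' corrected, scaled profile.
#'
#' @inheritParams background_correct
#' @param gene One of `"ALK"`, `"RET"`, `"ROS1"` (any gene in the probe set).
#' @param pseudocount Defaults to the value in `thresholds`.
#' @return A non-negative number.
#' @export
compute_ratio_3p5p <- function(profile, probe_set, gene,
                               thresholds = caller_thresholds(),
                               pseudocount = thresholds$pseudocount) {
  p5 <- probes_for(probe_set, gene, "five_prime")
  p3 <- probes_for(probe_set, gene, "three_prime")
  if (length(p5) == 0 || length(p3) == 0) {
    abort(sprintf("gene %s has no flank probes in this probe set", gene))
  }
  (mean(profile$counts[p3]) + pseudocount) /
    (mean(profile$counts[p5]) + pseudocount)
}

#' Maximum fusion-specific junction signal for one gene
#'
#' Returns the maximum corrected count over the gene's fusion-specific
#' probes and the fusion id attaining it; ties break to the
#' lexicographically smaller fusion id.
#'
#' @inheritParams compute_ratio_3p5p
#' @return A list with `max_specific_signal` and `best_fusion_id` (`NA` if
#'   the gene has no fusion-specific probes).
#' @export
compute_fusion_signal <- function(profile, probe_set, gene) {
  fs <- probe_set[probe_set$role == "fusion_specific" &
                    probe_set$gene %inn% gene, ]
  if (nrow(fs) == 0) {
    warn(sprintf("gene %s has no fusion-specific probes; signal is 0", gene))
    return(list(max_specific_signal = 0, best_fusion_id = NA_character_))
  }
  sig <- profile$counts[fs$probe_id]
  ord <- order(-sig, fs$fusion_id)[1]
  list(max_specific_signal = unname(sig[ord]), best_fusion_id = fs$fusion_id[ord])
}

#' Quadrant classification of one gene in one profile
#'
#' On the plane (3'/5' ratio, max fusion-specific signal): upper-right =
#' known fusion (both statistics at/above their cuts), lower-right = fusion
#' not covered by a junction probe (ratio positive, specific signal
#' negative), lower-left = negative. The upper-left quadrant (specific
#' signal without imbalance) is reported NEGATIVE with a warning flag, as
#' isolated junction signal without 3' elevation is uninterpretable.
#'
#' The profile must already have passed [qc_check()] and been through
#' [background_correct()] and [scale_by_positive_controls()].
#'
#' @inheritParams compute_ratio_3p5p
#' @param qc_ratio QC ratio to record in the call (optional).
#' @return A one-row tibble: `sample_id`, `gene`, `status`, `best_fusion_id`,
#'   `ratio_3p5p`, `max_specific_signal`, `qc_ratio`, `flag`.
#' @export
call_fusion <- function(profile, probe_set, thresholds = caller_thresholds(),
                        gene, qc_ratio = NA_real_) {
  ratio <- compute_ratio_3p5p(profile, probe_set, gene, thresholds)
  sig <- compute_fusion_signal(profile, probe_set, gene)
  rt <- threshold_for(thresholds, gene, "ratio_threshold")
  st <- threshold_for(thresholds, gene, "specific_signal_threshold")
  ratio_pos <- ratio >= rt
  sig_pos <- sig$max_specific_signal >= st
  status <- if (ratio_pos && sig_pos) "KNOWN_FUSION"
            else if (ratio_pos) "NOVEL_FUSION"
            else "NEGATIVE"
  flag <- if (!ratio_pos && sig_pos) "specific_signal_without_imbalance"
          else NA_character_
  tibble::tibble(
    sample_id = profile$sample_id,
    gene = gene,
    status = status,
    best_fusion_id = if (status == "KNOWN_FUSION") sig$best_fusion_id
                     else NA_character_,
    ratio_3p5p = ratio,
    max_specific_signal = sig$max_specific_signal,
    qc_ratio = qc_ratio,
    flag = flag
  )
}

#' Call fusions across a hybridization batch
#'
#' Runs QC on raw profiles, excludes failures (status `QC_FAIL` for every
#' gene), applies background correction and positive-control scaling to the
#' rest, classifies every gene in every analyzable profile, and summarizes
#' positivity per gene and overall. QC failures are excluded from all
#' positivity denominators.
#'
#' @param profiles Nonempty list of raw [count_profile()] objects.
#' @inheritParams background_correct
#' @param genes Genes to call; defaults to the probe set's flanked genes.
#' @param reference_hk Housekeeping reference; defaults to the calibrated
#'   level in `thresholds`, falling back to [batch_reference_hk()] of this
#'   batch when that is `NULL`.
#' @return A list of class `fusion_batch` with `calls` (tibble, one row per
#'   sample x gene) and `summary` (list: `n_profiles`, `n_failed`,
#'   `pct_failed`, `n_analyzed`, `n_positive`, `pct_positive`, and
#'   `per_gene` tibble). Percentages carry one decimal.
#' @export
call_batch <- function(profiles, probe_set, thresholds = caller_thresholds(),
                       genes = NULL, reference_hk = NULL) {
  if (length(profiles) == 0) abort("empty batch: no profiles to call")
  genes <- genes %||%
    sort(unique(probe_set$gene[probe_set$role == "five_prime"]))
  reference_hk <- reference_hk %||% thresholds$reference_hk %||%
    batch_reference_hk(profiles, probe_set)

  calls <- purrr::map_dfr(profiles, function(p) {
    qc <- qc_check(p, probe_set, thresholds, reference_hk)
    if (!qc$pass) {
      return(tibble::tibble(
        sample_id = p$sample_id, gene = genes, status = "QC_FAIL",
        best_fusion_id = NA_character_, ratio_3p5p = NA_real_,
        max_specific_signal = NA_real_, qc_ratio = qc$qc_ratio,
        flag = NA_character_))
    }
    corrected <- scale_by_positive_controls(
      background_correct(p, probe_set, thresholds), probe_set, thresholds)
    purrr::map_dfr(genes, function(g) {
      call_fusion(corrected, probe_set, thresholds, g, qc_ratio = qc$qc_ratio)
    })
  })

  failed_ids <- unique(calls$sample_id[calls$status == "QC_FAIL"])
  n_profiles <- length(profiles)
  n_failed <- length(failed_ids)
  n_analyzed <- n_profiles - n_failed
  positive <- calls$status %in% c("KNOWN_FUSION", "NOVEL_FUSION")
  pos_ids <- unique(calls$sample_id[positive])
  per_gene <- calls |>
    dplyr::filter(.data$status != "QC_FAIL") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_analyzed = dplyr::n(),
      n_positive = sum(.data$status %in% c("KNOWN_FUSION", "NOVEL_FUSION")),
      pct_positive = round1(100 * .data$n_positive / .data$n_analyzed),
      .groups = "drop")
  summary <- list(
    n_profiles = n_profiles,
    n_failed = n_failed,
    pct_failed = if (n_profiles > 0) round1(100 * n_failed / n_profiles) else NA_real_,
    n_analyzed = n_analyzed,
    n_positive = length(pos_ids),
    pct_positive = if (n_analyzed > 0) round1(100 * length(pos_ids) / n_analyzed)
                   else NA_real_,
    per_gene = per_gene)
  structure(list(calls = calls, summary = summary), class = "fusion_batch")
}

#' @export
print.fusion_batch <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<fusion_batch> %d profiles: %d failed QC (%.1f%%), %d/%d analyzable positive (%.1f%%)\n",
    s$n_profiles, s$n_failed, s$pct_failed, s$n_positive, s$n_analyzed,
    s$pct_positive))
  print(s$per_gene)
  invisible(x)
}
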