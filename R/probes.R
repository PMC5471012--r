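PROBE_ROLES <- c("five_prime", "three_prime", "fusion_specific",
                 "housekeeping", "pos_control", "neg_control")

FUSION_GENES <- c("ALK", "RET", "ROS1")

#' Construct and validate a fusion-assay probe set
#'
#' A probe set annotates every probe on the codeset with its role in the
#' caller: 5'- and 3'-flank probes bracketing the tyrosine-kinase exons of
#' each target gene, junction-spanning fusion-specific probes, housekeeping
#' probes used for RNA-integrity QC, and the spiked positive/negative
#' controls used for scaling and background estimation.
#'
#' @param probes A data frame with columns `probe_id`, `gene`, `role`,
#'   `fusion_id`, `nominal_amount`. `gene` is `NA` for shared
#'   (housekeeping/control) probes; `fusion_id` is set only for
#'   `fusion_specific` probes; `nominal_amount` (input amount in fM) only
#'   for `pos_control` probes.
#' @return A tibble of class `probe_set`.
#' @export
#' @examples
#' ps <- default_probe_set()
#' table(ps$role)
probe_set <- function(probes) {
  probes <- tibble::as_tibble(probes)
  stopifnot_cols(probes, c("probe_id", "gene", "role", "fusion_id",
                           "nominal_amount"), "probe set")
  if (anyDuplicated(probes$probe_id)) {
    abort("probe ids must be unique across roles")
  }
  bad_role <- setdiff(unique(probes$role), PROBE_ROLES)
  if (length(bad_role) > 0) {
    abort(sprintf("unknown probe role(s): %s", paste(bad_role, collapse = ", ")))
  }
  fs <- probes[probes$role == "fusion_specific", ]
  if (any(is.na(fs$fusion_id)) || any(is.na(fs$gene))) {
    abort("every fusion-specific probe must carry a gene and a fusion id")
  }
  for (g in intersect(FUSION_GENES, unique(probes$gene))) {
    for (side in c("five_prime", "three_prime")) {
      if (sum(probes$gene == g & probes$role == side, na.rm = TRUE) < 1) {
        abort(sprintf("gene %s needs at least one %s probe", g, side))
      }
    }
  }
  if (sum(probes$role == "housekeeping") < 1) {
    abort("probe set needs housekeeping probes")
  }
  if (sum(probes$role == "neg_control") < 2 ||
      sum(probes$role == "pos_control") < 2) {
    abort("probe set needs at least two positive and two negative controls")
  }
  class(probes) <- c("probe_set", class(probes))
  probes
}

#' Default ALK/RET/ROS1 probe set shipped with the package
#'
#' Three 5'-flank and three 3'-flank probes per target gene, toehold-style
#' fusion-specific probes for the recurrent EML4-ALK, NPM1-ALK, KIF5B-ALK,
#' CCDC6-RET, KIF5B-RET, NCOA4-RET, SLC34A2-ROS1, SDC4-ROS1, CD74-ROS1 and
#' EZR-ROS1 junctions, seven housekeeping probes and the standard
#' six-point positive-control titration plus negative controls.
#'
#' @return A `probe_set` tibble.
#' @export
default_probe_set <- function() {
  read_probe_table(system.file("extdata", "probe_set.tsv", package = "lungdx",
                               mustWork = TRUE))
}

probes_for <- function(probe_set, gene, role) {
  probe_set$probe_id[probe_set$role == role & probe_set$gene %inn% gene]
}

probes_role <- function(probe_set, role) {
  probe_set$probe_id[probe_set$role == role]
}

#' Construct a per-sample probe count profile
#'
#' @param sample_id Sample identifier.
#' @param counts Named non-negative numeric vector, names are probe ids.
#' @param batch_id Hybridization batch identifier.
#' @return A list of class `count_profile` with fields `sample_id`,
#'   `counts`, `batch_id`.
#' @export
count_profile <- function(sample_id, counts, batch_id = "batch1") {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("counts must be a named vector of probe counts")
  }
  if (any(counts < 0)) abort("probe counts must be non-negative")
  structure(list(sample_id = as.character(sample_id),
                 counts = counts,
                 batch_id = as.character(batch_id)),
            class = "count_profile")
}

#' @export
print.count_profile <- function(x, ...) {
  cat(sprintf("<count_profile> sample %s, batch %s, %d probes\n",
              x$sample_id, x$batch_id, length(x$counts)))
  invisible(x)
}

check_profile_complete <- function(profile, probe_set) {
  missing <- setdiff(probe_set$probe_id, names(profile$counts))
  if (length(missing) > 0) {
    abort(sprintf("profile %s is missing probe(s): %s", profile$sample_id,
                  paste(head(missing, 5), collapse = ", ")))
  }
  invisible(profile)
}

#' Convert between profile lists and a probes-by-samples count matrix
#'
#' @param profiles List of [count_profile()] objects sharing a probe set.
#' @return `profiles_to_matrix()`: numeric matrix, rows probes, columns
#'   samples. `matrix_to_profiles()`: list of `count_profile`.
#' @export
profiles_to_matrix <- function(profiles) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  probes <- names(profiles[[1]]$counts)
  m <- vapply(profiles, function(p) p$counts[probes], numeric(length(probes)))
  dimnames(m) <- list(probes, ids)
  m
}

#' @param counts Probes-by-samples matrix with dimnames.
#' @param batch_id Batch identifier attached to every profile.
#' @rdname profiles_to_matrix
#' @export
matrix_to_profiles <- function(counts, batch_id = "batch1") {
  lapply(colnames(counts), function(s) {
    count_profile(s, setNames(counts[, s], rownames(counts)), batch_id)
  })
}
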