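provenance_header <- function(seed = NULL) {
  c(sprintf("# lungdx %s", as.character(packageVersion("lungdx"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
}

write_with_header <- function(df, path, delim, header_lines) {
  writeLines(header_lines, path)
  readr::write_delim(df, path, delim = delim, na = ".", append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

read_table_checked <- function(path, delim, required, what) {
  df <- readr::read_delim(path, delim = delim, comment = "#", na = ".",
                          show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s %s is missing required column(s): %s", what, path,
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    warn(sprintf("%s %s has unknown column(s) (preserved): %s", what, path,
                 paste(extra, collapse = ", ")))
  }
  df
}

#' Read / write the package's delimited interchange formats
#'
#' All files are UTF-8 with a header row, `.` for missing values, and `#`
#' comment lines carrying provenance (package version and seed). Variant,
#' paired-call and probe tables are tab-separated; the count matrix is
#' CSV with probes as rows and samples as columns.
#'
#' @param path File path.
#' @param variants,calls,probes,counts Object to write.
#' @param seed Seed recorded in the provenance header (optional).
#' @return Readers return tibbles (or a matrix / `probe_set`); writers
#'   return the path invisibly.
#' @name lungdx-io
NULL

#' @rdname lungdx-io
#' @export
read_variant_table <- function(path) {
  df <- read_table_checked(path, "\t", VARIANT_COLS, "variant table")
  df$exon <- as.integer(df$exon)
  validate_variants(df)
}

#' @rdname lungdx-io
#' @export
write_variant_table <- function(variants, path, seed = NULL) {
  write_with_header(variants, path, "\t", provenance_header(seed))
}

PAIRED_CALL_COLS <- c("sample_id", "cohort", "gene", "ref_call", "test_call",
                      "ref_protein_change", "ref_coding_change",
                      "test_protein_change", "test_coding_change", "in_scope")

#' @rdname lungdx-io
#' @export
read_paired_call_table <- function(path) {
  read_table_checked(path, "\t", PAIRED_CALL_COLS, "paired-call table")
}

#' @rdname lungdx-io
#' @export
write_paired_call_table <- function(calls, path, seed = NULL) {
  write_with_header(calls, path, "\t", provenance_header(seed))
}

#' @rdname lungdx-io
#' @export
read_probe_table <- function(path) {
  df <- read_table_checked(path, "\t",
                           c("probe_id", "gene", "role", "fusion_id",
                             "nominal_amount"), "probe table")
  df$nominal_amount <- as.numeric(df$nominal_amount)
  probe_set(df)
}

#' @rdname lungdx-io
#' @export
write_probe_table <- function(probes, path, seed = NULL) {
  write_with_header(tibble::as_tibble(probes), path, "\t",
                    provenance_header(seed))
}

#' @rdname lungdx-io
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (names(df)[1] != "probe_id") {
    abort(sprintf("count matrix %s must have probe_id as its first column",
                  path))
  }
  m <- as.matrix(df[, -1])
  rownames(m) <- df$probe_id
  m
}

#' @rdname lungdx-io
#' @export
write_count_matrix <- function(counts, path, seed = NULL) {
  df <- tibble::as_tibble(counts, rownames = "probe_id")
  write_with_header(df, path, ",", provenance_header(seed))
}

#' Read caller thresholds from a YAML config
#'
#' Recognized keys mirror the arguments of [caller_thresholds()]; absent
#' keys keep their defaults. `gene_overrides` is a map gene -> thresholds.
#'
#' @param path YAML file.
#' @return A [caller_thresholds()] object.
#' @export
read_caller_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(caller_thresholds, cfg)
}

#' Write a report object as pretty JSON
#'
#' Strips S3 classes so reports (concordance, batch summary,
#' stratification) serialize as plain JSON objects; matrices become
#' row-major arrays with a separate `genes` vector.
#'
#' @param report A report object or list.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.matrix(x)) {
    return(list(genes = rownames(x), counts = unname(apply(x, 1, as.list))))
  }
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
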