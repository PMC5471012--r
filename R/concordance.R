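call_agrees <- function(calls) {
  same_verdict <- calls$ref_call == calls$test_call
  both_mut <- calls$ref_call == "mutation" & calls$test_call == "mutation"
  # variant identity: protein change when both report it, else coding change
  have_protein <- !is.na(calls$ref_protein_change) &
    !is.na(calls$test_protein_change)
  ident <- ifelse(have_protein,
                  normalize_protein(calls$ref_protein_change) ==
                    normalize_protein(calls$test_protein_change),
                  calls$ref_coding_change == calls$test_coding_change)
  same_verdict & (!both_mut | ident)
}

#' Concordance between a reference assay and the test panel
#'
#' A call is concordant when both methods agree on mutation vs no
#' mutation at the locus, comparing variant identity when both report a
#' mutation. With `exclude_out_of_scope`, calls flagged `in_scope = FALSE`
#' (panel-only variants at loci the single-gene reference assay does not
#' interrogate) are removed from both numerator and denominator.
#'
#' @param calls Paired-call tibble as produced by
#'   [generate_paired_calls()] (columns `ref_call`, `test_call`,
#'   `ref_protein_change`, `ref_coding_change`, `test_protein_change`,
#'   `test_coding_change`, `in_scope`).
#' @param exclude_out_of_scope Drop out-of-scope rows first? Default FALSE.
#' @return List of class `concordance_report`: `n_total`, `n_concordant`,
#'   `percent` (one decimal), `percent_int` (nearest integer, the headline
#'   rendering), `n_out_of_scope_excluded`.
#' @export
evaluate_concordance <- function(calls, exclude_out_of_scope = FALSE) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) abort("no paired calls to evaluate")
  stopifnot_cols(calls, c("ref_call", "test_call", "in_scope"),
                 "paired-call table")
  n_excluded <- 0L
  if (exclude_out_of_scope) {
    n_excluded <- sum(!calls$in_scope)
    calls <- calls[calls$in_scope, ]
    if (nrow(calls) == 0) abort("all calls were out of scope")
  }
  conc <- sum(call_agrees(calls))
  pct <- 100 * conc / nrow(calls)
  structure(list(n_total = nrow(calls), n_concordant = conc,
                 percent = round1(pct), percent_int = round(pct),
                 n_out_of_scope_excluded = n_excluded),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d/%d concordant (%d%%)",
              x$n_concordant, x$n_total, x$percent_int))
  if (x$n_out_of_scope_excluded > 0) {
    cat(sprintf(" after excluding %d out-of-scope call(s)",
                x$n_out_of_scope_excluded))
  }
  cat("\n")
  invisible(x)
}

#' Per-gene mutation / no-mutation call counts
#'
#' Tabulates the reference method's verdicts per gene, with a final
#' `total` row.
#'
#' @param calls Paired-call tibble (columns `gene`, `ref_call`).
#' @return Tibble with columns `gene`, `n_mutation`, `n_no_mutation`; the
#'   last row has `gene == "total"`.
#' @export
tabulate_by_gene <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) abort("no paired calls to tabulate")
  by_gene <- calls |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_mutation = sum(.data$ref_call == "mutation"),
                     n_no_mutation = sum(.data$ref_call == "no_mutation"),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene)
  dplyr::bind_rows(by_gene,
                   tibble::tibble(gene = "total",
                                  n_mutation = sum(by_gene$n_mutation),
                                  n_no_mutation = sum(by_gene$n_no_mutation)))
}
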