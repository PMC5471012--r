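AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V", Ter = "*")

VARIANT_CLASSES <- c("missense", "nonsense", "inframe_del", "inframe_ins",
                     "frameshift", "splice", "synonymous", "other")

normalize_protein <- function(x) {
  x <- stringr::str_trim(x)
  x <- stringr::str_remove(x, "^p\\.")
  x <- stringr::str_remove_all(x, "[()]")
  # three-letter -> one-letter amino-acid codes
  for (code in names(AA3)) {
    x <- gsub(code, AA3[[code]], x, fixed = TRUE)
  }
  x
}

parse_one_protein <- function(x) {
  none <- list(codon = NA_integer_, ref_aa = NA_character_,
               alt_aa = NA_character_, variant_class = "other")
  if (is.na(x) || !nzchar(stringr::str_trim(x))) return(none)
  raw <- stringr::str_trim(x)
  # "exon19del" / "exon 20 insertion" aliases carry no codon
  m <- stringr::str_match(tolower(raw), "^exon\\s*([0-9]+)\\s*(del(etion)?|ins(ertion)?)$")
  if (!is.na(m[1, 1])) {
    cls <- if (startsWith(m[1, 3], "del")) "inframe_del" else "inframe_ins"
    return(list(codon = NA_integer_, ref_aa = NA_character_,
                alt_aa = NA_character_, variant_class = cls))
  }
  p <- normalize_protein(raw)
  m <- stringr::str_match(p, "^([A-Z*])([0-9]+)([A-Z*]*)fs.*$")
  if (!is.na(m[1, 1])) {
    return(list(codon = as.integer(m[1, 3]), ref_aa = m[1, 2],
                alt_aa = NA_character_, variant_class = "frameshift"))
  }
  m <- stringr::str_match(p, "^([A-Z*])([0-9]+)(_[A-Z*][0-9]+)?delins[A-Z*]+$")
  if (!is.na(m[1, 1])) {
    return(list(codon = as.integer(m[1, 3]), ref_aa = m[1, 2],
                alt_aa = NA_character_, variant_class = "inframe_ins"))
  }
  m <- stringr::str_match(p, "^([A-Z*])([0-9]+)(_[A-Z*][0-9]+)?del$")
  if (!is.na(m[1, 1])) {
    return(list(codon = as.integer(m[1, 3]), ref_aa = m[1, 2],
                alt_aa = NA_character_, variant_class = "inframe_del"))
  }
  m <- stringr::str_match(p, "^([A-Z*])([0-9]+)(_[A-Z*][0-9]+)?(dup|ins[A-Z*]+)$")
  if (!is.na(m[1, 1])) {
    return(list(codon = as.integer(m[1, 3]), ref_aa = m[1, 2],
                alt_aa = NA_character_, variant_class = "inframe_ins"))
  }
  m <- stringr::str_match(p, "^([A-Z])([0-9]+)([A-Z*=])$")
  if (!is.na(m[1, 1])) {
    ref <- m[1, 2]; alt <- m[1, 4]
    cls <- if (alt == "*") "nonsense"
           else if (alt == "=" || alt == ref) "synonymous"
           else "missense"
    return(list(codon = as.integer(m[1, 3]), ref_aa = ref,
                alt_aa = if (alt == "=") ref else alt, variant_class = cls))
  }
  none
}

#' Parse an HGVS-like protein change
#'
#' Total function over free text: extracts the first affected codon and a
#' variant class from notations like `p.L858R`, `L858R`, `p.Leu858Arg`,
#' `p.E746_A750del`, `p.A767_V769dup`, `T790fs`, and the `exon19del` /
#' `exon 20 insertion` aliases. Anything unparseable yields class `other`
#' with `NA` codon; no input raises an error.
#'
#' @param notation Character vector of protein-change notations.
#' @return A tibble with columns `notation`, `codon`, `ref_aa`, `alt_aa`,
#'   `variant_class`.
#' @export
#' @examples
#' parse_protein_change(c("p.L858R", "p.E746_A750del", "p.Leu858Arg", ""))
parse_protein_change <- function(notation) {
  parsed <- lapply(as.character(notation), parse_one_protein)
  tibble::tibble(
    notation = as.character(notation),
    codon = vapply(parsed, function(p) p$codon, integer(1)),
    ref_aa = vapply(parsed, function(p) p$ref_aa, character(1)),
    alt_aa = vapply(parsed, function(p) p$alt_aa, character(1)),
    variant_class = vapply(parsed, function(p) p$variant_class, character(1))
  )
}

VARIANT_COLS <- c("sample_id", "gene", "coding_change", "protein_change",
                  "exon", "vaf", "detected_in_pool_a", "detected_in_pool_b",
                  "coverage")

validate_variants <- function(variants) {
  variants <- tibble::as_tibble(variants)
  stopifnot_cols(variants, VARIANT_COLS, "variant table")
  no_notation <- is.na(variants$coding_change) & is.na(variants$protein_change)
  if (any(no_notation)) {
    abort("every variant needs a coding or a protein change")
  }
  if (any(!is.na(variants$vaf) & (variants$vaf <= 0 | variants$vaf > 1))) {
    abort("VAF must lie in (0, 1]")
  }
  variants
}

#' Apply the panel's variant-retention filters
#'
#' A variant is retained iff it was detected in both library pools of the
#' bidirectional assay, its base coverage strictly exceeds `min_coverage`,
#' and its VAF is at or above `min_vaf` (the limit of detection is
#' inclusive; the coverage threshold is strict). The first failing rule in
#' the order pool -> coverage -> VAF is recorded as the rejection reason.
#'
#' @param variants Variant tibble (columns `sample_id`, `gene`,
#'   `coding_change`, `protein_change`, `exon`, `vaf`,
#'   `detected_in_pool_a`, `detected_in_pool_b`, `coverage`).
#' @param min_vaf Limit of detection as a fraction; default 0.04.
#' @param min_coverage Strict coverage threshold; default 1000.
#' @return The input with `retained` (logical) and `rejection_reason`
#'   (`NA`, `"pool_discordance"`, `"low_coverage"` or `"low_vaf"`) added.
#' @export
filter_variants <- function(variants, min_vaf = 0.04, min_coverage = 1000) {
  variants <- validate_variants(variants)
  both_pools <- variants$detected_in_pool_a & variants$detected_in_pool_b
  cov_ok <- variants$coverage > min_coverage
  vaf_ok <- variants$vaf >= min_vaf
  variants$retained <- both_pools & cov_ok & vaf_ok
  variants$rejection_reason <- dplyr::case_when(
    !both_pools ~ "pool_discordance",
    !cov_ok ~ "low_coverage",
    !vaf_ok ~ "low_vaf",
    TRUE ~ NA_character_)
  variants
}

#' Read the panel region definition (gene to exon sets)
#'
#' @param path TSV with columns `gene` and `exons` (comma-separated exon
#'   numbers). Defaults to the shipped 26-gene exon-focused panel.
#' @return A named list mapping gene symbol to an integer vector of exons.
#' @export
read_panel <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tst_panel.tsv",
                                package = "lungdx", mustWork = TRUE)
  df <- readr::read_tsv(path, col_types = "cc", comment = "#", progress = FALSE)
  stopifnot_cols(df, c("gene", "exons"), "panel file")
  exons <- lapply(strsplit(df$exons, ","), function(e) as.integer(e))
  if (any(lengths(exons) == 0)) abort("panel file has a gene with no exons")
  setNames(exons, df$gene)
}

#' Default shipped 26-gene panel definition
#' @return Named list, gene to exon vector.
#' @export
default_panel <- function() read_panel()

#' Test whether variants fall in the panel's interrogated regions
#'
#' TRUE iff the gene is on the panel and the exon (when recorded) is among
#' that gene's sequenced exons; used to validate synthetic inputs and flag
#' impossible records.
#'
#' @param variants Variant tibble (needs `gene`, `exon`).
#' @param panel Panel definition from [read_panel()].
#' @return Logical vector along the rows of `variants`.
#' @export
check_panel_membership <- function(variants, panel = default_panel()) {
  mapply(function(g, e) {
    if (!g %in% names(panel)) return(FALSE)
    is.na(e) || e %in% panel[[g]]
  }, variants$gene, variants$exon, USE.NAMES = FALSE)
}

#' Load actionability rules from a YAML file
#'
#' Each rule names a gene and one match kind: `codon_set` (set of protein
#' codons), `named_protein_change` (exact substitution such as `T790M`), or
#' `exon_event` (exon number plus variant class, e.g. exon 19
#' inframe deletion). Rules apply in file order; the loader rejects genes
#' absent from the panel and overlapping codon sets within a gene.
#'
#' @param path YAML rule file; defaults to the shipped curated NSCLC set.
#' @param panel Panel definition used to validate rule genes.
#' @return Tibble of class `actionability_rules` with columns `rule_id`,
#'   `gene`, `kind`, `codons` (list), `protein_change`, `event_exon`,
#'   `event_class`, `tier`.
#' @export
read_actionability_rules <- function(path = NULL, panel = default_panel()) {
  path <- path %||% system.file("extdata", "actionability_rules.yaml",
                                package = "lungdx", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  rules <- tibble::tibble(
    rule_id = vapply(raw, function(r) r$id, character(1)),
    gene = vapply(raw, function(r) r$gene, character(1)),
    kind = vapply(raw, function(r) r$kind, character(1)),
    codons = lapply(raw, function(r) as.integer(r$codons %||% integer(0))),
    protein_change = vapply(raw, function(r) r$protein_change %||% NA_character_,
                            character(1)),
    event_exon = vapply(raw, function(r) as.integer(r$event_exon %||% NA),
                        integer(1)),
    event_class = vapply(raw, function(r) r$event_class %||% NA_character_,
                         character(1)),
    tier = vapply(raw, function(r) r$tier, character(1))
  )
  unknown <- setdiff(rules$gene, names(panel))
  if (length(unknown) > 0) {
    abort(sprintf("rule file names gene(s) outside the panel: %s",
                  paste(unknown, collapse = ", ")))
  }
  bad_kind <- setdiff(rules$kind,
                      c("codon_set", "named_protein_change", "exon_event"))
  if (length(bad_kind) > 0) {
    abort(sprintf("unknown rule kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  for (g in unique(rules$gene[rules$kind == "codon_set"])) {
    sets <- rules$codons[rules$gene == g & rules$kind == "codon_set"]
    all_codons <- unlist(sets)
    if (anyDuplicated(all_codons)) {
      abort(sprintf("codon sets for gene %s overlap", g))
    }
  }
  class(rules) <- c("actionability_rules", class(rules))
  rules
}

#' Default shipped actionability rules
#' @return An `actionability_rules` tibble.
#' @export
default_actionability_rules <- function() read_actionability_rules()

# match one parsed variant row against one rule
rule_matches <- function(rule, gene, codon, protein_norm, exon, variant_class) {
  if (gene != rule$gene) return(FALSE)
  switch(rule$kind,
    codon_set = !is.na(codon) && codon %in% rule$codons[[1]] &&
      variant_class %in% c("missense", "inframe_del", "inframe_ins"),
    named_protein_change = !is.na(protein_norm) &&
      protein_norm == rule$protein_change,
    exon_event = !is.na(exon) && exon == rule$event_exon &&
      variant_class == rule$event_class,
    FALSE)
}

#' Classify retained variants against the actionability rules
#'
#' Applies the rule set in file order to every retained, parsed variant;
#' the first matching rule supplies the verdict and therapy tier.
#' Non-retained variants are never actionable.
#'
#' @param variants Output of [annotate_variants()] or a variant tibble with
#'   `retained`, `codon`, `variant_class` columns (they are computed when
#'   absent).
#' @param rules An `actionability_rules` tibble.
#' @param t790m_actionable Should EGFR T790M count as actionable rather
#'   than only as a resistance annotation? Default TRUE.
#' @return The input with `actionable` (logical), `rule_id`, `tier` added.
#' @export
classify_actionable <- function(variants, rules = default_actionability_rules(),
                                t790m_actionable = TRUE) {
  variants <- tibble::as_tibble(variants)
  if (!"retained" %in% names(variants)) variants <- filter_variants(variants)
  if (!"codon" %in% names(variants)) {
    parsed <- parse_protein_change(variants$protein_change)
    variants$codon <- parsed$codon
    variants$variant_class <- parsed$variant_class
  }
  if (!t790m_actionable) {
    rules <- rules[!(rules$kind == "named_protein_change" &
                       rules$protein_change == "T790M"), ]
  }
  protein_norm <- ifelse(is.na(variants$protein_change), NA_character_,
                         normalize_protein(variants$protein_change))
  n <- nrow(variants)
  variants$actionable <- logical(n)
  variants$rule_id <- NA_character_
  variants$tier <- NA_character_
  for (i in seq_len(n)) {
    if (!variants$retained[i]) next
    for (j in seq_len(nrow(rules))) {
      if (rule_matches(rules[j, ], variants$gene[i], variants$codon[i],
                       protein_norm[i], variants$exon[i],
                       variants$variant_class[i])) {
        variants$actionable[i] <- TRUE
        variants$rule_id[i] <- rules$rule_id[j]
        variants$tier[i] <- rules$tier[j]
        break
      }
    }
  }
  variants
}

#' Full per-variant annotation: filter, parse, classify
#'
#' Convenience wrapper chaining [filter_variants()],
#' [parse_protein_change()] and [classify_actionable()]; the unit of output
#' is one annotated variant with retention flag, rejection reason, codon,
#' variant class, actionability verdict and matched rule.
#'
#' @inheritParams filter_variants
#' @inheritParams classify_actionable
#' @param panel Panel definition; adds an `in_panel` column.
#' @return Annotated variant tibble.
#' @export
annotate_variants <- function(variants, min_vaf = 0.04, min_coverage = 1000,
                              rules = default_actionability_rules(),
                              panel = default_panel(),
                              t790m_actionable = TRUE) {
  out <- filter_variants(variants, min_vaf, min_coverage)
  parsed <- parse_protein_change(out$protein_change)
  out$codon <- parsed$codon
  out$variant_class <- parsed$variant_class
  # coding-only records with intronic offsets are splice-site events
  splice <- out$variant_class == "other" & !is.na(out$coding_change) &
    stringr::str_detect(out$coding_change, "[0-9]+[+-][0-9]+")
  out$variant_class[splice] <- "splice"
  out$in_panel <- check_panel_membership(out, panel)
  classify_actionable(out, rules, t790m_actionable)
}
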