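MOI_LEVELS <- c("AD", "AR", "XL", "SD")
ACMG_VERSIONS <- c("v1.0", "v2.0", "v3.0", "v3.1")
CATEGORY_LEVELS <- c("CVD", "cancer", "metabolic", "eye", "urinary",
                     "respiratory", "endocrine", "hematologic",
                     "dermatologic", "other")
EVIDENCE_GRADES <- c("A", "B", "C", "D", "N")

#' Total actionability score of gene-disease pairs
#'
#' The semiquantitative actionability rubric scores each gene-disease pair on
#' four 0-3 components: disease severity (3 = sudden death ... 0 = minimal or
#' no morbidity), likelihood of disease (3 = >40% chance ... 0 = <1% or
#' unknown), effectiveness of intervention (3 = highly effective ... 0 =
#' ineffective/none), and nature of the intervention (3 = low-risk/acceptable
#' ... 0 = high-risk/poor). The total is the plain sum, range 0-12. Evidence
#' grades (A-D/N) attach to the likelihood and effectiveness components but
#' are descriptive only and never enter the total.
#'
#' @param severity,likelihood,effectiveness,nature Integer vectors in 0-3.
#' @return Integer vector of totals in 0-12.
#' @examples
#' score_total(3, 2, 3, 2) # 10
#' @export
score_total <- function(severity, likelihood, effectiveness, nature) {
  comp <- list(severity = severity, likelihood = likelihood,
               effectiveness = effectiveness, nature = nature)
  for (nm in names(comp)) {
    v <- comp[[nm]]
    bad <- is.na(v) | v < 0 | v > 3 | v != trunc(v)
    if (any(bad)) {
      validation_error(
        sprintf("Score component `%s` must be an integer in [0, 3].", nm),
        which(bad)
      )
    }
  }
  as.integer(severity + likelihood + effectiveness + nature)
}

#' Add the total actionability score to a panel
#'
#' @param panel A panel tibble with `severity`, `likelihood`,
#'   `effectiveness`, `nature` columns.
#' @return The panel with a `score` column appended (recomputed if present).
#' @export
score_panel <- function(panel) {
  dplyr::mutate(
    panel,
    score = score_total(.data$severity, .data$likelihood,
                        .data$effectiveness, .data$nature)
  )
}

#' Retain gene-disease pairs at or above a score threshold
#'
#' The selection rule used to build a candidate actionable-gene list: keep
#' every scored pair whose total is at least `threshold` (default 10 of 12).
#' Input order is preserved. The final expert curation beyond the score is
#' not an algorithm; it is carried by the panel's `curated` column.
#'
#' @param panel A panel tibble; each row must have the four score components.
#' @param threshold Minimum total score to retain (default 10).
#' @return The retained rows, with a `score` column.
#' @examples
#' p <- tibble::tibble(gene = c("A", "B"), disease = c("a", "b"),
#'                     severity = c(3, 2), likelihood = c(2, 2),
#'                     effectiveness = c(3, 2), nature = c(2, 2))
#' select_actionable(p)$gene # "A" (score 10); B scores 8
#' @export
select_actionable <- function(panel, threshold = 10) {
  need <- c("severity", "likelihood", "effectiveness", "nature")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    validation_error("Panel rows are missing score components.", missing_cols)
  }
  if (nrow(panel) == 0) {
    return(dplyr::mutate(panel, score = integer(0)))
  }
  incomplete <- !stats::complete.cases(panel[need])
  if (any(incomplete)) {
    validation_error("Every pair must carry a full actionability score.",
                     paste0(panel$gene[incomplete], "/", panel$disease[incomplete]))
  }
  panel <- score_panel(panel)
  dplyr::filter(panel, .data$score >= threshold)
}

validate_panel <- function(panel, name = "panel") {
  need <- c("gene", "disease", "moi", "versions", "category", "hpo_terms")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    validation_error(sprintf("Panel `%s` lacks required columns.", name),
                     missing_cols)
  }
  dup <- duplicated(panel[c("gene", "disease")])
  if (any(dup)) {
    validation_error("Duplicate (gene, disease) keys in panel.",
                     paste0(panel$gene[dup], "/", panel$disease[dup]))
  }
  bad_moi <- !panel$moi %in% MOI_LEVELS
  if (any(bad_moi)) {
    validation_error(
      sprintf("Unknown mode of inheritance (allowed: %s).",
              paste(MOI_LEVELS, collapse = ", ")),
      paste0(panel$gene[bad_moi], ": ", panel$moi[bad_moi])
    )
  }
  bad_ver <- vapply(panel$versions,
                    function(v) length(setdiff(v, ACMG_VERSIONS)) > 0,
                    logical(1))
  if (any(bad_ver)) {
    validation_error("Unknown panel version labels.",
                     panel$gene[bad_ver])
  }
  bad_cat <- !panel$category %in% CATEGORY_LEVELS
  if (any(bad_cat)) {
    validation_error("Unknown disease category.",
                     paste0(panel$gene[bad_cat], ": ", panel$category[bad_cat]))
  }
  bad_hpo <- vapply(panel$hpo_terms, function(v) {
    length(v) > 0 && !all(grepl("^HP:\\d{7}$", v))
  }, logical(1))
  if (any(bad_hpo)) {
    validation_error("Malformed HPO term ids (expect HP:NNNNNNN).",
                     panel$gene[bad_hpo])
  }
  invisible(panel)
}

#' Read a gene-disease panel from a TSV file
#'
#' Expected UTF-8 tab-separated columns: `gene, disease, moi, versions,
#' category, severity, likelihood, likelihood_ev, effectiveness,
#' effectiveness_ev, nature, curated, hpo_terms`. `versions` and `hpo_terms`
#' are semicolon-separated; score columns may be empty (ACMG-listed pairs
#' carry no rubric score). Duplicate (gene, disease) keys and unknown
#' mode-of-inheritance or category vocabulary are rejected.
#'
#' @param path Path to the TSV file.
#' @param name Panel name recorded in the `panel_name` attribute.
#' @return A tibble with one row per gene-disease pair; `versions` and
#'   `hpo_terms` are list-columns of character vectors.
#' @export
read_panel <- function(path, name = basename(path)) {
  if (!file.exists(path)) {
    validation_error("Panel file does not exist.", path)
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene = readr::col_character(),
      disease = readr::col_character(),
      moi = readr::col_character(),
      versions = readr::col_character(),
      category = readr::col_character(),
      severity = readr::col_integer(),
      likelihood = readr::col_integer(),
      likelihood_ev = readr::col_character(),
      effectiveness = readr::col_integer(),
      effectiveness_ev = readr::col_character(),
      nature = readr::col_integer(),
      curated = readr::col_logical(),
      hpo_terms = readr::col_character()
    ),
    progress = FALSE
  )
  panel <- dplyr::mutate(
    raw,
    versions = split_semi(.data$versions),
    hpo_terms = split_semi(.data$hpo_terms)
  )
  bad_ev <- !(is.na(panel$likelihood_ev) | panel$likelihood_ev %in% EVIDENCE_GRADES) |
    !(is.na(panel$effectiveness_ev) | panel$effectiveness_ev %in% EVIDENCE_GRADES)
  if (any(bad_ev)) {
    validation_error("Evidence grades must be one of A, B, C, D, N.",
                     panel$gene[bad_ev])
  }
  validate_panel(panel, name)
  attr(panel, "panel_name") <- name
  panel
}

#' Write a panel to TSV
#'
#' Inverse of [read_panel()]; list-columns are re-joined with semicolons.
#'
#' @param panel A panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- dplyr::mutate(
    panel,
    versions = join_semi(.data$versions),
    hpo_terms = join_semi(.data$hpo_terms)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Restrict a panel to the pairs present in an earlier list version
#'
#' @param panel A panel tibble with a `versions` list-column.
#' @param version One of `"v1.0"`, `"v2.0"`, `"v3.0"`, `"v3.1"`.
#' @return The rows whose `versions` membership includes `version`.
#' @examples
#' \donttest{nrow(panel_version_subset(acmg_panel(), "v1.0")) # 56}
#' @export
panel_version_subset <- function(panel, version) {
  if (length(version) != 1 || !version %in% ACMG_VERSIONS) {
    validation_error(
      sprintf("Unknown panel version (allowed: %s).",
              paste(ACMG_VERSIONS, collapse = ", ")),
      version
    )
  }
  keep <- vapply(panel$versions, function(v) version %in% v, logical(1))
  panel[keep, ]
}

#' Packaged ACMG SF v3.1-shaped panel
#'
#' 78 gene-disease pairs with per-pair version membership flags back to
#' v1.0, disease categories, modes of inheritance and associated HPO terms.
#' Gene symbols and version history follow the published reporting lists;
#' the HPO annotations and the five v3.1-only rows are synthetic fixture
#' content (see the packaged file's header comment is not present -- the
#' provenance is documented in the package vignette).
#'
#' @return A panel tibble (78 rows).
#' @export
acmg_panel <- function() {
  read_panel(
    system.file("extdata", "acmg_sf_v31_panel.tsv", package = "sfscreenr"),
    name = "ACMG SF v3.1"
  )
}

#' Packaged non-ACMG actionable panel (39 pairs)
#'
#' The custom actionability-scored reporting list: 39 curated gene-disease
#' pairs, each with its four-component rubric score (all totals >= 10),
#' evidence grades, disease category and associated HPO terms. Pairs the
#' source study names are included under their field-standard gene symbols;
#' the remainder are clearly labelled synthetic placeholders (genes
#' `SYNG01`...).
#'
#' @return A panel tibble (39 rows).
#' @export
nonacmg_panel <- function() {
  read_panel(
    system.file("extdata", "nonacmg_sf_panel.tsv", package = "sfscreenr"),
    name = "non-ACMG SF"
  )
}
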