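#' Run the full secondary-findings screen on a cohort
#'
#' End-to-end pipeline: variant QC, phenotype-aware triage against the two
#' reporting panels (optionally restricted to an earlier ACMG list
#' version), and the cohort summary statistics.
#'
#' @param manifest Participant manifest tibble (or path to a manifest TSV).
#' @param calls Call tibble (or path to a variant TSV/VCF).
#' @param acmg_panel,nonacmg_panel Panel tibbles; defaults are the packaged
#'   panels.
#' @param panel_version Optional ACMG list version (`"v1.0"`..`"v3.1"`); the
#'   ACMG panel is restricted to pairs present in that version before
#'   triage.
#' @param qc A [qc_policy()].
#' @param ontology Optional `hpo_ontology`.
#' @param require_phase,xl_female_sf Triage flags, see [triage_cohort()].
#' @param quiet Suppress progress messages.
#' @return An object of class `sf_screen`: a list with `findings`,
#'   `summary` (a `cohort_summary`) and `config`.
#' @examples
#' \donttest{
#' ref <- reference_cohort()
#' scr <- screen_cohort(ref$manifest, ref$calls)
#' glance(scr)
#' }
#' @export
screen_cohort <- function(manifest, calls,
                          acmg_panel = sfscreenr::acmg_panel(),
                          nonacmg_panel = sfscreenr::nonacmg_panel(),
                          panel_version = NULL,
                          qc = qc_policy(), ontology = NULL,
                          require_phase = FALSE, xl_female_sf = FALSE,
                          quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(calls)) calls <- read_variant_table(calls, manifest = manifest)
  if (!is.null(panel_version)) {
    acmg_panel <- panel_version_subset(acmg_panel, panel_version)
  }
  findings <- triage_cohort(
    manifest, calls, acmg_panel, nonacmg_panel,
    qc = qc, ontology = ontology, require_phase = require_phase,
    xl_female_sf = xl_female_sf, quiet = quiet
  )
  summary <- summarize_cohort(manifest, findings)
  structure(
    list(
      findings = findings,
      summary = summary,
      config = list(
        panel_version = panel_version %||% "v3.1",
        qc = unclass(qc),
        require_phase = require_phase,
        xl_female_sf = xl_female_sf,
        n_acmg_pairs = nrow(acmg_panel),
        n_nonacmg_pairs = nrow(nonacmg_panel)
      )
    ),
    class = "sf_screen"
  )
}

#' @export
print.sf_screen <- function(x, ...) {
  cat(sprintf("Secondary-findings screen (ACMG list %s, %d + %d panel pairs)\n",
              x$config$panel_version, x$config$n_acmg_pairs,
              x$config$n_nonacmg_pairs))
  print(x$summary)
  invisible(x)
}

#' Tidy the findings of a screen
#' @param x An `sf_screen`.
#' @param ... Unused.
#' @return The findings tibble (reportable rows first).
#' @method tidy sf_screen
#' @export
tidy.sf_screen <- function(x, ...) {
  dplyr::arrange(x$findings, .data$finding_class == "NOT_REPORTABLE",
                 .data$participant_id)
}

#' One-row glance at a screen
#' @param x An `sf_screen`.
#' @param ... Unused.
#' @return One-row tibble of headline frequencies.
#' @method glance sf_screen
#' @export
glance.sf_screen <- function(x, ...) {
  dplyr::mutate(glance(x$summary), panel_version = x$config$panel_version)
}

screen_report_list <- function(x) {
  s <- x$summary
  list(
    config = x$config,
    class_frequencies = s$class_freq,
    demographics = s$demographics,
    ages = s$ages,
    categories = s$categories,
    allelic = s$allelic,
    ratios = s$ratios,
    n_findings = nrow(x$findings[x$findings$finding_class != "NOT_REPORTABLE", ])
  )
}

#' Write the full screening report to a directory
#'
#' Writes `findings.tsv`, `summary.json` (all tables, raw and rounded
#' values), and TSV tables: `table1.tsv` (cohort characterisation),
#' `class_frequencies.tsv`, `categories.tsv`, `allelic.tsv`, `ratios.tsv`.
#'
#' @param x An `sf_screen`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(x, dir) {
  stopifnot(inherits(x, "sf_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_findings(x$findings, file.path(dir, "findings.tsv"))
  s <- x$summary
  readr::write_tsv(s$demographics, file.path(dir, "table1.tsv"), progress = FALSE)
  readr::write_tsv(s$class_freq, file.path(dir, "class_frequencies.tsv"),
                   progress = FALSE)
  readr::write_tsv(s$categories, file.path(dir, "categories.tsv"),
                   progress = FALSE)
  readr::write_tsv(s$allelic, file.path(dir, "allelic.tsv"), progress = FALSE)
  readr::write_tsv(s$ratios, file.path(dir, "ratios.tsv"), progress = FALSE)
  jsonlite::write_json(screen_report_list(x), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(dir)
}

#' Structural validation of a written summary report
#'
#' Checks that a `summary.json` produced by [write_screen_report()] carries
#' the expected top-level sections and per-class frequency fields.
#'
#' @param path Path to a `summary.json`.
#' @return `TRUE` invisibly, or an error describing the missing fields.
#' @export
validate_report <- function(path) {
  js <- jsonlite::read_json(path)
  need <- c("config", "class_frequencies", "demographics", "ages",
            "categories", "allelic", "ratios")
  missing_keys <- setdiff(need, names(js))
  if (length(missing_keys)) {
    validation_error("Report is missing sections.", missing_keys)
  }
  cf_fields <- c("label", "n_findings", "n_participants", "denominator",
                 "percent_raw", "percent")
  ok <- vapply(js$class_frequencies,
               function(row) all(cf_fields %in% names(row)), logical(1))
  if (!all(ok)) {
    validation_error("class_frequencies rows lack required fields.")
  }
  invisible(TRUE)
}
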