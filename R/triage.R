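FINDING_CLASSES <- c("ACMG_SF", "NONACMG_SF", "ACMG_PF", "NONACMG_PF",
                     "CARRIER", "NOT_REPORTABLE")

#' Allelic status of a participant's calls in one gene
#'
#' A homozygous call, or at least two distinct heterozygous calls in the
#' same gene (a putative compound heterozygote, presumed in trans when
#' phasing is unavailable), makes the gene biallelic; a single heterozygous
#' or hemizygous call is monoallelic.
#'
#' @param calls A call tibble for one participant and one gene (all QC-passed).
#' @param require_phase If `TRUE`, unphased heterozygous pairs are NOT
#'   presumed in trans and count as monoallelic.
#' @return `"MONOALLELIC"` or `"BIALLELIC"`.
#' @export
allelic_status <- function(calls, require_phase = FALSE) {
  if (nrow(calls) == 0) validation_error("Empty call group.")
  if (any(calls$zygosity == "HOM")) return("BIALLELIC")
  n_het <- length(unique(calls$variant_id[calls$zygosity == "HET"]))
  if (n_het >= 2 && !require_phase) return("BIALLELIC")
  "MONOALLELIC"
}

#' Reporting disposition of an allelic status under a mode of inheritance
#'
#' Encodes "appropriate zygosity for the known mode of inheritance":
#' heterozygous (monoallelic) suffices for dominant genes, recessive genes
#' require both alleles hit, a single recessive allele is carrier status,
#' and X-linked monoallelic findings are reportable in hemizygous males
#' (heterozygous females only when `xl_female_sf = TRUE`). Semidominant
#' (`SD`) genes behave like dominant ones.
#'
#' @param status `"MONOALLELIC"` or `"BIALLELIC"` (vectorised).
#' @param moi Mode of inheritance: `"AD"`, `"AR"`, `"XL"` or `"SD"`.
#' @param hemi Whether the monoallelic call set contains a hemizygous call.
#' @param xl_female_sf Report X-linked heterozygous females.
#' @return Character vector over `{"REPORTABLE", "CARRIER", "NONE"}`.
#' @examples
#' moi_disposition("MONOALLELIC", "AR") # CARRIER
#' moi_disposition("BIALLELIC", "AR")   # REPORTABLE
#' @export
moi_disposition <- function(status, moi, hemi = FALSE, xl_female_sf = FALSE) {
  n <- max(length(status), length(moi))
  status <- rep_len(status, n); moi <- rep_len(moi, n)
  hemi <- rep_len(hemi, n)
  bad <- !moi %in% MOI_LEVELS
  if (any(bad)) validation_error("Unknown mode of inheritance.", moi[bad])
  bad_s <- !status %in% c("MONOALLELIC", "BIALLELIC")
  if (any(bad_s)) validation_error("Unknown allelic status.", status[bad_s])
  dplyr::case_when(
    moi %in% c("AD", "SD") ~ "REPORTABLE",
    moi == "AR" & status == "BIALLELIC" ~ "REPORTABLE",
    moi == "AR" ~ "CARRIER",
    moi == "XL" & status == "BIALLELIC" ~ "REPORTABLE",
    moi == "XL" & hemi ~ "REPORTABLE",
    moi == "XL" & xl_female_sf ~ "REPORTABLE",
    .default = "NONE"
  )
}

#' Read a participant manifest
#'
#' Tab-separated columns: `participant_id, family_id, role, sex, age_years,
#' clinical_status, consanguineous_parents, hpo_terms` (semicolon-separated
#' `HP:NNNNNNN` ids, empty for asymptomatic participants).
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with `hpo_terms` as a list-column.
#' @export
read_manifest <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      family_id = readr::col_character(),
      role = readr::col_character(),
      sex = readr::col_character(),
      age_years = readr::col_double(),
      clinical_status = readr::col_character(),
      consanguineous_parents = readr::col_character(),
      hpo_terms = readr::col_character()
    ),
    progress = FALSE
  )
  validate_manifest(dplyr::mutate(raw, hpo_terms = split_semi(.data$hpo_terms)))
}

validate_manifest <- function(manifest) {
  need <- c("participant_id", "family_id", "role", "sex", "age_years",
            "clinical_status", "consanguineous_parents", "hpo_terms")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols)) {
    validation_error("Manifest lacks required columns.", missing_cols)
  }
  if (anyDuplicated(manifest$participant_id)) {
    validation_error("Duplicate participant ids in manifest.",
                     manifest$participant_id[duplicated(manifest$participant_id)])
  }
  checks <- list(
    role = c("index", "relative"),
    sex = c("male", "female"),
    clinical_status = c("symptomatic", "asymptomatic"),
    consanguineous_parents = c("yes", "no", "undisclosed")
  )
  for (col in names(checks)) {
    bad <- !manifest[[col]] %in% checks[[col]]
    if (any(bad)) {
      validation_error(sprintf("Invalid `%s` values in manifest.", col),
                       unique(manifest[[col]][bad]))
    }
  }
  manifest
}

#' Write a participant manifest
#' @param manifest Manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- dplyr::mutate(manifest, hpo_terms = join_semi(.data$hpo_terms))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# one participant x gene group -> one finding row
triage_group <- function(grp, participant, pairs, ontology,
                         require_phase, xl_female_sf) {
  p_hpo <- participant$hpo_terms[[1]]
  base <- tibble(
    participant_id = participant$participant_id,
    gene = grp$gene[1],
    disease = NA_character_,
    panel = NA_character_,
    moi = NA_character_,
    category = NA_character_,
    finding_class = "NOT_REPORTABLE",
    allelic_status = NA_character_,
    includes_vus = FALSE,
    n_variants = 0L,
    variant_ids = "",
    hgvs = "",
    classifications = ""
  )
  fill_calls <- function(row, use) {
    use <- dplyr::arrange(use, .data$pos, .data$alt)
    row$allelic_status <- allelic_status(use, require_phase)
    row$includes_vus <- any(use$classification == "VUS")
    row$n_variants <- length(unique(use$variant_id))
    row$variant_ids <- paste(unique(use$variant_id), collapse = ";")
    row$hgvs <- paste(dplyr::coalesce(use$hgvs, "."), collapse = ";")
    row$classifications <- paste(use$classification, collapse = ";")
    row
  }
  fill_pair <- function(row, pair) {
    row$disease <- pair$disease
    row$panel <- pair$panel
    row$moi <- pair$moi
    row$category <- pair$category
    row
  }

  # (1) phenotype-matched symptomatic participant -> primary finding,
  # VUS calls allowed but flagged
  if (participant$clinical_status == "symptomatic" && length(p_hpo)) {
    overlap <- vapply(pairs$hpo_terms, function(t) {
      phenotype_overlap_n(p_hpo, t, ontology)
    }, integer(1))
    if (any(overlap > 0)) {
      ord <- order(-overlap, pairs$panel != "acmg", seq_len(nrow(pairs)))
      pair <- pairs[ord[1], ]
      row <- fill_pair(base, pair)
      row$finding_class <- if (pair$panel == "acmg") "ACMG_PF" else "NONACMG_PF"
      return(fill_calls(row, grp))
    }
  }

  # (2) secondary-finding / carrier path: P and LP calls only
  plp <- grp[grp$classification %in% c("P", "LP"), ]
  if (nrow(plp) == 0 || nrow(pairs) == 0) {
    row <- fill_calls(base, grp)
    row$includes_vus <- FALSE # the VUS flag is reserved for primary findings
    return(row)
  }
  status <- allelic_status(plp, require_phase)
  hemi <- any(plp$zygosity == "HEMI")
  disp <- moi_disposition(status, pairs$moi, hemi, xl_female_sf)
  priority <- c(REPORTABLE = 2L, CARRIER = 1L, NONE = 0L)[disp]
  # zygosity-MOI specificity: a biallelic genotype is attributed to a
  # recessive pair, a monoallelic one to a dominant/X-linked pair, when a
  # gene carries several disease associations
  specific <- ifelse(
    (status == "BIALLELIC" & pairs$moi == "AR") |
      (status == "MONOALLELIC" & pairs$moi != "AR"), 1L, 0L)
  ord <- order(-priority, -specific, pairs$panel != "acmg", seq_len(nrow(pairs)))
  pair <- pairs[ord[1], ]
  best <- disp[ord[1]]
  if (best == "NONE") return(fill_calls(base, plp))
  row <- fill_pair(base, pair)
  row$finding_class <- if (best == "CARRIER") "CARRIER"
    else if (pair$panel == "acmg") "ACMG_SF" else "NONACMG_SF"
  fill_calls(row, plp)
}

#' Triage a cohort's variant calls into findings
#'
#' The reporting logic applied per participant and gene, after variant QC:
#'
#' 1. If the participant is symptomatic and the gene has a panel pair whose
#'    phenotype terms overlap the participant's (primary finding), the gene
#'    group is reported as `ACMG_PF` / `NONACMG_PF`; uncertain (VUS) calls
#'    are allowed in primary findings and flagged via `includes_vus`.
#' 2. Otherwise only pathogenic / likely pathogenic calls are considered,
#'    and mode-of-inheritance-appropriate zygosity decides between a
#'    secondary finding (`ACMG_SF` / `NONACMG_SF`), recessive `CARRIER`
#'    status, or `NOT_REPORTABLE`.
#'
#' One finding row is produced per participant x gene group (including
#' `NOT_REPORTABLE` groups, so the classes partition the groups). When a
#' gene carries several panel pairs the best disposition wins, preferring a
#' pair whose inheritance mode matches the observed zygosity, ACMG panel
#' first.
#'
#' @param manifest Participant manifest tibble (see [read_manifest()]).
#' @param calls Call tibble (see [read_variant_table()]).
#' @param acmg_panel,nonacmg_panel Panel tibbles; the two must be disjoint
#'   on (gene, disease) keys. Defaults are the packaged panels.
#' @param qc A [qc_policy()]; applied before triage.
#' @param ontology Optional `hpo_ontology` for closure-based matching.
#' @param require_phase Treat unphased het pairs as monoallelic.
#' @param xl_female_sf Report X-linked heterozygous females as SFs.
#' @param quiet Suppress QC messages.
#' @return A findings tibble, one row per participant x gene group.
#' @export
triage_cohort <- function(manifest, calls,
                          acmg_panel = sfscreenr::acmg_panel(),
                          nonacmg_panel = sfscreenr::nonacmg_panel(),
                          qc = qc_policy(), ontology = NULL,
                          require_phase = FALSE, xl_female_sf = FALSE,
                          quiet = FALSE) {
  validate_manifest(manifest)
  overlap <- dplyr::inner_join(
    acmg_panel[c("gene", "disease")], nonacmg_panel[c("gene", "disease")],
    by = c("gene", "disease")
  )
  if (nrow(overlap)) {
    validation_error("Panels share (gene, disease) pairs.",
                     paste0(overlap$gene, "/", overlap$disease))
  }
  unknown <- setdiff(calls$participant_id, manifest$participant_id)
  if (length(unknown)) {
    validation_error("Calls reference participants absent from the manifest.",
                     unknown)
  }
  panel_all <- dplyr::bind_rows(
    dplyr::mutate(acmg_panel, panel = "acmg"),
    dplyr::mutate(nonacmg_panel, panel = "nonacmg")
  )
  kept <- qc_filter(calls, qc, quiet = quiet)
  kept <- kept[kept$classification %in% c("P", "LP", "VUS"), ]
  if (nrow(kept) == 0) return(empty_findings())
  kept <- dplyr::arrange(kept, .data$participant_id, .data$gene,
                         .data$pos, .data$alt)
  groups <- split(kept, paste(kept$participant_id, kept$gene, sep = "\r"))
  rows <- lapply(groups, function(grp) {
    participant <- manifest[manifest$participant_id == grp$participant_id[1], ]
    pairs <- panel_all[panel_all$gene == grp$gene[1], ]
    triage_group(grp, participant, pairs, ontology, require_phase, xl_female_sf)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$participant_id, .data$gene)
}

empty_findings <- function() {
  tibble(
    participant_id = character(0), gene = character(0),
    disease = character(0), panel = character(0), moi = character(0),
    category = character(0), finding_class = character(0),
    allelic_status = character(0), includes_vus = logical(0),
    n_variants = integer(0), variant_ids = character(0),
    hgvs = character(0), classifications = character(0)
  )
}

#' Count findings at a chosen level
#'
#' @param findings A findings tibble (usually pre-filtered to one class).
#' @param level `"finding"` (rows), `"participant"` (distinct participants;
#'   family members are deliberately NOT collapsed), `"unique_variant"`
#'   (distinct chrom:pos:ref:alt keys across all rows) or `"unique_gene"`.
#' @return An integer count.
#' @examples
#' \donttest{
#' f <- triage_cohort(reference_cohort()$manifest, reference_cohort()$calls)
#' count_findings(dplyr::filter(f, finding_class == "ACMG_SF"), "participant")
#' }
#' @export
count_findings <- function(findings,
                           level = c("finding", "participant",
                                     "unique_variant", "unique_gene")) {
  level <- match.arg(level)
  switch(level,
    finding = nrow(findings),
    participant = dplyr::n_distinct(findings$participant_id),
    unique_variant = length(unique(unlist(split_semi(findings$variant_ids)))),
    unique_gene = dplyr::n_distinct(findings$gene)
  )
}

#' Write a findings table to TSV
#' @param findings Findings tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_findings <- function(findings, path) {
  readr::write_tsv(findings, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a findings table written by [write_findings()]
#' @param path Path to the TSV.
#' @return Findings tibble.
#' @export
read_findings <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      gene = readr::col_character(),
      disease = readr::col_character(),
      panel = readr::col_character(),
      moi = readr::col_character(),
      category = readr::col_character(),
      finding_class = readr::col_character(),
      allelic_status = readr::col_character(),
      includes_vus = readr::col_logical(),
      n_variants = readr::col_integer(),
      variant_ids = readr::col_character(),
      hgvs = readr::col_character(),
      classifications = readr::col_character()
    ),
    progress = FALSE
  ) |>
    dplyr::mutate(dplyr::across(
      c("variant_ids", "hgvs", "classifications", "disease", "panel",
        "moi", "category", "allelic_status"),
      ~ dplyr::coalesce(.x, "")
    )) |>
    dplyr::mutate(dplyr::across(
      c("disease", "panel", "moi", "category", "allelic_status"),
      ~ dplyr::na_if(.x, "")
    ))
}
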