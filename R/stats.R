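#' Disease-category breakdown of a finding class
#'
#' @param findings Findings tibble.
#' @param class Finding class to summarise (e.g. `"ACMG_SF"`).
#' @return A tibble `category, n, percent` (percent of the class's findings,
#'   one decimal, half-up), sorted by descending count.
#' @export
category_breakdown <- function(findings, class) {
  sub <- findings[findings$finding_class == class, ]
  if (nrow(sub) == 0) {
    return(tibble(category = character(0), n = integer(0), percent = numeric(0)))
  }
  sub |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::mutate(percent = frequency(.data$n, nrow(sub), 1)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$category)
}

#' Allelic-status breakdown of a finding class
#'
#' @inheritParams category_breakdown
#' @param plp_only Restrict to findings without VUS (relevant for primary
#'   findings, which may include flagged VUS calls).
#' @return A tibble `allelic_status, n, percent` with both `MONOALLELIC`
#'   and `BIALLELIC` rows always present.
#' @export
allelic_breakdown <- function(findings, class, plp_only = FALSE) {
  sub <- findings[findings$finding_class == class, ]
  if (plp_only) sub <- sub[!sub$includes_vus, ]
  counts <- tibble(allelic_status = c("MONOALLELIC", "BIALLELIC")) |>
    dplyr::left_join(
      dplyr::count(sub, .data$allelic_status, name = "n"),
      by = "allelic_status"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  tot <- sum(counts$n)
  dplyr::mutate(
    counts,
    percent = if (tot > 0) frequency(.data$n, tot, 1) else NA_real_
  )
}

age_stats <- function(x) {
  tibble(
    n = length(x),
    mean = if (length(x)) mean(x) else NA_real_,
    median = if (length(x)) stats::median(x) else NA_real_,
    sd = if (length(x) > 1) stats::sd(x) else NA_real_,
    min = if (length(x)) min(x) else NA_real_,
    max = if (length(x)) max(x) else NA_real_
  )
}

class_frequency_table <- function(findings, n_total, n_symptomatic) {
  spec <- tibble(
    label = c("acmg_sf", "nonacmg_sf", "acmg_carrier", "nonacmg_carrier",
              "acmg_pf_plp", "acmg_pf_all", "nonacmg_pf_plp", "nonacmg_pf_all"),
    class = c("ACMG_SF", "NONACMG_SF", "CARRIER", "CARRIER",
              "ACMG_PF", "ACMG_PF", "NONACMG_PF", "NONACMG_PF"),
    panel = c(NA, NA, "acmg", "nonacmg", NA, NA, NA, NA),
    plp_only = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    denominator = c(n_total, n_total, n_total, n_total,
                    n_symptomatic, n_symptomatic, n_symptomatic, n_symptomatic),
    decimals = c(1L, 1L, 2L, 2L, 1L, 1L, 1L, 1L)
  )
  purrr::pmap_dfr(spec, function(label, class, panel, plp_only,
                                 denominator, decimals) {
    sub <- findings[findings$finding_class == class, ]
    if (!is.na(panel)) sub <- sub[!is.na(sub$panel) & sub$panel == panel, ]
    if (plp_only) sub <- sub[!sub$includes_vus, ]
    n_f <- nrow(sub)
    n_p <- dplyr::n_distinct(sub$participant_id)
    tibble(
      label = label,
      n_findings = n_f,
      n_participants = n_p,
      denominator = denominator,
      percent_raw = 100 * n_p / denominator,
      percent = frequency(n_p, denominator, decimals)
    )
  })
}

status_two_by_two <- function(findings, manifest, class,
                              direction = c("symptomatic_first",
                                            "asymptomatic_first")) {
  direction <- match.arg(direction)
  with_f <- unique(findings$participant_id[findings$finding_class == class])
  sym <- manifest$participant_id[manifest$clinical_status == "symptomatic"]
  asym <- manifest$participant_id[manifest$clinical_status == "asymptomatic"]
  a <- sum(sym %in% with_f); b <- length(sym) - a
  c <- sum(asym %in% with_f); d <- length(asym) - c
  if (direction == "symptomatic_first") {
    two_by_two(a, b, c, d, groups = c("symptomatic", "asymptomatic"),
               outcome = class)
  } else {
    two_by_two(c, d, a, b, groups = c("asymptomatic", "symptomatic"),
               outcome = class)
  }
}

#' Cohort summary: demographics, finding frequencies and 2x2 analyses
#'
#' Produces the cohort-characterisation table (roles, sex, clinical status,
#' consanguinity among index families, age distributions by clinical
#' status), per-class finding frequencies (participant level, with the
#' printed-style rounding: carrier percents at two decimals, all others at
#' one), disease-category and allelic-status breakdowns, and
#' symptomatic-vs-asymptomatic ratio estimates (risk ratio and odds ratio,
#' both directions) for the ACMG and non-ACMG secondary findings.
#'
#' @param manifest Participant manifest tibble.
#' @param findings Findings tibble from [triage_cohort()].
#' @return An object of class `cohort_summary`: a list of tibbles
#'   (`demographics`, `ages`, `class_freq`, `categories`, `allelic`,
#'   `ratios`).
#' @export
summarize_cohort <- function(manifest, findings) {
  validate_manifest(manifest)
  unknown <- setdiff(findings$participant_id, manifest$participant_id)
  if (length(unknown)) {
    validation_error("Findings reference participants absent from manifest.",
                     unknown)
  }
  n <- nrow(manifest)
  idx <- manifest[manifest$role == "index", ]
  n_sym <- sum(manifest$clinical_status == "symptomatic")

  demo_row <- function(section, label, count, denom) {
    tibble(section = section, label = label, n = count,
           denominator = denom, percent = frequency(count, denom, 2))
  }
  demographics <- dplyr::bind_rows(
    demo_row("role", "index", sum(manifest$role == "index"), n),
    demo_row("role", "relative", sum(manifest$role == "relative"), n),
    demo_row("sex", "male", sum(manifest$sex == "male"), n),
    demo_row("sex", "female", sum(manifest$sex == "female"), n),
    demo_row("clinical_status", "symptomatic", n_sym, n),
    demo_row("clinical_status", "asymptomatic", n - n_sym, n),
    demo_row("consanguinity_index", "yes",
             sum(idx$consanguineous_parents == "yes"), nrow(idx)),
    demo_row("consanguinity_index", "no",
             sum(idx$consanguineous_parents == "no"), nrow(idx)),
    demo_row("consanguinity_index", "undisclosed",
             sum(idx$consanguineous_parents == "undisclosed"), nrow(idx))
  )
  ages <- dplyr::bind_rows(
    dplyr::mutate(
      age_stats(manifest$age_years[manifest$clinical_status == "symptomatic"]),
      clinical_status = "symptomatic", .before = 1),
    dplyr::mutate(
      age_stats(manifest$age_years[manifest$clinical_status == "asymptomatic"]),
      clinical_status = "asymptomatic", .before = 1)
  )
  class_freq <- class_frequency_table(findings, n, n_sym)
  categories <- purrr::map_dfr(
    c("ACMG_SF", "NONACMG_SF", "ACMG_PF", "NONACMG_PF"),
    function(cl) dplyr::mutate(category_breakdown(findings, cl),
                               finding_class = cl, .before = 1)
  )
  allelic <- purrr::map_dfr(
    c("ACMG_SF", "NONACMG_SF", "ACMG_PF", "NONACMG_PF"),
    function(cl) {
      plp <- cl %in% c("ACMG_PF", "NONACMG_PF")
      dplyr::mutate(allelic_breakdown(findings, cl, plp_only = plp),
                    finding_class = cl, plp_only = plp, .before = 1)
    }
  )
  ratios <- purrr::map_dfr(c("ACMG_SF", "NONACMG_SF"), function(cl) {
    purrr::map_dfr(
      c("symptomatic_first", "asymptomatic_first"),
      function(dir) {
        tab <- status_two_by_two(findings, manifest, cl, dir)
        if (tab$a == 0 || tab$c == 0) return(tibble())
        dplyr::bind_rows(tidy(risk_ratio(tab)), tidy(odds_ratio(tab))) |>
          dplyr::mutate(finding_class = cl, .before = 1)
      }
    )
  })
  structure(
    list(demographics = demographics, ages = ages, class_freq = class_freq,
         categories = categories, allelic = allelic, ratios = ratios,
         n_participants = n, n_symptomatic = n_sym),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d participants (%d symptomatic)\n",
              x$n_participants, x$n_symptomatic))
  cat("\nFinding frequencies (participant level):\n")
  print(as.data.frame(x$class_freq), row.names = FALSE)
  invisible(x)
}

#' Tidy a cohort summary
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return The per-class frequency tibble.
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) x$class_freq

#' One-row glance at a cohort summary
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A one-row tibble of headline frequencies.
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  cf <- x$class_freq
  pick <- function(lbl) cf$percent[cf$label == lbl]
  tibble(
    n = x$n_participants,
    n_symptomatic = x$n_symptomatic,
    acmg_sf_pct = pick("acmg_sf"),
    nonacmg_sf_pct = pick("nonacmg_sf"),
    acmg_carrier_pct = pick("acmg_carrier"),
    nonacmg_carrier_pct = pick("nonacmg_carrier"),
    acmg_pf_plp_pct = pick("acmg_pf_plp"),
    nonacmg_pf_plp_pct = pick("nonacmg_pf_plp")
  )
}
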