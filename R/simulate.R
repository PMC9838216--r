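# Stochastic cohort simulator ------------------------------------------------

#' Default gene-disease pairs planted by the simulator
#'
#' A small set of pairs spanning both packaged panels and both inheritance
#' modes. For autosomal-recessive pairs `q` is the carrier allele
#' frequency; for dominant pairs `ad_rate` is the per-participant
#' heterozygote planting rate.
#'
#' @return A tibble `gene, disease, panel, moi, q, ad_rate`.
#' @export
default_sim_pairs <- function() {
  tibble::tribble(
    ~gene, ~disease, ~panel, ~moi, ~q, ~ad_rate,
    "TTN", "Dilated cardiomyopathy 1G", "acmg", "AD", NA, 0.012,
    "MYBPC3", "Hypertrophic cardiomyopathy 4", "acmg", "AD", NA, 0.008,
    "RYR1", "Malignant hyperthermia", "acmg", "AD", NA, 0.004,
    "MUTYH", "MUTYH-related familial adenomatous polyposis", "acmg", "AR", 0.004, NA,
    "CFTR", "Cystic fibrosis", "nonacmg", "AR", 0.010, NA,
    "AGXT", "Primary hyperoxaluria type 1", "nonacmg", "AR", 0.012, NA,
    "COL7A1", "Epidermolysis bullosa dystrophica", "nonacmg", "AR", 0.006, NA,
    "VWF", "von Willebrand disease 1", "nonacmg", "AD", NA, 0.004
  )
}

#' Simulator configuration
#'
#' Defaults mirror the reference cohort's structure: 863 participants (700
#' index, 163 relatives), 61.65% male, 85.86% symptomatic, 79.86% of index
#' families consanguineous (2.71% undisclosed), first-cousin inbreeding
#' coefficient F = 0.0625 applied to autosomal-recessive genotype
#' frequencies of participants from consanguineous families, and truncated
#' normal age models per clinical status.
#'
#' @param n_index,n_relatives Cohort composition.
#' @param male_fraction,symptomatic_fraction Participant-level fractions.
#' @param consanguineous_fraction,undisclosed_fraction Index-family-level
#'   fractions ("no" takes the remainder).
#' @param inbreeding_f Inbreeding coefficient F in \[0, 0.25\].
#' @param age_symptomatic,age_asymptomatic Named vectors
#'   `c(mean=, sd=, min=, max=)` for the truncated normal age draws.
#' @param pairs Planting table, see [default_sim_pairs()].
#' @param deterministic_margins Convert cohort fractions to integer counts
#'   by largest-remainder apportionment (so 0.8586 of 863 is exactly 741)
#'   instead of binomial draws.
#' @param seed Optional integer seed; with a fixed seed the simulator is
#'   fully reproducible.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_index = 700, n_relatives = 163,
                          male_fraction = 0.6165,
                          symptomatic_fraction = 0.8586,
                          consanguineous_fraction = 0.7986,
                          undisclosed_fraction = 0.0271,
                          inbreeding_f = 0.0625,
                          age_symptomatic = c(mean = 4.93, sd = 6.17,
                                              min = 0, max = 65),
                          age_asymptomatic = c(mean = 28.34, sd = 10.52,
                                               min = 0, max = 55),
                          pairs = default_sim_pairs(),
                          deterministic_margins = TRUE,
                          seed = NULL) {
  fracs <- c(male_fraction, symptomatic_fraction,
             consanguineous_fraction, undisclosed_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    validation_error("Cohort fractions must lie in [0, 1].")
  }
  if (consanguineous_fraction + undisclosed_fraction > 1) {
    validation_error("Consanguinity fractions exceed 1.")
  }
  if (inbreeding_f < 0 || inbreeding_f > 0.25) {
    validation_error("`inbreeding_f` must lie in [0, 0.25].")
  }
  if (any(!is.na(pairs$q) & (pairs$q <= 0 | pairs$q > 0.5))) {
    validation_error("Carrier allele frequencies q must lie in (0, 0.5].")
  }
  structure(
    list(n_index = n_index, n_relatives = n_relatives,
         male_fraction = male_fraction,
         symptomatic_fraction = symptomatic_fraction,
         consanguineous_fraction = consanguineous_fraction,
         undisclosed_fraction = undisclosed_fraction,
         inbreeding_f = inbreeding_f,
         age_symptomatic = age_symptomatic,
         age_asymptomatic = age_asymptomatic,
         pairs = pairs,
         deterministic_margins = deterministic_margins,
         seed = seed),
    class = "cohort_config"
  )
}

#' Largest-remainder apportionment of counts to fractions
#'
#' @param n Total to distribute.
#' @param fracs Non-negative fractions summing to at most 1 (a remainder
#'   class absorbs any shortfall when they sum below 1).
#' @return Integer counts summing to `n` (or to `round(n * sum(fracs))`).
#' @export
largest_remainder <- function(n, fracs) {
  quota <- n * fracs
  counts <- floor(quota)
  left <- round(sum(quota)) - sum(counts)
  if (left > 0) {
    order_rem <- order(quota - counts, decreasing = TRUE)
    counts[order_rem[seq_len(left)]] <- counts[order_rem[seq_len(left)]] + 1
  }
  as.integer(counts)
}

rtruncnorm <- function(n, mean, sd, min, max) {
  plo <- stats::pnorm(min, mean, sd)
  phi <- stats::pnorm(max, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Autosomal-recessive genotype frequencies under inbreeding
#'
#' With carrier allele frequency `q` and inbreeding coefficient `F`, the
#' probability of a biallelic (homozygous) genotype is
#' `q^2 + F q (1 - q)` and of a heterozygous genotype `2 q (1 - q) (1 - F)`.
#'
#' @param q Allele frequency in (0, 0.5].
#' @param f Inbreeding coefficient in \[0, 1\].
#' @return A named vector `c(biallelic =, het =)`.
#' @export
ar_genotype_probs <- function(q, f = 0) {
  c(biallelic = q^2 + f * q * (1 - q), het = 2 * q * (1 - q) * (1 - f))
}

#' Simulate a cohort with planted findings
#'
#' Draws a participant manifest (roles, sex, clinical status, family-level
#' consanguinity, truncated normal ages per clinical status) and plants
#' pathogenic variants per configured gene-disease pair: for
#' autosomal-recessive pairs each participant is biallelic with probability
#' `q^2 + F q (1-q)` when their family is consanguineous and `q^2`
#' otherwise (heterozygous carrier with the corresponding `2q(1-q)(1-F)`
#' complement); dominant pairs are planted as heterozygotes at `ad_rate`.
#' Read depths (10 + Poisson(30)) and binomial allele fractions are drawn
#' so that over 99% of planted calls pass the default QC policy.
#' Symptomatic participants receive a generic phenotype term absent from
#' the panels, so planted findings triage as secondary findings or carrier
#' states, never as primary findings — the planted truth records the
#' expected class per finding.
#'
#' @param cfg A [cohort_config()].
#' @return A list with `manifest`, `calls` and `truth` tibbles; `truth` has
#'   one row per planted participant x gene with the expected finding class
#'   and allelic status.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(cfg$seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(cfg$seed)
  }
  n <- cfg$n_index + cfg$n_relatives
  pid <- sprintf("S%05d", seq_len(n))
  role <- c(rep("index", cfg$n_index), rep("relative", cfg$n_relatives))
  fam_idx <- c(seq_len(cfg$n_index),
               sample.int(cfg$n_index, cfg$n_relatives, replace = TRUE))
  draw_flags <- function(n, frac) {
    if (cfg$deterministic_margins) {
      k <- largest_remainder(n, c(frac, 1 - frac))[1]
      flags <- rep(FALSE, n)
      flags[sample.int(n, k)] <- TRUE
      flags
    } else {
      stats::runif(n) < frac
    }
  }
  male <- draw_flags(n, cfg$male_fraction)
  symptomatic <- draw_flags(n, cfg$symptomatic_fraction)
  consang_counts <- largest_remainder(
    cfg$n_index,
    c(cfg$consanguineous_fraction, cfg$undisclosed_fraction,
      1 - cfg$consanguineous_fraction - cfg$undisclosed_fraction)
  )
  fam_status <- sample(rep(c("yes", "undisclosed", "no"), consang_counts))
  consang <- fam_status[fam_idx]
  age <- numeric(n)
  as_ <- cfg$age_symptomatic; aa <- cfg$age_asymptomatic
  age[symptomatic] <- rtruncnorm(sum(symptomatic), as_["mean"], as_["sd"],
                                 as_["min"], as_["max"])
  age[!symptomatic] <- rtruncnorm(sum(!symptomatic), aa["mean"], aa["sd"],
                                  aa["min"], aa["max"])
  hpo <- vector("list", n)
  hpo[symptomatic] <- list("HP:0001263")
  hpo[!symptomatic] <- list(character(0))
  manifest <- tibble(
    participant_id = pid,
    family_id = sprintf("SFAM%05d", fam_idx),
    role = role,
    sex = ifelse(male, "male", "female"),
    age_years = round(age, 1),
    clinical_status = ifelse(symptomatic, "symptomatic", "asymptomatic"),
    consanguineous_parents = consang,
    hpo_terms = hpo
  )

  calls <- list()
  truth <- list()
  for (j in seq_len(nrow(cfg$pairs))) {
    pair <- cfg$pairs[j, ]
    if (pair$moi == "AR") {
      pc <- ar_genotype_probs(pair$q, cfg$inbreeding_f)
      p0 <- ar_genotype_probs(pair$q, 0)
      u <- stats::runif(n)
      is_c <- consang == "yes"
      p_bi <- ifelse(is_c, pc["biallelic"], p0["biallelic"])
      p_het <- ifelse(is_c, pc["het"], p0["het"])
      geno <- ifelse(u < p_bi, "HOM", ifelse(u < p_bi + p_het, "HET", "NONE"))
      class_expected <- ifelse(geno == "HOM", pair_sf_class(pair$panel),
                               ifelse(geno == "HET", "CARRIER", NA))
    } else {
      geno <- ifelse(stats::runif(n) < pair$ad_rate, "HET", "NONE")
      class_expected <- ifelse(geno == "HET", pair_sf_class(pair$panel), NA)
    }
    planted <- which(geno != "NONE")
    if (!length(planted)) next
    k <- sample.int(3, length(planted), replace = TRUE) # small allelic series
    v <- ref_variant(pair$gene, 1) # series base; offset below
    dp <- 10 + stats::rpois(length(planted), 30)
    alt_n <- ifelse(geno[planted] == "HOM", dp,
                    stats::rbinom(length(planted), dp, 0.5))
    calls[[j]] <- tibble(
      participant_id = pid[planted],
      gene = pair$gene,
      chrom = v$chrom,
      pos = v$pos + 137 * (k - 1),
      ref = "A", alt = "G",
      hgvs = sprintf("NM_SYN(%s):c.%dA>G", pair$gene, 100 + k),
      classification = "P",
      zygosity = geno[planted],
      ref_reads = dp - alt_n,
      alt_reads = alt_n
    )
    truth[[j]] <- tibble(
      participant_id = pid[planted],
      gene = pair$gene,
      disease = pair$disease,
      panel = pair$panel,
      moi = pair$moi,
      zygosity_planted = geno[planted],
      class_expected = class_expected[planted],
      allelic_expected = ifelse(geno[planted] == "HOM",
                                "BIALLELIC", "MONOALLELIC")
    )
  }
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls)) {
    calls <- calls |>
      dplyr::mutate(
        depth = .data$ref_reads + .data$alt_reads,
        alt_fraction = .data$alt_reads / .data$depth,
        variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt,
                           sep = ":")
      )
  }
  list(manifest = manifest, calls = calls,
       truth = dplyr::bind_rows(truth), config = cfg)
}

pair_sf_class <- function(panel) {
  ifelse(panel == "acmg", "ACMG_SF", "NONACMG_SF")
}

#' Compare triage output against a simulation's planted truth
#'
#' Runs [triage_cohort()] on a simulated cohort and joins the result to the
#' planted truth. Planted findings whose calls failed QC (a small
#' stochastic fraction of heterozygotes with low drawn allele fractions)
#' are marked `qc_dropped` and excluded from the mismatch count, since no
#' reporting pipeline can recover a call its quality policy removed.
#'
#' @param sim Output of [simulate_cohort()].
#' @param ... Passed to [triage_cohort()] (panels, QC policy, flags).
#' @return A list with `detail` (per planted finding: expected vs observed
#'   class), `n_mismatch`, `n_qc_dropped`, and `rates` (per expected class:
#'   planted and recovered participant-level rates).
#' @export
recover_findings <- function(sim, ...) {
  findings <- triage_cohort(sim$manifest, sim$calls, quiet = TRUE, ...)
  qc_ok <- qc_pass(sim$calls, qc_policy())
  ok_keys <- paste(sim$calls$participant_id, sim$calls$gene)[qc_ok]
  detail <- sim$truth |>
    dplyr::left_join(
      dplyr::select(findings, "participant_id", "gene",
                    observed_class = "finding_class",
                    observed_allelic = "allelic_status"),
      by = c("participant_id", "gene")
    ) |>
    dplyr::mutate(
      qc_dropped = !paste(.data$participant_id, .data$gene) %in% ok_keys,
      match = !.data$qc_dropped &
        .data$observed_class == .data$class_expected &
        .data$observed_allelic == .data$allelic_expected
    )
  usable <- detail[!detail$qc_dropped, ]
  n <- nrow(sim$manifest)
  rates <- usable |>
    dplyr::group_by(class = .data$class_expected) |>
    dplyr::summarise(
      planted_participants = dplyr::n_distinct(.data$participant_id),
      planted_rate = .data$planted_participants / n,
      recovered = sum(.data$match),
      .groups = "drop"
    )
  list(detail = detail,
       n_mismatch = sum(!usable$match),
       n_qc_dropped = sum(detail$qc_dropped),
       rates = rates)
}

#' Write a simulated or reference cohort to a directory
#'
#' Writes `manifest.tsv`, `variants.tsv` (flat dialect), optionally
#' `variants.vcf` (multi-sample), `truth.tsv` when present, and a
#' `metadata.json` recording the configuration and seed.
#'
#' @param sim A list with `manifest` and `calls` (and optionally `truth`,
#'   `config`), as from [simulate_cohort()] or [reference_cohort()].
#' @param dir Output directory (created if needed).
#' @param vcf Also write a multi-sample VCF.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, vcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(sim$manifest, file.path(dir, "manifest.tsv"))
  write_variant_table(sim$calls, file.path(dir, "variants.tsv"))
  if (vcf) write_variant_vcf(sim$calls, file.path(dir, "variants.vcf"),
                             sim$manifest)
  if (!is.null(sim$truth)) {
    readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  }
  meta <- list(
    generator = "sfscreenr",
    n_participants = nrow(sim$manifest),
    n_calls = nrow(sim$calls),
    seed = if (!is.null(sim$config)) sim$config$seed,
    config = if (!is.null(sim$config)) {
      sim$config[c("n_index", "n_relatives", "male_fraction",
                   "symptomatic_fraction", "consanguineous_fraction",
                   "inbreeding_f", "deterministic_margins")]
    }
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
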