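# Deterministic reference cohort --------------------------------------------
#
# A fully synthetic 863-participant cohort, generated in code (no stored
# data), that reproduces the published aggregate structure of a large
# consanguineous genome-sequencing cohort: 700 index / 163 relatives, 532
# males, 741 symptomatic, 559 consanguineous index families, and the full
# composition of secondary findings, carrier states and primary findings at
# the printed per-gene counts. Variant coordinates and alleles are
# placeholders on correctly-typed contigs; HGVS strings are synthetic.

REF_GENE_INFO <- c(
  TMEM43 = "3", TTN = "2", MYBPC3 = "11", ACTC1 = "15", TNNT2 = "1",
  KCNQ1 = "11", LDLR = "19", PCSK9 = "1", APOB = "2", FBN1 = "15",
  MSH6 = "2", BRCA1 = "17", PALB2 = "16", RYR1 = "19", MUTYH = "1",
  ABCA4 = "1", BEST1 = "11", ABCG8 = "2", AGXT = "2", COQ8B = "19",
  SLC5A2 = "16", SLC34A1 = "5", MFAP5 = "12", DNAH5 = "5", IYD = "6",
  VWF = "12", COL7A1 = "3", PHOX2B = "4", THBD = "20", CFTR = "7",
  ITGB4 = "17", MEFV = "16", SLC7A9 = "19", BTD = "3", ATP7B = "13",
  GAA = "17", STK11 = "19", MLH1 = "3", RB1 = "13", MYH7 = "14",
  TNNI3 = "19", BRCA2 = "13", GJB2 = "13"
)

ref_variant <- function(gene, k) {
  base <- 1e6 * match(gene, names(REF_GENE_INFO))
  refs <- c("A", "C", "G", "T")
  list(
    chrom = unname(REF_GENE_INFO[gene]),
    pos = base + 137 * k,
    ref = refs[(k - 1) %% 4 + 1],
    alt = c("G", "T", "A", "C")[(k - 1) %% 4 + 1],
    hgvs = sprintf("NM_SYN(%s):c.%dA>G", gene, 100 + k)
  )
}

ref_ages_symptomatic <- function() {
  # lognormal quantile grid: meanlog/sdlog chosen so mean ~4.93, median ~3,
  # sd ~6.2, then truncated at 65 and integer-rounded; one upper-tail value
  # takes the fractional remainder so the mean is exactly 4.93
  v <- stats::qlnorm(stats::ppoints(741), meanlog = 1.124, sdlog = 0.971)
  w <- round(pmin(v, 65))
  target <- 741 * 4.93
  delta <- target - sum(w[-735])
  stopifnot(delta > 3.5, delta < 65)
  w[735] <- delta
  w
}

ref_ages_asymptomatic <- function() {
  # normal quantile grid split at the median so the printed median is 29.5
  p <- stats::ppoints(122)
  lower <- round(pmax(stats::qnorm(p[1:61], 28.34, 10.52), 0))
  lower <- pmin(lower, 29)
  lower[1] <- 0
  lower[61] <- 29
  upper <- round(pmin(stats::qnorm(p[62:122], 28.34, 10.52), 55))
  upper <- pmax(upper, 30)
  upper[61] <- 55
  w <- c(lower, upper)
  target <- 122 * 28.34
  delta <- target - sum(w[-100])
  stopifnot(delta > 30, delta < 55)
  w[100] <- delta
  w
}

ref_pf_terms <- c(
  BTD = "HP:0001250", ATP7B = "HP:0001392", GAA = "HP:0003198",
  LDLR = "HP:0003124", FBN1 = "HP:0001166", STK11 = "HP:0004390",
  MLH1 = "HP:0002664", RB1 = "HP:0009919", MYH7 = "HP:0001639",
  TNNI3 = "HP:0001639", CFTR = "HP:0002205", COL7A1 = "HP:0008066",
  ABCA4 = "HP:0007754"
)

ref_manifest <- function() {
  pid <- sprintf("PK%04d", 1:863)
  role <- c(rep("index", 700), rep("relative", 163))
  fam_idx <- c(1:700, 1:163)
  family_id <- sprintf("FAM%04d", fam_idx)
  sex <- rep("female", 863)
  sex[c(1:450, 701:782)] <- "male"
  clinical <- c(rep("symptomatic", 741), rep("asymptomatic", 122))
  consang <- dplyr::case_when(
    fam_idx <= 559 ~ "yes",
    fam_idx <= 681 ~ "no",
    .default = "undisclosed"
  )
  age <- numeric(863)
  age[clinical == "symptomatic"] <- ref_ages_symptomatic()
  age[clinical == "asymptomatic"] <- ref_ages_asymptomatic()
  hpo <- vector("list", 863)
  hpo[clinical == "symptomatic"] <- list("HP:0001263")
  hpo[clinical == "asymptomatic"] <- list(character(0))
  # phenotype-matched participants carry their gene's phenotype term
  pf_assign <- c(
    stats::setNames(rep("BTD", 14),
             sprintf("PK%04d", c(2, 702, 3, 703, 49:58))),
    stats::setNames(rep("ATP7B", 11), sprintf("PK%04d", c(4, 704, 59:67))),
    stats::setNames(rep("GAA", 4), sprintf("PK%04d", 68:71)),
    stats::setNames(rep("LDLR", 2), sprintf("PK%04d", 72:73)),
    stats::setNames(c("FBN1", "STK11", "MLH1", "RB1"), sprintf("PK%04d", 74:77)),
    stats::setNames(c("BTD", "ATP7B", "GAA", "MYH7", "LDLR", "TNNI3"),
             sprintf("PK%04d", 78:83)),
    stats::setNames(rep("CFTR", 4), sprintf("PK%04d", 84:87)),
    stats::setNames(rep("COL7A1", 5), sprintf("PK%04d", 88:92)),
    stats::setNames(rep("ABCA4", 2), sprintf("PK%04d", 93:94))
  )
  for (p in names(pf_assign)) {
    i <- match(p, pid)
    hpo[[i]] <- c(unname(ref_pf_terms[pf_assign[p]]), "HP:0001263")
  }
  tibble(
    participant_id = pid, family_id = family_id, role = role, sex = sex,
    age_years = age, clinical_status = clinical,
    consanguineous_parents = consang, hpo_terms = hpo
  )
}

ref_call_spec <- function() {
  # columns: participant index, gene, variant index within the gene's
  # synthetic allelic series, classification, zygosity
  spec <- list(
    # --- ACMG secondary findings: 24 findings in 23 participants ---------
    list(1, "TMEM43", 1, "P", "HET"), list(701, "TMEM43", 1, "P", "HET"),
    list(5, "TTN", 1, "P", "HET"), list(6, "TTN", 2, "P", "HET"),
    list(7, "TTN", 3, "LP", "HET"), list(8, "TTN", 4, "P", "HET"),
    list(5, "MYBPC3", 1, "P", "HET"), list(9, "MYBPC3", 2, "LP", "HET"),
    list(10, "ACTC1", 1, "P", "HET"),
    list(11, "TNNT2", 1, "LP", "HET"),
    list(12, "KCNQ1", 1, "P", "HET"), list(13, "KCNQ1", 1, "P", "HET"),
    list(14, "KCNQ1", 2, "LP", "HET"),
    list(15, "LDLR", 1, "P", "HET"), list(16, "LDLR", 2, "P", "HOM"),
    list(17, "PCSK9", 1, "LP", "HET"),
    list(18, "APOB", 1, "P", "HET"),
    list(19, "FBN1", 1, "P", "HET"),
    list(20, "MSH6", 1, "P", "HET"),
    list(21, "BRCA1", 1, "P", "HET"),
    list(22, "PALB2", 1, "LP", "HET"), list(23, "PALB2", 2, "P", "HET"),
    list(24, "RYR1", 1, "P", "HET"), list(750, "RYR1", 2, "P", "HET"),
    # --- ACMG carrier status ---------------------------------------------
    list(25, "MUTYH", 1, "LP", "HET"),
    # --- non-ACMG secondary findings: 16 in 16 participants --------------
    list(26, "ABCA4", 1, "P", "HET"), list(27, "ABCA4", 2, "LP", "HET"),
    list(28, "ABCA4", 6, "P", "HOM"),
    list(29, "BEST1", 1, "LP", "HET"),
    list(30, "ABCG8", 1, "P", "HOM"),
    list(31, "AGXT", 1, "P", "HOM"),
    list(32, "COQ8B", 1, "LP", "HOM"),
    list(33, "SLC5A2", 1, "P", "HET"),
    list(34, "SLC34A1", 1, "LP", "HOM"),
    list(35, "MFAP5", 1, "P", "HET"),
    list(36, "DNAH5", 1, "P", "HOM"),
    list(37, "IYD", 1, "LP", "HOM"),
    list(38, "VWF", 1, "P", "HET"),
    list(39, "COL7A1", 1, "LP", "HET"), list(39, "COL7A1", 2, "LP", "HET"),
    list(40, "PHOX2B", 1, "P", "HET"),
    list(751, "THBD", 1, "LP", "HET"),
    # --- non-ACMG AR carriers: 8 participants ----------------------------
    list(41, "CFTR", 10, "P", "HET"), list(42, "CFTR", 11, "P", "HET"),
    list(43, "CFTR", 12, "LP", "HET"), list(44, "CFTR", 13, "P", "HET"),
    list(45, "CFTR", 14, "P", "HET"),
    list(46, "ITGB4", 1, "LP", "HET"),
    list(47, "MEFV", 1, "P", "HET"),
    list(48, "SLC7A9", 1, "LP", "HET"),
    # --- ACMG primary findings, P/LP only: 35 ----------------------------
    list(2, "BTD", 1, "P", "HOM"), list(702, "BTD", 1, "P", "HOM"),
    list(3, "BTD", 2, "P", "HOM"), list(703, "BTD", 2, "P", "HOM"),
    list(49, "BTD", 3, "P", "HOM"), list(50, "BTD", 3, "P", "HOM"),
    list(51, "BTD", 3, "P", "HOM"), list(52, "BTD", 4, "LP", "HOM"),
    list(53, "BTD", 4, "LP", "HOM"), list(54, "BTD", 4, "LP", "HOM"),
    list(55, "BTD", 5, "P", "HOM"), list(56, "BTD", 5, "P", "HOM"),
    list(57, "BTD", 6, "P", "HOM"), list(58, "BTD", 7, "LP", "HOM"),
    list(4, "ATP7B", 1, "P", "HOM"), list(704, "ATP7B", 1, "P", "HOM"),
    list(59, "ATP7B", 2, "P", "HOM"), list(60, "ATP7B", 2, "P", "HOM"),
    list(61, "ATP7B", 3, "LP", "HOM"), list(62, "ATP7B", 3, "LP", "HOM"),
    list(63, "ATP7B", 4, "P", "HOM"), list(64, "ATP7B", 4, "P", "HOM"),
    list(65, "ATP7B", 5, "P", "HOM"), list(66, "ATP7B", 6, "LP", "HOM"),
    list(67, "ATP7B", 7, "P", "HOM"),
    list(68, "GAA", 1, "P", "HOM"), list(69, "GAA", 1, "P", "HOM"),
    list(70, "GAA", 2, "LP", "HOM"), list(71, "GAA", 3, "P", "HOM"),
    list(72, "LDLR", 3, "P", "HET"), list(73, "LDLR", 4, "LP", "HET"),
    list(74, "FBN1", 2, "P", "HET"),
    list(75, "STK11", 1, "P", "HET"),
    list(76, "MLH1", 1, "P", "HOM"),
    list(77, "RB1", 1, "P", "HOM"),
    # --- ACMG primary findings including VUS: 6 more ---------------------
    list(78, "BTD", 8, "LP", "HET"), list(78, "BTD", 9, "VUS", "HET"),
    list(79, "ATP7B", 8, "VUS", "HOM"),
    list(80, "GAA", 4, "VUS", "HOM"),
    list(81, "MYH7", 1, "VUS", "HET"),
    list(82, "LDLR", 5, "VUS", "HET"),
    list(83, "TNNI3", 1, "VUS", "HET"),
    # --- non-ACMG primary findings: 10 P/LP + 1 LP/VUS -------------------
    list(84, "CFTR", 1, "LP", "HOM"), list(85, "CFTR", 2, "LP", "HOM"),
    list(86, "CFTR", 3, "P", "HOM"), list(87, "CFTR", 4, "P", "HOM"),
    list(88, "COL7A1", 3, "P", "HOM"), list(89, "COL7A1", 4, "P", "HOM"),
    list(90, "COL7A1", 5, "P", "HOM"), list(91, "COL7A1", 6, "LP", "HOM"),
    list(92, "COL7A1", 7, "P", "HOM"),
    list(93, "ABCA4", 3, "LP", "HOM"),
    list(94, "ABCA4", 4, "LP", "HET"), list(94, "ABCA4", 5, "VUS", "HET"),
    # --- decoys exercising the filters (no findings expected) ------------
    list(100, "BRCA2", 1, "P", "HET", 4, 4),      # depth 8: QC fail
    list(101, "TTN", 9, "P", "MISSING", 0, 0),    # missing genotype
    list(102, "APOB", 9, "B", "HET"),             # benign: never triaged
    list(103, "KCNQ1", 9, "P", "HET", 90, 10),    # alt fraction 0.1: QC fail
    list(104, "GJB2", 1, "P", "HOM"),             # gene in no panel
    list(105, "TTN", 8, "VUS", "HET")             # VUS without phenotype match
  )
  rows <- lapply(spec, function(s) {
    v <- ref_variant(s[[2]], s[[3]])
    zyg <- s[[5]]
    ref_reads <- if (length(s) >= 6) s[[6]] else if (zyg == "HOM") 0 else 15
    alt_reads <- if (length(s) >= 7) s[[7]] else if (zyg == "HOM") 28 else 15
    tibble(
      participant_id = sprintf("PK%04d", s[[1]]),
      gene = s[[2]], chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      hgvs = v$hgvs, classification = s[[4]], zygosity = zyg,
      ref_reads = ref_reads, alt_reads = alt_reads
    )
  })
  dplyr::bind_rows(rows)
}

#' Deterministic reference cohort
#'
#' Generates, entirely in code, a synthetic 863-participant cohort whose
#' screening output reproduces a published secondary-findings study's
#' aggregate results exactly: 24 ACMG v3.1 secondary findings in 23
#' participants (22 unique variants, 14 genes; 18 cardiovascular including
#' four in TTN, 4 cancer, 2 malignant hyperthermia; one homozygous LDLR;
#' one participant with findings in both MYBPC3 and TTN; one asymptomatic
#' RYR1 finding; a family pair sharing a TMEM43 variant and two unrelated
#' participants sharing a KCNQ1 variant), one MUTYH carrier, 16 non-ACMG
#' secondary findings (8 biallelic, one asymptomatic), 8 non-ACMG AR
#' carriers, 35 P/LP ACMG primary findings (31 biallelic, 23 unique
#' variants, 8 genes) plus 6 VUS-flagged ones, and 10 P/LP non-ACMG primary
#' findings plus one LP/VUS compound heterozygote, all biallelic.
#'
#' @return A list with elements `manifest` (participant tibble), `calls`
#'   (call tibble in the format of [read_variant_table()]) and `expected`
#'   (tibble of the aggregate counts the fixture is constructed to yield).
#' @examples
#' \donttest{
#' ref <- reference_cohort()
#' nrow(ref$manifest) # 863
#' }
#' @export
reference_cohort <- function() {
  calls <- ref_call_spec() |>
    dplyr::mutate(
      depth = .data$ref_reads + .data$alt_reads,
      alt_fraction = dplyr::if_else(.data$depth > 0,
                                    .data$alt_reads / .data$depth, NA_real_),
      variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt,
                         sep = ":")
    ) |>
    dplyr::select(
      "participant_id", "gene", "chrom", "pos", "ref", "alt", "hgvs",
      "classification", "zygosity", "ref_reads", "alt_reads",
      "depth", "alt_fraction", "variant_id"
    )
  list(
    manifest = ref_manifest(),
    calls = calls,
    expected = reference_expected()
  )
}

#' Expected aggregate counts for the reference cohort
#'
#' The packaged expected report: every aggregate the deterministic
#' reference cohort is constructed to reproduce, for field-by-field
#' comparison against [summarize_cohort()] output in tests.
#'
#' @return A tibble with columns `quantity` and `value`.
#' @export
reference_expected <- function() {
  tibble::tribble(
    ~quantity, ~value,
    "n_participants", 863,
    "n_index", 700,
    "n_relatives", 163,
    "n_male", 532,
    "n_symptomatic", 741,
    "n_asymptomatic", 122,
    "n_consanguineous_index", 559,
    "acmg_sf_findings", 24,
    "acmg_sf_participants", 23,
    "acmg_sf_unique_variants", 22,
    "acmg_sf_genes", 14,
    "acmg_sf_biallelic", 1,
    "acmg_sf_cvd", 18,
    "acmg_sf_cancer", 4,
    "acmg_sf_mh", 2,
    "acmg_sf_symptomatic_participants", 22,
    "acmg_carrier_participants", 1,
    "nonacmg_sf_findings", 16,
    "nonacmg_sf_participants", 16,
    "nonacmg_sf_biallelic", 8,
    "nonacmg_sf_unique_variants", 17,
    "nonacmg_sf_genes", 14,
    "nonacmg_sf_eye", 4,
    "nonacmg_sf_symptomatic_participants", 15,
    "nonacmg_carrier_participants", 8,
    "acmg_pf_plp_findings", 35,
    "acmg_pf_plp_biallelic", 31,
    "acmg_pf_plp_unique_variants", 23,
    "acmg_pf_plp_genes", 8,
    "acmg_pf_all_findings", 41,
    "nonacmg_pf_plp_findings", 10,
    "nonacmg_pf_all_findings", 11,
    "sym_age_mean", 4.93,
    "sym_age_median", 3,
    "asym_age_median", 29.5
  )
}
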