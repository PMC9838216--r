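ref <- reference_cohort()
scr <- screen_cohort(ref$manifest, ref$calls, quiet = TRUE)
fnd <- scr$findings
cf <- scr$summary$class_freq
pick <- function(lbl, col) cf[[col]][cf$label == lbl]

test_that("the reference manifest reproduces the cohort characterisation table", {
  m <- ref$manifest
  expect_equal(nrow(m), 863)
  expect_equal(sum(m$role == "index"), 700)
  expect_equal(sum(m$role == "relative"), 163)
  expect_equal(sum(m$sex == "male"), 532)
  expect_equal(sum(m$clinical_status == "symptomatic"), 741)
  idx <- m[m$role == "index", ]
  expect_equal(sum(idx$consanguineous_parents == "yes"), 559)
  expect_equal(sum(idx$consanguineous_parents == "no"), 122)
  expect_equal(sum(idx$consanguineous_parents == "undisclosed"), 19)
  sym_age <- m$age_years[m$clinical_status == "symptomatic"]
  asym_age <- m$age_years[m$clinical_status == "asymptomatic"]
  expect_equal(mean(sym_age), 4.93, tolerance = 1e-9)
  expect_equal(median(sym_age), 3)
  expect_equal(range(sym_age), c(0, 65))
  expect_equal(sd(sym_age), 6.17, tolerance = 0.05)
  expect_equal(mean(asym_age), 28.34, tolerance = 1e-9)
  expect_equal(median(asym_age), 29.5)
  expect_equal(range(asym_age), c(0, 55))
  expect_equal(sd(asym_age), 10.52, tolerance = 0.05)
})

test_that("ACMG secondary findings match the published composition", {
  sf <- fnd[fnd$finding_class == "ACMG_SF", ]
  expect_equal(nrow(sf), 24)
  expect_equal(count_findings(sf, "participant"), 23)
  expect_equal(count_findings(sf, "unique_variant"), 22)
  expect_equal(count_findings(sf, "unique_gene"), 14)
  expect_equal(sum(sf$allelic_status == "BIALLELIC"), 1)
  expect_equal(sf$gene[sf$allelic_status == "BIALLELIC"], "LDLR")
  expect_equal(sum(sf$gene == "TTN"), 4)
  # the one participant with two ACMG SFs carries MYBPC3 and TTN
  two <- table(sf$participant_id)
  expect_equal(sum(two == 2), 1)
  expect_setequal(sf$gene[sf$participant_id == names(two)[two == 2]],
                  c("MYBPC3", "TTN"))
  # family-shared TMEM43 variant and the duplicated KCNQ1 variant
  tmem <- sf[sf$gene == "TMEM43", ]
  expect_equal(nrow(tmem), 2)
  expect_equal(dplyr::n_distinct(tmem$variant_ids), 1)
  kcnq <- sf[sf$gene == "KCNQ1", ]
  expect_equal(nrow(kcnq), 3)
  expect_equal(dplyr::n_distinct(kcnq$variant_ids), 2)
  # one asymptomatic SF, in RYR1
  asym <- ref$manifest$participant_id[
    ref$manifest$clinical_status == "asymptomatic"]
  expect_equal(sf$gene[sf$participant_id %in% asym], "RYR1")
})

test_that("reference frequencies and breakdowns equal the published values", {
  expect_equal(pick("acmg_sf", "percent"), 2.7)
  expect_equal(pick("nonacmg_sf", "percent"), 1.9)
  expect_equal(pick("acmg_carrier", "percent"), 0.12)
  expect_equal(pick("nonacmg_carrier", "percent"), 0.93)
  expect_equal(pick("acmg_pf_plp", "percent"), 4.7)
  expect_equal(pick("acmg_pf_all", "percent"), 5.5)
  expect_equal(pick("nonacmg_pf_plp", "percent"), 1.3)
  expect_equal(pick("nonacmg_pf_all", "percent"), 1.5)
  bd <- category_breakdown(fnd, "ACMG_SF")
  expect_equal(bd$percent[bd$category == "CVD"], 75.0)
  expect_equal(bd$n[bd$category == "CVD"], 18)
  expect_equal(bd$percent[bd$category == "cancer"], 16.7)
  expect_equal(bd$percent[bd$category == "other"], 8.3) # malignant hyperthermia
  nb <- category_breakdown(fnd, "NONACMG_SF")
  expect_equal(nb$n[nb$category == "eye"], 4)
  expect_equal(nb$percent[nb$category == "eye"], 25.0)
  al_non <- allelic_breakdown(fnd, "NONACMG_SF")
  expect_equal(al_non$percent[al_non$allelic_status == "BIALLELIC"], 50)
  al_pf <- allelic_breakdown(fnd, "ACMG_PF", plp_only = TRUE)
  expect_equal(al_pf$n[al_pf$allelic_status == "BIALLELIC"], 31)
  expect_equal(al_pf$percent[al_pf$allelic_status == "BIALLELIC"], 88.6)
})

test_that("carrier and primary-finding detail matches the construction", {
  car <- fnd[fnd$finding_class == "CARRIER", ]
  expect_equal(car$gene[car$panel == "acmg"], "MUTYH")
  expect_equal(sum(car$gene == "CFTR" & car$panel == "nonacmg"), 5)
  expect_equal(nrow(car[car$panel == "nonacmg", ]), 8)
  pf <- fnd[fnd$finding_class == "ACMG_PF" & !fnd$includes_vus, ]
  expect_equal(nrow(pf), 35)
  expect_equal(count_findings(pf, "unique_variant"), 23)
  expect_equal(count_findings(pf, "unique_gene"), 8)
  expect_equal(as.integer(table(pf$gene)[c("BTD", "ATP7B", "GAA")]),
               c(14L, 11L, 4L))
  npf <- fnd[fnd$finding_class == "NONACMG_PF", ]
  expect_equal(nrow(npf), 11)
  expect_equal(sum(!npf$includes_vus), 10)
  expect_true(all(npf$allelic_status == "BIALLELIC"))
  expect_equal(count_findings(npf, "unique_gene"), 3)
  # no identical variants shared between SF and PF occurrences of a gene
  sf_vars <- unlist(strsplit(
    fnd$variant_ids[fnd$finding_class %in% c("ACMG_SF", "NONACMG_SF")], ";"))
  pf_vars <- unlist(strsplit(
    fnd$variant_ids[fnd$finding_class %in% c("ACMG_PF", "NONACMG_PF")], ";"))
  expect_length(intersect(sf_vars, pf_vars), 0)
})

test_that("the screen summary equals the packaged expected report", {
  exp <- reference_expected()
  got <- c(
    n_participants = nrow(ref$manifest),
    n_index = sum(ref$manifest$role == "index"),
    n_relatives = sum(ref$manifest$role == "relative"),
    n_male = sum(ref$manifest$sex == "male"),
    n_symptomatic = sum(ref$manifest$clinical_status == "symptomatic"),
    n_asymptomatic = sum(ref$manifest$clinical_status == "asymptomatic"),
    n_consanguineous_index = sum(
      ref$manifest$consanguineous_parents[ref$manifest$role == "index"] == "yes"),
    acmg_sf_findings = pick("acmg_sf", "n_findings"),
    acmg_sf_participants = pick("acmg_sf", "n_participants"),
    acmg_sf_unique_variants = count_findings(
      fnd[fnd$finding_class == "ACMG_SF", ], "unique_variant"),
    acmg_sf_genes = count_findings(
      fnd[fnd$finding_class == "ACMG_SF", ], "unique_gene"),
    acmg_sf_biallelic = sum(
      fnd$finding_class == "ACMG_SF" & fnd$allelic_status == "BIALLELIC"),
    acmg_sf_cvd = sum(fnd$finding_class == "ACMG_SF" & fnd$category == "CVD"),
    acmg_sf_cancer = sum(
      fnd$finding_class == "ACMG_SF" & fnd$category == "cancer"),
    acmg_sf_mh = sum(fnd$finding_class == "ACMG_SF" & fnd$category == "other"),
    acmg_sf_symptomatic_participants = {
      sym <- ref$manifest$participant_id[
        ref$manifest$clinical_status == "symptomatic"]
      dplyr::n_distinct(fnd$participant_id[
        fnd$finding_class == "ACMG_SF" & fnd$participant_id %in% sym])
    },
    acmg_carrier_participants = pick("acmg_carrier", "n_participants"),
    nonacmg_sf_findings = pick("nonacmg_sf", "n_findings"),
    nonacmg_sf_participants = pick("nonacmg_sf", "n_participants"),
    nonacmg_sf_biallelic = sum(
      fnd$finding_class == "NONACMG_SF" & fnd$allelic_status == "BIALLELIC"),
    nonacmg_sf_unique_variants = count_findings(
      fnd[fnd$finding_class == "NONACMG_SF", ], "unique_variant"),
    nonacmg_sf_genes = count_findings(
      fnd[fnd$finding_class == "NONACMG_SF", ], "unique_gene"),
    nonacmg_sf_eye = sum(
      fnd$finding_class == "NONACMG_SF" & fnd$category == "eye"),
    nonacmg_sf_symptomatic_participants = {
      sym <- ref$manifest$participant_id[
        ref$manifest$clinical_status == "symptomatic"]
      dplyr::n_distinct(fnd$participant_id[
        fnd$finding_class == "NONACMG_SF" & fnd$participant_id %in% sym])
    },
    nonacmg_carrier_participants = pick("nonacmg_carrier", "n_participants"),
    acmg_pf_plp_findings = pick("acmg_pf_plp", "n_findings"),
    acmg_pf_plp_biallelic = sum(
      fnd$finding_class == "ACMG_PF" & !fnd$includes_vus &
        fnd$allelic_status == "BIALLELIC"),
    acmg_pf_plp_unique_variants = count_findings(
      fnd[fnd$finding_class == "ACMG_PF" & !fnd$includes_vus, ],
      "unique_variant"),
    acmg_pf_plp_genes = count_findings(
      fnd[fnd$finding_class == "ACMG_PF" & !fnd$includes_vus, ], "unique_gene"),
    acmg_pf_all_findings = pick("acmg_pf_all", "n_findings"),
    nonacmg_pf_plp_findings = pick("nonacmg_pf_plp", "n_findings"),
    nonacmg_pf_all_findings = pick("nonacmg_pf_all", "n_findings"),
    sym_age_mean = round_half_up(mean(
      ref$manifest$age_years[ref$manifest$clinical_status == "symptomatic"]), 2),
    sym_age_median = median(
      ref$manifest$age_years[ref$manifest$clinical_status == "symptomatic"]),
    asym_age_median = median(
      ref$manifest$age_years[ref$manifest$clinical_status == "asymptomatic"])
  )
  for (q in exp$quantity) {
    expect_equal(unname(got[q]), exp$value[exp$quantity == q], label = q)
  }
})

test_that("decoy calls are filtered, not reported", {
  # depth-8, low-fraction and benign calls plus an off-panel gene produce no
  # reportable findings for their carriers
  decoys <- c("PK0100", "PK0102", "PK0103", "PK0104", "PK0105")
  rep_f <- fnd[fnd$finding_class != "NOT_REPORTABLE", ]
  expect_length(intersect(rep_f$participant_id, decoys), 0)
})
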