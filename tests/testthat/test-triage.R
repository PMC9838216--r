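test_that("allelic status distinguishes mono- and biallelic genotypes", {
  hom <- make_call("P1", "BTD", zygosity = "HOM", ref_reads = 0, alt_reads = 28)
  expect_equal(allelic_status(hom), "BIALLELIC")
  two_het <- dplyr::bind_rows(
    make_call("P1", "BTD", pos = 100), make_call("P1", "BTD", pos = 200)
  )
  expect_equal(allelic_status(two_het), "BIALLELIC")
  expect_equal(allelic_status(two_het, require_phase = TRUE), "MONOALLELIC")
  expect_equal(allelic_status(make_call("P1", "BTD")), "MONOALLELIC")
  hemi <- make_call("P1", "OTC", chrom = "X", zygosity = "HEMI",
                    ref_reads = 0, alt_reads = 20)
  expect_equal(allelic_status(hemi), "MONOALLELIC")
  # the same het variant listed twice is not a compound heterozygote
  dup <- dplyr::bind_rows(make_call("P1", "BTD"), make_call("P1", "BTD"))
  expect_equal(allelic_status(dup), "MONOALLELIC")
  expect_error(allelic_status(make_call("P", "G")[0, ]), "Empty")
})

test_that("moi_disposition encodes zygosity-appropriate reporting", {
  expect_equal(moi_disposition("MONOALLELIC", "AD"), "REPORTABLE")
  expect_equal(moi_disposition("BIALLELIC", "AD"), "REPORTABLE")
  expect_equal(moi_disposition("BIALLELIC", "AR"), "REPORTABLE")
  expect_equal(moi_disposition("MONOALLELIC", "AR"), "CARRIER")
  expect_equal(moi_disposition("MONOALLELIC", "SD"), "REPORTABLE")
  expect_equal(moi_disposition("MONOALLELIC", "XL", hemi = TRUE), "REPORTABLE")
  expect_equal(moi_disposition("MONOALLELIC", "XL", hemi = FALSE), "NONE")
  expect_equal(moi_disposition("MONOALLELIC", "XL", hemi = FALSE,
                               xl_female_sf = TRUE), "REPORTABLE")
  expect_equal(moi_disposition("BIALLELIC", "XL"), "REPORTABLE")
  expect_error(moi_disposition("MONOALLELIC", "mitochondrial"), "inheritance")
})

test_that("phenotype matching intersects term sets, with ancestor closure", {
  expect_true(phenotype_match("HP:0001639", "HP:0001639"))
  expect_false(phenotype_match(character(0), "HP:0001639"))
  expect_false(phenotype_match("HP:0001639", "HP:0001644"))
  expect_error(phenotype_match("cardiomyopathy", "HP:0001639"), "Malformed")
  # 3-node chain: child -> mid -> root; child matches a pair annotated at root
  ont <- hpo_ontology(data.frame(
    id = c("HP:0000003", "HP:0000002", "HP:0000001"),
    parent = c("HP:0000002", "HP:0000001", NA)
  ))
  expect_false(phenotype_match("HP:0000003", "HP:0000001"))
  expect_true(phenotype_match("HP:0000003", "HP:0000001", ont))
  expect_setequal(hpo_ancestors("HP:0000003", ont),
                  c("HP:0000003", "HP:0000002", "HP:0000001"))
})

test_that("OBO parsing recovers ids and is_a edges", {
  tmp <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: HP:0000001", "name: All", "",
    "[Term]", "id: HP:0000002", "name: Mid", "is_a: HP:0000001 ! All", "",
    "[Term]", "id: HP:0000003", "name: Leaf", "is_a: HP:0000002 ! Mid"
  ), tmp)
  ont <- read_hpo_obo(tmp)
  expect_equal(nrow(ont), 3)
  expect_true(phenotype_match("HP:0000003", "HP:0000001", ont))
})

test_that("triage routes SF, carrier and PF paths as specified", {
  manifest <- dplyr::bind_rows(
    make_participant("P1", hpo = "HP:0001263"),             # symptomatic, no match
    make_participant("P2", hpo = "HP:0001263"),
    make_participant("P3", hpo = c("HP:0001250", "HP:0001263")), # matches BTD
    make_participant("P4", clinical_status = "asymptomatic")
  )
  calls <- dplyr::bind_rows(
    make_call("P1", "TTN"),                                   # het P, AD
    make_call("P2", "MUTYH", classification = "LP"),          # het LP, AR
    make_call("P3", "BTD", zygosity = "HOM", ref_reads = 0, alt_reads = 28),
    make_call("P4", "TTN")                                    # asymptomatic SF
  )
  f <- triage_mini(manifest, calls)
  expect_equal(f$finding_class[f$participant_id == "P1"], "ACMG_SF")
  expect_equal(f$finding_class[f$participant_id == "P2"], "CARRIER")
  expect_equal(f$finding_class[f$participant_id == "P3"], "ACMG_PF")
  expect_equal(f$finding_class[f$participant_id == "P4"], "ACMG_SF")
  expect_equal(f$allelic_status[f$participant_id == "P3"], "BIALLELIC")
  expect_false(any(f$includes_vus))
})

test_that("phenotype-matched VUS are flagged primary findings; unmatched VUS are not reported", {
  manifest <- dplyr::bind_rows(
    make_participant("P1", hpo = c("HP:0001250", "HP:0001263")),
    make_participant("P2", hpo = "HP:0001263")
  )
  calls <- dplyr::bind_rows(
    make_call("P1", "BTD", classification = "VUS", zygosity = "HOM",
              ref_reads = 0, alt_reads = 28),
    make_call("P2", "BTD", classification = "VUS")
  )
  f <- triage_mini(manifest, calls)
  expect_equal(f$finding_class[f$participant_id == "P1"], "ACMG_PF")
  expect_true(f$includes_vus[f$participant_id == "P1"])
  expect_equal(f$finding_class[f$participant_id == "P2"], "NOT_REPORTABLE")
  expect_false(f$includes_vus[f$participant_id == "P2"])
})

test_that("asymptomatic participants never receive primary findings", {
  manifest <- make_participant("P1", clinical_status = "asymptomatic")
  calls <- make_call("P1", "BTD", zygosity = "HOM",
                     ref_reads = 0, alt_reads = 28)
  f <- triage_mini(manifest, calls)
  expect_equal(f$finding_class, "ACMG_SF") # biallelic AR, no phenotype
})

test_that("X-linked routing depends on sex and the female-reporting flag", {
  manifest <- dplyr::bind_rows(
    make_participant("P1", sex = "male", hpo = "HP:0001263"),
    make_participant("P2", sex = "female", hpo = "HP:0001263")
  )
  calls <- dplyr::bind_rows(
    make_call("P1", "OTC", chrom = "X", zygosity = "HEMI",
              ref_reads = 0, alt_reads = 20),
    make_call("P2", "OTC", chrom = "X")
  )
  f <- triage_mini(manifest, calls)
  expect_equal(f$finding_class[f$participant_id == "P1"], "ACMG_SF")
  expect_equal(f$finding_class[f$participant_id == "P2"], "NOT_REPORTABLE")
  f2 <- triage_mini(manifest, calls, xl_female_sf = TRUE)
  expect_equal(f2$finding_class[f2$participant_id == "P2"], "ACMG_SF")
})

test_that("triage partitions gene groups, is idempotent and order-invariant", {
  set.seed(42)
  genes <- c("TTN", "MUTYH", "BTD", "CFTR", "VWF", "NOPANEL")
  classes <- c("P", "LP", "VUS")
  manifest <- dplyr::bind_rows(lapply(1:30, function(i) {
    make_participant(
      sprintf("R%02d", i),
      clinical_status = sample(c("symptomatic", "asymptomatic"), 1,
                               prob = c(0.85, 0.15)),
      hpo = if (stats::runif(1) < 0.3) c("HP:0001250", "HP:0001263")
            else "HP:0001263"
    )
  }))
  manifest$hpo_terms[manifest$clinical_status == "asymptomatic"] <-
    list(character(0))
  calls <- dplyr::bind_rows(lapply(1:120, function(j) {
    zyg <- sample(c("HET", "HOM"), 1)
    make_call(
      sprintf("R%02d", sample(30, 1)), sample(genes, 1),
      pos = sample(5, 1) * 100,
      classification = sample(classes, 1), zygosity = zyg,
      ref_reads = if (zyg == "HOM") 0 else 15, alt_reads = 20
    )
  })) |> dplyr::distinct(.data$participant_id, .data$variant_id,
                         .keep_all = TRUE)
  f <- triage_mini(manifest, calls)
  # partition: one finding per participant x gene group
  groups <- dplyr::distinct(calls, .data$participant_id, .data$gene)
  expect_equal(nrow(f), nrow(groups))
  expect_true(all(f$finding_class %in%
    c("ACMG_SF", "NONACMG_SF", "ACMG_PF", "NONACMG_PF",
      "CARRIER", "NOT_REPORTABLE")))
  # no VUS ever enters an SF or carrier finding
  sf_car <- f[f$finding_class %in% c("ACMG_SF", "NONACMG_SF", "CARRIER"), ]
  expect_false(any(grepl("VUS", sf_car$classifications)))
  expect_false(any(sf_car$includes_vus))
  # idempotence / order invariance
  f_shuffled <- triage_mini(manifest, calls[sample(nrow(calls)), ])
  expect_equal(f, f_shuffled)
})

test_that("genes with several panel pairs resolve to one finding without spurious carriers", {
  # ABCA4-style gene: dominant and recessive disease associations
  acmg <- mini_panels()$acmg
  non <- dplyr::bind_rows(
    mini_panels()$nonacmg,
    tibble::tibble(
      gene = "ABCA4", disease = "Macular degeneration", moi = "AD",
      versions = list(character(0)), category = "eye",
      severity = 2L, likelihood = 3L, likelihood_ev = "B",
      effectiveness = 3L, effectiveness_ev = "B", nature = 3L,
      curated = TRUE, hpo_terms = list("HP:0000608")
    ),
    tibble::tibble(
      gene = "ABCA4", disease = "Stargardt disease", moi = "AR",
      versions = list(character(0)), category = "eye",
      severity = 2L, likelihood = 3L, likelihood_ev = "A",
      effectiveness = 3L, effectiveness_ev = "B", nature = 2L,
      curated = TRUE, hpo_terms = list("HP:0007754")
    )
  )
  manifest <- dplyr::bind_rows(
    make_participant("P1", hpo = "HP:0001263"),
    make_participant("P2", hpo = "HP:0001263")
  )
  calls <- dplyr::bind_rows(
    make_call("P1", "ABCA4"),
    make_call("P2", "ABCA4", zygosity = "HOM", ref_reads = 0, alt_reads = 28)
  )
  f <- triage_cohort(manifest, calls, acmg, non, quiet = TRUE)
  expect_equal(nrow(f), 2) # one finding per participant, not per pair
  expect_equal(f$disease[f$participant_id == "P1"], "Macular degeneration")
  expect_equal(f$finding_class[f$participant_id == "P1"], "NONACMG_SF")
  expect_equal(f$disease[f$participant_id == "P2"], "Stargardt disease")
  expect_equal(f$finding_class[f$participant_id == "P2"], "NONACMG_SF")
})

test_that("restricting the panel to an earlier version shrinks the SF set", {
  ref <- reference_cohort()
  f31 <- triage_cohort(ref$manifest, ref$calls, quiet = TRUE)
  f20 <- triage_cohort(ref$manifest, ref$calls,
                       acmg_panel = panel_version_subset(acmg_panel(), "v2.0"),
                       quiet = TRUE)
  key <- function(f) paste(f$participant_id, f$gene)
  sf31 <- key(f31[f31$finding_class == "ACMG_SF", ])
  sf20 <- key(f20[f20$finding_class == "ACMG_SF", ])
  expect_true(all(sf20 %in% sf31))
  expect_lt(length(sf20), length(sf31))
})

test_that("count_findings levels deduplicate as documented", {
  f <- dplyr::bind_rows(
    tibble::tibble(participant_id = "A", gene = "TMEM43",
                   variant_ids = "3:100:A:G", finding_class = "ACMG_SF"),
    tibble::tibble(participant_id = "B", gene = "TMEM43",
                   variant_ids = "3:100:A:G", finding_class = "ACMG_SF"),
    tibble::tibble(participant_id = "A", gene = "TTN",
                   variant_ids = "2:200:C:T", finding_class = "ACMG_SF")
  )
  expect_equal(count_findings(f), 3)
  expect_equal(count_findings(f, "participant"), 2)
  expect_equal(count_findings(f, "unique_variant"), 2)
  expect_equal(count_findings(f, "unique_gene"), 2)
  expect_equal(count_findings(f[0, ]), 0)
  expect_error(count_findings(f, "family"))
})

test_that("overlapping panels and unknown participants are rejected", {
  p <- mini_panels()
  expect_error(
    triage_cohort(make_participant("P1"), make_call("P1", "TTN"),
                  p$acmg, p$acmg, quiet = TRUE),
    "share"
  )
  expect_error(
    triage_cohort(make_participant("P1"), make_call("P9", "TTN"),
                  p$acmg, p$nonacmg, quiet = TRUE),
    "absent"
  )
})
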