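# In-code fixtures shared across the suite. Everything is generated here;
# nothing is read from disk except the packaged panels.

make_call <- function(participant_id, gene, pos = 1000, classification = "P",
                      zygosity = "HET", ref_reads = 15, alt_reads = 15,
                      chrom = "1", ref = "A", alt = "G") {
  depth <- ref_reads + alt_reads
  tibble::tibble(
    participant_id = participant_id, gene = gene, chrom = chrom,
    pos = pos, ref = ref, alt = alt, hgvs = NA_character_,
    classification = classification, zygosity = zygosity,
    ref_reads = ref_reads, alt_reads = alt_reads, depth = depth,
    alt_fraction = ifelse(depth > 0, alt_reads / depth, NA_real_),
    variant_id = paste(chrom, pos, ref, alt, sep = ":")
  )
}

make_participant <- function(participant_id, clinical_status = "symptomatic",
                             sex = "female", hpo = character(0),
                             role = "index", family_id = participant_id,
                             consang = "no", age = 10) {
  tibble::tibble(
    participant_id = participant_id, family_id = family_id, role = role,
    sex = sex, age_years = age, clinical_status = clinical_status,
    consanguineous_parents = consang, hpo_terms = list(hpo)
  )
}

# a minimal two-panel setting: one AD pair and one AR pair per panel
mini_panels <- function() {
  mk <- function(gene, disease, moi, category, hpo) {
    tibble::tibble(
      gene = gene, disease = disease, moi = moi,
      versions = list(c("v3.0", "v3.1")), category = category,
      severity = 3L, likelihood = 3L, likelihood_ev = "A",
      effectiveness = 3L, effectiveness_ev = "A", nature = 3L,
      curated = TRUE, hpo_terms = list(hpo)
    )
  }
  list(
    acmg = dplyr::bind_rows(
      mk("TTN", "Dilated cardiomyopathy", "AD", "CVD", "HP:0001644"),
      mk("MUTYH", "Polyposis", "AR", "cancer", "HP:0002664"),
      mk("OTC", "OTC deficiency", "XL", "metabolic", "HP:0001939"),
      mk("BTD", "Biotinidase deficiency", "AR", "metabolic", "HP:0001250")
    ),
    nonacmg = dplyr::bind_rows(
      mk("CFTR", "Cystic fibrosis", "AR", "respiratory", "HP:0002205"),
      mk("VWF", "von Willebrand disease", "AD", "hematologic", "HP:0001871")
    )
  )
}

triage_mini <- function(manifest, calls, ...) {
  p <- mini_panels()
  triage_cohort(manifest, calls, p$acmg, p$nonacmg, quiet = TRUE, ...)
}
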