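CLASS_LEVELS <- c("P", "LP", "VUS", "LB", "B")
ZYGOSITY_LEVELS <- c("HET", "HOM", "HEMI", "MISSING")
SEX_CHROMS <- c("X", "Y", "chrX", "chrY")

#' Alternate-allele fraction from allelic depths
#'
#' @param ref_reads,alt_reads Non-negative read counts supporting the
#'   reference and alternate allele; the total must be positive.
#' @return `alt_reads / (ref_reads + alt_reads)`.
#' @examples
#' alt_allele_fraction(70, 30) # 0.3
#' @export
alt_allele_fraction <- function(ref_reads, alt_reads) {
  total <- ref_reads + alt_reads
  if (any(is.na(total)) || any(total <= 0)) {
    validation_error("Total read depth must be positive.",
                     which(is.na(total) | total <= 0))
  }
  alt_reads / total
}

#' Variant-quality policy
#'
#' The reporting pipeline keeps a call only when it is supported by at least
#' `min_depth` reads and an alternate-allele fraction of at least
#' `min_alt_fraction`. Defaults: nine reads and a fraction of 0.30.
#'
#' @param min_depth Minimum total read depth (inclusive), at least 1.
#' @param min_alt_fraction Minimum alternate-allele fraction (inclusive),
#'   in (0, 1].
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(min_depth = 9, min_alt_fraction = 0.30) {
  if (min_depth < 1) validation_error("`min_depth` must be >= 1.")
  if (min_alt_fraction <= 0 || min_alt_fraction > 1) {
    validation_error("`min_alt_fraction` must be in (0, 1].")
  }
  structure(list(min_depth = min_depth, min_alt_fraction = min_alt_fraction),
            class = "qc_policy")
}

#' @export
print.qc_policy <- function(x, ...) {
  cat(sprintf("QC policy: depth >= %s, alt fraction >= %s\n",
              x$min_depth, x$min_alt_fraction))
  invisible(x)
}

#' Does a call pass the variant-quality policy?
#'
#' Vectorised over the rows of a call table. Calls with a missing genotype
#' never pass. The thresholds are inclusive: depth 9 passes the default
#' policy, depth 8 does not.
#'
#' @param calls A call tibble (see [read_variant_table()]).
#' @param policy A [qc_policy()].
#' @return Logical vector, one element per call.
#' @export
qc_pass <- function(calls, policy = qc_policy()) {
  stopifnot(inherits(policy, "qc_policy"))
  !is.na(calls$zygosity) & calls$zygosity != "MISSING" &
    !is.na(calls$depth) & calls$depth >= policy$min_depth &
    !is.na(calls$alt_fraction) & calls$alt_fraction >= policy$min_alt_fraction
}

#' Apply the variant-quality policy to a call table
#'
#' Drops missing genotypes and calls failing the depth / allele-fraction
#' thresholds, reporting both counts as messages (the counts are also
#' attached as the `qc_drops` attribute).
#'
#' @inheritParams qc_pass
#' @param quiet Suppress the messages.
#' @return The surviving calls.
#' @export
qc_filter <- function(calls, policy = qc_policy(), quiet = FALSE) {
  missing_gt <- !is.na(calls$zygosity) & calls$zygosity == "MISSING"
  pass <- qc_pass(calls, policy)
  n_missing <- sum(missing_gt)
  n_fail <- sum(!pass & !missing_gt)
  if (!quiet) {
    inform(sprintf(
      "QC: %d of %d calls retained (%d missing genotype, %d below thresholds)",
      sum(pass), nrow(calls), n_missing, n_fail
    ))
  }
  out <- calls[pass, ]
  attr(out, "qc_drops") <- c(missing_genotype = n_missing, below_threshold = n_fail)
  out
}

derive_zygosity <- function(gt, chrom, sex, where) {
  gt <- dplyr::coalesce(gt, ".")
  alleles <- stringr::str_split(gt, "[/|]")
  vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (all(a %in% c(".", ""))) return("MISSING")
    if (length(a) == 1) {
      if (a == "0") return("MISSING") # haploid reference: no alt call
      if (!chrom[i] %in% SEX_CHROMS) {
        validation_error("Haploid genotype on an autosome.", where[i])
      }
      if (is.na(sex[i]) || sex[i] != "male") {
        validation_error(
          "Haploid sex-chromosome genotype for a participant not recorded male.",
          where[i]
        )
      }
      return("HEMI")
    }
    n_alt <- sum(a != "0" & a != ".")
    if (n_alt == 0) "REF" else if (n_alt == 1) "HET" else "HOM"
  }, character(1))
}

finish_calls <- function(calls) {
  bad_class <- !calls$classification %in% CLASS_LEVELS
  if (any(bad_class)) {
    validation_error(
      "Classification must be one of P, LP, VUS, LB, B.",
      paste0(calls$participant_id[bad_class], " ", calls$gene[bad_class],
             " (", calls$classification[bad_class], ")")
    )
  }
  calls <- dplyr::mutate(
    calls,
    depth = .data$ref_reads + .data$alt_reads,
    alt_fraction = dplyr::if_else(
      .data$depth > 0, .data$alt_reads / .data$depth, NA_real_
    ),
    variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":")
  )
  n_ref <- sum(calls$zygosity == "REF")
  if (n_ref > 0) {
    inform(sprintf("Dropped %d homozygous-reference genotype(s).", n_ref))
    calls <- calls[calls$zygosity != "REF", ]
  }
  dplyr::select(
    calls,
    "participant_id", "gene", "chrom", "pos", "ref", "alt", "hgvs",
    "classification", "zygosity", "ref_reads", "alt_reads",
    "depth", "alt_fraction", "variant_id"
  )
}

read_variant_tsv <- function(path, manifest = NULL) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      gene = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      classification = readr::col_character(),
      gt = readr::col_character(),
      ref_reads = readr::col_double(),
      alt_reads = readr::col_double(),
      hgvs = readr::col_character()
    ),
    progress = FALSE
  )
  sex <- participant_sex(raw$participant_id, manifest)
  raw$zygosity <- derive_zygosity(
    raw$gt, raw$chrom, sex,
    paste0(raw$participant_id, " ", raw$chrom, ":", raw$pos)
  )
  finish_calls(dplyr::select(raw, -"gt"))
}

participant_sex <- function(ids, manifest) {
  if (is.null(manifest)) return(rep(NA_character_, length(ids)))
  manifest$sex[match(ids, manifest$participant_id)]
}

read_variant_vcf <- function(path, manifest = NULL,
                             gene_key = "GENE", class_key = "CLASS") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gene <- vcfR::extract.info(vcf, element = gene_key)
  classification <- vcfR::extract.info(vcf, element = class_key)
  if (all(is.na(gene))) {
    validation_error(sprintf("No INFO/%s annotation found in VCF.", gene_key))
  }
  bad_ann <- is.na(gene) | is.na(classification)
  if (any(bad_ann)) {
    validation_error(
      "Records lack gene/classification annotation.",
      paste0(fix$CHROM[bad_ann], ":", fix$POS[bad_ann])
    )
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) validation_error("VCF has no GT FORMAT field.")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  samples <- colnames(gt)
  rows <- list()
  for (r in seq_len(nrow(gt))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      g <- gt[r, s]
      if (is.na(g)) g <- "."
      alleles <- strsplit(g, "[/|]")[[1]]
      ad_v <- if (!is.null(ad) && !is.na(ad[r, s])) {
        suppressWarnings(as.numeric(strsplit(ad[r, s], ",", fixed = TRUE)[[1]]))
      } else {
        rep(NA_real_, length(alts) + 1)
      }
      alt_idx <- sort(unique(suppressWarnings(as.integer(
        alleles[!alleles %in% c("0", ".", "")]
      ))))
      if (length(alt_idx) == 0) {
        # no alt allele called: missing or hom-ref; keep one row so the
        # missing-genotype count is visible downstream
        if (!all(alleles %in% c(".", ""))) next
        rows[[length(rows) + 1]] <- tibble(
          participant_id = s, gene = gene[r], chrom = fix$CHROM[r],
          pos = as.numeric(fix$POS[r]), ref = fix$REF[r], alt = alts[1],
          classification = classification[r], gt = g,
          ref_reads = ad_v[1] %||% NA_real_, alt_reads = NA_real_,
          hgvs = NA_character_
        )
        next
      }
      for (k in alt_idx) {
        # per-alt genotype string: the record's genotype restricted to
        # ref vs this alt, so 1/2 splits into two heterozygous calls
        a_here <- ifelse(alleles == as.character(k), "1",
                         ifelse(alleles %in% c(".", ""), ".", "0"))
        rows[[length(rows) + 1]] <- tibble(
          participant_id = s, gene = gene[r], chrom = fix$CHROM[r],
          pos = as.numeric(fix$POS[r]), ref = fix$REF[r], alt = alts[k],
          classification = classification[r],
          gt = paste(a_here, collapse = "/"),
          ref_reads = dplyr::coalesce(ad_v[1], 0),
          alt_reads = dplyr::coalesce(ad_v[k + 1], 0),
          hgvs = NA_character_
        )
      }
    }
  }
  raw <- dplyr::bind_rows(rows)
  sex <- participant_sex(raw$participant_id, manifest)
  gt_norm <- ifelse(!grepl("[/|]", raw$gt) | nchar(raw$gt) == 1, raw$gt, raw$gt)
  # haploid records keep their single-allele genotype for HEMI derivation
  raw$zygosity <- derive_zygosity(
    ifelse(grepl("^[01.]$", raw$gt), raw$gt, gt_norm),
    raw$chrom, sex, paste0(raw$participant_id, " ", raw$chrom, ":", raw$pos)
  )
  raw$ref_reads[is.na(raw$ref_reads)] <- 0
  raw$alt_reads[is.na(raw$alt_reads)] <- 0
  finish_calls(dplyr::select(raw, -"gt"))
}

#' Read an annotated variant table
#'
#' Accepts either a multi-sample VCF (v4.2/4.3; `GT` and `AD` FORMAT fields
#' plus per-record `INFO` annotations for gene symbol and five-tier
#' classification) or the equivalent flat TSV dialect with columns
#' `participant_id, gene, chrom, pos, ref, alt, classification, gt,
#' ref_reads, alt_reads, hgvs`. Multi-allelic VCF records are split into one
#' call per alternate allele. Genotypes map as `0/1 -> HET`, `1/1 -> HOM`,
#' haploid `1` on a sex chromosome of a male participant `-> HEMI`, and
#' `./." -> MISSING` (dropped later by [qc_filter()] with a logged count).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @param manifest Optional participant manifest (needed to resolve
#'   hemizygous genotypes: sex is looked up by `participant_id`).
#' @param gene_key,class_key INFO keys carrying the gene symbol and the
#'   ACMG/AMP five-tier classification in VCF input.
#' @return A call tibble with one row per participant x alternate allele:
#'   `participant_id, gene, chrom, pos, ref, alt, hgvs, classification,
#'   zygosity, ref_reads, alt_reads, depth, alt_fraction, variant_id`.
#' @export
read_variant_table <- function(path, format = c("auto", "vcf", "tsv"),
                               manifest = NULL,
                               gene_key = "GENE", class_key = "CLASS") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (!file.exists(path)) validation_error("Variant file does not exist.", path)
  switch(format,
    vcf = read_variant_vcf(path, manifest, gene_key, class_key),
    tsv = read_variant_tsv(path, manifest)
  )
}

#' Write a call table in the flat TSV dialect
#'
#' Inverse of the TSV branch of [read_variant_table()]: genotype strings are
#' reconstructed from zygosity (`HET -> 0/1`, `HOM -> 1/1`, `HEMI -> 1`,
#' `MISSING -> ./.`), so a round trip reproduces zygosity, depth and
#' alt fraction exactly.
#'
#' @param calls A call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  out <- dplyr::transmute(
    calls,
    participant_id = .data$participant_id,
    gene = .data$gene,
    chrom = .data$chrom,
    pos = .data$pos,
    ref = .data$ref,
    alt = .data$alt,
    classification = .data$classification,
    gt = dplyr::case_match(.data$zygosity,
      "HET" ~ "0/1", "HOM" ~ "1/1", "HEMI" ~ "1", "MISSING" ~ "./."
    ),
    ref_reads = .data$ref_reads,
    alt_reads = .data$alt_reads,
    hgvs = .data$hgvs
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write calls as a minimal multi-sample VCF
#'
#' Emits a plain-text VCF v4.2 with `INFO/GENE`, `INFO/CLASS` annotations
#' and `GT:AD` genotype fields, one column per participant in `manifest`
#' (or per participant observed in `calls`). One record per unique variant.
#'
#' @param calls A call tibble.
#' @param path Output path (`.vcf`).
#' @param manifest Optional manifest fixing the sample column order.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path, manifest = NULL) {
  samples <- if (!is.null(manifest)) manifest$participant_id else
    sort(unique(calls$participant_id))
  vars <- calls |>
    dplyr::distinct(.data$variant_id, .data$chrom, .data$pos, .data$ref,
                    .data$alt, .data$gene, .data$classification) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"ACMG/AMP five-tier classification\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  call_key <- paste(calls$variant_id, calls$participant_id)
  body <- vapply(seq_len(nrow(vars)), function(i) {
    v <- vars[i, ]
    idx <- match(paste(v$variant_id, samples), call_key)
    cells <- ifelse(
      is.na(idx), "0/0:.,.",
      paste0(
        dplyr::case_match(calls$zygosity[idx],
          "HET" ~ "0/1", "HOM" ~ "1/1", "HEMI" ~ "1", "MISSING" ~ "./."),
        ":", calls$ref_reads[idx], ",", calls$alt_reads[idx]
      )
    )
    paste(c(v$chrom, format(v$pos, scientific = FALSE), ".", v$ref, v$alt,
            ".", "PASS",
            sprintf("GENE=%s;CLASS=%s", v$gene, v$classification),
            "GT:AD", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
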