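#' Read a minimal Human Phenotype Ontology graph from an OBO file
#'
#' Parses `[Term]` stanzas for `id`, `name` and `is_a` lines only — enough
#' to support ancestor-closure phenotype matching. Obsolete terms are kept
#' (they simply have no parents unless stated).
#'
#' @param path Path to an OBO file.
#' @return A tibble with columns `id`, `name`, `parents` (list-column of
#'   parent term ids), with class `hpo_ontology`.
#' @export
read_hpo_obo <- function(path) {
  if (!file.exists(path)) validation_error("OBO file does not exist.", path)
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) validation_error("No [Term] stanzas in OBO file.")
  bounds <- c(term_starts, length(lines) + 1L)
  terms <- lapply(seq_along(term_starts), function(i) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[!grepl("^\\[", block)]
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE)[1])
    name <- sub("^name: *", "", grep("^name:", block, value = TRUE)[1])
    isa <- sub("^is_a: *([^ !]+).*$", "\\1", grep("^is_a:", block, value = TRUE))
    tibble(id = id, name = name %||% NA_character_, parents = list(isa))
  })
  out <- dplyr::bind_rows(terms)
  class(out) <- c("hpo_ontology", class(out))
  out
}

#' Build an ontology object from an edge table
#'
#' Convenience constructor for tests and small custom ontologies.
#'
#' @param edges A data frame with columns `id` and `parent` (one row per
#'   is-a edge); roots appear with `parent = NA` or not at all.
#' @return An `hpo_ontology` tibble as from [read_hpo_obo()].
#' @export
hpo_ontology <- function(edges) {
  out <- edges |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      parents = list(.data$parent[!is.na(.data$parent)]), .groups = "drop"
    ) |>
    dplyr::mutate(name = NA_character_, .after = "id")
  class(out) <- c("hpo_ontology", class(out))
  out
}

#' Ancestor closure of a set of ontology terms
#'
#' @param terms Character vector of term ids.
#' @param ontology An `hpo_ontology` object.
#' @return The input terms together with all their transitive ancestors.
#' @export
hpo_ancestors <- function(terms, ontology) {
  seen <- unique(terms)
  frontier <- seen
  while (length(frontier)) {
    idx <- match(frontier, ontology$id)
    parents <- unique(unlist(ontology$parents[idx[!is.na(idx)]]))
    frontier <- setdiff(parents, seen)
    seen <- c(seen, frontier)
  }
  seen
}

check_hpo_ids <- function(terms, what) {
  bad <- !grepl("^HP:\\d{7}$", terms)
  if (any(bad)) {
    validation_error(sprintf("Malformed %s HPO term id(s).", what), terms[bad])
  }
  invisible(terms)
}

#' Phenotype overlap between a participant and a gene-disease pair
#'
#' True when the participant's phenotype terms intersect the pair's
#' associated terms. With an ontology supplied, each participant term is
#' first expanded to its ancestor closure, so a child term matches a pair
#' annotated with any of its ancestors.
#'
#' @param participant_terms,pair_terms Character vectors of `HP:NNNNNNN` ids.
#' @param ontology Optional `hpo_ontology`.
#' @return Logical scalar.
#' @examples
#' phenotype_match("HP:0001639", "HP:0001639") # TRUE
#' phenotype_match(character(0), "HP:0001639") # FALSE
#' @export
phenotype_match <- function(participant_terms, pair_terms, ontology = NULL) {
  participant_terms <- participant_terms[!is.na(participant_terms)]
  pair_terms <- pair_terms[!is.na(pair_terms)]
  if (!length(participant_terms) || !length(pair_terms)) return(FALSE)
  check_hpo_ids(participant_terms, "participant")
  check_hpo_ids(pair_terms, "panel")
  if (!is.null(ontology)) {
    participant_terms <- hpo_ancestors(participant_terms, ontology)
  }
  length(intersect(participant_terms, pair_terms)) > 0
}

# internal: number of overlapping terms (after closure), used to rank
# competing pairs for primary-finding assignment
phenotype_overlap_n <- function(participant_terms, pair_terms, ontology = NULL) {
  if (!length(participant_terms) || !length(pair_terms)) return(0L)
  if (!is.null(ontology)) {
    participant_terms <- hpo_ancestors(participant_terms, ontology)
  }
  length(intersect(participant_terms, pair_terms))
}
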