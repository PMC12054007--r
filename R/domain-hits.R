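#' Domain-label synonym table
#'
#' Maps external domain identifiers (CD-Search style conserved-domain
#' accessions and common aliases) onto the controlled vocabulary of
#' [hdra_domain_labels()]. Ships as an editable TSV
#' (`extdata/domain_synonyms.tsv`) because external annotation dialects vary.
#'
#' @param path Optional path to an alternative synonym TSV
#'   (columns `alias`, `label`).
#' @return Tibble with columns `alias`, `label`.
#' @export
domain_synonyms <- function(path = NULL) {
  path <- path %||% hdra_extdata("domain_synonyms.tsv")
  syn <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  assert_cols(syn, c("alias", "label"), "synonym table")
  bad <- setdiff(unique(syn$label), hdra_domain_labels())
  if (length(bad) > 0) {
    abort(paste0("synonym table maps to unknown label(s): ",
                 paste(bad, collapse = ", ")))
  }
  syn
}

#' Read a precomputed domain-hit table
#'
#' Consumes CD-Search-style tabular evidence: a TSV with header columns
#' `protein_id, domain_label, from, to, score` in 1-based inclusive residue
#' coordinates. Coordinates are converted to 0-based half-open and labels are
#' mapped to the controlled vocabulary through the synonym table; rows whose
#' label cannot be mapped are skipped with a warning.
#'
#' @param path File path or character vector of TSV lines.
#' @param synonyms Synonym tibble, defaults to [domain_synonyms()].
#' @return Tibble with columns `protein_id`, `domain_label`, `start`, `end`,
#'   `score`, `origin` (always `"external"`).
#' @export
read_domain_hits <- function(path, synonyms = domain_synonyms()) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  empty <- tibble(protein_id = character(), domain_label = character(),
                  start = integer(), end = integer(), score = double(),
                  origin = character())
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 0) return(empty)
  hits <- readr::read_tsv(I(lines), show_col_types = FALSE,
                          col_types = readr::cols(
                            protein_id = "c", domain_label = "c",
                            from = "i", to = "i", score = "d"))
  assert_cols(hits, c("protein_id", "domain_label", "from", "to", "score"),
              "domain-hit table")
  if (nrow(hits) == 0) return(empty)
  if (any(hits$score < 0)) {
    abort(paste0("negative score for hit on ",
                 hits$protein_id[hits$score < 0][1]))
  }
  mapped <- syn_lookup(hits$domain_label, synonyms)
  if (anyNA(mapped)) {
    warn(paste0("skipped hit(s) with unmappable domain label(s): ",
                paste(unique(hits$domain_label[is.na(mapped)]), collapse = ", ")))
  }
  hits %>%
    mutate(domain_label = mapped) %>%
    filter(!is.na(.data$domain_label)) %>%
    mutate(start = .data$from - 1L, end = .data$to, origin = "external") %>%
    select("protein_id", "domain_label", "start", "end", "score", "origin")
}

syn_lookup <- function(labels, synonyms) {
  out <- synonyms$label[match(labels, synonyms$alias)]
  # canonical labels always map to themselves
  canon <- labels %in% hdra_domain_labels()
  out[canon] <- labels[canon]
  out
}
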