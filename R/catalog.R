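#' Load and validate the HdrA class catalog
#'
#' The catalog maps ordered domain templates to the 28 HdrA classes and their
#' 4 major types. Validation enforces the global constraints of the scheme:
#' exactly 28 classes partitioned 13 (type I) / 5 (type Ia) / 7 (type II) /
#' 3 (type III); 2-8 domains per template; pairwise-distinct templates; and
#' type/template consistency ([assign_type()] of every template must equal
#' the catalog's major type).
#'
#' @param path Optional path to an alternative catalog TSV
#'   (columns `class_name`, `major_type`, `template`).
#' @param validate Run the constraint checks (default `TRUE`).
#' @return Tibble with columns `class_name`, `major_type`, `template`
#'   (comma-joined), `domains` (list of token vectors), `n_domains`.
#' @export
hdra_catalog <- function(path = NULL, validate = TRUE) {
  path <- path %||% hdra_extdata("hdra_class_catalog.tsv")
  cat <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  assert_cols(cat, c("class_name", "major_type", "template"), "class catalog")
  cat <- cat %>%
    mutate(domains = strsplit(.data$template, ",", fixed = TRUE),
           n_domains = lengths(.data$domains))
  if (validate) validate_catalog(cat)
  cat
}

validate_catalog <- function(cat) {
  if (nrow(cat) != 28) {
    abort(paste0("catalog must contain exactly 28 classes, found ", nrow(cat)))
  }
  counts <- table(factor(cat$major_type, levels = c("I", "Ia", "II", "III")))
  expected <- c(I = 13L, Ia = 5L, II = 7L, III = 3L)
  if (!identical(as.integer(counts), unname(expected))) {
    abort(paste0("catalog type partition must be 13/5/7/3 (I/Ia/II/III), found ",
                 paste(counts, collapse = "/")))
  }
  if (any(cat$n_domains < 2 | cat$n_domains > 8)) {
    abort("catalog domain counts must lie within [2, 8]")
  }
  if (anyDuplicated(cat$template)) {
    abort(paste0("catalog templates must be pairwise distinct; duplicated: ",
                 cat$template[duplicated(cat$template)][1]))
  }
  if (anyDuplicated(cat$class_name)) abort("catalog class names must be unique")
  bad_tok <- setdiff(unique(unlist(cat$domains)), hdra_domain_labels())
  if (length(bad_tok) > 0) {
    abort(paste0("catalog uses unknown domain token(s): ",
                 paste(bad_tok, collapse = ", ")))
  }
  typed <- vapply(cat$domains, function(d) assign_type(d), character(1))
  if (!all(typed == cat$major_type)) {
    off <- cat$class_name[typed != cat$major_type][1]
    abort(paste0("catalog type/template inconsistency for class ", off))
  }
  invisible(cat)
}

#' Length-filter protein records
#'
#' Removes sequences shorter than the quality threshold (default 300 residues,
#' below which HdrA candidates are treated as incomplete gene calls). The
#' boundary is strict: a 300-residue sequence is kept, 299 is rejected.
#'
#' @param proteins Protein tibble with a `length` column.
#' @param min_length Minimum retained length in residues.
#' @return List with elements `kept` and `rejected`; `rejected` carries a
#'   `reason` column (`"too_short"`).
#' @export
length_filter <- function(proteins, min_length = 300) {
  assert_cols(proteins, c("id", "length"), "protein table")
  if (min_length <= 0) abort("min_length must be positive")
  keep <- proteins$length >= min_length
  list(kept = proteins[keep, , drop = FALSE],
       rejected = mutate(proteins[!keep, , drop = FALSE], reason = "too_short"))
}

#' Assign the major HdrA type of one domain architecture
#'
#' Type definitions, in decision order: no FAD-binding thioredoxin reductase
#' domain means the protein is not an HdrA; two such domains define type II;
#' an inserted GltD defines type III; a C-terminal fused MvhD defines type Ia;
#' anything else with one TRX_FAD is type I. GltD together with two TRX_FAD
#' domains, or GltD together with a terminal MvhD, matches no type in the
#' scheme and raises an error.
#'
#' @param domains Character vector of ordered domain tokens.
#' @return One of `"I"`, `"Ia"`, `"II"`, `"III"`, `"not-hdrA"`.
#' @export
#' @examples
#' assign_type(c("FeS_N", "TRX_FAD", "TRX_FeS", "Fd_ins", "Fd_C"))  # "I"
assign_type <- function(domains) {
  n_trx <- sum(domains == "TRX_FAD")
  has_gltd <- "GltD" %in% domains
  mvhd_last <- length(domains) > 0 && domains[length(domains)] == "MvhD"
  if (n_trx == 0) return("not-hdrA")
  if (has_gltd && (n_trx >= 2 || mvhd_last)) {
    abort("unassignable-combination: GltD with two TRX_FAD domains or with MvhD")
  }
  if (n_trx >= 2) return("II")
  if (has_gltd) return("III")
  if (mvhd_last) return("Ia")
  "I"
}

#' Classify domain architectures against the class catalog
#'
#' Assigns each protein's ordered architecture to a catalog class by exact
#' ordered template match within its assigned major type. Architectures that
#' match no template are reported as `"unassigned"` with the nearest template
#' (minimum edit distance over domain tokens) as evidence; proteins whose
#' domain combination matches no type (see [assign_type()]) get major type
#' `"unassignable-combination"`.
#'
#' @param architecture Architecture tibble from [resolve_architecture()].
#' @param catalog Catalog from [hdra_catalog()].
#' @param proteins Optional protein tibble; proteins without any domain call
#'   then appear in the output as `not-hdrA`.
#' @return Tibble: `protein_id`, `class_name`, `major_type`, `evidence`,
#'   `filter_status` (always `"passed"` here; see [length_filter()]).
#' @export
assign_class <- function(architecture, catalog = hdra_catalog(),
                         proteins = NULL) {
  assert_cols(architecture, c("protein_id", "domain", "start"), "architecture")
  archs <- architecture %>%
    arrange(.data$protein_id, .data$start) %>%
    group_by(.data$protein_id) %>%
    summarise(domains = list(.data$domain), .groups = "drop")
  if (!is.null(proteins)) {
    missing <- setdiff(proteins$id, archs$protein_id)
    if (length(missing) > 0) {
      archs <- bind_rows(archs, tibble(protein_id = missing,
                                       domains = list(character(0))))
    }
  }
  rows <- purrr::map2(archs$protein_id, archs$domains, function(pid, dom) {
    type <- tryCatch(assign_type(dom), error = function(e) "unassignable-combination")
    if (type %in% c("not-hdrA", "unassignable-combination")) {
      return(tibble(protein_id = pid, class_name = "unassigned",
                    major_type = type, evidence = ""))
    }
    templ <- paste(dom, collapse = ",")
    in_type <- catalog[catalog$major_type == type, , drop = FALSE]
    hit <- in_type$class_name[in_type$template == templ]
    if (length(hit) == 1) {
      tibble(protein_id = pid, class_name = hit, major_type = type,
             evidence = templ)
    } else {
      tibble(protein_id = pid, class_name = "unassigned", major_type = type,
             evidence = paste0("nearest:", nearest_template(dom, catalog)))
    }
  })
  bind_rows(rows) %>%
    mutate(filter_status = "passed") %>%
    arrange(.data$protein_id)
}

# nearest catalog entry by edit distance over domain tokens (each token
# mapped to one letter so adist operates on token strings)
nearest_template <- function(domains, catalog) {
  code <- setNames(LETTERS[seq_along(hdra_domain_labels())], hdra_domain_labels())
  enc <- function(d) paste(code[d], collapse = "")
  d <- utils::adist(enc(domains),
                    vapply(catalog$domains, enc, character(1)))[1, ]
  catalog$class_name[which.min(d)]
}

#' Classify proteins end to end
#'
#' Convenience wrapper chaining the quality filter, motif scan, architecture
#' resolution, and class assignment. External domain hits, when supplied,
#' take precedence over builtin motif evidence on overlapping spans.
#'
#' @param proteins Protein tibble from [read_fasta()] or
#'   [simulate_proteins()].
#' @param external_hits Optional hit tibble from [read_domain_hits()].
#' @param catalog Catalog from [hdra_catalog()].
#' @param min_length Quality filter threshold in residues.
#' @param motifs Motif set for the builtin scan.
#' @param rules Assembly rules for [resolve_architecture()].
#' @return Classification tibble as [assign_class()], with `filter_status`
#'   `"too_short"` rows for rejected records.
#' @export
classify_proteins <- function(proteins, external_hits = NULL,
                              catalog = hdra_catalog(), min_length = 300,
                              motifs = hdra_motifs(), rules = assembly_rules()) {
  flt <- length_filter(proteins, min_length)
  hits <- scan_motifs(flt$kept, motifs)
  if (!is.null(external_hits) && nrow(external_hits) > 0) {
    hits <- bind_rows(hits, dplyr::semi_join(
      external_hits, flt$kept, by = c(protein_id = "id")))
  }
  arch <- resolve_architecture(hits, flt$kept, rules)
  res <- assign_class(arch, catalog, proteins = flt$kept)
  if (nrow(flt$rejected) > 0) {
    res <- bind_rows(res, tibble(
      protein_id = flt$rejected$id, class_name = "unassigned",
      major_type = "not-hdrA", evidence = "", filter_status = "too_short"))
  }
  arrange(res, .data$protein_id)
}
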