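#' Run the full HdrA survey over proteins and (optionally) gene features
#'
#' Chains the stages in order: quality filter, motif scan (plus optional
#' external domain evidence), architecture resolution, class/type
#' assignment, FAD-stabilizing residue calls and bifurcation-competence
#' grading, and — when gene features are supplied — gene-cluster detection
#' and FBEB/FBEC function inference. hdrA features are linked to classified
#' proteins by matching `locus_id` to protein `id`.
#'
#' @param proteins Protein tibble (see [read_fasta()]).
#' @param features Optional gene feature tibble (see
#'   [read_feature_table()]).
#' @param external_hits Optional external domain-hit tibble.
#' @param catalog,motifs,rules,rulebook Stage configuration; see
#'   [hdra_catalog()], [hdra_motifs()], [assembly_rules()],
#'   [fbeb_rulebook()].
#' @param min_length Quality-filter threshold (residues).
#' @param anchor Reference anchor for residue calling; default the packaged
#'   synthetic frame [synthetic_hdra_anchor()].
#' @param scheme Alignment [scoring_scheme()].
#' @param max_gap,same_strand_required Gene-clustering rule.
#' @param molybdop_status Optional tibble for [infer_function()].
#' @return An object of class `hdra_survey`: a list of stage tibbles
#'   (`classification`, `architecture`, `residue_calls`, `competence`,
#'   `clusters`, `predictions`) plus the run parameters. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
hdra_survey <- function(proteins, features = NULL, external_hits = NULL,
                        catalog = hdra_catalog(), motifs = hdra_motifs(),
                        rules = assembly_rules(), rulebook = fbeb_rulebook(),
                        min_length = 300, anchor = synthetic_hdra_anchor(),
                        scheme = scoring_scheme(), max_gap = 200,
                        same_strand_required = TRUE, molybdop_status = NULL) {
  flt <- length_filter(proteins, min_length)
  hits <- scan_motifs(flt$kept, motifs)
  if (!is.null(external_hits) && nrow(external_hits) > 0) {
    hits <- bind_rows(hits, dplyr::semi_join(
      external_hits, flt$kept, by = c(protein_id = "id")))
  }
  arch <- resolve_architecture(hits, flt$kept, rules)
  classification <- assign_class(arch, catalog, proteins = flt$kept)
  if (nrow(flt$rejected) > 0) {
    classification <- bind_rows(classification, tibble(
      protein_id = flt$rejected$id, class_name = "unassigned",
      major_type = "not-hdrA", evidence = "", filter_status = "too_short")) %>%
      arrange(.data$protein_id)
  }
  hdra_ids <- classification$protein_id[
    classification$major_type %in% c("I", "Ia", "II", "III")]
  calls <- if (length(hdra_ids) > 0) {
    call_anchored_residues(flt$kept[flt$kept$id %in% hdra_ids, ], anchor,
                           scheme)
  } else {
    tibble(protein_id = character(), position = integer(),
           expected = character(), observed = character(),
           matches_expected = logical(), status = character())
  }
  competence <- if (nrow(calls) > 0) bifurcation_competence(calls) else
    tibble(protein_id = character(), status = character())
  clusters <- predictions <- NULL
  if (!is.null(features) && nrow(features) > 0) {
    clusters <- detect_gene_clusters(features, max_gap, same_strand_required)
    if (nrow(clusters) > 0) {
      type_map <- tibble(locus_id = classification$protein_id,
                         major_type = classification$major_type)
      predictions <- infer_function(clusters, type_map, rulebook,
                                    molybdop_status)
    }
  }
  structure(list(
    proteins = proteins, classification = classification,
    architecture = arch, residue_calls = calls, competence = competence,
    clusters = clusters, predictions = predictions,
    params = list(min_length = min_length, max_gap = max_gap,
                  same_strand_required = same_strand_required,
                  gap_open = scheme$gap_open, gap_extend = scheme$gap_extend,
                  anchor = anchor$ref_id)),
    class = "hdra_survey")
}

#' @export
print.hdra_survey <- function(x, ...) {
  cls <- x$classification
  cat("<hdra_survey>\n")
  cat("  proteins:       ", nrow(x$proteins), "\n")
  cat("  classified HdrA:",
      sum(cls$major_type %in% c("I", "Ia", "II", "III")), "\n")
  tt <- table(cls$major_type[cls$major_type %in% c("I", "Ia", "II", "III")])
  if (length(tt) > 0) {
    cat("  types:          ",
        paste(names(tt), as.integer(tt), sep = "=", collapse = " "), "\n")
  }
  if (!is.null(x$predictions)) {
    cat("  gene clusters:  ", nrow(x$predictions), "\n")
  }
  invisible(x)
}

#' Tidy a survey: one row per protein
#'
#' @param x An `hdra_survey`.
#' @param ... Unused.
#' @return Classification joined with bifurcation-competence status.
#' @method tidy hdra_survey
#' @export
tidy.hdra_survey <- function(x, ...) {
  out <- x$classification
  if (nrow(x$competence) > 0) {
    out <- left_join(out,
                     select(x$competence, "protein_id",
                            competence = "status"),
                     by = "protein_id")
  } else {
    out$competence <- NA_character_
  }
  out
}

#' Survey summary: one row
#'
#' @param x An `hdra_survey`.
#' @param ... Unused.
#' @method glance hdra_survey
#' @export
glance.hdra_survey <- function(x, ...) {
  cls <- x$classification
  typed <- cls$major_type[cls$major_type %in% c("I", "Ia", "II", "III")]
  tibble(
    n_proteins = nrow(x$proteins),
    n_hdra = length(typed),
    n_too_short = sum(cls$filter_status == "too_short"),
    n_unassigned = sum(cls$class_name == "unassigned" &
                         cls$major_type %in% c("I", "Ia", "II", "III")),
    n_classes_observed = dplyr::n_distinct(
      cls$class_name[cls$class_name != "unassigned"]),
    n_type_I = sum(typed == "I"), n_type_Ia = sum(typed == "Ia"),
    n_type_II = sum(typed == "II"), n_type_III = sum(typed == "III"),
    n_competent = sum(x$competence$status == "competent"),
    n_clusters = if (is.null(x$predictions)) 0L else nrow(x$predictions))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Domain-architecture diagram
#'
#' Draws each protein as a horizontal line with its resolved domains as
#' colored segments — the standard cartoon for domain-architecture surveys.
#'
#' @param object An `hdra_survey`.
#' @param max_proteins Cap on proteins drawn (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hdra_survey
#' @export
autoplot.hdra_survey <- function(object, max_proteins = 40, ...) {
  arch <- object$architecture
  ids <- head(unique(arch$protein_id), max_proteins)
  arch <- filter(arch, .data$protein_id %in% ids)
  lens <- tibble(protein_id = object$proteins$id,
                 length = nchar(object$proteins$seq)) %>%
    filter(.data$protein_id %in% ids)
  ggplot2::ggplot(arch) +
    ggplot2::geom_segment(
      data = lens,
      ggplot2::aes(x = 0, xend = .data$length, y = .data$protein_id,
                   yend = .data$protein_id),
      linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$protein_id,
                   yend = .data$protein_id, colour = .data$domain),
      linewidth = 4) +
    ggplot2::labs(x = "residue", y = NULL, colour = "domain") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Gene-cluster map
#'
#' Draws clustered gene neighborhoods as oriented arrows per contig.
#'
#' @param clusters Clustered feature tibble from [detect_gene_clusters()].
#' @return A ggplot object.
#' @export
plot_gene_clusters <- function(clusters) {
  assert_cols(clusters, c("contig", "start", "end", "strand", "label_norm",
                          "cluster_id"), "clusters")
  df <- clusters %>%
    mutate(x = ifelse(.data$strand == "+", .data$start, .data$end),
           xend = ifelse(.data$strand == "+", .data$end, .data$start))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$cluster_id,
                   yend = .data$cluster_id, colour = .data$label_norm),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      linewidth = 2) +
    ggplot2::labs(x = "contig position (nt)", y = NULL, colour = "gene") +
    ggplot2::theme_minimal()
}

#' Run the pipeline and write one TSV per stage plus a manifest
#'
#' File-level orchestration over [hdra_survey()]: reads FASTA (and optional
#' GFF3/TSV features and domain-hit TSV), executes the stages, and writes
#' `classification.tsv`, `architecture.tsv`, `residue_calls.tsv`,
#' `competence.tsv`, and, with features, `clusters.tsv` and
#' `predictions.tsv`, plus `manifest.tsv` (package version, parameters,
#' input checksums). Outputs are deterministic: rerunning an identical
#' configuration reproduces the files byte for byte.
#'
#' @param fasta Path to a protein FASTA file.
#' @param out_dir Output directory (created if needed).
#' @param features Optional path to a GFF3 (or feature TSV) file.
#' @param feature_dialect `"gff3"` or `"tsv"`.
#' @param domain_hits Optional path to an external domain-hit TSV.
#' @param ... Passed to [hdra_survey()].
#' @return The `hdra_survey` object, invisibly.
#' @export
run_hdra_pipeline <- function(fasta, out_dir, features = NULL,
                              feature_dialect = "gff3", domain_hits = NULL,
                              ...) {
  for (p in c(fasta, features, domain_hits)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("input file not found: ", p))
    }
  }
  proteins <- read_fasta(fasta)
  feats <- if (!is.null(features)) read_feature_table(features, feature_dialect)
  ext <- if (!is.null(domain_hits)) read_domain_hits(domain_hits)
  survey <- hdra_survey(proteins, features = feats, external_hits = ext, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- survey$params
  stage <- function(df, name) {
    if (!is.null(df)) {
      write_tsv_report(df, file.path(out_dir, paste0(name, ".tsv")), hdr)
    }
  }
  stage(survey$classification, "classification")
  stage(survey$architecture, "architecture")
  stage(survey$residue_calls, "residue_calls")
  stage(survey$competence, "competence")
  stage(survey$clusters, "clusters")
  stage(survey$predictions, "predictions")
  inputs <- c(fasta, features, domain_hits)
  manifest <- tibble(
    key = c("package", "version",
            paste0("param:", names(hdr)),
            paste0("md5:", basename(inputs))),
    value = c("hdrascan", as.character(utils::packageVersion("hdrascan")),
              vapply(hdr, as.character, character(1)),
              unname(tools::md5sum(inputs))))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(survey)
}
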