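#' Normalize gene annotation labels
#'
#' Canonicalizes gene labels for cluster-composition rules: matching is
#' case-insensitive, formyl-methanofuran dehydrogenase subunit genes collapse
#' to `fwd`/`fmd`, and `frhB` (the F420-reducing hydrogenase beta subunit
#' homologous to FdhB) maps to `fdhB`.
#'
#' @param labels Character vector of gene labels.
#' @return Canonical labels.
#' @export
normalize_gene_labels <- function(labels) {
  canon <- c("hdrA", "hdrB", "hdrC", "hdrD", "mvhA", "mvhG", "mvhD",
             "fdhA", "fdhB", "molybdop", "gltD-marker")
  low <- tolower(labels)
  out <- labels
  idx <- match(low, tolower(canon))
  out[!is.na(idx)] <- canon[idx[!is.na(idx)]]
  out[grepl("^fwd", low)] <- "fwd"
  out[grepl("^fmd", low)] <- "fmd"
  out[low == "frhb"] <- "fdhB"
  out
}

#' Detect gene clusters by strand and intergenic gap
#'
#' Operationalizes manual gene-cluster identification from transcription
#' direction and gaps: scanning each contig left to right, a feature joins
#' the open cluster iff it lies on the same contig, on the same strand (when
#' `same_strand_required`), and the intergenic gap (`next start - previous
#' end`) is at most `max_gap` nucleotides; otherwise a new cluster opens.
#' Clusters partition the input features. Overlapping features are both kept
#' with the gap treated as 0 (warned).
#'
#' @param features Feature tibble from [read_feature_table()] or
#'   [simulate_neighborhood()].
#' @param max_gap Maximum intergenic gap in nucleotides (default 200).
#' @param same_strand_required Require co-orientation (default `TRUE`).
#' @param only_hdra Keep only clusters containing an `hdrA`-labeled gene
#'   (default `TRUE`; set `FALSE` to obtain the full partition).
#' @return The feature tibble with added `label_norm`, `cluster_id`
#'   (contig-qualified), and `contains_hdrA` columns; member order preserved.
#' @export
detect_gene_clusters <- function(features, max_gap = 200,
                                 same_strand_required = TRUE,
                                 only_hdra = TRUE) {
  assert_cols(features, c("contig", "locus_id", "start", "end", "strand",
                          "label"), "feature table")
  if (max_gap < 0) abort("max_gap must be >= 0")
  feats <- arrange(features, .data$contig, .data$start) %>%
    mutate(label_norm = normalize_gene_labels(.data$label))
  feats <- feats %>%
    group_by(.data$contig) %>%
    mutate(gap = .data$start - lag(.data$end)) %>%
    ungroup()
  if (any(feats$gap < 0, na.rm = TRUE)) {
    warn("overlapping features detected; treating their gap as 0")
    feats$gap[!is.na(feats$gap) & feats$gap < 0] <- 0
  }
  feats <- feats %>%
    group_by(.data$contig) %>%
    mutate(new_cluster = is.na(.data$gap) | .data$gap > max_gap |
             (same_strand_required & .data$strand != lag(.data$strand,
                                                         default = first(.data$strand))),
           cluster_id = paste0(.data$contig, ":", cumsum(.data$new_cluster))) %>%
    ungroup() %>%
    select(-"gap", -"new_cluster") %>%
    group_by(.data$cluster_id) %>%
    mutate(contains_hdrA = any(.data$label_norm == "hdrA")) %>%
    ungroup()
  if (only_hdra) feats <- filter(feats, .data$contains_hdrA)
  feats
}

#' Load the FBEB/FBEC inference rulebook
#'
#' @param path Optional path to an alternative rulebook TSV (columns `field`,
#'   `priority`, `requires`, `value`, `confidence`, `note`).
#' @return Rulebook tibble.
#' @export
fbeb_rulebook <- function(path = NULL) {
  path <- path %||% hdra_extdata("fbeb_rulebook.tsv")
  rb <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  assert_cols(rb, c("field", "priority", "requires", "value", "confidence",
                    "note"), "rulebook")
  arrange(rb, .data$field, .data$priority)
}

#' Infer candidate FBEB/FBEC reactions from cluster composition
#'
#' For every hdrA-containing gene cluster, the rulebook is evaluated
#' most-specific-first per prediction field (mid-potential electron carrier,
#' high-potential arm, low-potential arm, free-text notes) against the
#' cluster's normalized gene labels, the major types of its hdrA genes, and
#' the Molybdop active-site status. The prediction is `validated` only when
#' every fired rule row is marked experimentally validated; otherwise it is
#' `predicted`. Every prediction cites the rulebook rows that fired.
#'
#' @param clusters Clustered feature tibble from [detect_gene_clusters()].
#' @param hdra_types Tibble mapping hdrA genes to types: columns `locus_id`,
#'   `major_type`.
#' @param rulebook Rulebook tibble from [fbeb_rulebook()].
#' @param molybdop_status Optional tibble (`locus_id`, `verdict`) from
#'   [molybdop_site_check()]; a cluster satisfies `molybdop_blocked` iff one
#'   of its molybdop genes has verdict `cofactor_blocked`.
#' @return Tibble: `cluster_id`, `contig`, `hdra_types`,
#'   `mid_potential_carrier`, `high_potential_arm`, `low_potential_arm`,
#'   `confidence`, `notes`, `rules_fired`.
#' @export
infer_function <- function(clusters, hdra_types, rulebook = fbeb_rulebook(),
                           molybdop_status = NULL) {
  assert_cols(clusters, c("cluster_id", "locus_id", "label_norm"), "clusters")
  assert_cols(hdra_types, c("locus_id", "major_type"), "hdrA type map")
  split_clusters <- split(clusters, clusters$cluster_id)
  out <- purrr::map(split_clusters, function(cl) {
    hdra_members <- cl$locus_id[cl$label_norm == "hdrA"]
    if (length(hdra_members) == 0) {
      abort(paste0("cluster ", cl$cluster_id[1], " contains no hdrA gene"))
    }
    types <- hdra_types$major_type[match(hdra_members, hdra_types$locus_id)]
    types <- types[!is.na(types)]
    blocked <- FALSE
    if (!is.null(molybdop_status)) {
      mo <- cl$locus_id[cl$label_norm == "molybdop"]
      blocked <- any(molybdop_status$verdict[
        molybdop_status$locus_id %in% mo] == "cofactor_blocked")
    }
    env <- list(labels = cl$label_norm, types = types,
                lone = nrow(cl) == 1, molybdop_blocked = blocked,
                second_hdrA_typeI = length(hdra_members) >= 2 && "I" %in% types)
    fired <- purrr::map(c("mid", "high", "low", "note"), function(f) {
      rows <- rulebook[rulebook$field == f, , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        if (rule_holds(rows$requires[i], env)) return(rows[i, , drop = FALSE])
      }
      NULL
    })
    names(fired) <- c("mid", "high", "low", "note")
    fired_rows <- bind_rows(fired)
    tibble(
      cluster_id = cl$cluster_id[1],
      contig = cl$contig[1],
      hdra_types = paste(sort(unique(types)), collapse = "+"),
      mid_potential_carrier = fired$mid$value %||% "unknown",
      high_potential_arm = fired$high$value %||% "none-detected",
      low_potential_arm = fired$low$value %||% "none",
      confidence = if (all(fired_rows$confidence[fired_rows$field != "note"]
                           == "validated")) "validated" else "predicted",
      notes = fired$note$value %||% "",
      rules_fired = paste(paste0(fired_rows$field, ":", fired_rows$priority),
                          collapse = ";"))
  })
  bind_rows(out)
}

# evaluate an &-of-|s condition string against the cluster environment
rule_holds <- function(requires, env) {
  atoms <- strsplit(requires, "&", fixed = TRUE)[[1]]
  all(vapply(atoms, function(atom) {
    alts <- strsplit(atom, "|", fixed = TRUE)[[1]]
    any(vapply(alts, atom_holds, logical(1), env = env))
  }, logical(1)))
}

atom_holds <- function(atom, env) {
  atom <- trimws(atom)
  if (atom == "always") return(TRUE)
  if (atom == "lone") return(env$lone)
  if (atom == "molybdop_blocked") return(env$molybdop_blocked)
  if (atom == "second_hdrA_typeI") return(env$second_hdrA_typeI)
  if (startsWith(atom, "label:")) {
    return(sub("label:", "", atom) %in% env$labels)
  }
  if (startsWith(atom, "type:")) {
    return(sub("type:", "", atom) %in% env$types)
  }
  abort(paste0("unknown rulebook condition atom: ", atom))
}
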