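msa_matrix <- function(msa) {
  assert_cols(msa, c("id", "aligned"), "MSA")
  if (nrow(msa) == 0) abort("MSA has no rows")
  widths <- nchar(msa$aligned)
  if (length(unique(widths)) != 1) abort("MSA rows differ in aligned length")
  m <- do.call(rbind, strsplit(msa$aligned, ""))
  rownames(m) <- msa$id
  m
}

#' Greedy identity clustering of protein sequences
#'
#' Redundancy reduction in the manner of greedy incremental clustering tools:
#' records are sorted by decreasing length (ties by id), and each record
#' joins the first existing cluster whose representative shares at least
#' `identity_cutoff` identity with it (identity over the shorter sequence,
#' see [pairwise_identity()]); otherwise it founds a new cluster. The
#' length sort makes the result independent of input order; the first-founded
#' cluster wins ties.
#'
#' @param proteins Protein tibble (columns `id`, `seq`).
#' @param identity_cutoff Identity fraction in (0, 1]; default 0.80.
#' @param scheme A [scoring_scheme()].
#' @return Tibble: `id`, `cluster` (integer), `representative` (id),
#'   `identity_to_rep`. Every record appears exactly once.
#' @export
greedy_cluster <- function(proteins, identity_cutoff = 0.80,
                           scheme = scoring_scheme()) {
  assert_cols(proteins, c("id", "seq"), "protein table")
  if (!(identity_cutoff > 0 && identity_cutoff <= 1)) {
    abort("identity_cutoff must lie in (0, 1]")
  }
  if (nrow(proteins) == 0) abort("no records to cluster")
  ord <- order(-nchar(proteins$seq), proteins$id)
  p <- proteins[ord, , drop = FALSE]
  reps <- integer(0)  # row indices of representatives within p
  assign <- integer(nrow(p))
  ident <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      idn <- pairwise_identity(p$seq[reps[k]], p$seq[i], scheme)
      if (idn >= identity_cutoff) {
        assign[i] <- k
        ident[i] <- idn
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
      ident[i] <- 1
    }
  }
  tibble(id = p$id, cluster = assign,
         representative = p$id[reps[assign]],
         identity_to_rep = ident)
}

#' Split a two-TRX (type II) sequence into N- and C-terminal halves
#'
#' Type II HdrA carries two FAD-binding thioredoxin reductase domains with
#' potentially distinct evolutionary histories; for phylogenetics each
#' sequence is split at the midpoint of the inter-domain linker (floor) into
#' an N-terminal and a C-terminal part, each containing exactly one TRX
#' domain.
#'
#' @param record Protein tibble row (columns `id`, `seq`) or one-row tibble.
#' @param trx_spans Two-row matrix or list of two `c(start, end)` 0-based
#'   half-open TRX_FAD spans, in order.
#' @return Two-row tibble (ids suffixed `_N` and `_C`) with columns `id`,
#'   `seq`, `length`.
#' @export
split_type2 <- function(record, trx_spans) {
  if (is.list(trx_spans) && !is.matrix(trx_spans)) {
    trx_spans <- do.call(rbind, trx_spans)
  }
  if (!is.matrix(trx_spans) || nrow(trx_spans) != 2) {
    abort("exactly two TRX_FAD spans are required to split a type II sequence")
  }
  trx_spans <- trx_spans[order(trx_spans[, 1]), , drop = FALSE]
  if (trx_spans[1, 2] > trx_spans[2, 1]) abort("TRX_FAD spans overlap")
  s <- record$seq[1]
  L <- nchar(s)
  if (trx_spans[2, 2] > L) abort("TRX_FAD span exceeds sequence length")
  split <- floor((trx_spans[1, 2] + trx_spans[2, 1]) / 2)
  tibble(id = paste0(record$id[1], c("_N", "_C")),
         seq = c(substr(s, 1, split), substr(s, split + 1, L))) %>%
    mutate(length = nchar(.data$seq))
}

#' Excise an inserted GltD domain
#'
#' Removes the inserted glutamate-synthase small-subunit (GltD) region of a
#' type III HdrA so that the insertion does not interfere with phylogenetic
#' analysis; the flanking regions are concatenated. The span must be strictly
#' internal — GltD is an insertion, not a terminal fusion.
#'
#' @param record Protein tibble row (columns `id`, `seq`).
#' @param gltd_span `c(start, end)` 0-based half-open span of the insertion.
#' @return One-row tibble (`id` suffixed `_noGltD`) with `id`, `seq`,
#'   `length` equal to the original length minus the span length.
#' @export
excise_gltd <- function(record, gltd_span) {
  if (is.null(gltd_span) || length(gltd_span) != 2) {
    abort("a GltD span is required")
  }
  s <- record$seq[1]
  L <- nchar(s)
  if (!(gltd_span[1] > 0 && gltd_span[2] < L && gltd_span[1] < gltd_span[2])) {
    abort("insertion expected internal: span must satisfy 0 < start < end < length")
  }
  tibble(id = paste0(record$id[1], "_noGltD"),
         seq = paste0(substr(s, 1, gltd_span[1]),
                      substr(s, gltd_span[2] + 1, L))) %>%
    mutate(length = nchar(.data$seq))
}

#' Entropy/gap trimming of alignment columns
#'
#' Keeps an alignment column iff the Shannon entropy of its non-gap residues
#' (in bits) is at most `entropy_max` and its gap fraction is at most
#' `gap_fraction_max`. All-gap columns are always removed. This is a
#' deliberate simplification of block-based entropy trimmers (no similarity
#' smoothing, no block gathering): it keeps conserved core columns and drops
#' high-entropy or gappy insert columns.
#'
#' @param msa MSA tibble (columns `id`, `aligned`; gap character `-`).
#' @param entropy_max Maximum column entropy in bits (default 1.5).
#' @param gap_fraction_max Maximum gap fraction (default 0.2).
#' @return List with `mask` (logical per input column) and `msa` (trimmed
#'   MSA tibble). If no column survives, warns and returns an empty MSA.
#' @export
trim_msa_columns <- function(msa, entropy_max = 1.5, gap_fraction_max = 0.2) {
  if (entropy_max < 0) abort("entropy_max must be >= 0")
  if (gap_fraction_max < 0 || gap_fraction_max > 1) {
    abort("gap_fraction_max must lie in [0, 1]")
  }
  m <- msa_matrix(msa)
  stats <- apply(m, 2, function(col) {
    gaps <- col == "-"
    res <- col[!gaps]
    h <- if (length(res) == 0) Inf else {
      p <- table(res) / length(res)
      -sum(p * log2(p))
    }
    c(entropy = h, gap_fraction = mean(gaps))
  })
  mask <- stats["entropy", ] <= entropy_max &
    stats["gap_fraction", ] <= gap_fraction_max
  if (!any(mask)) {
    warn("no alignment column passed the trimming thresholds")
    return(list(mask = mask,
                msa = tibble(id = msa$id, aligned = rep("", nrow(msa)))))
  }
  trimmed <- apply(m[, mask, drop = FALSE], 1, paste, collapse = "")
  list(mask = unname(mask), msa = tibble(id = msa$id, aligned = unname(trimmed)))
}

#' Extract reference-coordinate segments from an alignment
#'
#' Keeps the alignment columns in which a designated reference row is
#' ungapped and whose reference coordinate falls inside one of the mask
#' segments — the mechanism for applying a manually curated core-region mask
#' (e.g. residues within contact distance of FAD) to a full alignment.
#'
#' @param msa MSA tibble (columns `id`, `aligned`).
#' @param ref_id Id of the reference row.
#' @param segments Tibble or data frame with columns `start`, `end`
#'   (0-based half-open, in reference residue coordinates), disjoint and
#'   increasing. Zero rows yield an empty MSA.
#' @return Trimmed MSA tibble.
#' @export
extract_segment_mask <- function(msa, ref_id, segments) {
  m <- msa_matrix(msa)
  if (!ref_id %in% rownames(m)) {
    abort(paste0("reference id '", ref_id, "' is not a row of the MSA"))
  }
  assert_cols(segments, c("start", "end"), "segment mask")
  if (nrow(segments) > 1) {
    seg <- segments[order(segments$start), ]
    if (any(seg$end[-nrow(seg)] > seg$start[-1])) {
      abort("mask segments must be disjoint and increasing")
    }
  }
  ref <- m[ref_id, ]
  ref_coord <- cumsum(ref != "-") - 1L  # 0-based residue coordinate
  in_mask <- rep(FALSE, ncol(m))
  for (i in seq_len(nrow(segments))) {
    in_mask <- in_mask |
      (ref_coord >= segments$start[i] & ref_coord < segments$end[i])
  }
  keep <- in_mask & ref != "-"
  if (!any(keep)) {
    return(tibble(id = msa$id, aligned = rep("", nrow(msa))))
  }
  trimmed <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  tibble(id = msa$id, aligned = unname(trimmed))
}

#' Prepare classified HdrA sequences for phylogenetics
#'
#' Chains the published preparation protocol over a classified survey:
#' redundancy clustering at 80% identity, splitting of type II sequences at
#' the inter-TRX linker midpoint, and excision of the inserted GltD domain
#' from type III sequences. The returned table holds one phylogeny-ready
#' sequence per cluster representative (type II representatives contribute
#' their `_N` and `_C` halves).
#'
#' @param proteins Protein tibble.
#' @param classification Output of [classify_proteins()] or [assign_class()].
#' @param architecture Output of [resolve_architecture()] (supplies TRX and
#'   GltD spans).
#' @param identity_cutoff Clustering cutoff (default 0.80).
#' @param scheme A [scoring_scheme()].
#' @return Tibble: `id`, `seq`, `length`, `source_id`, `major_type`.
#' @export
prepare_phylogeny_set <- function(proteins, classification, architecture,
                                  identity_cutoff = 0.80,
                                  scheme = scoring_scheme()) {
  keep_ids <- classification$protein_id[
    classification$major_type %in% c("I", "Ia", "II", "III")]
  set <- proteins[proteins$id %in% keep_ids, , drop = FALSE]
  if (nrow(set) == 0) abort("no classified HdrA sequences to prepare")
  cl <- greedy_cluster(set, identity_cutoff, scheme)
  reps <- unique(cl$representative)
  out <- purrr::map(reps, function(id) {
    rec <- set[set$id == id, , drop = FALSE]
    type <- classification$major_type[classification$protein_id == id][1]
    arch <- architecture[architecture$protein_id == id, , drop = FALSE]
    if (type == "II") {
      spans <- as.matrix(arch[arch$domain == "TRX_FAD", c("start", "end")])
      res <- split_type2(rec, spans)
    } else if (type == "III") {
      span <- unlist(arch[arch$domain == "GltD", c("start", "end")][1, ])
      res <- excise_gltd(rec, span)
    } else {
      res <- tibble(id = rec$id, seq = rec$seq, length = nchar(rec$seq))
    }
    mutate(res, source_id = id, major_type = type)
  })
  bind_rows(out)
}
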