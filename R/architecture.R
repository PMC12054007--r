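#' Assembly rules for resolving motif hits into domains
#'
#' Window parameters that turn raw motif occurrences into domain calls:
#' two [4Fe-4S] motifs within `fd_pair_max` residues form one ferredoxin
#' domain (two clusters); a single [4Fe-4S] motif starting within the first
#' `fes_n_window` residues is the N-terminal cluster domain; a FAD-binding
#' thioredoxin reductase domain requires two Rossmann fingerprints separated
#' by `rossmann_pair_min`..`rossmann_pair_max` residues; a [2Fe-2S] (MvhD)
#' site is two C-X2-C half-motifs `mvhd_gap_min`..`mvhd_gap_max` residues
#' apart near the C-terminus (`mvhd_cterm_window`). Distances are
#' start-to-start. All windows are calibrated to the packaged synthetic domain
#' templates; for real data the external domain-hit pathway is authoritative.
#'
#' @param ... Named overrides of any default.
#' @return Named list of assembly parameters.
#' @export
assembly_rules <- function(...) {
  rules <- list(
    fes_n_window = 80L,
    fd_pair_max = 60L,
    rossmann_pair_min = 80L,
    rossmann_pair_max = 300L,
    mvhd_gap_min = 25L,
    mvhd_gap_max = 40L,
    mvhd_cterm_window = 150L
  )
  utils::modifyList(rules, list(...))
}

#' Resolve motif hits into an ordered domain architecture
#'
#' Groups motif-level hits into domain calls, resolves overlaps by
#' (higher score, then longer span, then leftmost), and labels iron-sulfur
#' calls by their context: the first single [4Fe-4S] motif inside the
#' N-terminal window is `FeS_N`; a single immediately following a `TRX_FAD`
#' call is `TRX_FeS`; other singles are `FeS_extra`; the first [4Fe-4S] pair
#' after a `TRX_FAD` is the inserted ferredoxin `Fd_ins` and the second is the
#' C-terminal ferredoxin `Fd_C`. An unpaired Rossmann fingerprint flanked by
#' [4Fe-4S] motifs on both sides is the inserted `GltD` domain. External
#' domain-level hits (origin `"external"`) pass through as domain calls and
#' win over builtin motif evidence on the same span (logged).
#'
#' @param hits Hit tibble from [scan_motifs()] and/or [read_domain_hits()].
#' @param proteins Protein tibble; every hit's `protein_id` must appear here.
#' @param rules Assembly parameters from [assembly_rules()].
#' @return Architecture tibble: `protein_id`, `domain`, `start`, `end`,
#'   `score`, ordered by (protein, start); spans are non-overlapping. Proteins
#'   without any domain call contribute no rows.
#' @export
resolve_architecture <- function(hits, proteins, rules = assembly_rules()) {
  assert_cols(proteins, c("id", "seq"), "protein table")
  empty <- tibble(protein_id = character(), domain = character(),
                  start = integer(), end = integer(), score = double())
  if (nrow(hits) == 0) return(empty)
  unknown <- setdiff(unique(hits$protein_id), proteins$id)
  if (length(unknown) > 0) {
    abort(paste0("hits reference unknown protein(s): ",
                 paste(unknown, collapse = ", ")))
  }
  lens <- setNames(nchar(proteins$seq), proteins$id)
  out <- hits %>%
    group_by(.data$protein_id) %>%
    dplyr::group_split() %>%
    purrr::map(function(h) {
      resolve_one(h, lens[[h$protein_id[1]]], rules)
    }) %>%
    bind_rows()
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$protein_id, .data$start)
}

resolve_one <- function(h, len, rules) {
  pid <- h$protein_id[1]
  ext <- h[h$origin == "external", , drop = FALSE]
  bi <- h[h$origin != "external", , drop = FALSE]
  # external evidence wins over builtin motifs on the same span
  if (nrow(ext) > 0 && nrow(bi) > 0) {
    clash <- overlaps_any(bi$start, bi$end, ext$start, ext$end)
    if (any(clash)) {
      inform(paste0(pid, ": ", sum(clash),
                    " builtin motif hit(s) superseded by external evidence"))
      bi <- bi[!clash, , drop = FALSE]
    }
  }
  calls <- bind_rows(
    if (nrow(ext) > 0) {
      tibble(kind = ext$domain_label, start = ext$start, end = ext$end,
             score = ext$score)
    },
    assemble_builtin(bi, len, rules)
  )
  if (nrow(calls) == 0) return(NULL)
  calls <- drop_overlaps(calls)
  calls <- label_fes_calls(calls, rules)
  tibble(protein_id = pid, domain = calls$kind, start = calls$start,
         end = calls$end, score = calls$score)
}

overlaps_any <- function(s1, e1, s2, e2) {
  vapply(seq_along(s1), function(i) any(s1[i] < e2 & e1[i] > s2), logical(1))
}

assemble_builtin <- function(bi, len, rules) {
  if (nrow(bi) == 0) return(NULL)
  bi <- arrange(bi, .data$start)
  ross <- bi[bi$domain_label %in% c("ROSSMANN_NAD", "ROSSMANN_NADP"), ]
  fes4 <- bi[bi$domain_label == "FES4", ]
  fe2s2 <- bi[bi$domain_label == "FE2S2", ]
  calls <- list()

  # TRX_FAD = two Rossmann fingerprints, greedy left-to-right pairing
  taken <- rep(FALSE, nrow(ross))
  i <- 1
  while (i <= nrow(ross)) {
    if (!taken[i]) {
      j <- which(!taken & seq_len(nrow(ross)) > i &
                   (ross$start - ross$start[i]) >= rules$rossmann_pair_min &
                   (ross$start - ross$start[i]) <= rules$rossmann_pair_max)
      if (length(j) > 0) {
        j <- j[1]
        taken[c(i, j)] <- TRUE
        calls[[length(calls) + 1]] <- tibble(
          kind = "TRX_FAD", start = ross$start[i], end = ross$end[j],
          score = ross$score[i] + ross$score[j])
      }
    }
    i <- i + 1
  }
  # an unpaired fingerprint flanked by [4Fe-4S] motifs is an inserted GltD
  for (i in which(!taken)) {
    if (nrow(fes4) > 0 &&
        any(fes4$end <= ross$start[i]) && any(fes4$start >= ross$end[i])) {
      calls[[length(calls) + 1]] <- tibble(
        kind = "GltD", start = ross$start[i], end = ross$end[i],
        score = ross$score[i])
    }
  }
  # MvhD = paired C-X2-C half-motifs near the C-terminus, outside [4Fe-4S] hits
  if (nrow(fe2s2) > 0 && nrow(fes4) > 0) {
    inside <- overlaps_any(fe2s2$start, fe2s2$end, fes4$start, fes4$end)
    fe2s2 <- fe2s2[!inside, , drop = FALSE]
  }
  if (nrow(fe2s2) > 1) {
    taken2 <- rep(FALSE, nrow(fe2s2))
    for (i in seq_len(nrow(fe2s2) - 1)) {
      if (taken2[i]) next
      gap <- fe2s2$start - fe2s2$start[i]
      j <- which(!taken2 & seq_len(nrow(fe2s2)) > i &
                   gap >= rules$mvhd_gap_min & gap <= rules$mvhd_gap_max)
      if (length(j) > 0 && fe2s2$start[i] >= (len - rules$mvhd_cterm_window)) {
        j <- j[1]
        taken2[c(i, j)] <- TRUE
        calls[[length(calls) + 1]] <- tibble(
          kind = "MvhD", start = fe2s2$start[i], end = fe2s2$end[j],
          score = fe2s2$score[i] + fe2s2$score[j])
      }
    }
  }
  # [4Fe-4S] motifs: pairs within the window form one ferredoxin domain
  if (nrow(fes4) > 0) {
    i <- 1
    while (i <= nrow(fes4)) {
      if (i < nrow(fes4) &&
          (fes4$start[i + 1] - fes4$start[i]) <= rules$fd_pair_max) {
        calls[[length(calls) + 1]] <- tibble(
          kind = "FD_PAIR", start = fes4$start[i], end = fes4$end[i + 1],
          score = fes4$score[i] + fes4$score[i + 1])
        i <- i + 2
      } else {
        calls[[length(calls) + 1]] <- tibble(
          kind = "FES_SINGLE", start = fes4$start[i], end = fes4$end[i],
          score = fes4$score[i])
        i <- i + 1
      }
    }
  }
  bind_rows(calls)
}

# keep a maximal non-overlapping set, preferring higher score, longer span,
# then leftmost
drop_overlaps <- function(calls) {
  ord <- order(-calls$score, -(calls$end - calls$start), calls$start)
  keep <- logical(nrow(calls))
  for (i in ord) {
    kept <- which(keep)
    if (length(kept) == 0 ||
        !any(calls$start[i] < calls$end[kept] & calls$end[i] > calls$start[kept])) {
      keep[i] <- TRUE
    }
  }
  arrange(calls[keep, , drop = FALSE], .data$start)
}

label_fes_calls <- function(calls, rules) {
  fes_n_taken <- any(calls$kind == "FeS_N")
  pairs_since_trx <- 0L
  seen_trx <- any(calls$kind == "TRX_FAD") & FALSE  # running flag
  for (i in seq_len(nrow(calls))) {
    k <- calls$kind[i]
    if (k == "TRX_FAD") {
      seen_trx <- TRUE
      pairs_since_trx <- 0L
    } else if (k == "FES_SINGLE") {
      if (!fes_n_taken && !seen_trx && calls$start[i] < rules$fes_n_window) {
        calls$kind[i] <- "FeS_N"
        fes_n_taken <- TRUE
      } else if (i > 1 && calls$kind[i - 1] == "TRX_FAD") {
        calls$kind[i] <- "TRX_FeS"
      } else {
        calls$kind[i] <- "FeS_extra"
      }
    } else if (k == "FD_PAIR") {
      calls$kind[i] <- if (pairs_since_trx == 0L) "Fd_ins" else "Fd_C"
      pairs_since_trx <- pairs_since_trx + 1L
    }
  }
  calls
}
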