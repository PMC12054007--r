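# Synthetic domain templates.
#
# Consensus strings are deterministic and synthetic: filler positions cycle
# through an alphabet that excludes C and G, so every motif occurrence
# (all are C- or G-anchored) exists only where planted. They are NOT real
# HdrA segments — no accession is required to run the suite.

SYNTH_FILLER <- "ADEFHIKLMNPQRSTVWY"  # 18 letters, no C, no G
SUB_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Deterministic non-periodic filler: a fixed Lehmer stream keyed by `phase`,
# independent of R's RNG. Aperiodicity matters — repetitive filler would make
# alignment registers ambiguous and positional residue calls meaningless.
filler_chars <- function(n, phase = 0) {
  pool <- strsplit(SYNTH_FILLER, "")[[1]]
  s <- (phase * 7919 + 12345) %% 2147483647 + 1
  out <- character(n)
  for (i in seq_len(n)) {
    s <- (48271 * s) %% 2147483647
    out[i] <- pool[(s %% length(pool)) + 1]
  }
  out
}

FES4_INST <- c("C", "L", "K", "C", "D", "E", "C", "I", "V", "A", "C")

plant <- function(chars, at, inst) {   # at: 0-based offset
  chars[at + seq_along(inst)] <- inst
  chars
}

# Each template: sequence chars, fixed (motif-critical) 0-based positions,
# and for TRX_FAD the 0-based offsets of the FAD-stabilizing K and E sites.
synth_templates <- function() {
  t <- list()
  mk_fes <- function(phase) {
    ch <- plant(filler_chars(50, phase), 5, FES4_INST)
    list(chars = ch, fixed = 5:15, k = NA, e = NA)
  }
  t$FeS_N <- mk_fes(0)
  t$TRX_FeS <- mk_fes(4)
  t$FeS_extra <- mk_fes(9)
  fd <- plant(plant(filler_chars(100, 2), 5, FES4_INST), 45, FES4_INST)
  t$Fd_ins <- list(chars = fd, fixed = c(5:15, 45:55), k = NA, e = NA)
  t$Fd_C <- t$Fd_ins
  trx <- filler_chars(240, 6)
  trx <- plant(trx, 10, strsplit("GAGLLG", "")[[1]])
  trx <- plant(trx, 110, strsplit("GSGTLG", "")[[1]])
  trx[61] <- "E"   # E-site, 0-based offset 60
  trx[81] <- "K"   # K-site, 0-based offset 80
  t$TRX_FAD <- list(chars = trx, fixed = c(10:15, 110:115, 60, 80),
                    k = 80L, e = 60L)
  gl <- plant(filler_chars(60, 11), 20, strsplit("GAGLLG", "")[[1]])
  t$GltD <- list(chars = gl, fixed = 20:25, k = NA, e = NA)
  mv <- filler_chars(60, 13)
  mv <- plant(mv, 10, c("C", "I", "R", "C"))
  mv <- plant(mv, 40, c("C", "V", "E", "C"))
  t$MvhD <- list(chars = mv, fixed = c(10:13, 40:43), k = NA, e = NA)
  t
}

#' Simulate HdrA proteins of a known class
#'
#' Builds each record by concatenating the synthetic per-domain consensus
#' templates of the class, joined by random linkers of 20-60 residues drawn
#' from a C/G-free alphabet. Point substitutions are applied at
#' `substitution_rate` per residue outside motif-critical positions (the
#' motif positions themselves and the K/E FAD-stabilizing sites), so at rate
#' 0 the scanner and classifier recover the planted truth exactly;
#' `corrupt_motifs = TRUE` lifts that protection so scanner robustness can be
#' probed independently. The K- and E-site residues are planted or ablated
#' (to alanine) per the flags, in every TRX_FAD instance. Fully deterministic
#' under `seed`.
#'
#' @param class_name Catalog class to emulate.
#' @param n Number of records.
#' @param substitution_rate Per-residue substitution probability in [0, 1).
#' @param plant_K409,plant_E356 Plant (`TRUE`) or ablate (`FALSE`) the
#'   K409-/E356-equivalent FAD-stabilizing residues.
#' @param seed Integer seed; the single RNG source for the call.
#' @param corrupt_motifs Allow substitutions at motif-critical positions.
#' @param catalog Class catalog (see [hdra_catalog()]).
#' @return List: `proteins` (tibble as [read_fasta()]), `truth` (one row per
#'   record: planted class/type, 1-based K/E positions of the first TRX_FAD,
#'   residue flags), `spans` (planted domain spans, 0-based half-open).
#' @export
simulate_proteins <- function(class_name, n, substitution_rate = 0,
                              plant_K409 = TRUE, plant_E356 = TRUE,
                              seed = 1, corrupt_motifs = FALSE,
                              catalog = hdra_catalog()) {
  if (!(substitution_rate >= 0 && substitution_rate < 1)) {
    abort("substitution_rate must lie in [0, 1)")
  }
  if (n < 1) abort("n must be >= 1")
  entry <- catalog[catalog$class_name == class_name, , drop = FALSE]
  if (nrow(entry) != 1) abort(paste0("unknown class: ", class_name))
  tokens <- entry$domains[[1]]
  templates <- synth_templates()
  withr::with_seed(seed, {
    recs <- purrr::map(seq_len(n), function(i) {
      build_protein(tokens, templates, substitution_rate,
                    plant_K409, plant_E356, corrupt_motifs)
    })
    ids <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "_", class_name),
                   seq_len(n))
    proteins <- tibble(
      id = ids,
      seq = vapply(recs, function(r) r$seq, character(1))) %>%
      mutate(length = nchar(.data$seq),
             sec_flag = FALSE,
             source = paste0("synthetic:", class_name, ":seed=", seed))
    truth <- tibble(
      id = ids, class_name = class_name, major_type = entry$major_type,
      k_pos = vapply(recs, function(r) r$k_pos, integer(1)),
      e_pos = vapply(recs, function(r) r$e_pos, integer(1)),
      k_present = plant_K409, e_present = plant_E356,
      template = entry$template)
    spans <- purrr::map2_dfr(ids, recs, function(id, r) {
      mutate(r$spans, id = id, .before = 1)
    })
    list(proteins = proteins, truth = truth, spans = spans)
  })
}

build_protein <- function(tokens, templates, rate, plant_k, plant_e,
                          corrupt_motifs) {
  chars <- character(0)
  fixed <- integer(0)
  spans <- list()
  k_pos <- NA_integer_
  e_pos <- NA_integer_
  for (i in seq_along(tokens)) {
    if (i > 1) {
      linker_len <- sample(20:60, 1)
      chars <- c(chars, sample(strsplit(SYNTH_FILLER, "")[[1]],
                               linker_len, replace = TRUE))
    }
    tpl <- templates[[tokens[i]]]
    off <- length(chars)
    dom <- tpl$chars
    if (!is.na(tpl$k)) {
      if (!plant_k) dom[tpl$k + 1] <- "A"
      if (!plant_e) dom[tpl$e + 1] <- "A"
      if (is.na(k_pos)) {       # anchor frame = first TRX_FAD instance
        k_pos <- off + tpl$k + 1L
        e_pos <- off + tpl$e + 1L
      }
    }
    chars <- c(chars, dom)
    fixed <- c(fixed, off + tpl$fixed)
    spans[[i]] <- tibble(domain = tokens[i], start = off,
                         end = off + length(dom))
  }
  if (rate > 0) {
    editable <- setdiff(seq_along(chars) - 1L,
                        if (corrupt_motifs) integer(0) else fixed)
    hit <- editable[stats::runif(length(editable)) < rate]
    for (p in hit) {
      cur <- chars[p + 1]
      chars[p + 1] <- sample(setdiff(SUB_ALPHABET, cur), 1)
    }
  }
  list(seq = paste(chars, collapse = ""), spans = bind_rows(spans),
       k_pos = k_pos, e_pos = e_pos)
}

#' The synthetic HdrA reference anchor
#'
#' A deterministic class-A1 sequence (fixed 40-residue linkers, no noise)
#' with the two FAD-stabilizing residues planted, packaged as the default
#' reference frame for residue calling. It is synthetic — a stand-in frame,
#' not the published reference protein — but plays the same role: anchored
#' positions name its K and E sites, and calls on queries are made through
#' alignment to it.
#'
#' @return A [reference_anchor()] with attributes `k_pos` and `e_pos`.
#' @export
synthetic_hdra_anchor <- function() {
  templates <- synth_templates()
  tokens <- c("FeS_N", "TRX_FAD", "TRX_FeS", "Fd_ins", "Fd_C")
  chars <- character(0)
  k_pos <- e_pos <- NA_integer_
  for (i in seq_along(tokens)) {
    if (i > 1) chars <- c(chars, filler_chars(40, 7))
    tpl <- templates[[tokens[i]]]
    if (!is.na(tpl$k) && is.na(k_pos)) {
      k_pos <- length(chars) + tpl$k + 1L
      e_pos <- length(chars) + tpl$e + 1L
    }
    chars <- c(chars, tpl$chars)
  }
  anchored <- setNames(c("K", "E"), c(k_pos, e_pos))
  a <- reference_anchor("HdrA_ref_synthetic", paste(chars, collapse = ""),
                        anchored)
  attr(a, "k_pos") <- k_pos
  attr(a, "e_pos") <- e_pos
  a
}

#' The synthetic Molybdop active-site reference anchor
#'
#' A deterministic 300-residue synthetic frame with the key cofactor-
#' coordinating cysteine at position 118 and the occluding proline and
#' phenylalanine at positions 234 and 235 (the reference frame of the
#' molybdopterin oxidoreductase active-site check). Synthetic stand-in; see
#' [molybdop_site_check()].
#'
#' @return A [reference_anchor()].
#' @export
synthetic_molybdop_anchor <- function() {
  chars <- filler_chars(300, 3)
  chars[118] <- "C"
  chars[234] <- "P"
  chars[235] <- "F"
  reference_anchor("Molybdop_ref_synthetic", paste(chars, collapse = ""),
                   c("118" = "C", "234" = "P", "235" = "F"))
}

#' Simulate a gene neighborhood with a planted cluster layout
#'
#' Places oriented genes left to right on one contig with the specified
#' intergenic gaps and strands; gene lengths are drawn uniformly from
#' 600-2,400 nt under the seed. The truth table records the intended
#' partition (evaluated under the stated clustering rule at generation time).
#'
#' @param layout Tibble or data frame with columns `label`, `strand`, `gap`
#'   (nucleotides to the previous gene; the first gene's gap is ignored).
#' @param seed Integer seed.
#' @param contig Contig name.
#' @param max_gap,same_strand_required Clustering rule used to derive the
#'   planted partition.
#' @return List: `features` (tibble as [read_feature_table()]), `gff3`
#'   (character lines), `truth` (`locus_id`, `cluster_planted`).
#' @export
simulate_neighborhood <- function(layout, seed = 1, contig = "contig_1",
                                  max_gap = 200, same_strand_required = TRUE) {
  assert_cols(layout, c("label", "strand", "gap"), "layout")
  if (any(layout$gap[-1] < 0, na.rm = TRUE)) abort("gaps must be non-negative")
  if (!all(layout$strand %in% c("+", "-"))) abort("strand must be + or -")
  n <- nrow(layout)
  withr::with_seed(seed, {
    lens <- sample(600:2400, n, replace = TRUE)
    starts <- integer(n)
    pos <- 100L
    for (i in seq_len(n)) {
      if (i > 1) pos <- pos + as.integer(layout$gap[i])
      starts[i] <- pos
      pos <- pos + lens[i]
    }
    feats <- tibble(
      contig = contig,
      locus_id = sprintf("g%03d", seq_len(n)),
      start = starts, end = starts + lens,
      strand = layout$strand, label = layout$label)
    new_cl <- c(TRUE, (layout$gap[-1] > max_gap) |
                  (same_strand_required &
                     layout$strand[-1] != layout$strand[-n]))
    truth <- tibble(locus_id = feats$locus_id,
                    cluster_planted = cumsum(new_cl))
    list(features = feats, gff3 = write_gff3(feats), truth = truth)
  })
}

#' Simulate an alignment fixture with conserved core and noisy inserts
#'
#' Core columns have one dominant residue at >= 90% expected frequency and no
#' gaps; insert columns draw uniformly over the 20 standard residues with 30%
#' gaps. Column kinds are interleaved at random under the seed, and the truth
#' mask labels every column, so trimmer behavior can be scored against known
#' ground truth.
#'
#' @param n_rows,core_cols,insert_cols Dimensions (all >= 1).
#' @param seed Integer seed.
#' @return List: `msa` (tibble `id`, `aligned`), `truth` (`column` 1-based,
#'   `kind` core/insert).
#' @export
simulate_msa <- function(n_rows = 10, core_cols = 100, insert_cols = 50,
                         seed = 1) {
  if (min(n_rows, core_cols, insert_cols) < 1) abort("all counts must be >= 1")
  withr::with_seed(seed, {
    total <- core_cols + insert_cols
    kind <- sample(c(rep("core", core_cols), rep("insert", insert_cols)))
    cols <- purrr::map(kind, function(k) {
      if (k == "core") {
        dom <- sample(SUB_ALPHABET, 1)
        ifelse(stats::runif(n_rows) < 0.92, dom,
               sample(SUB_ALPHABET, n_rows, replace = TRUE))
      } else {
        ifelse(stats::runif(n_rows) < 0.30, "-",
               sample(SUB_ALPHABET, n_rows, replace = TRUE))
      }
    })
    m <- do.call(cbind, cols)
    msa <- tibble(id = sprintf("row%02d", seq_len(n_rows)),
                  aligned = apply(m, 1, paste, collapse = ""))
    list(msa = msa, truth = tibble(column = seq_len(total), kind = kind))
  })
}

#' Simulate a full survey bundle
#'
#' One call producing a miniature survey with known truth: `per_class`
#' proteins for every catalog class plus a planted gene neighborhood, ready
#' for [run_hdra_pipeline()] or stage-by-stage use.
#'
#' @param per_class Records per catalog class.
#' @param substitution_rate Per-residue substitution rate.
#' @param seed Integer seed.
#' @param catalog Class catalog.
#' @return List: `proteins`, `truth`, `spans` (as [simulate_proteins()],
#'   concatenated over classes), `neighborhood` (as
#'   [simulate_neighborhood()]).
#' @export
simulate_survey <- function(per_class = 10, substitution_rate = 0, seed = 1,
                            catalog = hdra_catalog()) {
  sims <- purrr::imap(setNames(catalog$class_name, catalog$class_name),
                      function(cls, nm) {
    simulate_proteins(cls, per_class, substitution_rate, seed = seed +
                        match(cls, catalog$class_name), catalog = catalog)
  })
  layout <- tibble(
    label = c("hdrA", "hdrB", "hdrC", "mvhA", "mvhG", "mvhD",
              "hdrA", "fdhB", "molybdop"),
    strand = c(rep("+", 6), rep("-", 3)),
    gap = c(NA, 50, 80, 120, 60, 90, 400, 100, 50))
  list(proteins = bind_rows(purrr::map(sims, "proteins")),
       truth = bind_rows(purrr::map(sims, "truth")),
       spans = bind_rows(purrr::map(sims, "spans")),
       neighborhood = simulate_neighborhood(layout, seed = seed))
}
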