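#' Construct a reference anchor for residue calling
#'
#' A reference anchor names a reference sequence and the 1-based reference
#' positions whose aligned query residues are of interest — e.g. the
#' FAD-stabilizing lysine/glutamate pair of HdrA (K409/E356 in the
#' *Methanothermococcus thermolithotrophicus* reference frame), or the
#' molybdopterin oxidoreductase active-site frame (Cys118 plus the
#' Pro234/Phe235 positions that, when occupied, occlude the Mo/W-bisPGD
#' cofactor site).
#'
#' @param ref_id Reference identifier.
#' @param ref_seq Reference amino-acid sequence.
#' @param anchored Named character vector: names are 1-based reference
#'   positions, values the expected single-letter residues, e.g.
#'   `c("409" = "K", "356" = "E")`.
#' @return A `reference_anchor` object.
#' @export
reference_anchor <- function(ref_id, ref_seq, anchored) {
  check_protein_seq(ref_seq, ref_id)
  pos <- as.integer(names(anchored))
  if (anyNA(pos) || any(pos < 1) || any(pos > nchar(ref_seq))) {
    abort("anchored positions must be 1-based and within the reference length")
  }
  if (any(nchar(anchored) != 1)) abort("expected residues must be single letters")
  structure(list(ref_id = ref_id, ref_seq = ref_seq,
                 position = pos, expected = unname(anchored)),
            class = "reference_anchor")
}

#' Call residues at reference-anchored positions
#'
#' Globally aligns the query to the anchor's reference sequence and reports,
#' for every anchored reference position, the query residue occupying that
#' alignment column (or a gap). Queries whose alignment identity to the
#' reference falls below `min_pid` percent are below the twilight zone where
#' positional equivalence is meaningful: they are reported `unalignable` with
#' all positions undetermined.
#'
#' @param query A protein tibble row (columns `id`, `seq`) or a single
#'   sequence string.
#' @param anchor A [reference_anchor()].
#' @param scheme A [scoring_scheme()].
#' @param min_pid Identity floor, percent of identical alignment columns.
#' @return Tibble: `protein_id`, `position`, `expected`, `observed` (residue,
#'   `"-"` for gap, `NA` if unalignable), `matches_expected`, `status`
#'   (`"determined"` or `"unalignable"`).
#' @export
call_anchored_residues <- function(query, anchor, scheme = scoring_scheme(),
                                   min_pid = 15) {
  if (is.character(query)) query <- tibble(id = "query", seq = query)
  assert_cols(query, c("id", "seq"), "query")
  purrr::map2_dfr(query$id, query$seq, function(id, s) {
    aln <- global_align(anchor$ref_seq, s, scheme)
    if (aln$pid < min_pid) {
      return(tibble(protein_id = id, position = anchor$position,
                    expected = anchor$expected, observed = NA_character_,
                    matches_expected = NA, status = "unalignable"))
    }
    ref_cols <- strsplit(aln$aligned_a, "")[[1]]
    qry_cols <- strsplit(aln$aligned_b, "")[[1]]
    ref_coord <- cumsum(ref_cols != "-")
    obs <- vapply(anchor$position, function(p) {
      col <- which(ref_coord == p & ref_cols != "-")[1]
      qry_cols[col]
    }, character(1))
    tibble(protein_id = id, position = anchor$position,
           expected = anchor$expected, observed = obs,
           matches_expected = obs == anchor$expected, status = "determined")
  })
}

#' Grade electron-bifurcation competence from a residue call
#'
#' Both FAD-stabilizing residues (the K409- and E356-equivalents) must be
#' present for a protein to be graded `competent`; exactly one gives
#' `partial`, neither gives `absent`. The individual flags are always
#' reported alongside, because presence/absence is informative per residue.
#' Undetermined positions give `unknown`.
#'
#' @param call Residue-call tibble from [call_anchored_residues()] (one or
#'   more proteins).
#' @return Tibble: `protein_id`, `status`, `n_matched`, `n_positions`, plus
#'   one logical column per anchored position (`pos_<position>`).
#' @export
bifurcation_competence <- function(call) {
  assert_cols(call, c("protein_id", "position", "matches_expected", "status"),
              "residue call")
  call %>%
    group_by(.data$protein_id) %>%
    summarise(
      status = if (any(.data$status == "unalignable") ||
                   anyNA(.data$matches_expected)) "unknown"
      else if (all(.data$matches_expected)) "competent"
      else if (any(.data$matches_expected)) "partial"
      else "absent",
      n_matched = sum(.data$matches_expected, na.rm = TRUE),
      n_positions = dplyr::n(),
      flags = list(setNames(.data$matches_expected,
                            paste0("pos_", .data$position))),
      .groups = "drop") %>%
    tidyr::unnest_wider("flags")
}

#' Molybdopterin oxidoreductase active-site check
#'
#' Grades the Mo/W-bisPGD active-site state of a Molybdop-family protein
#' against a reference frame carrying the key coordinating cysteine site and
#' the proline/phenylalanine positions whose side chains occlude the cofactor
#' pocket: cysteine at the Cys-equivalent gives `catalytic`; serine there
#' gives `serine_substituted` (a substitution known to abolish catalysis
#' while preserving the fold); no cysteine plus proline or phenylalanine at
#' the occluding positions gives `cofactor_blocked`; anything else — or an
#' unalignable query — is `ambiguous`.
#'
#' @param query Protein tibble or sequence string.
#' @param anchor A [reference_anchor()] whose expected residues are exactly
#'   one `C`, one `P`, and one `F` (e.g. `c("118"="C","234"="P","235"="F")`).
#' @inheritParams call_anchored_residues
#' @return Tibble: `protein_id`, `verdict`, `reason`.
#' @export
molybdop_site_check <- function(query, anchor, scheme = scoring_scheme(),
                                min_pid = 15) {
  if (!identical(sort(anchor$expected), c("C", "F", "P"))) {
    abort("molybdop anchor must carry exactly one C, one P and one F position")
  }
  calls <- call_anchored_residues(query, anchor, scheme, min_pid)
  calls %>%
    group_by(.data$protein_id) %>%
    summarise(verdict = {
      if (any(.data$status == "unalignable")) "ambiguous"
      else {
        obs_c <- .data$observed[.data$expected == "C"]
        obs_p <- .data$observed[.data$expected == "P"]
        obs_f <- .data$observed[.data$expected == "F"]
        if (obs_c == "C") "catalytic"
        else if (obs_c == "S") "serine_substituted"
        else if (obs_p == "P" || obs_f == "F") "cofactor_blocked"
        else "ambiguous"
      }
    },
    reason = if (any(.data$status == "unalignable")) {
      "alignment identity below floor"
    } else {
      paste0("C-site=", .data$observed[.data$expected == "C"],
             " P-site=", .data$observed[.data$expected == "P"],
             " F-site=", .data$observed[.data$expected == "F"])
    },
    .groups = "drop")
}
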