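#' Alignment scoring scheme
#'
#' Defaults: BLOSUM62 substitution values with affine gap penalties
#' (open 10, extend 0.5). Selenocysteine (`U`) is scored as cysteine —
#' Sec-containing HdrA must align normally rather than be rejected — and the
#' unknown residue `X` scores 0 against everything.
#'
#' @param matrix Substitution matrix name (currently `"BLOSUM62"`).
#' @param gap_open,gap_extend Non-negative penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`. `gap_open >= gap_extend` is required.
#' @return A `scoring_scheme` list with the expanded substitution matrix.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  if (!(gap_open >= gap_extend && gap_extend >= 0)) {
    abort("gap penalties must satisfy gap_open >= gap_extend >= 0")
  }
  structure(list(matrix_name = matrix, sub = expand_submat(matrix),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

expand_submat <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  # U scores as C; X scores 0 against everything
  m <- rbind(m, U = m["C", ])
  m <- cbind(m, U = m[, "C"])
  m["U", "U"] <- m["C", "C"]
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

check_alignable <- function(s, what) {
  if (!nzchar(s)) abort(paste0(what, " sequence is empty"))
  check_protein_seq(s, what)
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch-style global alignment under the affine-gap
#' scoring of [scoring_scheme()], computed with `Biostrings::pairwiseAlignment`.
#' The optimal score is unique; where several alignments achieve it, the one
#' reported by the aligner is returned (deterministic for fixed inputs).
#'
#' @param a,b Protein sequences (non-empty; standard residues plus U/X).
#' @param scheme A [scoring_scheme()].
#' @return List with `aligned_a`, `aligned_b` (equal-length gapped strings,
#'   gap character `-`), `score`, and `pid` (percent identical columns over
#'   the alignment length).
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  check_alignable(a, "first")
  check_alignable(b, "second")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scheme$sub,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "global")
  list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
       aligned_b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln),
       pid = Biostrings::pid(aln, type = "PID1"))
}

#' Pairwise sequence identity over the shorter sequence
#'
#' Identical columns of the global alignment divided by the length of the
#' shorter sequence — the identity convention of greedy redundancy clustering
#' tools, so that a perfect fragment of a longer sequence scores 1.
#'
#' @inheritParams global_align
#' @return Identity fraction in [0, 1] (may marginally exceed definitions
#'   based on alignment length; capped at 1).
#' @export
pairwise_identity <- function(a, b, scheme = scoring_scheme()) {
  check_alignable(a, "first")
  check_alignable(b, "second")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scheme$sub,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "global")
  min(Biostrings::nmatch(aln) / min(nchar(a), nchar(b)), 1)
}
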