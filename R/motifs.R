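#' Built-in conserved-motif definitions
#'
#' The deterministic amino-acid patterns used to detect HdrA domains when no
#' external domain-hit table is supplied. `X` matches any residue; bracketed
#' alternatives (`[ST]`) match any listed residue. Shipped as an editable TSV
#' (`extdata/motifs.tsv`) — the set of accepted iron-sulfur motif variants is
#' the intended extension point.
#'
#' Defaults: `FES4` is the bacterial-ferredoxin [4Fe-4S] binding motif
#' C-X2-C-X2-C-X3-C; `FE2S2` is the C-X2-C half-motif whose pairing into a
#' [2Fe-2S] (MvhD-type) site is resolved downstream; `ROSSMANN_NAD`
#' (G-X-G-X-X-G) and `ROSSMANN_NADP` (G-X-G-X-X-A) are the dinucleotide-binding
#' fingerprints whose terminal residue discriminates NAD+ from NADP+
#' preference.
#'
#' @param path Optional path to an alternative motif TSV
#'   (columns `name`, `pattern`, `context`).
#' @return Tibble with columns `name`, `pattern`, `context`.
#' @export
hdra_motifs <- function(path = NULL) {
  path <- path %||% hdra_extdata("motifs.tsv")
  motifs <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  assert_cols(motifs, c("name", "pattern", "context"), "motif table")
  if (anyDuplicated(motifs$name)) abort("motif names must be unique")
  n_pos <- vapply(motifs$pattern, function(p) length(compile_pattern(p)$tokens),
                  integer(1))
  if (any(n_pos < 4)) {
    abort(paste0("motif pattern shorter than 4 positions: ",
                 paste(motifs$name[n_pos < 4], collapse = ", ")))
  }
  motifs
}

# tokenize a pattern into per-position character sets; "X" = wildcard
compile_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  tokens <- list()
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1
      while (j <= length(chars) && chars[j] != "]") j <- j + 1
      if (j > length(chars)) abort(paste0("unclosed '[' in pattern: ", pattern))
      tokens[[length(tokens) + 1]] <- chars[(i + 1):(j - 1)]
      i <- j + 1
    } else {
      tokens[[length(tokens) + 1]] <- chars[i]
      i <- i + 1
    }
  }
  fixed <- !vapply(tokens, function(t) identical(t, "X"), logical(1))
  regex <- paste0(vapply(tokens, function(t) {
    if (identical(t, "X")) "." else if (length(t) > 1) {
      paste0("[", paste(t, collapse = ""), "]")
    } else t
  }, character(1)), collapse = "")
  list(tokens = tokens, fixed = fixed, regex = regex, n_fixed = sum(fixed))
}

#' Scan protein sequences for conserved motifs
#'
#' Reports every occurrence of every motif pattern, including overlapping
#' occurrences of the same motif (resolution into domains happens in
#' [resolve_architecture()]). The score of a hit is the number of
#' fixed (non-wildcard) pattern positions — patterns are all-or-nothing, so
#' equal-pattern hits score equally by design; the score exists to rank
#' different motifs competing for one span.
#'
#' @param proteins Protein tibble (columns `id`, `seq`), e.g. from
#'   [read_fasta()] or [simulate_proteins()].
#' @param motifs Motif definition tibble, defaults to [hdra_motifs()].
#' @return Hit tibble: `protein_id`, `domain_label` (the motif name), `start`,
#'   `end` (0-based half-open), `score`, `origin = "builtin"`. No match yields
#'   zero rows.
#' @export
scan_motifs <- function(proteins, motifs = hdra_motifs()) {
  assert_cols(proteins, c("id", "seq"), "protein table")
  if (nrow(motifs) == 0) abort("motif set is empty")
  compiled <- purrr::map(motifs$pattern, compile_pattern)
  res <- purrr::pmap(list(motifs$name, compiled, motifs$context), function(nm, cp, ctx) {
    look <- paste0("(?=", cp$regex, ")")
    k <- length(cp$tokens)
    purrr::map2_dfr(proteins$id, proteins$seq, function(id, s) {
      m <- gregexpr(look, s, perl = TRUE)[[1]]
      starts <- as.integer(m[m > 0]) - 1L     # to 0-based
      starts <- starts[starts + k <= nchar(s)]  # lookahead at string end
      starts <- apply_context(starts, k, nchar(s), ctx)
      if (length(starts) == 0) return(NULL)
      tibble(protein_id = id, domain_label = nm, start = starts,
             end = starts + k, score = as.double(cp$n_fixed),
             origin = "builtin")
    })
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(protein_id = character(), domain_label = character(),
                  start = integer(), end = integer(), score = double(),
                  origin = character()))
  }
  arrange(out, .data$protein_id, .data$start, .data$domain_label)
}

apply_context <- function(starts, k, len, ctx) {
  if (is.na(ctx) || ctx == "any" || !nzchar(ctx)) return(starts)
  parts <- strsplit(ctx, ":", fixed = TRUE)[[1]]
  w <- as.integer(parts[2])
  switch(parts[1],
         nterm = starts[starts < w],
         cterm = starts[(starts + k) > (len - w)],
         abort(paste0("unknown motif context: ", ctx)))
}

#' Classify a Rossmann-fold fingerprint window
#'
#' The glycine-rich dinucleotide-binding fingerprint ends in glycine
#' (G-X-G-X-X-G) in NAD+-preferring folds and in alanine (G-X-G-X-X-A) in
#' NADP+-preferring folds; the two patterns are mutually exclusive at any one
#' position. The first match in the window decides.
#'
#' @param window Amino-acid string of length >= 6.
#' @return `"NAD"`, `"NADP"`, or `"none"`.
#' @export
#' @examples
#' call_rossmann("GAGAAG")  # "NAD"
#' call_rossmann("GAGAAA")  # "NADP"
call_rossmann <- function(window) {
  if (nchar(window) < 6) abort("Rossmann window must be at least 6 residues")
  nad <- regexpr("G.G..G", window)[1]
  nadp <- regexpr("G.G..A", window)[1]
  if (nad < 0 && nadp < 0) return("none")
  if (nad < 0) return("NADP")
  if (nadp < 0) return("NAD")
  if (nad <= nadp) "NAD" else "NADP"
}
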