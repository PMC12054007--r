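#' Read protein sequences from FASTA
#'
#' Parses multi-record FASTA (wrapped or unwrapped) into a protein table.
#' Residues are upper-cased. Selenocysteine (`U`) is retained and flagged via
#' `sec_flag`: Sec-containing genes are routinely truncated or misread by gene
#' callers, so these records must survive parsing rather than be rejected.
#' In-sequence stop characters (`*`) are stripped with a warning and the
#' record is kept.
#'
#' @param path Path to a FASTA file, or a character vector of FASTA lines.
#' @param source Free-text provenance stored with every record.
#' @return A tibble with columns `id`, `seq`, `length`, `sec_flag`, `source` —
#'   one row per record. Empty input yields a zero-row tibble.
#' @export
#' @examples
#' read_fasta(c(">a", "MKV"))
read_fasta <- function(path, source = "fasta") {
  lines <- if (length(path) == 1 && !startsWith(path[1], ">") && file.exists(path)) {
    readLines(path)
  } else {
    path
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(id = character(), seq = character(), length = integer(),
                  sec_flag = logical(), source = character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    abort(paste0("malformed FASTA: line 1 ('", substr(lines[1], 1, 30),
                 "') is not a header"))
  }
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[is_header])
  if (any(ids == ">" | ids == "")) {
    abort(paste0("malformed FASTA header at line ", which(is_header)[ids == ""][1]))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  grp <- cumsum(is_header)
  seqs <- vapply(split(lines[!is_header], grp[!is_header]),
                 function(x) paste(x, collapse = ""), character(1))
  # headers with no sequence lines
  seqs <- unname(seqs[match(seq_along(ids), as.integer(names(seqs)))])
  seqs[is.na(seqs)] <- ""
  seqs <- toupper(gsub("\\s", "", seqs))
  if (any(grepl("\\*", seqs))) {
    hit <- ids[grepl("\\*", seqs)]
    warn(paste0("stripped in-sequence stop character(s) '*' from: ",
                paste(hit, collapse = ", ")))
    seqs <- gsub("\\*", "", seqs)
  }
  if (any(!nzchar(seqs))) {
    abort(paste0("record(s) with empty sequence: ",
                 paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  purrr::walk2(seqs, ids, check_protein_seq)
  tibble(
    id = ids,
    seq = seqs,
    length = nchar(seqs),
    sec_flag = grepl("U", seqs, fixed = TRUE),
    source = source
  )
}

#' Write a protein table to FASTA
#'
#' @param proteins Tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path Output file path.
#' @param width Line-wrap width; `Inf` writes each sequence on one line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  assert_cols(proteins, c("id", "seq"), "protein table")
  out <- purrr::map2(proteins$id, proteins$seq, function(id, s) {
    body <- if (is.finite(width)) {
      starts <- seq(1, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1, nchar(s)))
    } else s
    c(paste0(">", id), body)
  })
  writeLines(unlist(out), path)
  invisible(path)
}
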