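#' Read a gene feature table (GFF3 or simple TSV)
#'
#' Normalizes gene features into the internal convention: 0-based half-open
#' nucleotide coordinates, sorted by (contig, start). GFF3 input (1-based
#' inclusive) has its coordinates shifted at this boundary; the simple TSV
#' dialect (columns `contig, locus, start, end, strand, label`) is taken to be
#' 0-based half-open already.
#'
#' @param path File path or character vector of lines.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return Tibble with columns `contig`, `locus_id`, `start`, `end`, `strand`,
#'   `label`, sorted by (contig, start).
#' @export
read_feature_table <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (dialect == "gff3") {
    if (length(lines) == 0) return(empty_features())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 9)
    if (length(bad) > 0) {
      abort(paste0("GFF3 row ", bad[1], " does not have 9 tab-separated fields"))
    }
    m <- do.call(rbind, fields)
    feats <- tibble(
      contig = m[, 1],
      locus_id = gff3_attr(m[, 9], "ID"),
      start = suppressWarnings(as.integer(m[, 4])) - 1L,
      end = suppressWarnings(as.integer(m[, 5])),
      strand = m[, 7],
      label = gff3_attr(m[, 9], "label")
    )
  } else {
    feats <- readr::read_tsv(I(lines), show_col_types = FALSE,
                             col_types = readr::cols(
                               contig = "c", locus = "c", start = "i",
                               end = "i", strand = "c", label = "c"))
    assert_cols(feats, c("contig", "locus", "start", "end", "strand", "label"),
                "feature TSV")
    feats <- rename(feats, locus_id = "locus")
  }
  validate_features(feats)
}

empty_features <- function() {
  tibble(contig = character(), locus_id = character(), start = integer(),
         end = integer(), strand = character(), label = character())
}

gff3_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexpr(pat, attrs, perl = TRUE))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(pat, attrs, perl = TRUE)
  out[hit] <- sub(pat, "\\1", regmatches(attrs, regexpr(pat, attrs, perl = TRUE)),
                  perl = TRUE)
  out
}

validate_features <- function(feats) {
  if (any(is.na(feats$start)) || any(is.na(feats$end))) {
    abort("feature table has non-numeric coordinates")
  }
  bad_strand <- !feats$strand %in% c("+", "-")
  if (any(bad_strand)) {
    abort(paste0("unknown strand symbol '", feats$strand[bad_strand][1],
                 "' for feature ", feats$locus_id[bad_strand][1] %||% "?"))
  }
  bad_span <- feats$start >= feats$end
  if (any(bad_span)) {
    abort(paste0("feature ", feats$locus_id[bad_span][1],
                 " has start >= end after normalization"))
  }
  arrange(feats, .data$contig, .data$start)
}

#' Write gene features as GFF3
#'
#' Inverse of [read_feature_table()] for the GFF3 dialect: internal 0-based
#' half-open coordinates are converted back to 1-based inclusive.
#'
#' @param feats Feature tibble (see [read_feature_table()]).
#' @param path Output path, or `NULL` to return the lines.
#' @return The GFF3 lines, invisibly if written to a file.
#' @export
write_gff3 <- function(feats, path = NULL) {
  assert_cols(feats, c("contig", "locus_id", "start", "end", "strand", "label"),
              "feature table")
  lines <- c("##gff-version 3",
             paste(feats$contig, "hdrascan", "gene",
                   feats$start + 1L, feats$end, ".", feats$strand, ".",
                   paste0("ID=", feats$locus_id, ";label=", feats$label),
                   sep = "\t"))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
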