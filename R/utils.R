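`%||%` <- rlang::`%||%`

hdra_extdata <- function(file) {
  path <- system.file("extdata", file, package = "hdrascan", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) the file may sit under inst/
    path <- system.file("inst", "extdata", file, package = "hdrascan", mustWork = FALSE)
  }
  if (!nzchar(path)) abort(paste0("packaged data file not found: ", file))
  path
}

#' The eight HdrA domain labels
#'
#' Controlled vocabulary for conserved domains recognized on HdrA proteins:
#' N-terminal iron-sulfur cluster domain (`FeS_N`), FAD-binding thioredoxin
#' reductase domain (`TRX_FAD`), its associated iron-sulfur cluster
#' (`TRX_FeS`), inserted and C-terminal ferredoxin domains (`Fd_ins`, `Fd_C`),
#' fused [2Fe-2S] MvhD domain (`MvhD`), inserted glutamate synthase small
#' subunit (`GltD`), and additional iron-sulfur cluster domains (`FeS_extra`).
#'
#' @return Character vector of the eight domain labels.
#' @export
hdra_domain_labels <- function() {
  c("FeS_N", "TRX_FAD", "TRX_FeS", "Fd_ins", "Fd_C", "MvhD", "GltD", "FeS_extra")
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# residues accepted in protein sequences: 20 standard + U (Sec) + X (unknown)
PROTEIN_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                      "R","S","T","V","W","Y","U","X")

check_protein_seq <- function(seq, id = "?") {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), PROTEIN_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("sequence '", id, "' contains non-residue character(s): ",
                 paste(bad, collapse = "")))
  }
  invisible(seq)
}

write_tsv_report <- function(df, path, params = NULL) {
  header <- if (!is.null(params)) {
    paste0("# ", names(params), " = ", unlist(params))
  }
  body <- readr::format_tsv(df)
  body <- sub("\n$", "", body)
  writeLines(c(header, strsplit(body, "\n", fixed = TRUE)[[1]]), path)
  invisible(path)
}
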