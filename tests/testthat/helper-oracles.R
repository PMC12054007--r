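# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations, kept separate from the package code
# paths they check.

# Brute-force sliding-window pattern matcher: for every start position,
# check each pattern position explicitly. Returns 0-based start positions.
oracle_scan <- function(seq, pattern) {
  chars <- strsplit(seq, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  # expand bracketed alternatives into a list of allowed sets
  tokens <- list()
  i <- 1
  while (i <= length(pat)) {
    if (pat[i] == "[") {
      j <- i + 1
      while (pat[j] != "]") j <- j + 1
      tokens[[length(tokens) + 1]] <- pat[(i + 1):(j - 1)]
      i <- j + 1
    } else {
      tokens[[length(tokens) + 1]] <- pat[i]
      i <- i + 1
    }
  }
  k <- length(tokens)
  n <- length(chars)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (s in 0:(n - k)) {
    ok <- TRUE
    for (p in seq_len(k)) {
      t <- tokens[[p]]
      if (!identical(t, "X") && !(chars[s + p] %in% t)) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Exhaustive affine-gap global alignment score (Gotoh three-state DP).
# Gap of length L costs open + L * ext, matching the package scheme.
oracle_align_score <- function(a, b, sub, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # last pair aligned
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[A[i], B[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Shannon entropy in bits of the non-gap characters of a column.
oracle_entropy <- function(col) {
  res <- col[col != "-"]
  if (length(res) == 0) return(Inf)
  p <- table(res) / length(res)
  -sum(p * log2(p))
}

random_protein <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
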