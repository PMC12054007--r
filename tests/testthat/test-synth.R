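test_that("generators are fully deterministic under a seed", {
  a <- simulate_proteins("A2-1", 5, substitution_rate = 0.05, seed = 4)
  b <- simulate_proteins("A2-1", 5, substitution_rate = 0.05, seed = 4)
  expect_identical(a, b)
  c <- simulate_proteins("A2-1", 5, substitution_rate = 0.05, seed = 5)
  expect_false(identical(a$proteins$seq, c$proteins$seq))

  lay <- tibble::tibble(label = c("hdrA", "hdrB"), strand = "+",
                        gap = c(NA, 50))
  expect_identical(simulate_neighborhood(lay, seed = 2)$gff3,
                   simulate_neighborhood(lay, seed = 2)$gff3)

  expect_identical(simulate_msa(10, 100, 50, seed = 3)$msa,
                   simulate_msa(10, 100, 50, seed = 3)$msa)
})

test_that("generator validates its inputs", {
  expect_error(simulate_proteins("NOPE", 1), "unknown class")
  expect_error(simulate_proteins("A1", 0), "n must be")
  expect_error(simulate_proteins("A1", 1, substitution_rate = 1), "rate")
  lay <- tibble::tibble(label = "hdrA", strand = "*", gap = NA)
  expect_error(simulate_neighborhood(lay), "strand")
  lay2 <- tibble::tibble(label = c("a", "b"), strand = "+", gap = c(NA, -5))
  expect_error(simulate_neighborhood(lay2), "non-negative")
  expect_error(simulate_msa(0, 10, 10), ">= 1")
})

test_that("all generated survey sequences pass the length filter", {
  cat_tbl <- hdra_catalog()
  for (cls in cat_tbl$class_name) {
    sim <- simulate_proteins(cls, 3, seed = 23, catalog = cat_tbl)
    expect_true(all(sim$proteins$length >= 300), info = cls)
  }
})

test_that("residue planting flags control the generated sites", {
  anchor <- synthetic_hdra_anchor()
  off <- simulate_proteins("A1", 3, plant_K409 = FALSE, plant_E356 = FALSE,
                           seed = 6)
  expect_false(any(off$truth$k_present))
  calls <- call_anchored_residues(off$proteins, anchor)
  expect_true(all(!calls$matches_expected))
  # the planted K/E positions in truth point at the real residues
  on <- simulate_proteins("A12", 2, seed = 6)
  for (i in 1:2) {
    expect_equal(substr(on$proteins$seq[i], on$truth$k_pos[i],
                        on$truth$k_pos[i]), "K")
    expect_equal(substr(on$proteins$seq[i], on$truth$e_pos[i],
                        on$truth$e_pos[i]), "E")
  }
})

test_that("neighborhood generator plants the intended partition", {
  lay <- tibble::tibble(
    label = c("hdrA", "hdrB", "hdrC", "mvhA", "hdrA", "fdhB"),
    strand = c("+", "+", "+", "-", "-", "-"),
    gap = c(NA, 50, 50, 100, 500, 80))
  nb <- simulate_neighborhood(lay, seed = 10)
  cl <- detect_gene_clusters(nb$features, only_hdra = FALSE)
  got <- as.integer(factor(cl$cluster_id, levels = unique(cl$cluster_id)))
  expect_equal(got, nb$truth$cluster_planted)
})

test_that("msa fixture has the requested geometry and truth labels", {
  fx <- simulate_msa(10, 100, 50, seed = 3)
  expect_equal(nrow(fx$msa), 10L)
  expect_equal(unique(nchar(fx$msa$aligned)), 150L)
  expect_equal(sum(fx$truth$kind == "core"), 100L)
  expect_equal(sum(fx$truth$kind == "insert"), 50L)
  # core columns are gap-free and near-conserved
  m <- do.call(rbind, strsplit(fx$msa$aligned, ""))
  core <- which(fx$truth$kind == "core")
  expect_false(any(m[, core] == "-"))
})

test_that("recovery degrades monotonically on average with substitutions", {
  # motif-critical positions are protected by default, so classification is
  # robust to background substitutions; corrupt_motifs lifts the protection
  # and recovery must then fall off with the rate
  rates <- c(0, 0.02, 0.05, 0.1)
  recovery <- function(r, corrupt) {
    hits <- 0L
    total <- 0L
    for (cls in c("A1", "A2-1", "A3", "A9")) {
      for (s in 1:2) {
        sim <- simulate_proteins(cls, 4, substitution_rate = r,
                                 seed = 100 + s, corrupt_motifs = corrupt)
        res <- classify_proteins(sim$proteins)
        hits <- hits + sum(res$class_name == cls)
        total <- total + nrow(res)
      }
    }
    hits / total
  }
  protected <- vapply(rates, recovery, numeric(1), corrupt = FALSE)
  expect_equal(protected[1], 1)
  expect_true(all(diff(protected) <= 0.05 + 1e-9))
  corrupted <- vapply(rates, recovery, numeric(1), corrupt = TRUE)
  expect_equal(corrupted[1], 1)
  expect_true(all(diff(corrupted) <= 0.05 + 1e-9))
  expect_lt(corrupted[4], 1)
})
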