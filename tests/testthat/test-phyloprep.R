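test_that("greedy clustering separates by identity and ignores input order", {
  p <- tibble::tibble(id = c("a", "b", "c"),
                      seq = c("AAAAAAAAAA", "AAAAAAAAAT", "TTTTTTTTTT"))
  cl <- greedy_cluster(p, 0.8)
  expect_equal(dplyr::n_distinct(cl$cluster), 2L)
  expect_equal(cl$representative[cl$id == "b"], "a")
  # every member is within the cutoff of its representative
  expect_true(all(cl$identity_to_rep >= 0.8))
  # singletons when nothing reaches the cutoff
  p2 <- tibble::tibble(id = c("a", "b"), seq = c("AAAAAAAA", "TTTTTTTT"))
  expect_equal(dplyr::n_distinct(greedy_cluster(p2, 0.8)$cluster), 2L)
  # permutation invariance (length sort makes order free)
  withr::with_seed(5, {
    for (i in 1:4) {
      perm <- p[sample(nrow(p)), ]
      cl2 <- greedy_cluster(perm, 0.8)
      expect_equal(dplyr::arrange(cl2, id), dplyr::arrange(cl, id))
    }
  })
})

test_that("cluster count is non-increasing in the identity cutoff", {
  sims <- lapply(c("A1", "A6", "A12"), function(cls) {
    simulate_proteins(cls, 3, substitution_rate = 0.1, seed = 8)$proteins
  })
  prots <- dplyr::bind_rows(sims)
  counts <- vapply(c(0.5, 0.8, 0.95, 1.0), function(cut) {
    dplyr::n_distinct(greedy_cluster(prots, cut)$cluster)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("type II splitting cuts at the inter-TRX linker midpoint", {
  rec <- tibble::tibble(id = "p", seq = strrep("A", 700))
  parts <- split_type2(rec, rbind(c(50, 200), c(400, 560)))
  expect_equal(parts$id, c("p_N", "p_C"))
  expect_equal(parts$length, c(300L, 400L))
  # adjacent spans: empty linker, split at the junction
  parts2 <- split_type2(rec, rbind(c(50, 200), c(200, 350)))
  expect_equal(parts2$length[1], 200L)
  expect_error(split_type2(rec, rbind(c(50, 200))), "two")
  expect_error(split_type2(rec, rbind(c(50, 200), c(150, 350))), "overlap")
  # each half of a real type II carries exactly one TRX domain
  sim <- simulate_proteins("A4", 1, seed = 12)
  arch <- resolve_architecture(scan_motifs(sim$proteins), sim$proteins)
  spans <- as.matrix(arch[arch$domain == "TRX_FAD", c("start", "end")])
  halves <- split_type2(sim$proteins, spans)
  arch_halves <- resolve_architecture(scan_motifs(halves), halves)
  n_trx <- table(arch_halves$protein_id[arch_halves$domain == "TRX_FAD"])
  expect_equal(unname(as.integer(n_trx)), c(1L, 1L))
})

test_that("GltD excision removes the insertion and preserves the flanks", {
  rec <- tibble::tibble(id = "p", seq = strrep("A", 600))
  out <- excise_gltd(rec, c(300, 450))
  expect_equal(out$length, 450L)
  expect_equal(out$id, "p_noGltD")
  expect_error(excise_gltd(rec, c(0, 100)), "internal")
  expect_error(excise_gltd(rec, NULL), "required")
  # on a simulated type III: GltD no longer detected, flanks unchanged
  sim <- simulate_proteins("A9", 1, seed = 14)
  arch <- resolve_architecture(scan_motifs(sim$proteins), sim$proteins)
  span <- unlist(arch[arch$domain == "GltD", c("start", "end")])
  cut <- excise_gltd(sim$proteins, span)
  arch2 <- resolve_architecture(scan_motifs(cut), cut)
  expect_false("GltD" %in% arch2$domain)
  expect_equal(arch2$domain, c("TRX_FAD", "TRX_FeS", "Fd_ins"))
})

test_that("column trimming applies entropy and gap thresholds", {
  msa <- tibble::tibble(id = c("r1", "r2", "r3", "r4"),
                        aligned = c("AAA", "CCA", "DAA", "EA-"))
  # columns: ACDE (entropy 2 bits), ACAA (0.81 bits), AAA- (gap 1/4)
  tr <- trim_msa_columns(msa)
  expect_equal(tr$mask, c(FALSE, TRUE, FALSE))
  expect_equal(oracle_entropy(c("A", "C", "D", "E")), 2)
  # all-gap columns are always removed
  msa2 <- tibble::tibble(id = c("a", "b"), aligned = c("A-", "A-"))
  expect_equal(trim_msa_columns(msa2)$mask, c(TRUE, FALSE))
  # nothing kept: warning and empty alignment
  msa3 <- tibble::tibble(id = c("a", "b"), aligned = c("-", "-"))
  expect_warning(tr3 <- trim_msa_columns(msa3), "no alignment column")
  expect_equal(tr3$msa$aligned, c("", ""))
})

test_that("trimming is idempotent and separates core from insert columns", {
  fx <- simulate_msa(10, 100, 50, seed = 3)
  tr <- trim_msa_columns(fx$msa)
  core_kept <- sum(tr$mask & fx$truth$kind == "core") /
    sum(fx$truth$kind == "core")
  insert_removed <- sum(!tr$mask & fx$truth$kind == "insert") /
    sum(fx$truth$kind == "insert")
  expect_gte(core_kept, 0.9)
  expect_gte(insert_removed, 0.9)
  tr2 <- trim_msa_columns(tr$msa)
  expect_true(all(tr2$mask))
  expect_equal(tr2$msa, tr$msa)
})

test_that("segment masks extract reference-coordinate columns", {
  # gap-free reference: output width equals the total mask length
  msa <- tibble::tibble(
    id = c("ref", "q1"),
    aligned = c(strrep("A", 200), paste0(strrep("C", 100), strrep("-", 100))))
  segs <- tibble::tibble(start = c(0, 50, 120, 180), end = c(40, 83, 160, 200))
  out <- extract_segment_mask(msa, "ref", segs)
  expect_equal(unique(nchar(out$aligned)), 133L)
  # reference gap columns are excluded
  msa2 <- tibble::tibble(id = c("ref", "q1"),
                         aligned = c("AB-CD", "EEEEE"))
  out2 <- extract_segment_mask(msa2, "ref", tibble::tibble(start = 0, end = 4))
  expect_equal(out2$aligned[out2$id == "ref"], "ABCD")
  expect_equal(out2$aligned[out2$id == "q1"], "EEEE")
  # empty mask, absent reference
  out3 <- extract_segment_mask(msa2, "ref",
                               tibble::tibble(start = integer(),
                                              end = integer()))
  expect_equal(unique(out3$aligned), "")
  expect_error(extract_segment_mask(msa2, "nope", segs), "not a row")
})

test_that("phylogeny preparation splits type II and excises GltD", {
  sims <- lapply(c("A1", "A4", "A9"), function(cls) {
    simulate_proteins(cls, 2, seed = 19)
  })
  prots <- dplyr::bind_rows(lapply(sims, `[[`, "proteins"))
  cls <- classify_proteins(prots)
  arch <- resolve_architecture(scan_motifs(prots), prots)
  prep <- prepare_phylogeny_set(prots, cls, arch, identity_cutoff = 0.99)
  expect_true(all(grepl("_N$|_C$", prep$id[prep$major_type == "II"])))
  expect_true(all(grepl("_noGltD$", prep$id[prep$major_type == "III"])))
  expect_true(all(prep$id[prep$major_type == "I"] %in% prots$id))
})
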