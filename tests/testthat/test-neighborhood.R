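mk_feats <- function(starts, ends, strands, labels, contig = "c1") {
  tibble::tibble(contig = contig,
                 locus_id = sprintf("g%02d", seq_along(starts)),
                 start = as.integer(starts), end = as.integer(ends),
                 strand = strands, label = labels)
}

test_that("gap and strand rules decide cluster boundaries", {
  # gap 100 <= 200: one cluster
  f <- mk_feats(c(0, 1100), c(1000, 2100), c("+", "+"), c("hdrA", "hdrB"))
  cl <- detect_gene_clusters(f)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1L)
  # boundary: gap 201 opens a new cluster
  f2 <- mk_feats(c(0, 1201), c(1000, 2100), c("+", "+"), c("hdrA", "hdrB"))
  cl2 <- detect_gene_clusters(f2, only_hdra = FALSE)
  expect_equal(dplyr::n_distinct(cl2$cluster_id), 2L)
  # adjacent genes on opposite strands never cluster
  f3 <- mk_feats(c(0, 1050), c(1000, 2100), c("+", "-"), c("hdrA", "hdrB"))
  cl3 <- detect_gene_clusters(f3, only_hdra = FALSE)
  expect_equal(dplyr::n_distinct(cl3$cluster_id), 2L)
  # unless the strand requirement is lifted
  cl4 <- detect_gene_clusters(f3, same_strand_required = FALSE,
                              only_hdra = FALSE)
  expect_equal(dplyr::n_distinct(cl4$cluster_id), 1L)
})

test_that("clusters partition features and default to hdrA-containing", {
  f <- mk_feats(c(0, 1100, 5000, 6100), c(1000, 2100, 6000, 7000),
                rep("+", 4), c("hdrA", "hdrB", "abc", "xyz"))
  all_cl <- detect_gene_clusters(f, only_hdra = FALSE)
  expect_equal(nrow(all_cl), nrow(f))
  expect_equal(sort(all_cl$locus_id), sort(f$locus_id))
  hdra_cl <- detect_gene_clusters(f)
  expect_equal(sort(hdra_cl$locus_id), c("g01", "g02"))
  # member order preserved within contig
  expect_equal(all_cl$locus_id, f$locus_id)
})

test_that("overlapping features are kept with gap treated as zero", {
  f <- mk_feats(c(0, 900), c(1000, 2000), c("+", "+"), c("hdrA", "hdrB"))
  expect_warning(cl <- detect_gene_clusters(f), "overlap")
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1L)
  expect_equal(nrow(cl), 2L)
})

test_that("smaller gap thresholds refine larger-threshold partitions", {
  withr::with_seed(77, {
    for (r in 1:40) {
      n <- sample(4:12, 1)
      lay <- tibble::tibble(
        label = sample(c("hdrA", "hdrB", "mvhA", "fdhB"), n, replace = TRUE),
        strand = sample(c("+", "-"), n, replace = TRUE),
        gap = c(NA, sample(0:600, n - 1, replace = TRUE)))
      feats <- simulate_neighborhood(lay, seed = r)$features
      for (gaps in list(c(100, 300), c(0, 200), c(200, 600))) {
        p1 <- detect_gene_clusters(feats, max_gap = gaps[1],
                                   only_hdra = FALSE)$cluster_id
        p2 <- detect_gene_clusters(feats, max_gap = gaps[2],
                                   only_hdra = FALSE)$cluster_id
        # refinement: every fine cluster sits inside one coarse cluster
        expect_true(all(tapply(p2, p1, dplyr::n_distinct) == 1))
      }
    }
  })
})

test_that("function inference follows the rulebook most-specific-first", {
  types <- function(...) tibble::tibble(locus_id = names(c(...)),
                                        major_type = unname(c(...)))
  run <- function(labels, tmap, mo = NULL) {
    n <- length(labels)
    f <- mk_feats(seq(0, by = 1200, length.out = n),
                  seq(1000, by = 1200, length.out = n),
                  rep("+", n), labels)
    # locus ids of hdrA genes must match the type map
    f$locus_id[f$label == "hdrA"] <- names(tmap)[tmap != ""][seq_len(sum(labels == "hdrA"))]
    cl <- detect_gene_clusters(f)
    infer_function(cl, types(tmap), molybdop_status = mo)
  }
  # classic validated H2-bifurcating Mvh-Hdr cluster
  p1 <- run(c("hdrA", "hdrB", "hdrC", "mvhA", "mvhG", "mvhD"), c(h1 = "I"))
  expect_equal(p1$mid_potential_carrier, "H2")
  expect_equal(p1$high_potential_arm, "CoM-S-S-CoB via HdrBC")
  expect_equal(p1$low_potential_arm, "Fd")
  expect_equal(p1$confidence, "validated")
  # type II with FdhB and a cofactor-blocked Molybdop: F420H2, predicted
  mo <- tibble::tibble(locus_id = "g06", verdict = "cofactor_blocked")
  p2 <- run(c("hdrA", "hdrB", "hdrC", "mvhD", "fdhB", "molybdop"),
            c(h1 = "II"), mo)
  expect_equal(p2$mid_potential_carrier, "F420H2")
  expect_equal(p2$confidence, "predicted")
  # without the blocked verdict the F420H2 rule does not fire
  p2b <- run(c("hdrA", "hdrB", "hdrC", "mvhD", "fdhB", "molybdop"),
             c(h1 = "II"))
  expect_false(p2b$mid_potential_carrier == "F420H2")
  # type III with mvhADG: NADH donor and H2-evolving low arm
  p3 <- run(c("hdrA", "mvhA", "mvhD", "mvhG"), c(h1 = "III"))
  expect_equal(p3$mid_potential_carrier, "NADH")
  expect_equal(p3$low_potential_arm, "H2-evolution")
  expect_equal(p3$confidence, "predicted")
  # lone hdrA: everything unknown/none
  p4 <- run("hdrA", c(h1 = "I"))
  expect_equal(p4$mid_potential_carrier, "unknown")
  expect_equal(p4$high_potential_arm, "none-detected")
  expect_equal(p4$low_potential_arm, "none")
  # fwd genes pull the low arm to formyl-methanofuran
  p5 <- run(c("hdrA", "hdrB", "hdrC", "mvhA", "mvhG", "fwdB"), c(h1 = "I"))
  expect_equal(p5$low_potential_arm, "CO2->formyl-MFR")
  # every prediction cites the rows that fired
  expect_match(p1$rules_fired, "mid:")
})

test_that("two hdrA genes with types II and I raise the two-step note", {
  f <- mk_feats(c(0, 1100, 2300, 3500), c(1000, 2200, 3400, 4500),
                rep("+", 4), c("hdrA", "hdrD", "hdrA", "fdhB"))
  tmap <- tibble::tibble(locus_id = c("g01", "g03"), major_type = c("II", "I"))
  cl <- detect_gene_clusters(f)
  p <- infer_function(cl, tmap)
  expect_match(p$notes, "two-step")
  expect_equal(p$high_potential_arm, "CoM-S-S-CoB via HdrD")
})

test_that("clusters without hdrA cannot be scored", {
  f <- mk_feats(0, 1000, "+", "hdrB")
  cl <- detect_gene_clusters(f, only_hdra = FALSE)
  expect_error(infer_function(cl, tibble::tibble(locus_id = character(),
                                                 major_type = character())),
               "no hdrA")
})

test_that("gene label normalization collapses family variants", {
  expect_equal(normalize_gene_labels(c("HdrA", "fwdC", "fmdB", "frhB", "mvhD")),
               c("hdrA", "fwd", "fmd", "fdhB", "mvhD"))
})
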