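test_that("shipped catalog satisfies the global constraints of the scheme", {
  cat_tbl <- hdra_catalog()
  expect_equal(nrow(cat_tbl), 28L)
  counts <- table(cat_tbl$major_type)
  expect_equal(as.integer(counts[c("I", "Ia", "II", "III")]),
               c(13L, 5L, 7L, 3L))
  expect_equal(range(cat_tbl$n_domains), c(2L, 8L))
  expect_false(anyDuplicated(cat_tbl$template) > 0)
  # type/template consistency
  expect_equal(vapply(cat_tbl$domains, assign_type, character(1)),
               cat_tbl$major_type)
})

test_that("catalog validation reports violated constraints", {
  cat_tbl <- readr::read_tsv(system.file("extdata", "hdra_class_catalog.tsv",
                                         package = "hdrascan"),
                             show_col_types = FALSE, comment = "#")
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(cat_tbl[-1, ], f)          # one row missing
  expect_error(hdra_catalog(f), "28")
  bad <- cat_tbl
  bad$major_type[bad$class_name == "A0"] <- "Ia"  # breaks partition
  readr::write_tsv(bad, f)
  expect_error(hdra_catalog(f), "13/5/7/3|partition")
})

test_that("length filter boundary is 'fewer than' the threshold", {
  prots <- tibble::tibble(id = c("a", "b", "c"),
                          seq = strrep("A", c(299, 300, 302)),
                          length = c(299L, 300L, 302L))
  flt <- length_filter(prots)
  expect_equal(flt$kept$id, c("b", "c"))
  expect_equal(flt$rejected$id, "a")
  expect_equal(flt$rejected$reason, "too_short")
  # all long: rejected set empty
  flt2 <- length_filter(prots[prots$length >= 300, ])
  expect_equal(nrow(flt2$rejected), 0L)
})

test_that("major type assignment follows the decision order", {
  expect_equal(assign_type(c("FeS_N", "TRX_FAD", "TRX_FeS", "Fd_ins", "Fd_C")),
               "I")
  expect_equal(assign_type(c("FeS_N", "TRX_FAD", "TRX_FeS", "Fd_ins", "Fd_C",
                             "MvhD")), "Ia")
  expect_equal(assign_type(c("TRX_FAD", "TRX_FeS", "GltD", "Fd_ins")), "III")
  expect_equal(assign_type(c("TRX_FAD", "TRX_FeS", "Fd_ins", "TRX_FAD",
                             "TRX_FeS", "Fd_ins")), "II")
  # two TRX + terminal MvhD is type II (TRX count decided first)
  expect_equal(assign_type(c("TRX_FAD", "TRX_FeS", "TRX_FAD", "MvhD")), "II")
  expect_equal(assign_type(character(0)), "not-hdrA")
  expect_equal(assign_type(c("FeS_N", "Fd_ins")), "not-hdrA")
  expect_error(assign_type(c("TRX_FAD", "GltD", "TRX_FAD")), "unassignable")
  expect_error(assign_type(c("TRX_FAD", "GltD", "MvhD")), "unassignable")
})

test_that("class assignment matches templates exactly and reports nearest", {
  cat_tbl <- hdra_catalog()
  mk_arch <- function(domains) {
    tibble::tibble(protein_id = "p", domain = domains,
                   start = seq_along(domains) * 100L,
                   end = seq_along(domains) * 100L + 50L, score = 1)
  }
  a1 <- assign_class(mk_arch(c("FeS_N", "TRX_FAD", "TRX_FeS", "Fd_ins",
                               "Fd_C")), cat_tbl)
  expect_equal(a1$class_name, "A1")
  a1c <- assign_class(mk_arch(c("FeS_N", "TRX_FAD", "TRX_FeS", "Fd_ins")),
                      cat_tbl)
  expect_equal(a1c$class_name, "A1-C")
  a6 <- assign_class(mk_arch(c("TRX_FAD", "TRX_FeS", "Fd_ins")), cat_tbl)
  expect_equal(a6$class_name, "A6")
  # unmatched ordering: unassigned with nearest template as evidence
  odd <- assign_class(mk_arch(c("TRX_FAD", "TRX_FeS", "Fd_ins", "Fd_C",
                                "Fd_C")), cat_tbl)
  expect_equal(odd$class_name, "unassigned")
  expect_match(odd$evidence, "^nearest:")
  expect_equal(odd$major_type, "I")
})

test_that("planted classes and types are recovered at zero substitution", {
  cat_tbl <- hdra_catalog()
  for (cls in cat_tbl$class_name) {
    sim <- simulate_proteins(cls, 2, substitution_rate = 0, seed = 17,
                             catalog = cat_tbl)
    res <- classify_proteins(sim$proteins, catalog = cat_tbl)
    expect_equal(res$class_name, sim$truth$class_name, info = cls)
    expect_equal(res$major_type, sim$truth$major_type, info = cls)
    expect_true(all(res$filter_status == "passed"), info = cls)
  }
})

test_that("too-short records surface in classification with filter status", {
  sim <- simulate_proteins("A1", 1, seed = 2)
  short <- tibble::tibble(id = "stub", seq = strrep("A", 120), length = 120L,
                          sec_flag = FALSE, source = "synthetic")
  res <- classify_proteins(dplyr::bind_rows(sim$proteins, short))
  expect_equal(res$filter_status[res$protein_id == "stub"], "too_short")
  expect_equal(res$class_name[res$protein_id == "stub"], "unassigned")
  expect_equal(res$class_name[res$protein_id != "stub"], "A1")
})
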