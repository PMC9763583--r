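test_that("otu_table validates its invariants", {
  t <- make_table(matrix(c(5, 2, 0, 2, 1, 2), 2, 3))
  expect_equal(unname(rowSums(t)), c(6, 6))
  expect_error(make_table(matrix(c(1, -1, 2, 3), 2, 2)), "negative")
  expect_error(make_table(matrix(c(0, 0, 0, 5), 2, 2, byrow = TRUE)), "s1")
  expect_error(otu_table(matrix(1:4, 2, 2,
    dimnames = list(c("a", "a"), c("x", "y")))), "duplicate sample")
  expect_error(otu_table(matrix(1:4, 2, 2,
    dimnames = list(c("a", "b"), c("x", "x")))), "duplicate OTU")
  expect_error(make_table(matrix(c(1.5, 1, 1, 1), 2, 2)), "integer")
})

test_that("TSV and BIOM-JSON round-trips reproduce counts exactly", {
  t <- make_table(matrix(c(5, 2, 0, 2, 1, 2), 2, 3))
  for (fmt in c("tsv", "biom-json")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_otu_table(t, f, format = fmt)
    expect_identical(unclass(read_otu_table(f, format = fmt)), unclass(t),
                     info = fmt)
  }
  # samples-as-rows orientation must be explicit, never guessed
  f <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(t, f, orientation = "samples-as-rows")
  t2 <- read_otu_table(f, orientation = "samples-as-rows")
  expect_identical(unclass(t2), unclass(t))
})

test_that("reader rejects an all-zero sample by name", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tgood\tempty", "o1\t5\t0", "o2\t3\t0"), f)
  expect_error(read_otu_table(f), "empty")
})

test_that("to_relative_abundance normalises rows and is idempotent", {
  t <- make_table(matrix(c(10, 30, 60), 1, 3))
  r <- to_relative_abundance(t)
  expect_equal(unname(r[1, ]), c(0.1, 0.3, 0.6))
  expect_equal(unname(to_relative_abundance(make_table(matrix(7, 1, 1)))[1, 1]), 1)
  expect_equal(unname(to_relative_abundance(make_table(matrix(1, 1, 4)))[1, ]),
               rep(0.25, 4))
  expect_equal(unclass(to_relative_abundance(r)), unclass(r))
  expect_true(all(abs(rowSums(r) - 1) < 1e-9))
})

test_that("aggregate_by_rank is additive and conserves totals", {
  t <- make_table(matrix(c(3, 1, 4, 2, 5, 7), 2, 3))
  tax <- taxonomy_map(c("o1", "o2"), c(
    "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella",
    "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella"))
  ag <- aggregate_by_rank(t, tax, "genus")
  prev <- grep("Prevotella", colnames(ag), value = TRUE)
  expect_equal(unname(unclass(ag)[, prev]), c(3 + 4, 1 + 2))
  # o3 is unmapped -> pooled as unclassified
  expect_true("unclassified" %in% colnames(ag))
  expect_equal(unname(unclass(ag)[, "unclassified"]), c(5, 7))
  # conservation at any rank
  for (rk in c("phylum", "genus"))
    expect_equal(rowSums(aggregate_by_rank(t, tax, rk)), rowSums(t))
  expect_error(aggregate_by_rank(t, tax, "species"), "unknown rank")
})

test_that("fb_ratio handles both phyla, zeros, and the Bacteroidota synonym", {
  tax <- taxonomy_map(c("f1", "f2", "b1"), c(
    "Bacteria;Firmicutes;C;O;F;G1", "Bacteria;Firmicutes;C;O;F;G2",
    "Bacteria;Bacteroidota;C;O;F;G3"))
  t <- make_table(matrix(c(30, 0, 10, 0, 20, 5), 2, 3), otus = c("f1", "f2", "b1"))
  r <- fb_ratio(t, tax)
  expect_equal(unname(r[1]), 40 / 20)
  expect_equal(unname(r[2]), 0 / 5)
  t2 <- make_table(matrix(c(3, 2, 0, 1), 1, 4),
                   otus = c("f1", "f2", "b1", "x"))
  tax2 <- taxonomy_map(c("f1", "f2", "b1"), c(
    "Bacteria;Firmicutes;C;O;F;G", "Bacteria;Firmicutes;C;O;F;G",
    "Bacteria;Bacteroidetes;C;O;F;G"))
  r2 <- fb_ratio(t2, tax2)
  expect_true(is.na(r2[1]))
  expect_equal(attr(r2, "undefined"), "s1")
  tax3 <- taxonomy_map("x", "Bacteria;Proteobacteria;C;O;F;G")
  expect_error(fb_ratio(t2, tax3), "neither")
})

test_that("rarefy_table hits the target depth and drops shallow samples", {
  t <- make_table(matrix(c(50, 30, 20, 5, 3, 2), 2, 3, byrow = TRUE))
  expect_warning(r <- rarefy_table(t, 50, seed = 1), "below depth")
  expect_equal(unname(rowSums(r)), 50)
  expect_identical(rownames(r), "s1")
})
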