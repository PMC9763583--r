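test_that("generated cohorts satisfy the container invariants and determinism", {
  spec <- synthetic_spec(n_otus = 60, n_case = 10, n_control = 12)
  a <- generate_cohort(spec, seed = 60)
  b <- generate_cohort(spec, seed = 60)
  expect_identical(unclass(a$table), unclass(b$table))
  expect_identical(a$metadata$SCr, b$metadata$SCr)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  c2 <- generate_cohort(spec, seed = 61)
  expect_false(identical(unclass(a$table), unclass(c2$table)))
  expect_s3_class(a$table, "otu_table")
  expect_equal(nrow(a$table), 22)
  expect_true(all(rowSums(a$table) >= 1000)) # depth floor
  expect_equal(sort(a$tree$tip.label), sort(colnames(a$table)))
  expect_length(a$truth$effect_otus, spec$n_effect)
  expect_error(generate_cohort(
    synthetic_spec(couplings = list(list(indicator = "SCr",
                                         otu = "effect99", slope = 1,
                                         noise = .1))), seed = 1),
    "effect")
})

test_that("non-effect OTUs are exchangeable between groups", {
  spec <- synthetic_spec(n_case = 60, n_control = 60, n_otus = 80,
                         n_effect = 4)
  co <- generate_cohort(spec, seed = 62)
  rel <- unclass(to_relative_abundance(co$table))
  grp <- co$metadata$group
  others <- setdiff(colnames(rel), co$truth$effect_otus)
  # standardised group difference of mean relative abundance, per OTU
  zs <- vapply(others, function(o) {
    x <- rel[grp == "case", o]; y <- rel[grp == "control", o]
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }, numeric(1))
  zs <- zs[is.finite(zs)]
  expect_lt(abs(mean(zs)), 0.2)
  expect_gt(mean(abs(zs) < 2.5), 0.95)
})

test_that("planted effects point the stated way", {
  spec <- synthetic_spec(n_case = 40, n_control = 40, n_otus = 60)
  co <- generate_cohort(spec, seed = 63)
  rel <- unclass(to_relative_abundance(co$table))
  grp <- co$metadata$group
  dirs <- co$truth$direction
  for (o in names(dirs)) {
    diff <- mean(rel[grp == "case", o]) - mean(rel[grp == "control", o])
    expect_equal(sign(diff), unname(dirs[o]), info = o)
  }
})

test_that("multicohort sharing, batch offsets and the adversarial flip work", {
  spec <- synthetic_spec(n_otus = 50, n_case = 12, n_control = 12)
  cs <- generate_multicohort(spec, n_cohorts = 3, batch_sigma = 0.5,
                             seed = 64, sizes = list(NULL, c(8, 9), c(10, 10)))
  expect_length(cs, 3)
  expect_identical(cs[[1]]$truth$effect_otus, cs[[2]]$truth$effect_otus)
  expect_equal(nrow(cs[[2]]$table), 17)
  expect_equal(nrow(cs[[3]]$table), 20)
  expect_length(cs[[2]]$truth$batch_offsets, 50)
  # flipped external cohort reverses every planted effect direction
  fl <- generate_multicohort(spec, n_cohorts = 2, batch_sigma = 0,
                             seed = 64, flip_effects = TRUE)
  rel <- unclass(to_relative_abundance(fl[[2]]$table))
  grp <- fl[[2]]$metadata$group
  dirs <- fl[[1]]$truth$direction
  flips <- vapply(names(dirs), function(o)
    sign(mean(rel[grp == "case", o]) - mean(rel[grp == "control", o])),
    numeric(1))
  expect_true(all(flips == -dirs))
})

test_that("write_cohort emits files the readers accept", {
  co <- generate_cohort(synthetic_spec(n_otus = 25, n_case = 6,
                                       n_control = 6, n_effect = 4), seed = 65)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_identical(unclass(read_otu_table(paths["table"])),
                   unclass(co$table))
  meta <- read_metadata(paths["metadata"])
  expect_equal(meta$sample_id, co$metadata$sample_id)
  tree <- read_otu_tree(paths["tree"])
  expect_setequal(tree$tip.label, colnames(co$table))
  tax <- read_taxonomy(paths["taxonomy"])
  expect_equal(nrow(tax), 25)
  truth <- jsonlite::fromJSON(paths["truth"])
  expect_equal(truth$effect_otus, co$truth$effect_otus)
})
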