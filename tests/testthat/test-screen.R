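test_that("abundance filter uses a strict threshold", {
  rel <- to_relative_abundance(make_table(matrix(c(
    5, 5, 990, 6, 4, 990), 2, 3, byrow = TRUE)))
  # o1 sits exactly at 0.005 in s1 and above in s2
  expect_true("o1" %in% abundance_filter(rel, 0.005))
  rel2 <- to_relative_abundance(make_table(matrix(c(5, 995, 5, 995), 2, 2,
                                                  byrow = TRUE)))
  expect_false("o1" %in% abundance_filter(rel2, 0.005)) # exactly 0.005
  expect_setequal(abundance_filter(rel2, 0), c("o1", "o2"))
})

test_that("wilcoxon screen matches enumeration and flags constants", {
  counts <- matrix(10, 10, 3)
  counts[, 1] <- c(6:10, 1:5) * 10 # complete separation case > control
  counts[, 2] <- c(
    31, 17, 25, 40, 28, 33, 21, 26, 35, 23) # arbitrary noise
  t <- make_table(counts)
  lab <- rep(c("case", "control"), each = 5)
  res <- wilcoxon_screen(to_relative_abundance(t), lab)
  # o3 is constant in counts but not after normalisation; test on counts
  res_c <- wilcoxon_screen(unclass(t), lab)
  expect_equal(res_c$p[1], 2 / choose(10, 5))
  expect_true(res_c$constant[3])
  expect_equal(res_c$p[3], 1)
  expect_equal(res_c$p[1],
               enum_mw_p(counts[1:5, 1], counts[6:10, 1]))
})

test_that("importance screen keeps a separating OTU and honours thresholds", {
  set.seed(30)
  n <- 30
  X <- matrix(rpois(n * 20, 50), n, 20)
  lab <- rep(c("control", "case"), each = 15)
  X[lab == "case", 7] <- X[lab == "case", 7] + 120
  t <- make_table(X)
  keep <- importance_screen(unclass(to_relative_abundance(t)), lab,
                            colnames(t), n_trees = 300, seed = 1)
  expect_true("o7" %in% keep)
  expect_length(importance_screen(unclass(t), lab, colnames(t),
                                  n_trees = 100, seed = 1,
                                  threshold = Inf), 0)
  expect_error(importance_screen(unclass(t), lab, "o1"), "at least 2")
})

test_that("three-criterion screen is an intersection and is order-invariant", {
  co <- generate_cohort(synthetic_spec(n_otus = 60, n_case = 15,
                                       n_control = 15), seed = 31)
  lab <- co$metadata$group
  scr <- select_candidates(co$table, lab, n_trees = 300, seed = 5)
  tab <- scr$table
  expect_equal(tab$passed,
               tab$max_abundance > scr$thresholds$abundance &
                 tab$p < scr$thresholds$p_key &
                 !is.na(tab$mda) & tab$mda > scr$thresholds$importance)
  # relaxing the abundance criterion to trivial = intersection of the rest
  scr2 <- select_candidates(co$table, lab, abundance = 0, n_trees = 300,
                            seed = 5)
  t2 <- scr2$table
  expect_setequal(t2$otu_id[t2$passed],
                  t2$otu_id[t2$p < 0.01 & !is.na(t2$mda) & t2$mda > 1e-4])
  # permuting samples and OTUs leaves the candidate set unchanged
  perm_s <- sample(rownames(co$table))
  perm_o <- sample(colnames(co$table))
  t_perm <- co$table[perm_s, perm_o]
  lab_perm <- lab[match(perm_s, co$metadata$sample_id)]
  scr3 <- select_candidates(t_perm, lab_perm, n_trees = 300, seed = 5)
  expect_setequal(scr3$candidates, scr$candidates)
})

test_that("tightening any threshold never enlarges the candidate set", {
  co <- generate_cohort(synthetic_spec(n_otus = 60, n_case = 15,
                                       n_control = 15), seed = 32)
  lab <- co$metadata$group
  base <- select_candidates(co$table, lab, n_trees = 300, seed = 6)
  for (tweak in list(list(abundance = 0.01), list(p_key = 0.001),
                     list(importance = 1e-3))) {
    args <- c(list(t = co$table, labels = lab, n_trees = 300, seed = 6),
              tweak)
    tight <- do.call(select_candidates, args)
    expect_true(all(tight$candidates %in% base$candidates),
                info = names(tweak))
  }
})
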