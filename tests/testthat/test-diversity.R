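test_that("observed richness counts strictly positive entries", {
  expect_equal(observed_otus(c(5, 0, 1, 0)), 2)
  expect_equal(observed_otus(rep(3, 10)), 10)
  t <- make_table(matrix(c(5, 0, 1, 0, 2, 2), 2, 3)) # s1=(5,1,2), s2=(0,0,2)
  expect_equal(unname(observed_otus(t)), c(3, 1))
})

test_that("ACE matches the hand-evaluated closed form", {
  # no rare component -> observed richness
  expect_equal(ace_index(c(11, 20, 50)), 3)
  x <- c(1, 1, 2, 3, 11, 20)
  # S_abund = 2, S_rare = 4, N_rare = 7, F1 = 2, C = 5/7,
  # sum i(i-1)F_i = 2*1*1 + 3*2*1 = 8
  expect_equal(ace_index(x), ace_oracle(x))
  expect_equal(ace_index(x), 2 + 4 / (5 / 7) +
                 (2 / (5 / 7)) * max(0, (4 / (5 / 7)) * 8 / (7 * 6) - 1))
  # doubling counts changes ACE only through the frequency table
  x2 <- c(2, 2, 4, 6, 22, 40)
  expect_equal(ace_index(x2), ace_oracle(x2))
  # all rare singletons -> flagged Chao1 fallback
  y <- c(1, 1, 1, 30)
  f <- ace_index(y)
  expect_true(isTRUE(attr(f, "fallback")))
  expect_equal(as.numeric(f), 4 + 3 * 2 / 2)
})

test_that("two-group comparison is exact for small tie-free n", {
  cmp <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(cmp$p, 0.1)
  expect_equal(cmp$method, "mann-whitney-exact")
  expect_equal(cmp$p, enum_mw_p(c(1, 2, 3), c(4, 5, 6)))
  # identical groups -> p near 1 (ties force the normal approximation)
  cmp2 <- compare_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_gt(cmp2$p, 0.9)
  # beyond the exact limit the normal approximation kicks in
  set.seed(1)
  cmp3 <- compare_groups(rnorm(30), rep(c("a", "b"), 15))
  expect_equal(cmp3$method, "mann-whitney-normal")
  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "a")), "least")
  kw <- compare_groups(c(1, 2, 9, 10, 5, 6), rep(c("a", "b", "c"), each = 2),
                       mode = "multi-group")
  expect_equal(kw$method, "kruskal-wallis")
  expect_true(kw$p > 0 && kw$p <= 1)
})

test_that("alpha_diversity summarises and compares per group", {
  co <- generate_cohort(synthetic_spec(n_otus = 50, n_case = 8,
                                       n_control = 8), seed = 2)
  a <- alpha_diversity(co$table, co$metadata$group)
  expect_equal(nrow(a$per_sample), 16)
  expect_true(all(a$per_sample$ace >= a$per_sample$observed - 1e-8 |
                    a$per_sample$ace >= 0))
  expect_setequal(a$comparisons$index, c("observed", "ace"))
})

test_that("Bray-Curtis obeys its closed form and bounds", {
  t <- make_table(matrix(c(2, 0, 1, 0, 2, 1), 2, 3))
  d <- bray_curtis(t)
  expect_equal(d[1, 2], (2 + 2) / 6)
  t2 <- make_table(rbind(c(2, 0), c(0, 2)))
  expect_equal(bray_curtis(t2)[1, 2], 1)
  t3 <- make_table(rbind(c(1, 1), c(1, 1)))
  expect_equal(bray_curtis(t3)[1, 2], 0)
  co <- generate_cohort(synthetic_spec(n_otus = 30, n_case = 5,
                                       n_control = 5), seed = 3)
  d2 <- bray_curtis(co$table)
  expect_true(all(d2 >= 0 & d2 <= 1))
  expect_equal(unname(diag(d2)), rep(0, 10))
})

test_that("UniFrac matches the brute-force branch oracle", {
  tree <- toy_tree("((o1:0.5,o2:1.5):1,o3:2);")
  counts <- rbind(c(10, 5, 1), c(2, 0, 8))
  t <- make_table(counts, otus = tree$tip.label[c(1, 2, 3)])
  for (w in c(FALSE, TRUE)) for (nz in c(TRUE, FALSE)) {
    d <- unifrac(t, tree, weighted = w, normalized = nz)
    expect_equal(d[1, 2],
                 brute_unifrac(tree,
                               setNames(counts[1, ], colnames(t)),
                               setNames(counts[2, ], colnames(t)),
                               weighted = w, normalized = nz),
                 info = paste(w, nz))
  }
})

test_that("UniFrac limit cases and invariances hold", {
  tree <- toy_tree()
  t_same <- make_table(rbind(c(3, 1, 2, 5), c(3, 1, 2, 5)),
                       otus = c("o1", "o2", "o3", "o4"))
  expect_equal(unifrac(t_same, tree)[1, 2], 0)
  expect_equal(unifrac(t_same, tree, weighted = TRUE)[1, 2], 0)
  # disjoint subtrees -> unweighted 1
  t_disj <- make_table(rbind(c(3, 1, 0, 0), c(0, 0, 2, 5)),
                       otus = c("o1", "o2", "o3", "o4"))
  expect_equal(unifrac(t_disj, tree)[1, 2], 1)
  # presence/absence: count magnitude must not matter
  t_scaled <- make_table(rbind(c(30, 10, 0, 0), c(0, 0, 2, 5)),
                         otus = c("o1", "o2", "o3", "o4"))
  expect_equal(unifrac(t_scaled, tree)[1, 2], unifrac(t_disj, tree)[1, 2])
  # weighted normalised: per-sample scaling cancels
  t_a <- make_table(rbind(c(4, 2, 1, 1), c(1, 1, 6, 2)),
                    otus = c("o1", "o2", "o3", "o4"))
  t_b <- make_table(rbind(c(40, 20, 10, 10), c(1, 1, 6, 2)),
                    otus = c("o1", "o2", "o3", "o4"))
  expect_equal(unifrac(t_a, tree, weighted = TRUE)[1, 2],
               unifrac(t_b, tree, weighted = TRUE)[1, 2])
  # OTU missing from the tree is a named hard error
  t_bad <- make_table(rbind(c(1, 1), c(2, 1)), otus = c("o1", "zz"))
  expect_error(unifrac(t_bad, tree), "zz")
})

test_that("distance matrices enforce their axioms", {
  expect_error(dist_matrix(matrix(c(0, 1, 2, 0), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b")))), "symmetric")
  m <- matrix(c(0.5, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(dist_matrix(m), "diagonal")
  d <- dist_matrix(matrix(c(0, 1, 1, 0), 2, 2,
                          dimnames = list(c("a", "b"), c("a", "b"))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dist_matrix(d, f)
  expect_equal(unclass(read_dist_matrix(f)), unclass(d))
})
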