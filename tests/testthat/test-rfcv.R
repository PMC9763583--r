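test_that("random forest is deterministic, separable, and predicts votes", {
  set.seed(40)
  X <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(paste0("s", 1:40), paste0("f", 1:6)))
  y <- rep(c(0, 1), each = 20)
  X[y == 1, 3] <- X[y == 1, 3] + 10 # perfect separator
  fit <- rf_fit(X, y, n_trees = 200, seed = 2)
  expect_equal(fit$importance$feature[1], "f3")
  votes <- predict(fit, X)
  expect_true(all((votes > 0.5) == y)) # training error 0
  fit2 <- rf_fit(X, y, n_trees = 200, seed = 2)
  expect_identical(fit$trees, fit2$trees)
  expect_identical(fit$importance, fit2$importance)
  # one tree -> vote fraction is 0 or 1
  f1 <- rf_fit(X, y, n_trees = 1, seed = 3)
  expect_true(all(predict(f1, X) %in% c(0, 1)))
  expect_error(predict(fit, X[, 1:2]), "absent")
})

test_that("choose_feature_count implements both rules", {
  curve <- structure(list(k = c(2, 4, 8, 16),
                          mean_error = c(.30, .10, .10, .12),
                          sd_error = c(.02, .02, .02, .02),
                          errors = matrix(0, 25, 4)),
                     class = "rfcv_curve")
  expect_equal(choose_feature_count(curve, "min"), 4)
  flat <- curve; flat$mean_error <- rep(0.2, 4)
  expect_equal(choose_feature_count(flat, "min"), 2)
  se_curve <- structure(list(k = c(2, 4, 8),
                             mean_error = c(.30, .12, .10),
                             sd_error = c(.02, .02, .02),
                             errors = matrix(0, 1, 3)),
                        class = "rfcv_curve")
  expect_equal(choose_feature_count(se_curve, "one-se"), 4)
})

test_that("cv_error_curve evaluates the degenerate full-candidate grid", {
  co <- generate_cohort(synthetic_spec(n_otus = 40, n_case = 12,
                                       n_control = 12), seed = 41)
  lab <- co$metadata$group
  cand <- colnames(co$table)[1:6]
  curve <- cv_error_curve(co$table, lab, cand, folds = 3, repeats = 2,
                          n_trees = 100, seed = 7, grid = c(2, 6))
  expect_equal(curve$k, c(2, 6))
  expect_true(all(curve$mean_error >= 0 & curve$mean_error <= 1))
  expect_true(curve$chosen_k %in% curve$k)
  expect_equal(dim(curve$errors), c(6, 2))
  # determinism
  curve2 <- cv_error_curve(co$table, lab, cand, folds = 3, repeats = 2,
                           n_trees = 100, seed = 7, grid = c(2, 6))
  expect_identical(curve$errors, curve2$errors)
  expect_error(cv_error_curve(co$table, lab, cand, folds = 30,
                              n_trees = 50, seed = 1), "fewer folds")
})

test_that("train_final reports sub-floor panel members and is reproducible", {
  co <- generate_cohort(synthetic_spec(n_otus = 40, n_case = 15,
                                       n_control = 15), seed = 42)
  lab <- co$metadata$group
  panel <- c(co$truth$effect_otus[1:4], colnames(co$table)[1:2])
  m1 <- train_final(co$table, lab, panel, n_trees = 300, seed = 9)
  m2 <- train_final(co$table, lab, panel, n_trees = 300, seed = 9)
  expect_identical(m1$importance, m2$importance)
  expect_true(all(m1$below_floor %in% panel))
  expect_error(train_final(co$table, lab, c(panel, "nope")), "nope")
})

test_that("POD modes agree with their contracts", {
  co <- generate_cohort(synthetic_spec(n_otus = 40, n_case = 15,
                                       n_control = 15), seed = 43)
  lab <- co$metadata$group
  panel <- co$truth$effect_otus
  model <- train_final(co$table, lab, panel, n_trees = 300, seed = 10)
  pod_ext <- compute_pod(model, co$table, mode = "external")
  expect_true(all(pod_ext$pod >= 0 & pod_ext$pod <= 1))
  pod_cv <- compute_pod(model, co$table, lab, mode = "cross-validated",
                        repeats = 2, seed = 10)
  auc_cv <- roc_analysis(pod_cv, lab, case_level = model$case_level)$auc
  auc_ext <- roc_analysis(pod_ext, lab, case_level = model$case_level)$auc
  # resubstitution with the trained forest is optimistic vs leak-free CV
  expect_gte(auc_ext, auc_cv)
  expect_error(compute_pod(model, co$table, mode = "cross-validated"),
               "labels")
  # missing panel OTU: hard error unless zero-fill requested
  t_sub <- co$table[, setdiff(colnames(co$table), panel[1])]
  expect_error(compute_pod(model, t_sub, mode = "external"), panel[1])
  expect_warning(pod_fill <- compute_pod(model, t_sub, mode = "external",
                                         fill_missing = "zero"), "zero")
  expect_equal(nrow(pod_fill), nrow(co$table))
})

test_that("ROC analysis equals the rank statistic and reports a consistent cut-off", {
  res <- roc_analysis(c(0.9, 0.8, 0.2, 0.1),
                      c("case", "case", "control", "control"),
                      case_level = "case")
  expect_equal(res$auc, 1)
  expect_true(res$cutoff > 0.2 && res$cutoff < 0.8)
  expect_equal(res$sensitivity + res$specificity - 1, 1)
  set.seed(44)
  for (i in 1:10) {
    sc <- rnorm(30)
    lb <- rep(c("control", "case"), 15)
    r <- roc_analysis(sc, lb, case_level = "case")
    w <- wilcox.test(sc[lb == "case"], sc[lb == "control"], exact = FALSE)
    expect_equal(r$auc, unname(w$statistic) / (15 * 15), tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(roc_analysis(exp(sc), lb, case_level = "case")$auc, r$auc)
    # reported sens/spec recomputable from the stored curve
    row <- r$curve[r$curve$threshold == r$cutoff, ]
    expect_equal(row$sensitivity, r$sensitivity)
    expect_equal(row$specificity, r$specificity)
  }
  expect_error(roc_analysis(c(.1, .2), c("case", "case")), "two groups")
})

test_that("external validation reuses the model and flags overlap", {
  cs <- generate_multicohort(synthetic_spec(n_otus = 40, n_case = 12,
                                            n_control = 12),
                             n_cohorts = 2, batch_sigma = 0.3, seed = 45)
  lab1 <- cs[[1]]$metadata$group
  model <- train_final(cs[[1]]$table, lab1, cs[[1]]$truth$effect_otus,
                       n_trees = 300, seed = 11)
  roc <- validate_external(model, cs[[2]]$table, cs[[2]]$metadata$group)
  expect_s3_class(roc, "roc_result")
  expect_true(!is.null(attr(roc, "pod")))
  expect_warning(validate_external(model, cs[[1]]$table, lab1), "overlap")
})

test_that("model JSON round-trip preserves predictions exactly", {
  co <- generate_cohort(synthetic_spec(n_otus = 30, n_case = 10,
                                       n_control = 10), seed = 46)
  lab <- co$metadata$group
  model <- train_final(co$table, lab, co$truth$effect_otus, n_trees = 100,
                       seed = 12)
  f <- withr::local_tempfile(fileext = ".json")
  write_pod_model(model, f)
  model2 <- read_pod_model(f)
  expect_equal(compute_pod(model2, co$table, mode = "external")$pod,
               compute_pod(model, co$table, mode = "external")$pod)
  expect_identical(model2$panel, model$panel)
})
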