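as_feature_matrix <- function(t) {
  if (inherits(t, "otu_table")) unclass(to_relative_abundance(t))
  else unclass(as.matrix(t))
}

stratified_folds <- function(y, folds) {
  # returns fold id per sample; assumes set.seed() already called
  if (any(table(y) < folds))
    stop("a fold would lose one class entirely; use fewer folds for this n")
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  if (any(vapply(split(y, fold), function(g) length(unique(g)), 1L) < 2))
    stop("a fold lost one class entirely; use fewer folds for this n")
  fold
}

default_feature_grid <- function(n_features) {
  ks <- n_features
  while (tail(ks, 1) > 1) ks <- c(ks, floor(tail(ks, 1) / 2))
  sort(unique(c(ks[ks >= 1], seq_len(min(10, n_features)))))
}

#' Cross-validated error curve over feature counts
#'
#' The feature-count selection step of the diagnostic model: repeated
#' stratified k-fold cross-validation in which, within every training fold,
#' the candidate OTUs are re-ranked by forest importance and forests are
#' refit on the top-k features for each k of a descending grid (halvings of
#' the candidate count plus every k <= 10). Re-ranking inside the fold is
#' essential -- ranking once on the full data leaks the selection and
#' silently inflates downstream AUCs; `legacy_leaky = TRUE` reproduces that
#' naive protocol for comparison only.
#'
#' @param t an [otu_table] or feature matrix (converted to relative
#'   abundances when a count table is given).
#' @param labels two-group labels.
#' @param candidate_ids screened candidate OTUs (>= 2).
#' @param folds,repeats cross-validation design (default 5 x 5).
#' @param n_trees trees per forest.
#' @param seed integer seed (controls folds and forests).
#' @param grid feature counts to evaluate; default as described.
#' @param rule selection rule passed to [choose_feature_count].
#' @param legacy_leaky rank features once on all data (biased; off by
#'   default).
#' @return List of class `rfcv_curve`: `k`, `mean_error`, `sd_error`
#'   (across the folds x repeats units), `chosen_k`, `rule`, `errors`
#'   (units x k matrix).
#' @export
cv_error_curve <- function(t, labels, candidate_ids, folds = 5, repeats = 5,
                           n_trees = 500, seed = 1, grid = NULL,
                           rule = c("min", "one-se"), legacy_leaky = FALSE) {
  rule <- match.arg(rule)
  if (length(candidate_ids) < 2) stop("need at least 2 candidate features")
  X <- as_feature_matrix(t)
  missing <- setdiff(candidate_ids, colnames(X))
  if (length(missing)) stop("candidates absent: ", paste(missing, collapse = ", "))
  X <- X[, candidate_ids, drop = FALSE]
  y <- as_binary_labels(labels)
  ks <- grid %||% default_feature_grid(ncol(X))
  ks <- sort(unique(pmin(ks, ncol(X))))

  leak_rank <- NULL
  if (legacy_leaky) {
    fit <- rf_fit(X, y, n_trees = n_trees, seed = derive_seed(seed, "rank"))
    leak_rank <- fit$importance$feature
  }

  units <- list()
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, paste0("folds", r)))
    fold <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      ranking <- leak_rank %||% {
        fit <- rf_fit(X[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                      seed = derive_seed(seed, paste0("rank", r, ".", f)))
        fit$importance$feature
      }
      err_k <- vapply(ks, function(k) {
        feats <- ranking[seq_len(k)]
        fit_k <- rf_fit(X[tr, feats, drop = FALSE], y[tr], n_trees = n_trees,
                        seed = derive_seed(seed, paste0("k", k, ".", r, ".", f)))
        votes <- predict(fit_k, X[!tr, feats, drop = FALSE])
        mean((votes > 0.5) != y[!tr])
      }, numeric(1))
      units[[length(units) + 1]] <- err_k
    }
  }
  errors <- do.call(rbind, units)
  colnames(errors) <- ks
  curve <- structure(list(k = ks, mean_error = colMeans(errors),
                          sd_error = apply(errors, 2, sd), errors = errors,
                          folds = folds, repeats = repeats, rule = rule,
                          seed = seed),
                     class = "rfcv_curve")
  curve$chosen_k <- choose_feature_count(curve, rule)
  curve
}

#' Pick the feature count from an error curve
#'
#' `"min"`: the smallest k achieving the minimum mean CV error (ties break
#' toward fewer variables -- the "lower CV error with fewer variables"
#' rule). `"one-se"`: the smallest k whose mean error is within one
#' standard error of the minimum.
#'
#' @param curve an `rfcv_curve`.
#' @param rule `"min"` or `"one-se"`.
#' @return The chosen k.
#' @export
choose_feature_count <- function(curve, rule = c("min", "one-se")) {
  rule <- match.arg(rule)
  k <- curve$k
  m <- curve$mean_error
  if (rule == "min") return(k[which.min(m)])
  i_min <- which.min(m)
  se <- curve$sd_error[i_min] / sqrt(nrow(curve$errors))
  k[min(which(m <= m[i_min] + se))]
}

#' @export
print.rfcv_curve <- function(x, ...) {
  cat("RFCV curve: chosen k =", x$chosen_k, sprintf("(%s rule)\n", x$rule))
  print(data.frame(k = x$k, mean_error = round(x$mean_error, 4),
                   sd_error = round(x$sd_error, 4), row.names = NULL))
  invisible(x)
}

#' Train the final diagnostic forest on a selected OTU panel
#'
#' Refits the forest on the full discovery data restricted to the panel and
#' records both importance flavours. Panel members whose refit mean
#' decrease in accuracy falls below `importance_floor` (default 0.001) are
#' reported in `below_floor` and, when `drop_below_floor = TRUE`, removed
#' and the forest refit once.
#'
#' @param t discovery [otu_table] or feature matrix.
#' @param labels discovery two-group labels.
#' @param panel_ids the selected OTU panel.
#' @param importance_floor model-level importance floor.
#' @param n_trees,seed forest parameters (default 1000 trees).
#' @param drop_below_floor drop sub-floor members and refit.
#' @param cohort_id free-text training-cohort tag.
#' @return List of class `pod_model`: `panel`, `forest` (a `gutpod_rf`),
#'   `importance` (mda + gini), `below_floor`, `case_level`,
#'   `control_level`, `training_ids`, `params`.
#' @export
train_final <- function(t, labels, panel_ids, importance_floor = 0.001,
                        n_trees = 1000, seed = 1, drop_below_floor = FALSE,
                        cohort_id = "discovery") {
  X <- as_feature_matrix(t)
  missing <- setdiff(panel_ids, colnames(X))
  if (length(missing)) stop("panel OTUs absent from table: ",
                            paste(missing, collapse = ", "))
  if (!length(panel_ids)) stop("empty panel")
  y <- as_binary_labels(labels)
  fit <- rf_fit(X[, panel_ids, drop = FALSE], y, n_trees = n_trees, seed = seed)
  below <- fit$importance$feature[fit$importance$mda < importance_floor]
  if (drop_below_floor && length(below) && length(below) < length(panel_ids)) {
    panel_ids <- setdiff(panel_ids, below)
    fit <- rf_fit(X[, panel_ids, drop = FALSE], y, n_trees = n_trees,
                  seed = seed)
  }
  structure(list(panel = panel_ids, forest = fit, importance = fit$importance,
                 below_floor = below, importance_floor = importance_floor,
                 case_level = attr(y, "case_level"),
                 control_level = attr(y, "control_level"),
                 training_ids = rownames(X), cohort_id = cohort_id,
                 params = list(n_trees = n_trees, seed = seed)),
            class = "pod_model")
}

#' @export
print.pod_model <- function(x, ...) {
  cat(sprintf("POD model: %d-OTU panel, %d trees, trained on %s (n = %d)\n",
              length(x$panel), x$params$n_trees, x$cohort_id,
              length(x$training_ids)))
  cat("panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' Probability-of-disease (POD) scores
#'
#' POD for a sample is the fraction of forest trees voting the disease
#' class. In `"external"` mode the final trained forest is applied as-is to
#' new samples. In `"cross-validated"` mode (internal scoring of the
#' training cohort) each sample is scored only by forests whose training
#' folds excluded it, averaged over repeated fold assignments -- the
#' leak-free way to show discovery-cohort separation.
#'
#' @param model a `pod_model`.
#' @param t an [otu_table] or feature matrix to score.
#' @param labels required for cross-validated mode (used to stratify folds
#'   and refit fold forests).
#' @param mode `"external"` or `"cross-validated"`.
#' @param folds,repeats,seed cross-validated design (default 5 x 5).
#' @param fill_missing `"error"` (default: a panel OTU absent from `t` is a
#'   hard error) or `"zero"` (fill with zeros, with a warning).
#' @return data.frame of class `pod_scores`: `sample_id`, `pod`; attribute
#'   `mode`.
#' @export
compute_pod <- function(model, t, labels = NULL,
                        mode = c("external", "cross-validated"),
                        folds = 5, repeats = 5, seed = 1,
                        fill_missing = c("error", "zero")) {
  mode <- match.arg(mode)
  fill_missing <- match.arg(fill_missing)
  stopifnot(inherits(model, "pod_model"))
  X <- as_feature_matrix(t)
  missing <- setdiff(model$panel, colnames(X))
  if (length(missing)) {
    if (fill_missing == "error")
      stop("panel OTU(s) absent from table: ", paste(missing, collapse = ", "))
    warning("filling absent panel OTU(s) with zeros: ",
            paste(missing, collapse = ", "))
    X <- cbind(X, matrix(0, nrow(X), length(missing),
                         dimnames = list(rownames(X), missing)))
  }
  X <- X[, model$panel, drop = FALSE]

  if (mode == "external") {
    pod <- predict(model$forest, X)
  } else {
    if (is.null(labels)) stop("cross-validated mode requires labels")
    y <- as_binary_labels(labels, case_level = model$case_level)
    acc <- matrix(0, nrow(X), repeats)
    for (r in seq_len(repeats)) {
      set.seed(derive_seed(seed, paste0("podfolds", r)))
      fold <- stratified_folds(y, folds)
      for (f in seq_len(folds)) {
        tr <- fold != f
        fit <- rf_fit(X[tr, , drop = FALSE], y[tr],
                      n_trees = model$params$n_trees,
                      seed = derive_seed(seed, paste0("pod", r, ".", f)))
        acc[!tr, r] <- predict(fit, X[!tr, , drop = FALSE])
      }
    }
    pod <- rowMeans(acc)
    names(pod) <- rownames(X)
  }
  structure(data.frame(sample_id = rownames(X), pod = unname(pod),
                       stringsAsFactors = FALSE),
            mode = mode, class = c("pod_scores", "data.frame"))
}

#' ROC analysis of POD scores
#'
#' AUC is computed from midranks -- exactly the Mann-Whitney statistic
#' \eqn{U/(n_1 n_0)}, which equals the trapezoidal area under the empirical
#' ROC curve with tie handling. The operating cut-off maximises Youden's
#' \eqn{J = sens + spec - 1} over the midpoints between consecutive
#' distinct scores (ties broken toward higher specificity);
#' `rule = "closest-topleft"` minimises the distance to (0, 1) instead.
#' Predicted disease means POD >= cut-off.
#'
#' @param pod a `pod_scores` data.frame (or numeric vector of scores).
#' @param labels two-group labels; the case level is the positive class.
#' @param case_level which label is the disease class (default: second
#'   level).
#' @param rule cut-off criterion.
#' @return List of class `roc_result`: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `curve` (threshold/sens/spec), `n_case`, `n_control`.
#' @export
roc_analysis <- function(pod, labels, case_level = NULL,
                         rule = c("youden", "closest-topleft")) {
  rule <- match.arg(rule)
  scores <- if (inherits(pod, "pod_scores")) pod$pod else as.numeric(pod)
  y <- as_binary_labels(labels, case_level = case_level)
  if (length(scores) != length(y)) stop("scores/labels length mismatch")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(s) mean(scores[y == 1] >= s), numeric(1))
  spec <- vapply(thr, function(s) mean(scores[y == 0] < s), numeric(1))
  curve <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  crit <- if (rule == "youden") sens + spec - 1 else
    -((1 - sens)^2 + (1 - spec)^2)
  best <- which(crit == max(crit))
  best <- best[which.max(spec[best])]
  structure(list(auc = auc, cutoff = thr[best], sensitivity = sens[best],
                 specificity = spec[best], curve = curve, rule = rule,
                 n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "AUC %.2f%% (cut-off %.4g, sensitivity %.4g, specificity %.4g; %d cases vs %d controls)\n",
    100 * x$auc, x$cutoff, x$sensitivity, x$specificity, x$n_case,
    x$n_control))
  invisible(x)
}

#' Validate a trained model on an external cohort
#'
#' Applies the discovery-trained forest unchanged (no refit) to an external
#' cohort and summarises discrimination as AUC, cut-off, sensitivity and
#' specificity.
#'
#' @param model a `pod_model`.
#' @param external_t external [otu_table] (samples disjoint from training).
#' @param external_labels external two-group labels.
#' @param ... passed to [compute_pod] (e.g. `fill_missing`).
#' @return A `roc_result` with the external `pod_scores` attached as
#'   attribute `"pod"`.
#' @export
validate_external <- function(model, external_t, external_labels, ...) {
  X <- as_feature_matrix(external_t)
  overlap <- intersect(rownames(X), model$training_ids)
  if (length(overlap))
    warning("external cohort overlaps training samples: ",
            paste(head(overlap, 5), collapse = ", "))
  pod <- compute_pod(model, external_t, mode = "external", ...)
  roc <- roc_analysis(pod, external_labels, case_level = model$case_level)
  attr(roc, "pod") <- pod
  roc
}

#' Persist / restore a POD model as JSON
#'
#' The model -- panel, parameters, seeds and the serialised forest -- is
#' written as a single versioned JSON sidecar, so external validation can
#' run in a later session without recomputing discovery.
#'
#' @param model a `pod_model`; `path` a file path.
#' @return `path` (write) or a `pod_model` (read).
#' @export
write_pod_model <- function(model, path) {
  stopifnot(inherits(model, "pod_model"))
  obj <- list(format = "gutpod-model", version = 1L,
              package_version = as.character(packageVersion("gutpod")),
              panel = model$panel, importance = model$importance,
              below_floor = model$below_floor,
              importance_floor = model$importance_floor,
              case_level = model$case_level,
              control_level = model$control_level,
              training_ids = model$training_ids, cohort_id = model$cohort_id,
              params = model$params,
              forest = list(params = model$forest$params,
                            oob_error = model$forest$oob_error,
                            features = model$forest$features,
                            trees = model$forest$trees))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_pod_model
#' @export
read_pod_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(obj$format, "gutpod-model")) stop("not a gutpod model file")
  forest <- structure(list(
    trees = lapply(obj$forest$trees, function(m) matrix(as.numeric(m),
                                                        ncol = 5)),
    oob_votes = NULL, oob_error = obj$forest$oob_error,
    importance = as.data.frame(obj$importance),
    features = obj$forest$features, params = obj$forest$params),
    class = "gutpod_rf")
  structure(list(panel = obj$panel, forest = forest,
                 importance = as.data.frame(obj$importance),
                 below_floor = obj$below_floor,
                 importance_floor = obj$importance_floor,
                 case_level = obj$case_level, control_level = obj$control_level,
                 training_ids = obj$training_ids, cohort_id = obj$cohort_id,
                 params = obj$params),
            class = "pod_model")
}

#' @importFrom utils tail
NULL
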