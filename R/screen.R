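#' Abundance filter
#'
#' OTUs whose maximum per-sample relative abundance strictly exceeds
#' `threshold` (default 0.5%). Strict inequality: an OTU sitting exactly on
#' the threshold in every sample is excluded.
#'
#' @param rel a `rel_abundance` matrix (see [to_relative_abundance]).
#' @param threshold proportion cut-off, default 0.005.
#' @return Character vector of passing OTU ids.
#' @export
abundance_filter <- function(rel, threshold = 0.005) {
  m <- unclass(as.matrix(rel))
  colnames(m)[apply(m, 2, max) > threshold]
}

#' Per-OTU Wilcoxon rank-sum screen
#'
#' Two-sided rank-sum p-value per OTU between the two groups, using the
#' same statistical engine as [compare_groups]. P-values are raw -- the
#' screening criteria threshold raw p, not adjusted p. OTUs constant across
#' all samples get p = 1 by convention and are flagged.
#'
#' @param t an [otu_table] or `rel_abundance` matrix.
#' @param labels two-group labels.
#' @return data.frame `otu_id`, `p`, `constant` (one row per OTU).
#' @export
wilcoxon_screen <- function(t, labels) {
  m <- unclass(as.matrix(t))
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2 || any(table(labels) < 2))
    stop("two groups with at least two samples each are required")
  res <- apply(m, 2, function(x) {
    if (length(unique(x)) == 1) return(c(p = 1, constant = 1))
    c(p = compare_groups(x, labels, "two-group")$p, constant = 0)
  })
  data.frame(otu_id = colnames(m), p = res["p", ],
             constant = res["constant", ] == 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Forest-importance screen
#'
#' Fits a random forest on the candidate OTUs and keeps those whose OOB
#' permutation importance (mean decrease in accuracy) strictly exceeds
#' `threshold` (default 1e-4, the screening floor; the final model uses its
#' own, larger floor).
#'
#' @param t an [otu_table] or `rel_abundance` matrix.
#' @param labels two-group labels.
#' @param candidate_ids OTUs to feed the forest (>= 2).
#' @param n_trees trees in the screening forest (default 1000).
#' @param seed integer seed.
#' @param threshold importance floor (strict).
#' @return Character vector of retained OTU ids, with the fitted screening
#'   forest attached as attribute `"forest"`.
#' @export
importance_screen <- function(t, labels, candidate_ids, n_trees = 1000,
                              seed = 1, threshold = 1e-4) {
  if (length(candidate_ids) < 2) stop("need at least 2 candidate OTUs")
  m <- unclass(as.matrix(t))
  missing <- setdiff(candidate_ids, colnames(m))
  if (length(missing)) stop("candidates absent from table: ",
                            paste(missing, collapse = ", "))
  fit <- rf_fit(m[, candidate_ids, drop = FALSE], as_binary_labels(labels),
                n_trees = n_trees, seed = seed)
  keep <- fit$importance$feature[fit$importance$mda > threshold]
  attr(keep, "forest") <- fit
  keep
}

#' Three-criterion candidate-OTU screen
#'
#' The discovery-cohort screen: a key OTU must (1) exceed `abundance`
#' relative abundance in at least one sample, (2) have a rank-sum p below
#' `p_key`, and (3) have forest mean-decrease-accuracy importance above
#' `importance`. Following the two-stage protocol, a looser `p_pre` pre-pass
#' (default 0.05) selects which OTUs enter the screening forest; the key-OTU
#' p threshold (default 0.01) is applied afterwards. Statistics are computed
#' on relative abundances by default (the abundance criterion is expressed
#' in percent); set `use_counts = TRUE` to screen raw counts instead.
#'
#' @param t an [otu_table] (discovery cohort only).
#' @param labels two-group labels for the discovery samples.
#' @param abundance,p_pre,p_key,importance the four thresholds.
#' @param n_trees,seed forest parameters.
#' @param use_counts run the rank-sum and forest on counts, not proportions.
#' @return List of class `screen_result`: `table` (per-OTU max abundance,
#'   p, importance, passed), `candidates` (ids, descending importance),
#'   and the thresholds used.
#' @export
select_candidates <- function(t, labels, abundance = 0.005, p_pre = 0.05,
                              p_key = 0.01, importance = 1e-4,
                              n_trees = 1000, seed = 1, use_counts = FALSE) {
  stopifnot(inherits(t, "otu_table"))
  rel <- to_relative_abundance(t)
  stat_m <- if (use_counts) unclass(t) else unclass(rel)
  max_rel <- apply(unclass(rel), 2, max)
  wres <- wilcoxon_screen(stat_m, labels)

  pre_ids <- wres$otu_id[wres$p < p_pre & max_rel > abundance]
  imp <- setNames(rep(NA_real_, ncol(t)), colnames(t))
  if (length(pre_ids) >= 2) {
    fit <- attr(importance_screen(stat_m, labels, pre_ids, n_trees = n_trees,
                                  seed = seed, threshold = importance),
                "forest")
    imp[fit$importance$feature] <- fit$importance$mda
  }

  tab <- data.frame(otu_id = wres$otu_id, max_abundance = unname(max_rel),
                    p = wres$p, mda = unname(imp[wres$otu_id]),
                    stringsAsFactors = FALSE)
  tab$passed <- tab$max_abundance > abundance & tab$p < p_key &
    !is.na(tab$mda) & tab$mda > importance
  cand <- tab[tab$passed, ]
  cand <- cand$otu_id[order(-cand$mda, cand$otu_id)]
  if (!length(cand))
    message("screen produced no candidate OTUs")
  structure(list(table = tab, candidates = cand,
                 thresholds = list(abundance = abundance, p_pre = p_pre,
                                   p_key = p_key, importance = importance),
                 seed = seed),
            class = "screen_result")
}

#' Write a screen result as CSV
#' @param x a `screen_result`; `path` a file path.
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(x, path) {
  stopifnot(inherits(x, "screen_result"))
  write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen: %d/%d OTUs passed all three criteria\n",
              length(x$candidates), nrow(x$table)))
  invisible(x)
}

#' @importFrom utils write.csv read.csv
NULL
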