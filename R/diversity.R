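#' Observed OTU richness
#'
#' @param sample_counts nonnegative count vector for one sample, or an
#'   [otu_table] (one value per sample).
#' @return Integer count(s) of OTUs with at least one read.
#' @export
observed_otus <- function(sample_counts) {
  if (inherits(sample_counts, "otu_table") || is.matrix(sample_counts))
    return(apply(unclass(sample_counts), 1, function(x) sum(x > 0)))
  if (any(sample_counts < 0)) stop("negative counts")
  sum(sample_counts > 0)
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator. With `S_abund` the OTUs above the
#' rare threshold, `S_rare` those at or below it, `N_rare` the reads in rare
#' OTUs, `F1` the singletons and sample coverage `C = 1 - F1/N_rare`:
#' \deqn{ACE = S_{abund} + S_{rare}/C + (F_1/C)\,\gamma^2}
#' where \eqn{\gamma^2} is the bias-corrected squared coefficient of
#' variation of rare-OTU frequencies,
#' \eqn{\gamma^2 = \max(0, S_{rare} \sum_i i(i-1)F_i / (C N_{rare}(N_{rare}-1)) - 1)}.
#' The rare threshold of 10 follows the mothur/EstimateS convention. When no
#' OTU is rare the estimator equals the observed richness. When every rare
#' OTU is a singleton the coverage is zero and ACE is undefined; the
#' bias-corrected Chao1 estimate
#' \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))} is returned instead and the result
#' flagged via the `"fallback"` attribute.
#'
#' @param sample_counts nonnegative count vector (one sample).
#' @param rare_threshold counts at or below this are "rare" (default 10).
#' @return Estimated richness (>= number of abundant OTUs); attribute
#'   `fallback = TRUE` marks the Chao1 fallback.
#' @export
ace_index <- function(sample_counts, rare_threshold = 10) {
  x <- sample_counts[sample_counts > 0]
  if (!length(x)) stop("sample has no positive counts")
  s_abund <- sum(x > rare_threshold)
  rare <- x[x <= rare_threshold]
  s_rare <- length(rare)
  if (s_rare == 0) return(length(x))
  n_rare <- sum(rare)
  f <- tabulate(rare, nbins = rare_threshold)
  f1 <- f[1]
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    f2 <- if (rare_threshold >= 2) f[2] else 0
    out <- length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
    attr(out, "fallback") <- TRUE
    return(out)
  }
  i <- seq_len(rare_threshold)
  gamma2 <- max(0, s_rare * sum(i * (i - 1) * f) /
                  (c_ace * n_rare * (n_rare - 1)) - 1)
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

#' Nonparametric group comparison of a diversity index
#'
#' Two groups are compared with the Mann-Whitney U (Wilcoxon rank-sum) test:
#' exact p when the combined sample size is at most `exact_limit` and the
#' data are tie-free, otherwise the normal approximation with tie
#' correction. Three or more groups use the Kruskal-Wallis H test with its
#' chi-squared p.
#'
#' @param values numeric vector of per-sample index values.
#' @param labels group labels, same length.
#' @param mode `"two-group"` or `"multi-group"`.
#' @param exact_limit combined-n threshold for the exact two-group p.
#' @return List with `statistic`, `p`, `method`.
#' @export
compare_groups <- function(values, labels, mode = c("two-group", "multi-group"),
                           exact_limit = 20) {
  mode <- match.arg(mode)
  labels <- as.factor(as.character(labels))
  if (any(table(labels) == 0) || nlevels(labels) < 2)
    stop("each group needs at least one observation")
  if (mode == "two-group") {
    if (nlevels(labels) != 2) stop("two-group mode needs exactly two groups")
    g <- split(values, labels)
    exact <- (length(values) <= exact_limit) && !anyDuplicated(values)
    ht <- suppressWarnings(
      wilcox.test(g[[1]], g[[2]], exact = exact, correct = !exact))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = if (exact) "mann-whitney-exact" else "mann-whitney-normal")
  } else {
    ht <- kruskal.test(values, labels)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "kruskal-wallis")
  }
}

#' Alpha-diversity summary with group comparisons
#'
#' @param t an [otu_table].
#' @param labels per-sample group labels (optional).
#' @param rare_threshold passed to [ace_index].
#' @return List with `per_sample` (data.frame sample_id/observed/ace) and,
#'   when labels are given, `comparisons` (one row per index).
#' @export
alpha_diversity <- function(t, labels = NULL, rare_threshold = 10) {
  stopifnot(inherits(t, "otu_table"))
  m <- unclass(t)
  per <- data.frame(
    sample_id = rownames(m),
    observed = apply(m, 1, function(x) sum(x > 0)),
    ace = apply(m, 1, function(x) as.numeric(ace_index(x, rare_threshold))),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(per_sample = per)
  if (!is.null(labels)) {
    labels <- as.factor(as.character(labels))
    mode <- if (nlevels(labels) == 2) "two-group" else "multi-group"
    out$comparisons <- do.call(rbind, lapply(c("observed", "ace"), function(ix) {
      cmp <- compare_groups(per[[ix]], labels, mode)
      data.frame(index = ix, statistic = cmp$statistic, p = cmp$p,
                 method = cmp$method, stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Bray-Curtis dissimilarity
#'
#' \eqn{BC(a,b) = \sum_j |x_{aj} - x_{bj}| / \sum_j (x_{aj} + x_{bj})},
#' computed on counts or relative abundances.
#'
#' @param t an [otu_table] or `rel_abundance` matrix.
#' @return A `dist_matrix` (square symmetric matrix with zero diagonal).
#' @export
bray_curtis <- function(t) {
  m <- unclass(as.matrix(t))
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  dist_matrix(d, rownames(m))
}

#' Distance matrices
#'
#' Container for pairwise sample dissimilarities: validates symmetry (to
#' 1e-12), a zero diagonal and nonnegativity.
#'
#' @param m square numeric matrix.
#' @param sample_ids identifiers (default rownames).
#' @return Matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(m, sample_ids = rownames(m)) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(sample_ids)) stop("sample ids required")
  if (any(abs(m - t(m)) > 1e-12)) stop("distance matrix not symmetric")
  if (any(diag(m) != 0)) stop("nonzero diagonal")
  if (any(m < 0)) stop("negative dissimilarity")
  m <- (m + t(m)) / 2
  dimnames(m) <- list(sample_ids, sample_ids)
  class(m) <- c("dist_matrix", "matrix", "array")
  m
}

#' Write / read a distance matrix as square TSV
#' @param d a [dist_matrix]; `path` a file path.
#' @return `path` (write) or a [dist_matrix] (read).
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), unclass(d), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  dist_matrix(m)
}
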