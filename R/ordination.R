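#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of \eqn{-D^2/2} followed
#' by eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues, ordered by descending eigenvalue.
#' Negative eigenvalues -- the signature of a non-Euclidean dissimilarity --
#' are reported, never silently corrected; pass `correction = "cailliez"`
#' to add the Cailliez constant instead.
#'
#' @param D a [dist_matrix].
#' @param k number of axes requested (fewer are returned, with a warning,
#'   if the matrix has fewer positive eigenvalues).
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return List of class `ordination` with `method = "pcoa"`, `coords`
#'   (samples x axes), `eigenvalues` (all, descending), and
#'   `prop_explained` (positive eigenvalues over their sum).
#' @export
pcoa <- function(D, k = 2, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  stopifnot(inherits(D, "dist_matrix"))
  n <- nrow(D)
  if (n < 3) stop("need at least 3 samples")
  if (correction == "cailliez") {
    res <- ape::pcoa(stats::as.dist(unclass(D)), correction = "cailliez")
    vec <- res$vectors.cor %||% res$vectors
    ev <- res$values$Corr_eig %||% res$values$Eigenvalues
  } else {
    A <- -0.5 * unclass(D)^2
    J <- diag(n) - matrix(1 / n, n, n)
    G <- J %*% A %*% J
    eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
    ev <- eig$values
    pos <- ev > max(ev) * 1e-10
    vec <- sweep(eig$vectors[, pos, drop = FALSE], 2, sqrt(ev[pos]), `*`)
  }
  n_pos <- ncol(vec)
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalues; returning ", n_pos,
            " axes")
    k <- n_pos
  }
  coords <- vec[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(method = "pcoa", coords = coords, eigenvalues = ev,
                 prop_explained = pmax(ev, 0) / sum(pmax(ev, 0)),
                 negative_eigenvalues = sum(ev < -max(abs(ev)) * 1e-10)),
            class = "ordination")
}

#' Non-metric multidimensional scaling
#'
#' Rank-preserving embedding minimising Kruskal stress-1, using the
#' \pkg{vegan} `monoMDS` engine (global non-metric model, primary/weak tie
#' treatment) under seeded random restarts; the lowest-stress solution is
#' returned and flagged if its run did not converge.
#'
#' @param D a [dist_matrix].
#' @param k embedding dimension (requires `n >= k + 2`).
#' @param restarts number of random starts.
#' @param max_iter,tol iteration cap and convergence tolerance per start.
#' @param seed integer seed; identical seeds give identical coordinates.
#' @return List of class `ordination` with `method = "nmds"`, `coords`,
#'   `stress` (Kruskal stress-1) and `converged`.
#' @export
nmds <- function(D, k = 2, restarts = 20, max_iter = 300, tol = 1e-7, seed = 1) {
  stopifnot(inherits(D, "dist_matrix"))
  n <- nrow(D)
  if (n < k + 2) stop("NMDS needs n >= k + 2")
  d <- stats::as.dist(unclass(D))
  best <- NULL
  set.seed(derive_seed(seed, "nmds"))
  for (r in seq_len(restarts)) {
    init <- matrix(rnorm(n * k), n, k)
    fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                          maxit = max_iter, sratmax = 1 - tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$points
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("NMDS", seq_len(k))
  # icause: 1 = max iterations reached (not converged); 2-4 = stress /
  # stress-ratio / scale-gradient criteria met
  structure(list(method = "nmds", coords = coords, stress = best$stress,
                 converged = best$icause != 1L,
                 restarts = restarts, seed = seed),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("ordination:", x$method, "-", nrow(x$coords), "samples,",
      ncol(x$coords), "axes\n")
  if (x$method == "nmds") cat("stress:", format(x$stress, digits = 4), "\n")
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a distance matrix.
#' All \eqn{n(n-1)/2} dissimilarities are ranked (midranks on ties) and
#' \deqn{R = \frac{\bar r_{between} - \bar r_{within}}{n(n-1)/4}}
#' (Clarke's denominator). Significance comes from permuting the group
#' labels: \eqn{p = (1 + \#\{R^{perm} \ge R\}) / (1 + n_{perm})}, so p is
#' never exactly zero.
#'
#' @param D a [dist_matrix].
#' @param labels group labels (>= 2 groups, each with >= 2 samples).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return List of class `anosim_result`: `R`, `p`, `n_perm`,
#'   `perm_R` (the permutation distribution).
#' @export
anosim <- function(D, labels, n_perm = 999, seed = 1) {
  stopifnot(inherits(D, "dist_matrix"))
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) < 2) stop("need at least two groups")
  if (any(table(labels) < 2)) stop("singleton group(s) not allowed")
  n <- nrow(D)
  if (length(labels) != n) stop("labels length mismatch")
  lower <- lower.tri(matrix(0, n, n))
  dvec <- unclass(D)[lower]
  rk <- rank(dvec) # midranks on ties
  denom <- n * (n - 1) / 4
  pair_i <- row(matrix(0, n, n))[lower]
  pair_j <- col(matrix(0, n, n))[lower]
  stat <- function(lab) {
    within <- lab[pair_i] == lab[pair_j]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  R_obs <- stat(labels)
  set.seed(derive_seed(seed, "anosim"))
  perm_R <- vapply(seq_len(n_perm), function(b) stat(sample(labels)),
                   numeric(1))
  p <- (1 + sum(perm_R >= R_obs)) / (1 + n_perm)
  structure(list(R = R_obs, p = p, n_perm = n_perm, perm_R = perm_R),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%d permutations)\n",
              x$R, x$p, x$n_perm))
  invisible(x)
}
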