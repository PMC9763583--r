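# Solve basis variances from a log-ratio variation matrix under sparsity,
# iteratively excluding the strongest-correlated pair above exclusion_rho.
# T_ij = Var(log(x_i/x_j)) = w_i^2 + w_j^2 - 2 rho_ij w_i w_j; assuming most
# rho ~ 0, row sums over included pairs give a linear system for w^2.
sparcc_basis <- function(Tmat, exclusion_rho = 0.1, max_exclusions = 10) {
  p <- ncol(Tmat)
  incl <- matrix(TRUE, p, p); diag(incl) <- FALSE
  n_excl <- 0L; n_clip <- 0L
  repeat {
    d <- rowSums(incl)
    if (any(d < 2)) break # component too excluded to re-solve
    A <- incl * 1; diag(A) <- d
    t_i <- rowSums(Tmat * incl)
    w2 <- tryCatch(solve(A, t_i), error = function(e) rep(NA_real_, p))
    if (any(!is.finite(w2))) break
    bad <- w2 <= 0
    n_clip <- n_clip + sum(bad)
    w2[bad] <- 1e-10
    w <- sqrt(w2)
    rho <- (outer(w2, w2, `+`) - Tmat) / (2 * outer(w, w))
    over <- rho > 1; under <- rho < -1
    n_clip <- n_clip + (sum(over) + sum(under) - sum(diag(over))) / 2
    rho[over] <- 1; rho[under] <- -1
    diag(rho) <- 1
    if (n_excl >= max_exclusions) break
    cand <- abs(rho) * incl; diag(cand) <- 0
    m <- max(cand)
    if (m <= exclusion_rho) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    incl[ij[1], ij[2]] <- incl[ij[2], ij[1]] <- FALSE
    n_excl <- n_excl + 1L
  }
  list(rho = rho, omega2 = w2, n_excluded = n_excl, n_clipped = n_clip)
}

# One posterior draw of log abundances: columns flagged `resample` get
# Dirichlet-posterior (uniform prior) gamma draws from their counts; fixed
# columns (e.g. clinical pseudo-components) enter as log of their values.
# Per-sample scaling cancels in log-ratio variances, so no normalisation is
# needed.
draw_log_abundance <- function(counts, resample) {
  L <- matrix(NA_real_, nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  if (any(resample)) {
    cc <- counts[, resample, drop = FALSE]
    L[, resample] <- log(matrix(rgamma(length(cc), shape = cc + 1),
                                nrow(cc), ncol(cc)))
  }
  if (any(!resample)) L[, !resample] <- log(counts[, !resample, drop = FALSE])
  L
}

variation_matrix <- function(L) {
  C <- cov(L)
  v <- diag(C)
  outer(v, v, `+`) - 2 * C
}

#' SparCC compositional correlation
#'
#' Estimates correlations between the (unobserved) basis abundances
#' underlying compositional count data. Each inner resample draws component
#' fractions from the Dirichlet posterior under a uniform prior, computes
#' the log-ratio variation matrix \eqn{T_{ij} = Var(\log(x_i/x_j))}, solves
#' the basis-variance linear system under the sparsity assumption
#' (iteratively excluding the strongest pair above `exclusion_rho` and
#' re-solving), and forms
#' \eqn{\rho_{ij} = (\omega_i^2 + \omega_j^2 - T_{ij}) / (2\omega_i\omega_j)}.
#' Estimates are averaged over resamples; values outside \eqn{[-1, 1]} and
#' negative basis variances are clipped and counted.
#'
#' @param counts samples x components count matrix (>= 4 components; >= 10
#'   samples recommended).
#' @param n_inner posterior resamples to average (default 20).
#' @param exclusion_rho threshold triggering pair exclusion (default 0.1).
#' @param max_exclusions exclusion-loop cap (default 10).
#' @param seed integer seed.
#' @param resample logical per column: `FALSE` marks fixed (non-count)
#'   pseudo-components that skip the posterior draw. Default all `TRUE`.
#' @return List of class `sparcc_result`: `ids`, `rho` (symmetric, unit
#'   diagonal), `omega2`, `n_clipped`, `n_excluded`, `params`.
#' @export
sparcc_correlate <- function(counts, n_inner = 20, exclusion_rho = 0.1,
                             max_exclusions = 10, seed = 1, resample = NULL) {
  counts <- as.matrix(counts)
  p <- ncol(counts)
  if (p < 4) stop("SparCC needs >= 4 components for an identifiable system")
  if (is.null(colnames(counts))) colnames(counts) <- paste0("c", seq_len(p))
  resample <- resample %||% rep(TRUE, p)
  set.seed(derive_seed(seed, "sparcc"))
  rho_sum <- matrix(0, p, p)
  w2_sum <- numeric(p)
  n_clip <- 0L; n_excl <- 0L
  for (b in seq_len(n_inner)) {
    L <- draw_log_abundance(counts, resample)
    res <- sparcc_basis(variation_matrix(L), exclusion_rho, max_exclusions)
    rho_sum <- rho_sum + res$rho
    w2_sum <- w2_sum + res$omega2
    n_clip <- n_clip + res$n_clipped
    n_excl <- n_excl + res$n_excluded
  }
  rho <- rho_sum / n_inner
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  structure(list(ids = colnames(counts), rho = rho,
                 omega2 = setNames(w2_sum / n_inner, colnames(counts)),
                 n_clipped = n_clip, n_excluded = n_excl,
                 params = list(n_inner = n_inner,
                               exclusion_rho = exclusion_rho,
                               max_exclusions = max_exclusions, seed = seed,
                               resample = resample)),
            class = "sparcc_result")
}

#' @export
print.sparcc_result <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("SparCC: %d components; |rho| max %.3f, median %.3f\n",
              length(x$ids), max(abs(off)), median(abs(off))))
  invisible(x)
}

#' Bootstrap pseudo-p-values for SparCC correlations
#'
#' Null datasets are built by shuffling each component's values across
#' samples independently (column-wise permutation), which breaks all
#' cross-component association while preserving marginals. Two-sided
#' add-one pseudo-p: \eqn{p = (1 + \#\{|\rho^{boot}| \ge |\rho^{obs}|\}) /
#' (1 + n_{boot})}; p is never zero.
#'
#' @param counts the matrix `observed` was computed on.
#' @param observed a `sparcc_result`.
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return Symmetric matrix of pseudo-p-values (diagonal 1).
#' @export
sparcc_pvalues <- function(counts, observed, n_boot = 100, seed = 1) {
  stopifnot(inherits(observed, "sparcc_result"))
  if (n_boot < 1) stop("n_boot must be >= 1")
  counts <- as.matrix(counts)
  pars <- observed$params
  exceed <- matrix(0, ncol(counts), ncol(counts))
  set.seed(derive_seed(seed, "sparccboot"))
  perm_seeds <- sample.int(2^30, n_boot)
  for (b in seq_len(n_boot)) {
    shuf <- apply(counts, 2, sample)
    res <- sparcc_correlate(shuf, n_inner = pars$n_inner,
                            exclusion_rho = pars$exclusion_rho,
                            max_exclusions = pars$max_exclusions,
                            seed = perm_seeds[b], resample = pars$resample)
    exceed <- exceed + (abs(res$rho) >= abs(observed$rho))
  }
  pmat <- (1 + exceed) / (1 + n_boot)
  diag(pmat) <- 1
  dimnames(pmat) <- dimnames(observed$rho)
  pmat
}

#' Correlation between panel OTUs and clinical indicators
#'
#' Explores how the diagnostic panel relates to clinical chemistry (serum
#' albumin, 24-h urine protein, serum creatinine). Indicators are appended
#' to the OTU count matrix as fixed log pseudo-components (min-shifted when
#' zeros occur, and flagged) and the joint matrix goes through
#' [sparcc_correlate] and [sparcc_pvalues]; only the OTU x indicator block
#' is reported. Because running a compositional estimator across data types
#' is a modelling stretch, `method = "spearman"` provides a plain
#' rank-correlation fallback on log relative abundances.
#'
#' @param t an [otu_table] restricted (or restrictable) to the panel OTUs.
#' @param meta a [sample_metadata] carrying the indicator columns.
#' @param panel_ids OTUs to correlate (default: all columns of `t`).
#' @param indicators indicator column names (default ALB, Pro24h, SCr).
#' @param method `"sparcc"` or `"spearman"`.
#' @param n_inner,n_boot,seed passed to the SparCC engine.
#' @return List of class `clinical_assoc`: `block` (long data.frame otu /
#'   indicator / rho / p / stars), `rho`, `p` (joint matrices for sparcc),
#'   `n_samples`, `n_dropped`, `shifted_indicators`, `method`.
#' @export
clinical_association <- function(t, meta, panel_ids = NULL,
                                 indicators = c("ALB", "Pro24h", "SCr"),
                                 method = c("sparcc", "spearman"),
                                 n_inner = 20, n_boot = 100, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(meta, "sample_metadata"))
  m <- unclass(as.matrix(t))
  panel_ids <- panel_ids %||% colnames(m)
  m <- m[, panel_ids, drop = FALSE]
  missing <- setdiff(indicators, names(meta))
  if (length(missing)) stop("indicator(s) absent from metadata: ",
                            paste(missing, collapse = ", "))
  idx <- match(rownames(m), meta$sample_id)
  if (any(is.na(idx))) stop("samples absent from metadata")
  ind <- as.matrix(meta[idx, indicators, drop = FALSE])
  rownames(ind) <- rownames(m)
  ok <- complete.cases(ind)
  n_dropped <- sum(!ok)
  if (sum(ok) < 10)
    stop("fewer than 10 samples with complete indicators (", sum(ok), ")")
  m <- m[ok, , drop = FALSE]; ind <- ind[ok, , drop = FALSE]
  if (any(ind < 0)) stop("negative indicator values")
  const <- apply(ind, 2, function(x) var(x) == 0)
  if (any(const)) stop("zero-variance indicator(s): ",
                       paste(indicators[const], collapse = ", "))
  shifted <- character(0)
  for (j in seq_len(ncol(ind))) {
    if (any(ind[, j] <= 0)) {
      ind[, j] <- ind[, j] + min(ind[ind[, j] > 0, j]) / 2
      shifted <- c(shifted, indicators[j])
    }
  }

  if (method == "sparcc") {
    joint <- cbind(m, ind)
    resample <- c(rep(TRUE, ncol(m)), rep(FALSE, ncol(ind)))
    obs <- sparcc_correlate(joint, n_inner = n_inner, seed = seed,
                            resample = resample)
    pmat <- sparcc_pvalues(joint, obs, n_boot = n_boot, seed = seed)
    rho <- obs$rho; pv <- pmat
  } else {
    rel <- m / rowSums(m)
    logrel <- log(rel + 1e-6)
    rho <- diag(1, ncol(m) + ncol(ind))
    pv <- matrix(1, ncol(m) + ncol(ind), ncol(m) + ncol(ind))
    nm <- c(colnames(m), colnames(ind))
    dimnames(rho) <- dimnames(pv) <- list(nm, nm)
    for (i in seq_len(ncol(m))) for (j in seq_len(ncol(ind))) {
      ct <- suppressWarnings(stats::cor.test(logrel[, i], ind[, j],
                                             method = "spearman"))
      rho[i, ncol(m) + j] <- rho[ncol(m) + j, i] <- unname(ct$estimate)
      pv[i, ncol(m) + j] <- pv[ncol(m) + j, i] <- ct$p.value
    }
  }

  block <- expand.grid(otu = panel_ids, indicator = indicators,
                       stringsAsFactors = FALSE)
  block$rho <- rho[cbind(block$otu, block$indicator)]
  block$p <- pv[cbind(block$otu, block$indicator)]
  block$stars <- cut(block$p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                     labels = c("***", "**", "*", ""))
  structure(list(block = block, rho = rho, p = pv, n_samples = nrow(m),
                 n_dropped = n_dropped, shifted_indicators = shifted,
                 method = method),
            class = "clinical_assoc")
}

#' @export
print.clinical_assoc <- function(x, ...) {
  cat(sprintf("clinical association (%s): %d samples (%d dropped)\n",
              x$method, x$n_samples, x$n_dropped))
  print(x$block, row.names = FALSE)
  invisible(x)
}
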