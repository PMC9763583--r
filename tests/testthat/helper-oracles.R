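# Independent oracles: deliberately different code paths from the package
# (enumeration, per-branch loops, closed forms) so dual-route checks mean
# something.

# Exact two-sided Mann-Whitney p by full enumeration of label assignments
# (tie-free data only; uses the symmetric |U - mu| definition, which equals
# the doubled-tail definition when the null distribution is symmetric).
enum_mw_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) sum(outer(v[idx], v[-idx], ">")) +
    0.5 * sum(outer(v[idx], v[-idx], "=="))
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(length(v), n1), 2, u_of)
  mu <- n1 * (length(v) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Brute-force UniFrac: loop over every branch, tips below it found with
# phangorn::Descendants (independent of the package's postorder pass).
brute_unifrac <- function(tree, ca, cb, weighted, normalized = TRUE) {
  pa <- ca / sum(ca)
  pb <- cb / sum(cb)
  num <- den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[phangorn::Descendants(tree, tree$edge[e, 2],
                                                 "tips")[[1]]]
    ua <- sum(pa[tips]); ub <- sum(pb[tips]); b <- tree$edge.length[e]
    if (weighted) {
      num <- num + b * abs(ua - ub)
      den <- den + b * (ua + ub)
    } else {
      if (xor(ua > 0, ub > 0)) num <- num + b
      if (ua > 0 || ub > 0) den <- den + b
    }
  }
  if (weighted && !normalized) num else num / den
}

# All permutations of 1:n (tiny n only).
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exhaustive ANOSIM p using vegan's statistic as the independent engine.
enum_anosim_p <- function(D, labels) {
  d <- stats::as.dist(unclass(D))
  R_of <- function(lab) vegan::anosim(d, lab, permutations = 0)$statistic
  R_obs <- R_of(labels)
  perms <- all_perms(length(labels))
  Rs <- apply(perms, 1, function(idx) R_of(labels[idx]))
  mean(Rs >= R_obs - 1e-12)
}

# Closed-form ACE evaluated by direct symbolic substitution.
ace_oracle <- function(x, thr = 10) {
  x <- x[x > 0]
  s_ab <- sum(x > thr)
  rare <- x[x <= thr]
  if (!length(rare)) return(length(x))
  f <- tabulate(rare, nbins = thr)
  n_r <- sum(rare)
  c_ace <- 1 - f[1] / n_r
  g2 <- max(0, length(rare) / c_ace *
              sum(seq_len(thr) * (seq_len(thr) - 1) * f) /
              (n_r * (n_r - 1)) - 1)
  s_ab + length(rare) / c_ace + f[1] / c_ace * g2
}

# small fixture builders -----------------------------------------------

make_table <- function(counts, samples = NULL, otus = NULL) {
  samples <- samples %||% paste0("s", seq_len(nrow(counts)))
  otus <- otus %||% paste0("o", seq_len(ncol(counts)))
  dimnames(counts) <- list(samples, otus)
  otu_table(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_tree <- function(text = "((o1:1,o2:2):1,(o3:1.5,o4:0.5):2);") {
  ape::read.tree(text = text)
}

small_meta <- function(n_case = 10, n_control = 10, age_shift = 0,
                       seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  sample_metadata(data.frame(
    sample_id = paste0("s", seq_len(n)),
    group = rep(c("control", "case"), c(n_control, n_case)),
    age = rnorm(n, 45 + age_shift * rep(c(0, 1), c(n_control, n_case)), 10),
    sex = rbinom(n, 1, 0.5)))
}
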