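#' UniFrac dissimilarities
#'
#' Phylogeny-aware beta diversity between all sample pairs of an OTU table.
#' For each branch of the rooted tree let \eqn{p_A} be the fraction of
#' sample A's reads descending from that branch. Unweighted UniFrac is the
#' branch length unique to one sample's leaf set divided by the branch
#' length present in either set (presence/absence only); weighted UniFrac
#' is \eqn{\sum_e b_e |p_A - p_B|}, optionally normalised by
#' \eqn{\sum_e b_e (p_A + p_B)} so values are comparable across sequencing
#' depths (the default for the weighted variant).
#'
#' @param t an [otu_table]; every OTU with a nonzero count must be a tip of
#'   `tree` (extra tips are allowed and carry zero weight).
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param weighted abundance-weighted (`TRUE`) or presence/absence.
#' @param normalized for the weighted variant, divide by the total
#'   branch-length flow (ignored for unweighted, which is scale-free).
#' @return A [dist_matrix].
#' @export
unifrac <- function(t, tree, weighted = FALSE, normalized = TRUE) {
  stopifnot(inherits(t, "otu_table"))
  tree <- validate_otu_tree(tree)
  m <- unclass(t)
  present <- colnames(m)[colSums(m) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("OTU(s) not in tree: ", paste(missing, collapse = ", "))

  # tips x samples proportion matrix aligned to tree$tip.label
  p <- matrix(0, length(tree$tip.label), nrow(m),
              dimnames = list(tree$tip.label, rownames(m)))
  shared <- intersect(colnames(m), tree$tip.label)
  p[shared, ] <- t(m[, shared, drop = FALSE] / rowSums(m))

  flow <- edge_flow(tree, p)            # edges x samples
  b <- tree$edge.length
  n <- nrow(m)
  d <- matrix(0, n, n)
  if (weighted) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(b * abs(flow[, i] - flow[, j]))
      if (normalized) {
        den <- sum(b * (flow[, i] + flow[, j]))
        d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
      } else d[i, j] <- d[j, i] <- num
    }
  } else {
    pres <- flow > 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      either <- pres[, i] | pres[, j]
      uniq <- xor(pres[, i], pres[, j])
      den <- sum(b[either])
      d[i, j] <- d[j, i] <- if (den > 0) sum(b[uniq]) / den else 0
    }
  }
  dist_matrix(d, rownames(m))
}

# Fraction of each sample's reads descending from every edge: postorder
# accumulation of tip proportions up the tree.
edge_flow <- function(tree, tip_props) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  acc <- matrix(0, n_node, ncol(tip_props))
  acc[seq_len(n_tip), ] <- tip_props
  edges <- tree$edge
  for (e in ape::postorder(tree)) {
    acc[edges[e, 1], ] <- acc[edges[e, 1], ] + acc[edges[e, 2], ]
  }
  acc[edges[, 2], , drop = FALSE]
}
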