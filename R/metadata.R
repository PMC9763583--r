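#' Sample metadata
#'
#' Per-sample clinical and demographic information: case/control group,
#' age (years), sex, the three clinical indicators used for correlation
#' analysis -- serum albumin ALB (g/L), 24-h urine protein Pro24h (g/24 h)
#' and serum creatinine SCr (umol/L) -- and a cohort label for multi-centre
#' designs. Clinical fields may be missing (`NA`) but never negative.
#'
#' @param df data.frame with columns `sample_id`, `group` and optionally
#'   `age`, `sex`, `ALB`, `Pro24h`, `SCr`, `cohort`.
#' @param group_levels the exact set of allowed group labels; the first
#'   level is treated as control, the second as case/disease.
#' @return A validated data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df, group_levels = c("control", "case")) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("sample_id", "group")
  if (!all(req %in% names(df)))
    stop("metadata needs columns: ", paste(req, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  bad <- setdiff(unique(as.character(df$group)), group_levels)
  if (length(bad))
    stop("group labels outside declared levels: ", paste(bad, collapse = ", "))
  df$group <- factor(as.character(df$group), levels = group_levels)
  for (v in c("age", "ALB", "Pro24h", "SCr")) {
    if (v %in% names(df)) {
      df[[v]] <- as.numeric(df[[v]])
      if (any(df[[v]] < 0, na.rm = TRUE)) stop("negative values in ", v)
    }
  }
  if (!"cohort" %in% names(df)) df$cohort <- "cohort1"
  attr(df, "group_levels") <- group_levels
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from CSV
#'
#' @param path CSV file with a `sample_id` and `group` column.
#' @inheritParams sample_metadata
#' @return A [sample_metadata] data.frame.
#' @export
read_metadata <- function(path, group_levels = c("control", "case")) {
  sample_metadata(read.csv(path, stringsAsFactors = FALSE), group_levels)
}

#' Read a rooted phylogeny over OTUs
#'
#' Thin wrapper over [ape::read.tree] that enforces what UniFrac needs: a
#' rooted tree, unique tip labels, and nonnegative branch lengths.
#'
#' @param path newick file.
#' @return An [ape::phylo] tree.
#' @export
read_otu_tree <- function(path) {
  tree <- ape::read.tree(path)
  validate_otu_tree(tree)
}

validate_otu_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

# labels -> 0/1 disease indicator, honouring declared level order when given
as_binary_labels <- function(labels, case_level = NULL) {
  if (is.factor(labels)) {
    lv <- levels(labels)
  } else {
    lv <- unique(as.character(labels))
  }
  if (length(lv) != 2) stop("exactly two groups required, got: ",
                            paste(lv, collapse = ", "))
  case <- case_level %||% lv[2]
  y <- as.integer(as.character(labels) == case)
  attr(y, "case_level") <- case
  attr(y, "control_level") <- setdiff(lv, case)
  y
}
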