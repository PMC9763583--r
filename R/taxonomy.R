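#' Taxonomy maps and taxon-level aggregation
#'
#' A `taxonomy_map` stores, per OTU, a ranked lineage from domain to genus.
#' Lineages shorter than six ranks are padded with `NA`; aggregation pools
#' anything unannotated at the requested rank under the reserved label
#' `"unclassified"` so that per-sample totals are conserved.
#'
#' @param otu_ids unique OTU identifiers.
#' @param lineages character vector of semicolon-separated lineages, ordered
#'   domain;phylum;class;order;family;genus (trailing ranks may be absent).
#' @return A data.frame of class `taxonomy_map` with one column per rank.
#' @export
taxonomy_map <- function(otu_ids, lineages) {
  otu_ids <- as.character(otu_ids)
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids in taxonomy")
  if (length(otu_ids) != length(lineages))
    stop("otu_ids and lineages differ in length")
  ranks <- tax_ranks()
  parts <- strsplit(as.character(lineages), ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p[p == ""] <- NA_character_
    length(p) <- length(ranks)
    p
  }, character(length(ranks))))
  out <- data.frame(otu_id = otu_ids, m, stringsAsFactors = FALSE)
  names(out) <- c("otu_id", ranks)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

tax_ranks <- function() c("domain", "phylum", "class", "order", "family", "genus")

#' Read a taxonomy map from TSV
#'
#' Expects two columns: OTU id and a semicolon-separated lineage.
#'
#' @param path file path.
#' @return A [taxonomy_map].
#' @export
read_taxonomy <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "", quote = "")
  taxonomy_map(df[[1]], df[[2]])
}

#' Aggregate OTU counts at a taxonomic rank
#'
#' Counts are summed over OTUs sharing the full lineage prefix down to
#' `rank`; OTUs without an annotation at that rank (or absent from the map
#' altogether) are pooled under `"unclassified"`, so column sums per sample
#' are conserved exactly.
#'
#' @param t an [otu_table].
#' @param tax a [taxonomy_map].
#' @param rank one of domain, phylum, class, order, family, genus.
#' @return An [otu_table] whose "OTUs" are lineage prefixes at `rank`.
#' @export
aggregate_by_rank <- function(t, tax, rank) {
  stopifnot(inherits(t, "otu_table"), inherits(tax, "taxonomy_map"))
  ranks <- tax_ranks()
  if (!rank %in% ranks) stop("unknown rank: ", rank)
  depth <- match(rank, ranks)
  idx <- match(colnames(t), tax$otu_id)
  key <- vapply(seq_along(idx), function(k) {
    if (is.na(idx[k])) return("unclassified")
    lin <- unlist(tax[idx[k], ranks[seq_len(depth)]], use.names = FALSE)
    if (any(is.na(lin))) return("unclassified")
    paste(lin, collapse = ";")
  }, character(1))
  groups <- unique(key)
  m <- vapply(groups, function(g)
    rowSums(unclass(t)[, key == g, drop = FALSE]), numeric(nrow(t)))
  if (nrow(t) == 1) m <- matrix(m, 1, dimnames = list(rownames(t), groups))
  otu_table(m, sample_ids = rownames(t), otu_ids = groups)
}

#' Per-sample Firmicutes/Bacteroidetes ratio
#'
#' A coarse dysbiosis indicator: total Firmicutes reads divided by total
#' Bacteroidetes reads in each sample. "Bacteroidota" (the SILVA 138 name)
#' is treated as a synonym of "Bacteroidetes" by default; the synonym table
#' is configurable. Samples with zero Bacteroidetes reads get `NA` (the
#' ratio is undefined, not infinite) and are listed in the `"undefined"`
#' attribute.
#'
#' @param t an [otu_table].
#' @param tax a [taxonomy_map] with phylum annotations.
#' @param synonyms named character vector mapping alternative phylum names
#'   to their canonical form.
#' @return Named numeric vector of ratios (one per sample), with attribute
#'   `undefined` listing samples whose Bacteroidetes total is zero.
#' @export
fb_ratio <- function(t, tax,
                     synonyms = c(Bacteroidota = "Bacteroidetes",
                                  Bacillota = "Firmicutes")) {
  stopifnot(inherits(t, "otu_table"), inherits(tax, "taxonomy_map"))
  phy <- tax$phylum[match(colnames(t), tax$otu_id)]
  hit <- match(phy, names(synonyms))
  phy[!is.na(hit)] <- synonyms[hit[!is.na(hit)]]
  firm <- !is.na(phy) & phy == "Firmicutes"
  bact <- !is.na(phy) & phy == "Bacteroidetes"
  if (!any(firm) && !any(bact))
    stop("neither Firmicutes nor Bacteroidetes annotated in taxonomy")
  f <- rowSums(unclass(t)[, firm, drop = FALSE])
  b <- rowSums(unclass(t)[, bact, drop = FALSE])
  ratio <- ifelse(b > 0, f / b, NA_real_)
  names(ratio) <- rownames(t)
  attr(ratio, "undefined") <- rownames(t)[b == 0]
  ratio
}
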