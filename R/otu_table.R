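#' OTU count tables
#'
#' An `otu_table` is a nonnegative integer matrix of sequence counts with
#' samples as rows and OTUs as columns, plus validated identifiers. It is the
#' universal input of the pipeline: every per-sample total must be positive
#' (a sample with zero reads carries no compositional information and is
#' rejected at load time rather than propagating NaNs downstream).
#'
#' @param counts numeric matrix of nonnegative integers, samples x OTUs.
#' @param sample_ids,otu_ids character vectors of unique identifiers;
#'   default to the dimnames of `counts`.
#' @return A matrix of class `otu_table` with `sample_ids` as rownames and
#'   `otu_ids` as colnames.
#' @examples
#' t <- otu_table(matrix(c(5, 2, 0, 2, 1, 2), 2, 3,
#'   dimnames = list(c("s1", "s2"), c("o1", "o2", "o3"))))
#' rowSums(t)
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(otu_ids))
    stop("sample and OTU identifiers are required")
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (nrow(counts) != length(sample_ids) || ncol(counts) != length(otu_ids))
    stop("identifier lengths do not match the count matrix")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (nrow(counts) < 1 || ncol(counts) < 1)
    stop("need at least one sample and one OTU")
  if (any(!is.finite(counts)) || !is.numeric(counts))
    stop("counts must be finite numbers")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  counts <- round(counts)
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total counts: ",
         paste(sample_ids[totals == 0], collapse = ", "))
  dimnames(counts) <- list(sample_ids, otu_ids)
  storage.mode(counts) <- "double"
  class(counts) <- c("otu_table", "matrix", "array")
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (total reads %s)\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) class(out) <- c("otu_table", "matrix", "array")
  out
}

#' Read an OTU table from TSV or BIOM-JSON
#'
#' The TSV dialect is the common mothur/QIIME export: one header row of
#' sample ids and a first column of OTU ids (orientation `"otus-as-rows"`,
#' the default). Orientation is never guessed from the data -- silent
#' transposition is the classic microbiome-pipeline bug -- so tables with
#' samples as rows must say so explicitly.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"` (BIOM 1.0, read via
#'   \pkg{biomformat}).
#' @param orientation `"otus-as-rows"` (default) or `"samples-as-rows"`;
#'   applies to TSV only (BIOM stores orientation internally).
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json"),
                           orientation = c("otus-as-rows", "samples-as-rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     row.names = NULL, stringsAsFactors = FALSE,
                     comment.char = "")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in ", path)
    rownames(m) <- ids
    if (orientation == "otus-as-rows") m <- t(m)
  } else {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # OTUs x samples
    m <- t(m)
  }
  otu_table(m)
}

#' Write an OTU table
#'
#' @param t an [otu_table].
#' @inheritParams read_otu_table
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(t, path, format = c("tsv", "biom-json"),
                            orientation = c("otus-as-rows", "samples-as-rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  stopifnot(inherits(t, "otu_table"))
  if (format == "tsv") {
    m <- if (orientation == "otus-as-rows") t(unclass(t)) else unclass(t)
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    names(df)[1] <- if (orientation == "otus-as-rows") "#OTU ID" else "#Sample ID"
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- biomformat::make_biom(t(unclass(t)))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Convert counts to per-sample relative abundances
#'
#' @param t an [otu_table] (or an already-relative table, which is
#'   re-normalised -- the transform is idempotent).
#' @return A matrix of class `rel_abundance` whose rows each sum to 1.
#' @examples
#' t <- otu_table(matrix(c(10, 30, 60), 1, 3,
#'   dimnames = list("s1", c("a", "b", "c"))))
#' to_relative_abundance(t)
#' @export
to_relative_abundance <- function(t) {
  m <- unclass(as.matrix(t))
  totals <- rowSums(m)
  if (any(totals <= 0)) stop("sample with non-positive total")
  out <- m / totals
  class(out) <- c("rel_abundance", "matrix", "array")
  out
}

#' Rarefy an OTU table to a fixed depth
#'
#' Optional sensitivity-analysis step: subsamples each sample's reads to a
#' common depth without replacement. Diversity statistics are computed on
#' raw counts by default; rarefaction is opt-in and seeded so the unstated
#' normalisation choice is explicit and reproducible.
#'
#' @param t an [otu_table].
#' @param depth target depth; samples below it are dropped with a warning.
#' @param seed integer seed.
#' @return A rarefied [otu_table].
#' @export
rarefy_table <- function(t, depth, seed) {
  stopifnot(inherits(t, "otu_table"), depth >= 1)
  keep <- rowSums(t) >= depth
  if (!all(keep))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth)
  if (!any(keep)) stop("no sample reaches depth ", depth)
  m <- unclass(t)[keep, , drop = FALSE]
  set.seed(derive_seed(seed, "rarefy"))
  out <- t(apply(m, 1, function(x) {
    reads <- rep.int(seq_along(x), x)
    tabulate(sample(reads, depth), nbins = length(x))
  }))
  colnames(out) <- colnames(m)
  otu_table(out)
}
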