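# Gene-overlap cross-tabulation between (consistently enriched) categories,
# over full memberships or restricted to a query gene list.

#' Pairwise gene-overlap matrix between categories
#'
#' Symmetric matrix of shared-member counts between the selected categories
#' of a collection; the diagonal holds category sizes.  With `restrict_to`,
#' every category is first intersected with the given gene list, so the
#' table counts only (for example) the GWAS genes of a thresholded list.
#'
#' @param collection gene-set data.frame (as from [read_gmt()]).
#' @param ids category ids to tabulate (default: all, >= 2 required).
#' @param restrict_to optional `gene_list`/character vector restricting the
#'   memberships.
#' @return an `overlap_matrix`: integer matrix with `dimnames` the category
#'   ids, class `c("overlap_matrix", "matrix")`.
#' @export
overlap_matrix <- function(collection, ids = NULL, restrict_to = NULL) {
  if (is.null(ids)) ids <- collection$set_id
  missing <- setdiff(ids, collection$set_id)
  if (length(missing)) {
    stop("category id(s) absent from collection: ",
         paste(missing, collapse = ", "))
  }
  if (length(ids) < 2) stop("need at least 2 categories to cross-tabulate")
  members <- collection$members[match(ids, collection$set_id)]
  if (!is.null(restrict_to)) {
    keep <- as_gene_ids(restrict_to)
    members <- lapply(members, intersect, keep)
  }
  m <- length(ids)
  counts <- matrix(0L, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    counts[i, i] <- length(members[[i]])
    for (j in seq_len(m)[-seq_len(i)]) {
      o <- length(intersect(members[[i]], members[[j]]))
      counts[i, j] <- o
      counts[j, i] <- o
    }
  }
  structure(counts, class = c("overlap_matrix", "matrix"))
}

#' Pairwise overlap percentages from an overlap matrix
#'
#' For each unordered category pair, the shared-member count expressed as a
#' percentage of each category's size (both denominators are reported, since
#' "x% overlap" is ambiguous otherwise).  Pairs involving a zero-size
#' category (possible under restriction) get `NA` percentages — undefined,
#' not 0.
#'
#' @param x an `overlap_matrix` from [overlap_matrix()].
#' @return data.frame with one row per pair `i < j`: `id_a`, `id_b`,
#'   `size_a`, `size_b`, `overlap`, `pct_of_a`, `pct_of_b`.
#' @export
overlap_percentages <- function(x) {
  stopifnot(inherits(x, "overlap_matrix"))
  ids <- rownames(x)
  sizes <- diag(x)
  pairs <- which(upper.tri(x), arr.ind = TRUE)
  out <- data.frame(
    id_a = ids[pairs[, 1]],
    id_b = ids[pairs[, 2]],
    size_a = sizes[pairs[, 1]],
    size_b = sizes[pairs[, 2]],
    overlap = x[pairs],
    stringsAsFactors = FALSE
  )
  out$pct_of_a <- ifelse(out$size_a > 0, 100 * out$overlap / out$size_a, NA_real_)
  out$pct_of_b <- ifelse(out$size_b > 0, 100 * out$overlap / out$size_b, NA_real_)
  rownames(out) <- NULL
  out
}

#' Write an overlap matrix as an upper-triangle TSV
#'
#' First column: category id; first data column: category size (the
#' diagonal); remaining columns: shared-member counts for pairs in the upper
#' triangle (lower triangle left empty), mirroring the usual published
#' layout of such cross-tabulations.
#'
#' @param x an `overlap_matrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_overlap_matrix <- function(x, path) {
  ids <- rownames(x)
  m <- length(ids)
  cells <- matrix("", m, m)
  cells[upper.tri(cells)] <- as.character(x[upper.tri(x)])
  diag(cells) <- "-"
  df <- data.frame(id = ids, n_genes = diag(x), cells,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("id", "n_genes", ids)
  write_tsv_raw(df, path)
}
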