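# SNP-to-gene annotation under symmetric flanking windows, best-SNP-per-gene
# collapse, and p-value-thresholded gene lists.

#' Map SNPs to genes under a flanking-window scheme
#'
#' A SNP maps to a gene iff, on the same (normalized) chromosome,
#' `start(g) - 1000*w <= pos0(s) < end(g) + 1000*w`, where `pos0` is the
#' SNP's 0-based position and `w` the window width in kb.  `w = 0` restricts
#' to the annotated gene span (the union of its UTRs, introns and exons);
#' the windowed scheme additionally captures SNPs in flanking regulatory
#' regions.  The flank is strand-symmetric, so strand never affects the
#' mapping.  One SNP may map to several overlapping or nearby genes; genes
#' with no mapped SNP are absent from the result.
#'
#' @param snps association data.frame (`snp_id`, `chrom`, `pos`, `p`).
#' @param genes gene-model data.frame (BED convention).
#' @param window_kb flank width in kb (>= 0; e.g. 0 or 20).
#' @return data.frame with one row per (gene, SNP) pair: `gene_id`,
#'   `snp_id`, `chrom`, `pos`, `p`, ordered by gene (file order) then SNP
#'   (file order).
#' @export
map_snps_to_genes <- function(snps, genes, window_kb = 0) {
  if (window_kb < 0) stop("window_kb must be >= 0")
  w <- as.integer(round(window_kb * 1000))
  empty <- data.frame(gene_id = character(), snp_id = character(),
                      chrom = character(), pos = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(snps) == 0 || nrow(genes) == 0) return(empty)
  # BED half-open [start - w, end + w) in 0-based == closed
  # [start - w + 1, end + w] in 1-based, which is where SNP pos lives
  gene_gr <- GenomicRanges::GRanges(
    seqnames = norm_chrom(genes$chrom),
    ranges = IRanges::IRanges(start = genes$start - w + 1L,
                              end = genes$end + w)
  )
  snp_gr <- GenomicRanges::GRanges(
    seqnames = norm_chrom(snps$chrom),
    ranges = IRanges::IRanges(start = snps$pos, width = 1L)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snp_gr, gene_gr))
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  ord <- order(gi, si)
  out <- data.frame(
    gene_id = genes$gene_id[gi[ord]],
    snp_id = snps$snp_id[si[ord]],
    chrom = snps$chrom[si[ord]],
    pos = snps$pos[si[ord]],
    p = snps$p[si[ord]],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Collapse a SNP-to-gene mapping to the best SNP per gene
#'
#' For every mapped gene, keeps the SNP with the lowest allelic p-value
#' (limiting the bias of large genes that harbor many SNPs).  Ties on p are
#' broken deterministically by smaller position, then lexicographic SNP id.
#'
#' @param mapping data.frame from [map_snps_to_genes()].
#' @return data.frame with one row per mapped gene: `gene_id`, `best_p`,
#'   `best_snp_id`, `n_snps`, ordered by `gene_id`.
#' @export
best_snp_per_gene <- function(mapping) {
  if (nrow(mapping) == 0) {
    return(data.frame(gene_id = character(), best_p = numeric(),
                      best_snp_id = character(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(mapping$gene_id, mapping$p, mapping$pos, mapping$snp_id)
  m <- mapping[ord, , drop = FALSE]
  first <- !duplicated(m$gene_id)
  out <- data.frame(
    gene_id = m$gene_id[first],
    best_p = m$p[first],
    best_snp_id = m$snp_id[first],
    n_snps = as.integer(table(m$gene_id)[m$gene_id[first]]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

new_gene_list <- function(gene_id, best_p, label, cutoff = NA_real_,
                          window_kb = NA_real_) {
  out <- data.frame(gene_id = as.character(gene_id),
                    best_p = as.numeric(best_p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, label = label, cutoff = cutoff, window_kb = window_kb,
            class = c("gene_list", "data.frame"))
}

#' Build a p-value-thresholded gene list
#'
#' Selects genes with `best_p` strictly below the cutoff and orders them by
#' ascending best p (ties by gene id).  The strict inequality matches the
#' usual "< tau" reading of cut-off tables.
#'
#' @param scores data.frame from [best_snp_per_gene()].
#' @param cutoff allelic p-value threshold in (0, 1].
#' @param window_kb window used to produce `scores` (recorded in the label).
#' @param label optional list label; default e.g. `"0.01"` or
#'   `"0.01+-20kb"`.
#' @return a `gene_list`: data.frame (`gene_id`, `best_p`) with attributes
#'   `label`, `cutoff`, `window_kb`.
#' @export
make_gene_list <- function(scores, cutoff, window_kb = NA, label = NULL) {
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must be in (0, 1]")
  if (is.null(label)) {
    label <- if (!is.na(window_kb) && window_kb > 0) {
      sprintf("%g+-%gkb", cutoff, window_kb)
    } else {
      sprintf("%g", cutoff)
    }
  }
  keep <- scores$best_p < cutoff
  sel <- scores[keep, , drop = FALSE]
  ord <- order(sel$best_p, sel$gene_id)
  new_gene_list(sel$gene_id[ord], sel$best_p[ord], label = label,
                cutoff = cutoff, window_kb = window_kb)
}

#' Extract gene ids from a gene list, score table or character vector
#'
#' @param x a `gene_list`, a data.frame with a `gene_id` column, or a
#'   character vector of gene ids.
#' @return character vector of gene ids.
#' @export
as_gene_ids <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x) && "gene_id" %in% names(x)) return(x$gene_id)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a gene list")
}

#' Tabulate SNP and gene counts across cutoffs and windows
#'
#' For each combination of allelic p-value cutoff and window width, counts
#' the SNPs below the cutoff, the subset of those mapped to at least one
#' gene, and the distinct genes they map to — the standard summary table of
#' a windowed SNP-to-gene annotation.
#'
#' @param snps association data.frame.
#' @param genes gene-model data.frame.
#' @param cutoffs numeric vector of p-value cutoffs (non-empty).
#' @param windows numeric vector of window widths in kb.
#' @return data.frame with columns `cutoff`, `window_kb`, `n_snps_total`,
#'   `n_snps_mapped`, `n_genes`.
#' @export
summarize_counts <- function(snps, genes, cutoffs, windows = c(0, 20)) {
  if (length(cutoffs) == 0) stop("cutoffs must be non-empty")
  rows <- list()
  for (w in windows) {
    mapping <- map_snps_to_genes(snps, genes, window_kb = w)
    for (tau in cutoffs) {
      sel_snps <- snps$snp_id[snps$p < tau]
      sub <- mapping[mapping$p < tau, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = tau, window_kb = w,
        n_snps_total = length(sel_snps),
        n_snps_mapped = length(unique(sub$snp_id)),
        n_genes = length(unique(sub$gene_id))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
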