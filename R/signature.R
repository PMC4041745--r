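# Dual-list signature comparison: enrich two gene lists against the same
# collection under identical settings, keep the categories both lists hit,
# rank them jointly and flag those significant in both at an FDR threshold.

#' Simultaneous enrichment of two gene lists against one collection
#'
#' Runs [run_ora()] on each list with the same method configuration, keeps
#' the categories with at least `config$min_genes` query genes in BOTH
#' lists, ranks them by the better of the two adjusted p-values (ties by
#' the worse p, then `set_id`), and flags dual significance when both
#' adjusted p-values fall below `q`.  Swapping the lists swaps the p
#' columns and preserves ranking and the dual flag.
#'
#' @param list_a,list_b gene lists (`gene_list`, data.frame with `gene_id`,
#'   or character vector).
#' @param collection gene-set data.frame.
#' @param background character vector: the reference universe.
#' @param config a [method_config()]; default hypergeometric/BH.
#' @param q dual-significance threshold on the adjusted p (default FDR 0.05).
#' @return data.frame with one row per jointly covered category: `set_id`,
#'   `name`, `k_a`, `p_adj_a`, `k_b`, `p_adj_b`, `rank`,
#'   `dual_significant`, ordered by `rank`.
#' @export
compare_two_lists <- function(list_a, list_b, collection, background,
                              config = default_method_profiles()[["default-0.05"]],
                              q = 0.05) {
  ta <- run_ora(list_a, collection, background, config, list_label = "A")
  tb <- run_ora(list_b, collection, background, config, list_label = "B")
  idx <- match(ta$set_id, tb$set_id)
  merged <- data.frame(
    set_id = ta$set_id, name = ta$name,
    k_a = ta$k, p_adj_a = ta$p_adj,
    k_b = tb$k[idx], p_adj_b = tb$p_adj[idx],
    stringsAsFactors = FALSE
  )
  keep <- merged$k_a >= config$min_genes & merged$k_b >= config$min_genes
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) > 0) {
    better <- pmin(merged$p_adj_a, merged$p_adj_b)
    worse <- pmax(merged$p_adj_a, merged$p_adj_b)
    ord <- order(better, worse, merged$set_id)
    merged <- merged[ord, , drop = FALSE]
    merged$rank <- seq_len(nrow(merged))
  } else {
    merged$rank <- integer()
  }
  merged$dual_significant <- merged$p_adj_a < q & merged$p_adj_b < q
  rownames(merged) <- NULL
  merged
}
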