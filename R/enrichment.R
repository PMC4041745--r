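# Over-representation analysis (ORA) of a gene list against a gene-set
# collection.  The 2x2 table per category is
#   k = |query ∩ category|,  K = |category ∩ background|,
#   n = |query ∩ background|, N = |background|.
# Named method profiles (statistic, correction, alpha) emulate the
# behavioral spread of independent enrichment tools for the consensus step.

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` category members when `n` genes are drawn without
#' replacement from a background of `N` genes of which `K` are in the
#' category.  Identical to the one-sided Fisher exact p of the 2x2 table.
#' The tail is accumulated in log space from the smallest term so the
#' 1e-6-scale thresholds of strict profiles are not hit by underflow.
#'
#' @param k observed overlap (query genes in the category).
#' @param K category size in the background.
#' @param n query size in the background.
#' @param N background size.
#' @return p-value in \[0, 1\].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  check_2x2_bounds(k, K, n, N)
  if (k == 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  log_terms <- stats::dhyper(k:hi, m = K, n = N - K, k = n, log = TRUE)
  log_terms <- sort(log_terms)  # accumulate from the smallest term
  m <- log_terms[length(log_terms)]
  min(1, exp(m + log(sum(exp(log_terms - m)))))
}

#' Upper-tail binomial enrichment p-value
#'
#' `P(Bin(n, K/N) >= k)`: the sampling-with-replacement approximation to the
#' hypergeometric tail that several enrichment tools offer.
#'
#' @inheritParams hypergeometric_tail
#' @return p-value in \[0, 1\].
#' @export
binomial_tail <- function(k, K, n, N) {
  check_2x2_bounds(k, K, n, N)
  if (N == 0) stop("N must be > 0")
  if (k == 0) return(1)
  stats::pbinom(k - 1, size = n, prob = K / N, lower.tail = FALSE)
}

#' One-sided chi-square enrichment p-value on the ORA 2x2 table
#'
#' Pearson chi-square (1 df, optionally Yates-corrected) on
#' `[[k, n-k], [K-k, N-K-n+k]]`, upper tail.  One-sidedness is enforced by
#' returning p = 1 whenever the category is at or below its expected
#' representation (`k <= n*K/N`).  Categories with a zero expected cell are
#' untestable and return p = 1 with a warning.
#'
#' @inheritParams hypergeometric_tail
#' @param yates apply the Yates continuity correction?
#' @return p-value in \[0, 1\].
#' @export
chisq_2x2 <- function(k, K, n, N, yates = FALSE) {
  check_2x2_bounds(k, K, n, N)
  o <- c(k, n - k, K - k, N - K - n + k)
  row_tot <- c(n, N - n)
  col_tot <- c(K, N - K)
  e <- outer(row_tot, col_tot) / N
  if (any(e == 0)) {
    warning("zero expected cell: category untestable, returning p = 1")
    return(1)
  }
  if (k <= n * K / N) return(1)
  dev <- abs(o - as.vector(t(e)))
  if (yates) dev <- pmax(0, dev - 0.5)
  x2 <- sum(dev^2 / as.vector(t(e)))
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

check_2x2_bounds <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0) stop("counts must be >= 0")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  invisible(TRUE)
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper mapping the pipeline's correction labels onto
#' [stats::p.adjust()]: `"BH"` (Benjamini-Hochberg step-up FDR),
#' `"bonferroni"`, `"holm"` (step-down), or `"none"` (identity).  Output is
#' in the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param method one of `"BH"`, `"bonferroni"`, `"holm"`, `"none"`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "bonferroni", "holm", "none")) {
  method <- match.arg(method)
  if (length(pvals) == 0) return(numeric())
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]")
  }
  if (method == "none") return(pvals)
  stats::p.adjust(pvals, method = method)
}

#' Construct a method profile
#'
#' A method profile is a named (statistic, correction, alpha) combination
#' standing in for one independent enrichment tool in the consensus step.
#'
#' @param name profile label.
#' @param statistic one of `"hypergeometric"`, `"binomial"`, `"chisq"`,
#'   `"chisq_yates"`.
#' @param correction one of `"BH"`, `"bonferroni"`, `"holm"`, `"none"`.
#' @param alpha adjusted-p significance threshold in (0, 1].
#' @param min_genes minimum query genes in a category for the `enriched`
#'   flag (default 2).
#' @return an object of class `method_config`.
#' @export
method_config <- function(name, statistic = "hypergeometric",
                          correction = "BH", alpha = 0.05, min_genes = 2L) {
  statistic <- match.arg(statistic,
                         c("hypergeometric", "binomial", "chisq", "chisq_yates"))
  correction <- match.arg(correction, c("BH", "bonferroni", "holm", "none"))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (min_genes < 1) stop("min_genes must be >= 1")
  structure(list(name = name, statistic = statistic, correction = correction,
                 alpha = alpha, min_genes = as.integer(min_genes)),
            class = "method_config")
}

#' The four default method profiles
#'
#' Emulates the behavioral spread of a panel of independent enrichment
#' tools: same minimum-gene filter everywhere, but different statistics and
#' significance thresholds ranging from permissive (adjusted p < 0.05) to
#' strict (adjusted p < 1e-6, the stringency needed by tools that otherwise
#' report hundreds of categories).
#'
#' @return named list of [method_config()] objects: `strict-1e6`
#'   (hypergeometric, BH, 1e-6), `strict-1e4` (binomial, BH, 1e-4),
#'   `mid-0.01` (chi-square, BH, 0.01), `default-0.05` (hypergeometric, BH,
#'   0.05).
#' @export
default_method_profiles <- function() {
  list(
    `strict-1e6`   = method_config("strict-1e6", "hypergeometric", "BH", 1e-6),
    `strict-1e4`   = method_config("strict-1e4", "binomial", "BH", 1e-4),
    `mid-0.01`     = method_config("mid-0.01", "chisq", "BH", 0.01),
    `default-0.05` = method_config("default-0.05", "hypergeometric", "BH", 0.05)
  )
}

#' Resolve method profiles by name or inline spec
#'
#' Accepts default profile names (see [default_method_profiles()]) or inline
#' `"statistic:correction:alpha"` strings, e.g. `"binomial:holm:0.01"`.
#'
#' @param x character vector of names/inline specs, or a list of
#'   [method_config()] objects (returned unchanged).
#' @return named list of `method_config` objects.
#' @export
resolve_profiles <- function(x) {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "method_config"))) {
    names(x) <- vapply(x, `[[`, "", "name")
    return(x)
  }
  defaults <- default_method_profiles()
  out <- lapply(x, function(nm) {
    if (nm %in% names(defaults)) return(defaults[[nm]])
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) {
      stop("unknown profile '", nm,
           "' (expected a default name or statistic:correction:alpha)")
    }
    method_config(nm, parts[1], parts[2], as.numeric(parts[3]))
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

ora_statistic <- function(statistic) {
  switch(statistic,
    hypergeometric = hypergeometric_tail,
    binomial = binomial_tail,
    chisq = function(k, K, n, N) chisq_2x2(k, K, n, N, yates = FALSE),
    chisq_yates = function(k, K, n, N) chisq_2x2(k, K, n, N, yates = TRUE)
  )
}

#' Over-representation analysis of one gene list against one collection
#'
#' For every category with at least one background member, builds the ORA
#' 2x2 table after intersecting the query, the category and the background,
#' computes the profile's raw enrichment p-value, corrects across all tested
#' categories of the collection, and flags enrichment at the profile's
#' adjusted-p threshold subject to the minimum-gene filter.  The result is
#' invariant to query order and to duplicated query genes.
#'
#' @param gene_list a `gene_list`, data.frame with `gene_id`, or character
#'   vector of query genes.
#' @param collection gene-set data.frame (as from [read_gmt()]).
#' @param background character vector of gene ids forming the reference
#'   universe (typically all genes of the gene-model file).
#' @param config a [method_config()].
#' @param list_label label recorded on the table (defaults to the gene
#'   list's own label, if any).
#' @return an `enrichment_table`: data.frame with one row per tested
#'   category (`set_id`, `name`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`,
#'   `enriched` and list column `overlap_genes`), ordered by `p_raw` then
#'   `set_id`, with attributes `m` (tests corrected over), `config` and
#'   `list_label`.
#' @export
run_ora <- function(gene_list, collection, background,
                    config = default_method_profiles()[["default-0.05"]],
                    list_label = NULL) {
  stopifnot(inherits(config, "method_config"))
  if (is.null(list_label)) {
    list_label <- attr(gene_list, "label")
    if (is.null(list_label)) list_label <- "query"
  }
  background <- unique(as.character(background))
  query <- unique(intersect(as_gene_ids(gene_list), background))
  if (length(query) == 0) {
    stop("gene list is empty after intersection with the background")
  }
  n <- length(query)
  N <- length(background)
  stat_fun <- ora_statistic(config$statistic)

  members_bg <- lapply(collection$members, function(m) intersect(m, background))
  K <- vapply(members_bg, length, 1L)
  keep <- K >= 1L
  members_bg <- members_bg[keep]
  K <- K[keep]
  overlap <- lapply(members_bg, function(m) sort(intersect(query, m)))
  k <- vapply(overlap, length, 1L)
  p_raw <- vapply(seq_along(k), function(i) stat_fun(k[i], K[i], n, N), 0)
  p_adj <- adjust_pvalues(p_raw, config$correction)

  out <- data.frame(
    set_id = collection$set_id[keep],
    name = collection$name[keep],
    k = k, K = K, n = n, N = N,
    p_raw = p_raw, p_adj = p_adj,
    enriched = p_adj < config$alpha & k >= config$min_genes,
    stringsAsFactors = FALSE
  )
  out$overlap_genes <- overlap
  ord <- order(out$p_raw, out$set_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, m = length(p_raw), config = config, list_label = list_label,
            class = c("enrichment_table", "data.frame"))
}

#' Ids of the categories flagged enriched in an enrichment table
#'
#' @param table an `enrichment_table` from [run_ora()].
#' @return character vector of enriched `set_id`s.
#' @export
enriched_ids <- function(table) {
  table$set_id[table$enriched]
}
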