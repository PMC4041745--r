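# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written from first principles (enumeration,
# sorted-formula definitions, brute-force scans) and never call the code
# paths they check.

# P(X >= k) for X ~ Hypergeometric(N, K, n) by exhaustive enumeration of
# all C(N, n) unordered draws from a labelled urn (items 1..K in category).
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  sum(hits >= k) / ncol(draws)
}

# direct summation of the upper binomial tail
oracle_binom_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:n
  sum(choose(n, i) * (K / N)^i * (1 - K / N)^(n - i))
}

# sorted-formula multiple-testing corrections, coded independently of
# stats::p.adjust
oracle_adjust <- function(p, method) {
  m <- length(p)
  if (m == 0) return(numeric())
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- switch(method,
    bonferroni = pmin(1, ps * m),
    holm = {
      raw <- pmin(1, (m - seq_len(m) + 1) * ps)
      cummax(raw)                       # step-down monotonicity
    },
    BH = {
      raw <- pmin(1, ps * m / seq_len(m))
      rev(cummin(rev(raw)))             # step-up monotonicity
    },
    none = ps
  )
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# O(n_snps * n_genes) exhaustive interval check of the SNP-to-gene rule:
# same normalized chromosome and start - w <= pos0 < end + w (pos0 0-based)
oracle_map <- function(snps, genes, window_kb) {
  w <- window_kb * 1000
  rows <- list()
  strip <- function(x) sub("^chr", "", x)
  for (gi in seq_len(nrow(genes))) {
    for (si in seq_len(nrow(snps))) {
      if (strip(genes$chrom[gi]) != strip(snps$chrom[si])) next
      pos0 <- snps$pos[si] - 1
      if (pos0 >= genes$start[gi] - w && pos0 < genes$end[gi] + w) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = genes$gene_id[gi], snp_id = snps$snp_id[si],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(), snp_id = character()))
  }
  do.call(rbind, rows)
}

# -- fixture builders --------------------------------------------------

toy_assoc <- function(snp_id, chrom, pos, p) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos), p = p,
             stringsAsFactors = FALSE)
}

toy_genes <- function(gene_id, chrom, start, end, strand = "+") {
  data.frame(gene_id = gene_id, symbol = gene_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

toy_sets <- function(...) {
  members <- list(...)
  out <- data.frame(
    set_id = names(members),
    name = paste("set", names(members)),
    namespace = "TOY",
    n_members = vapply(members, length, 1L),
    stringsAsFactors = FALSE
  )
  out$members <- unname(members)
  rownames(out) <- NULL
  out
}

# random association/gene tables for property tests
random_snps <- function(n, chroms = c("1", "2"), max_pos = 50000) {
  toy_assoc(sprintf("rs%04d", seq_len(n)),
            sample(chroms, n, replace = TRUE),
            sample.int(max_pos, n, replace = TRUE),
            stats::runif(n))
}

random_genes <- function(m, chroms = c("1", "2"), max_pos = 50000) {
  start <- sample.int(max_pos, m, replace = TRUE)
  len <- sample.int(3000, m, replace = TRUE)
  toy_genes(sprintf("G%03d", seq_len(m)),
            sample(chroms, m, replace = TRUE), start, start + len)
}

# enrichment tables with prescribed enriched sets, for consensus tests
fake_table <- function(enriched_ids, list_label, method_name,
                       universe = paste0("S", 1:8)) {
  df <- data.frame(set_id = universe, name = universe,
                   k = 2L, K = 5L, n = 10L, N = 100L,
                   p_raw = 0.5, p_adj = 0.5,
                   enriched = universe %in% enriched_ids,
                   stringsAsFactors = FALSE)
  structure(df, m = length(universe),
            config = method_config(method_name),
            list_label = list_label,
            class = c("enrichment_table", "data.frame"))
}
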