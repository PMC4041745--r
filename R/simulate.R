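# Synthetic GWAS generator: toy genome, gene-set collection, and a
# case-control allelic association scan with planted pathway signals.
# Everything is deterministic given the spec's seed, so downstream stages
# can be tested end-to-end with known ground truth.

#' Specify a synthetic case-control allelic scan
#'
#' Bundles every parameter of the generator.  The defaults emulate a
#' 369-case vs 369-control allelic association scan over a toy genome of
#' 2,000 genes.  Effect SNPs carry a per-allele odds ratio `theta`: a causal
#' SNP with population minor-allele frequency `f` has case allele frequency
#' `theta*f / (1 - f + theta*f)` while controls keep `f`.
#'
#' @param n_cases,n_controls group sizes (default 369 each).
#' @param n_genes number of genes on the toy genome.
#' @param gene_len mean gene length in bp (geometric draw).
#' @param gap_len mean intergenic gap in bp (geometric draw).
#' @param snps_per_gene mean number of SNPs per gene body (Poisson draw).
#' @param intergenic_snp_frac fraction of all SNPs placed between genes.
#' @param maf_low,maf_high bounds of the uniform minor-allele-frequency draw;
#'   the 0.05 lower default mirrors the usual MAF < 5% QC exclusion.
#' @param theta planted per-allele odds ratio, >= 1 (1 = null).
#' @param causal_sets character vector of gene-set ids carrying signal.
#' @param causal_gene_frac fraction of each causal set's genes that receive
#'   one causal SNP.
#' @param seed integer RNG seed.
#' @return an object of class `simulation_spec` (a named list).
#' @export
simulation_spec <- function(n_cases = 369L, n_controls = 369L,
                            n_genes = 2000L, gene_len = 2000,
                            gap_len = 30000, snps_per_gene = 3,
                            intergenic_snp_frac = 0.3,
                            maf_low = 0.05, maf_high = 0.5,
                            theta = 1, causal_sets = character(),
                            causal_gene_frac = 0.5, seed = 1L) {
  if (n_cases <= 0 || n_controls <= 0) stop("n_cases and n_controls must be > 0")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (!(maf_low > 0 && maf_low < maf_high && maf_high <= 0.5)) {
    stop("require 0 < maf_low < maf_high <= 0.5")
  }
  if (theta < 1) stop("theta must be >= 1")
  if (!(causal_gene_frac > 0 && causal_gene_frac <= 1)) {
    stop("causal_gene_frac must be in (0, 1]")
  }
  if (intergenic_snp_frac < 0 || intergenic_snp_frac >= 1) {
    stop("intergenic_snp_frac must be in [0, 1)")
  }
  if (gene_len < 1 || gap_len < 1) stop("gene_len and gap_len must be >= 1")
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes), gene_len = gene_len, gap_len = gap_len,
    snps_per_gene = snps_per_gene,
    intergenic_snp_frac = intergenic_snp_frac,
    maf_low = maf_low, maf_high = maf_high, theta = theta,
    causal_sets = as.character(causal_sets),
    causal_gene_frac = causal_gene_frac, seed = as.integer(seed)
  ), class = "simulation_spec")
}

# positive integer draw with the requested mean (geometric + 1)
rgeom_mean <- function(n, mean) {
  stats::rgeom(n, prob = 1 / mean) + 1L
}

#' Lay out a toy genome
#'
#' Genes are placed left-to-right on synthetic chromosomes (at most 1,000
#' genes per chromosome), with lengths and intergenic gaps drawn from
#' geometric distributions around `spec$gene_len` and `spec$gap_len`.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return gene-model data.frame (BED convention) as from
#'   [read_gene_models()], in coordinate order.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  lens <- rgeom_mean(n, spec$gene_len)
  gaps <- rgeom_mean(n, spec$gap_len)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  per_chrom <- 1000L
  chrom_idx <- (seq_len(n) - 1L) %/% per_chrom + 1L
  start <- integer(n)
  offset <- 0L
  for (i in seq_len(n)) {
    if (i > 1L && chrom_idx[i] != chrom_idx[i - 1L]) offset <- 0L
    start[i] <- offset + gaps[i]
    offset <- start[i] + lens[i]
  }
  data.frame(
    gene_id = sprintf("G%05d", seq_len(n)),
    symbol = sprintf("G%05d", seq_len(n)),
    chrom = as.character(chrom_idx),
    start = start, end = start + lens,
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Generate a random gene-set collection
#'
#' Each set samples members uniformly with replacement across the genome's
#' genes and then de-duplicates, so sets overlap by chance in the way GO and
#' KEGG categories do.
#'
#' @param genes gene-model data.frame (only `gene_id` is used).
#' @param n_sets number of sets.
#' @param size_mean mean set size (Poisson draw, floored at 2 so every
#'   category can satisfy the minimum-gene filter).
#' @param seed integer RNG seed.
#' @param namespace collection label (default `"SYN"`).
#' @return gene-set data.frame as from [read_gmt()].
#' @export
simulate_genesets <- function(genes, n_sets, size_mean, seed,
                              namespace = "SYN") {
  if (n_sets < 1) stop("n_sets must be >= 1")
  if (size_mean < 2) stop("size_mean must be >= 2")
  force(genes)  # see simulate_scan: force before seeding
  set.seed(as.integer(seed))
  ids <- genes$gene_id
  sizes <- pmax(2L, stats::rpois(n_sets, size_mean))
  members <- lapply(sizes, function(s) unique(sample(ids, s, replace = TRUE)))
  out <- data.frame(
    set_id = sprintf("SET%04d", seq_len(n_sets)),
    name = sprintf("synthetic gene set %d", seq_len(n_sets)),
    namespace = namespace,
    n_members = vapply(members, length, 1L),
    stringsAsFactors = FALSE
  )
  out$members <- members
  out
}

#' Allelic case-control association test
#'
#' The 1-df Pearson chi-square on the 2x2 table of allele counts in cases vs
#' controls (the "allelic" test of a case-control scan), vectorized over
#' SNPs.  No continuity correction by default; set `yates = TRUE` for the
#' Yates-corrected variant.  Monomorphic SNPs (either allele absent from the
#' pooled sample) return p = 1.
#'
#' @param a,b case reference- and alternate-allele counts.
#' @param c,d control reference- and alternate-allele counts.
#' @param yates apply the Yates continuity correction?
#' @return vector of p-values in \[0, 1\].
#' @export
allelic_test <- function(a, b, c, d, yates = FALSE) {
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("allele counts must be >= 0")
  a <- as.numeric(a); b <- as.numeric(b)  # doubles: products overflow int32
  c <- as.numeric(c); d <- as.numeric(d)
  ra <- a + b
  rc <- c + d
  if (any(ra == 0 | rc == 0)) stop("both groups must have a positive allele total")
  ref <- a + c
  alt <- b + d
  n <- ra + rc
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(0, dev - n / 2)
  x2 <- n * dev^2 / (ra * rc * ref * alt)
  p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  p[ref == 0 | alt == 0] <- 1
  p
}

#' Case allele frequency under a per-allele odds ratio
#'
#' Maps a control (population) allele frequency `f` to the case allele
#' frequency implied by odds ratio `theta`:
#' `f' = theta*f / (1 - f + theta*f)`.
#'
#' @param f allele frequency in controls.
#' @param theta per-allele odds ratio.
#' @return case allele frequency.
#' @export
causal_allele_freq <- function(f, theta) {
  theta * f / (1 - f + theta * f)
}

#' Simulate a case-control allelic association scan
#'
#' SNPs are placed in gene bodies (Poisson count per gene) and in intergenic
#' gaps, each with a minor-allele frequency drawn uniformly from
#' `[maf_low, maf_high]`.  Null SNPs draw case and control alternate-allele
#' counts from `Binomial(2N, f)` (alleles independent: Hardy-Weinberg holds
#' by construction).  Each causal gene — a `causal_gene_frac` fraction of
#' every set in `spec$causal_sets` — receives one extra causal SNP placed
#' uniformly in its gene body, whose case allele frequency is shifted by the
#' odds ratio `spec$theta` (see [causal_allele_freq()]).  P-values come from
#' [allelic_test()].  Deterministic given `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @param genes gene-model data.frame from [simulate_genome()].
#' @param sets gene-set data.frame from [simulate_genesets()]; may be `NULL`
#'   when `spec$causal_sets` is empty.
#' @return list with `associations` (data.frame `snp_id`, `chrom`, `pos`,
#'   `p`, in coordinate order) and `truth` (list `causal_set_ids`,
#'   `causal_gene_ids`, `causal_snp_ids`).
#' @export
simulate_scan <- function(spec, genes, sets = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  force(genes)  # evaluate before seeding: a lazily forced simulate_genome()
  force(sets)   # call would reset the RNG stream mid-scan

  if (length(spec$causal_sets)) {
    if (is.null(sets)) stop("causal_sets given but no gene-set collection supplied")
    missing <- setdiff(spec$causal_sets, sets$set_id)
    if (length(missing)) {
      stop("causal set id(s) absent from collection: ",
           paste(missing, collapse = ", "))
    }
  }
  set.seed(spec$seed + 1L)
  n_genes <- nrow(genes)

  # gene-body SNPs
  counts <- stats::rpois(n_genes, spec$snps_per_gene)
  gi <- rep(seq_len(n_genes), counts)
  body_pos0 <- floor(genes$start[gi] +
                       stats::runif(length(gi)) * (genes$end[gi] - genes$start[gi]))
  body <- data.frame(chrom = genes$chrom[gi], pos = as.integer(body_pos0) + 1L,
                     causal = FALSE, stringsAsFactors = FALSE)

  # intergenic SNPs, uniform over the gaps between consecutive genes
  frac <- spec$intergenic_snp_frac
  inter <- NULL
  if (frac > 0) {
    n_inter <- stats::rpois(1L, n_genes * spec$snps_per_gene * frac / (1 - frac))
    if (n_inter > 0) {
      gaps <- intergenic_gaps(genes)
      if (nrow(gaps) > 0) {
        pick <- sample(nrow(gaps), n_inter, replace = TRUE,
                       prob = gaps$len)
        pos0 <- floor(gaps$start[pick] + stats::runif(n_inter) * gaps$len[pick])
        inter <- data.frame(chrom = gaps$chrom[pick],
                            pos = as.integer(pos0) + 1L,
                            causal = FALSE, stringsAsFactors = FALSE)
      }
    }
  }

  # one causal SNP per selected gene of each causal set, inside the body
  causal_gene_ids <- character()
  causal <- NULL
  if (length(spec$causal_sets)) {
    for (sid in spec$causal_sets) {
      mem <- sets$members[[match(sid, sets$set_id)]]
      mem <- intersect(mem, genes$gene_id)
      n_pick <- ceiling(spec$causal_gene_frac * length(mem))
      if (n_pick > 0) {
        causal_gene_ids <- union(causal_gene_ids,
                                 sample(mem, n_pick, replace = FALSE))
      }
    }
    ci <- match(causal_gene_ids, genes$gene_id)
    pos0 <- floor(genes$start[ci] +
                    stats::runif(length(ci)) * (genes$end[ci] - genes$start[ci]))
    causal <- data.frame(chrom = genes$chrom[ci], pos = as.integer(pos0) + 1L,
                         causal = TRUE, stringsAsFactors = FALSE)
  }

  snps <- rbind(body, inter, causal)
  ord <- order(snps$chrom, snps$pos, !snps$causal)
  snps <- snps[ord, , drop = FALSE]
  snps$snp_id <- ifelse(snps$causal,
                        sprintf("cs%06d", seq_len(nrow(snps))),
                        sprintf("rs%06d", seq_len(nrow(snps))))

  # allele counts and allelic test
  f <- stats::runif(nrow(snps), spec$maf_low, spec$maf_high)
  f_case <- ifelse(snps$causal, causal_allele_freq(f, spec$theta), f)
  n_case_al <- 2L * spec$n_cases
  n_ctrl_al <- 2L * spec$n_controls
  b <- stats::rbinom(nrow(snps), n_case_al, f_case)
  d <- stats::rbinom(nrow(snps), n_ctrl_al, f)
  p <- allelic_test(n_case_al - b, b, n_ctrl_al - d, d)

  assoc <- data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
                      pos = snps$pos, p = p, stringsAsFactors = FALSE)
  rownames(assoc) <- NULL
  list(
    associations = assoc,
    truth = list(
      causal_set_ids = sort(spec$causal_sets),
      causal_gene_ids = sort(causal_gene_ids),
      causal_snp_ids = sort(snps$snp_id[snps$causal])
    )
  )
}

# gaps between consecutive genes on each chromosome (0-based half-open)
intergenic_gaps <- function(genes) {
  out <- lapply(split(genes, genes$chrom), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    gap_start <- c(0L, g$end[-nrow(g)])
    gap_end <- g$start
    keep <- gap_end > gap_start
    data.frame(chrom = g$chrom[keep], start = gap_start[keep],
               len = (gap_end - gap_start)[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write the ground truth of a simulated scan as JSON
#'
#' @param truth the `truth` element of [simulate_scan()]'s result.
#' @param spec the [simulation_spec()] used.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(truth, spec, path) {
  jsonlite::write_json(
    list(causal_set_ids = truth$causal_set_ids,
         causal_gene_ids = truth$causal_gene_ids,
         causal_snp_ids = truth$causal_snp_ids,
         spec = unclass(spec)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
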