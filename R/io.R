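# Readers and writers for every external format the pipeline touches.
# Conventions: SNP positions are 1-based (PLINK/VCF); gene intervals are
# 0-based half-open (BED).  Cross-comparisons convert SNP pos to 0-based at
# a single choke point inside map_snps_to_genes().

#' Normalize chromosome labels
#'
#' Strips an optional `chr` prefix so that mixed dialects (`chr1` vs `1`)
#' compare equal.  Applied to both SNP tables and gene models before any
#' interval comparison.
#'
#' @param x character vector of chromosome labels.
#' @return character vector without the `chr` prefix.
#' @export
norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read a GWAS association table
#'
#' Reads a PLINK-style whitespace- or tab-delimited table with a header row
#' containing at least the columns `SNP`, `CHR`, `BP` and `P`
#' (case-insensitive; extra columns are ignored).  Rows whose p-value is
#' missing or non-numeric are dropped and counted; the count is attached as
#' attribute `n_dropped` and reported via [message()].
#'
#' @param path path to the association table.
#' @return data.frame with columns `snp_id`, `chrom`, `pos` (1-based), `p`,
#'   in file order, with attribute `n_dropped`.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop("association file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "P")
  idx <- match(need, toupper(names(tab)))
  if (anyNA(idx)) {
    stop("association table is missing mandatory column(s): ",
         paste(need[is.na(idx)], collapse = ", "))
  }
  out <- data.frame(
    snp_id = tab[[idx[1]]],
    chrom  = tab[[idx[2]]],
    pos    = suppressWarnings(as.integer(tab[[idx[3]]])),
    p      = suppressWarnings(as.numeric(tab[[idx[4]]])),
    stringsAsFactors = FALSE
  )
  drop <- is.na(out$p)
  n_dropped <- sum(drop)
  if (n_dropped > 0) {
    message("read_associations: dropped ", n_dropped,
            " row(s) with missing/non-numeric P")
    out <- out[!drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  if (nrow(out) > 0) {
    if (anyNA(out$pos) || any(out$pos < 1)) {
      stop("invalid BP position (must be an integer >= 1)")
    }
    if (any(out$p < 0 | out$p > 1)) {
      stop("p-value outside [0, 1] in SNP(s): ",
           paste(out$snp_id[out$p < 0 | out$p > 1], collapse = ", "))
    }
    dup <- duplicated(out$snp_id)
    if (any(dup)) {
      stop("duplicate SNP id(s): ", paste(unique(out$snp_id[dup]), collapse = ", "))
    }
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a GWAS association table
#'
#' Inverse of [read_associations()]: writes the canonical `SNP CHR BP P`
#' header with tab separation; p-values in scientific notation.
#'
#' @param assoc data.frame as returned by [read_associations()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_associations <- function(assoc, path) {
  out <- data.frame(SNP = assoc$snp_id, CHR = assoc$chrom, BP = assoc$pos,
                    P = format_pvalue(assoc$p), stringsAsFactors = FALSE)
  write_tsv_raw(out, path)
}

#' Read gene models from a BED file
#'
#' Accepts BED4 or BED6 (chrom, start, end, name, \[score, strand\]).
#' Intervals stay in the native BED convention: 0-based, half-open.
#' Missing strand is recorded as `*` (unknown).
#'
#' @param path path to the BED file.
#' @return data.frame with columns `gene_id`, `symbol`, `chrom`, `start`
#'   (0-based inclusive), `end` (exclusive), `strand`, in file order.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("BED file must have at least 4 columns")
  start <- suppressWarnings(as.integer(tab[[2]]))
  end <- suppressWarnings(as.integer(tab[[3]]))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer start/end at line ",
         which(is.na(start) | is.na(end))[1])
  }
  bad <- start >= end
  if (any(bad)) {
    stop("empty or inverted interval (start >= end) at line ", which(bad)[1])
  }
  strand <- if (ncol(tab) >= 6) tab[[6]] else rep("*", nrow(tab))
  strand[!strand %in% c("+", "-")] <- "*"
  out <- data.frame(
    gene_id = tab[[4]], symbol = tab[[4]],
    chrom = tab[[1]], start = start, end = end, strand = strand,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out$gene_id)
  if (any(dup)) {
    stop("duplicate gene id(s): ", paste(unique(out$gene_id[dup]), collapse = ", "))
  }
  out
}

#' Write gene models as BED6
#'
#' @param genes data.frame as returned by [read_gene_models()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_models <- function(genes, path) {
  lines <- paste(genes$chrom, genes$start, genes$end, genes$gene_id, 0L,
                 genes$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is tab-separated: column 1 = set id, column 2 = description,
#' columns 3+ = member gene ids.  Duplicate members within a line are
#' de-duplicated (first occurrence wins); empty member fields are skipped.
#'
#' @param path path to the GMT file.
#' @param namespace collection label attached to every set (e.g. `"GO"`,
#'   `"KEGG"`).  Defaults to the file name without extension.
#' @return data.frame with columns `set_id`, `name`, `namespace`, `n_members`
#'   and a list column `members`, in file order.
#' @export
read_gmt <- function(path, namespace = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  if (is.null(namespace)) {
    namespace <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short)) {
    stop("GMT line ", which(short)[1], " has fewer than 3 columns")
  }
  set_id <- vapply(fields, `[[`, "", 1L)
  dup <- duplicated(set_id)
  if (any(dup)) {
    stop("duplicate gene-set id(s): ", paste(unique(set_id[dup]), collapse = ", "))
  }
  members <- lapply(fields, function(f) {
    m <- f[-(1:2)]
    unique(m[nzchar(m)])
  })
  empty <- vapply(members, length, 1L) == 0L
  if (any(empty)) {
    stop("gene set with no members at line ", which(empty)[1])
  }
  out <- data.frame(
    set_id = set_id,
    name = vapply(fields, `[[`, "", 2L),
    namespace = namespace,
    n_members = vapply(members, length, 1L),
    stringsAsFactors = FALSE
  )
  out$members <- members
  out
}

#' Write a gene-set collection as GMT
#'
#' @param sets data.frame as returned by [read_gmt()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_id[i], sets$name[i], sets$members[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a thresholded gene list
#'
#' Two tab-separated columns, one gene per line: gene id and its best
#' (minimum) SNP p-value, in the list's order (ascending best p).
#'
#' @param gene_list a `gene_list` as returned by [make_gene_list()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_list <- function(gene_list, path) {
  writeLines(paste(gene_list$gene_id, format_pvalue(gene_list$best_p),
                   sep = "\t"), path)
  invisible(path)
}

#' Read a gene list written by [write_gene_list()] (or any one/two column
#' plain-text gene list, one gene per line)
#'
#' @param path input path.
#' @param label optional human-readable label for the list; defaults to the
#'   file name without extension and without a `genelist_` prefix, so lists
#'   written by the annotate stage keep their original labels.
#' @return a `gene_list` data.frame with columns `gene_id` and `best_p`
#'   (`NA` if the file has a single column).
#' @export
read_gene_list <- function(path, label = NULL) {
  if (is.null(label)) {
    label <- sub("^genelist_", "", sub("\\.[^.]*$", "", basename(path)))
  }
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[ \t]+")
  gene_id <- vapply(fields, `[[`, "", 1L)
  best_p <- vapply(fields, function(f) {
    if (length(f) >= 2L) suppressWarnings(as.numeric(f[2])) else NA_real_
  }, 0)
  dup <- duplicated(gene_id)
  if (any(dup)) stop("duplicate gene id(s) in gene list: ",
                     paste(unique(gene_id[dup]), collapse = ", "))
  new_gene_list(gene_id, best_p, label = label)
}

#' Write any homogeneous result table as deterministic TSV
#'
#' Header plus one row per record.  List columns are flattened to
#' comma-joined strings; non-integer numeric columns are rendered in
#' scientific notation with seven significant digits, so identical inputs
#' always produce byte-identical files.
#'
#' @param records a data.frame of one homogeneous record type.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.list(col)) {
      out[[nm]] <- vapply(col, function(x) paste(x, collapse = ","), "")
    } else if (is.double(col) && !all(is.na(col) | col == floor(col))) {
      out[[nm]] <- format_pvalue(col)
    }
  }
  write_tsv_raw(out, path)
}

# scientific notation, 7 significant digits (>= 6 required by the output
# contract); NA rendered as "NA"
format_pvalue <- function(p) {
  out <- formatC(p, format = "e", digits = 6)
  out[is.na(p)] <- "NA"
  out
}

write_tsv_raw <- function(df, path) {
  con <- file(path, open = "wb")  # binary mode: fixed "\n" eol on any OS
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     na = "NA")
  invisible(path)
}
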