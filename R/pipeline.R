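# End-to-end driver: (optional) simulate -> annotate -> enrich -> consensus
# -> overlap, with a JSON run manifest recording config, input checksums,
# versions, seed and per-stage record counts.  Identical config + inputs
# produce byte-identical outputs.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param simulate generate the inputs with the synthetic scan generator?
#' @param assoc,genes,gmt input paths (required when `simulate = FALSE`).
#' @param cutoffs allelic p-value cutoffs defining the gene lists
#'   (default 0.01 and 0.005).
#' @param windows window widths in kb (default 0 and 20), crossed with
#'   `cutoffs` to give the gene lists (default: four lists).
#' @param summary_cutoffs cutoff grid for the SNP/gene count summary table.
#' @param profiles method-profile names or inline specs
#'   (see [resolve_profiles()]).
#' @param min_methods consensus support threshold (default 2).
#' @param seed RNG seed for simulation.
#' @param sim named list of overrides for [simulation_spec()] (e.g.
#'   `list(theta = 1.8, causal_sets = "SET0001")`).
#' @param n_sets,set_size_mean gene-set collection parameters used when
#'   simulating.
#' @return a named list usable as the `config` of [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, simulate = TRUE,
                            assoc = NULL, genes = NULL, gmt = NULL,
                            cutoffs = c(0.01, 0.005), windows = c(0, 20),
                            summary_cutoffs = c(0.05, 0.01, 0.005, 0.001, 1e-4),
                            profiles = names(default_method_profiles()),
                            min_methods = 2L, seed = 1L, sim = list(),
                            n_sets = 200L, set_size_mean = 25) {
  list(out_dir = out_dir, simulate = simulate, assoc = assoc, genes = genes,
       gmt = gmt, cutoffs = cutoffs, windows = windows,
       summary_cutoffs = summary_cutoffs, profiles = profiles,
       min_methods = min_methods, seed = seed, sim = sim,
       n_sets = n_sets, set_size_mean = set_size_mean)
}

stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the whole consensus enrichment pipeline
#'
#' Executes simulate (optional), annotate, enrich, consensus and overlap in
#' order, writing every intermediate and final table under
#' `config$out_dir`, plus a `manifest.json` with the config, input MD5
#' checksums, versions, seed and per-stage record counts.  Paths are
#' validated before any computation; any stage error aborts with the
#' failing stage named.  Progress goes to stderr; results only ever on
#' disk.
#'
#' @param config a list as from [pipeline_config()], or the path to a YAML
#'   file holding one.
#' @return invisibly, the manifest (a named list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_config(out_dir = config$out_dir)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")

  # validate before any compute
  with_stage("validate", {
    if (!isTRUE(config$simulate)) {
      for (key in c("assoc", "genes", "gmt")) {
        path <- config[[key]]
        if (is.null(path)) stop("input path '", key, "' missing")
        if (!file.exists(path)) stop("input path '", key, "' not found: ", path)
      }
    }
    resolve_profiles(config$profiles)
  })
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    versions = list(gwasora = as.character(utils::packageVersion("gwasora")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    inputs = list(), outputs = character(), counts = list()
  )

  # -- simulate ---------------------------------------------------------
  if (isTRUE(config$simulate)) {
    with_stage("simulate", {
      spec <- do.call(simulation_spec,
                      utils::modifyList(list(seed = config$seed), config$sim))
      genes <- simulate_genome(spec)
      sets <- simulate_genesets(genes, n_sets = config$n_sets,
                                size_mean = config$set_size_mean,
                                seed = spec$seed + 2L)
      scan <- simulate_scan(spec, genes, sets)
      config$assoc <- out("associations.tsv")
      config$genes <- out("genes.bed")
      config$gmt <- out("sets.gmt")
      write_associations(scan$associations, config$assoc)
      write_gene_models(genes, config$genes)
      write_gmt(sets, config$gmt)
      write_ground_truth(scan$truth, spec, out("ground_truth.json"))
      manifest$counts$simulate <- list(n_snps = nrow(scan$associations),
                                        n_genes = nrow(genes),
                                        n_sets = nrow(sets))
      stage_log("simulate", nrow(scan$associations), " SNPs, ",
                nrow(genes), " genes, ", nrow(sets), " sets")
    })
  }
  for (key in c("assoc", "genes", "gmt")) {
    manifest$inputs[[key]] <- list(path = config[[key]],
                                   md5 = unname(tools::md5sum(config[[key]])))
  }

  # -- annotate ---------------------------------------------------------
  snps <- genes <- sets <- NULL
  gene_lists <- list()
  with_stage("annotate", {
    snps <- read_associations(config$assoc)
    genes <- read_gene_models(config$genes)
    sets <- read_gmt(config$gmt)
    for (w in config$windows) {
      scores <- best_snp_per_gene(map_snps_to_genes(snps, genes, w))
      for (tau in config$cutoffs) {
        gl <- make_gene_list(scores, cutoff = tau, window_kb = w)
        gene_lists[[attr(gl, "label")]] <- gl
        write_gene_list(gl, out(sprintf("genelist_%s.tsv", attr(gl, "label"))))
      }
    }
    summary_tab <- summarize_counts(snps, genes, config$summary_cutoffs,
                                    config$windows)
    write_table(summary_tab, out("snp_gene_counts.tsv"))
    manifest$counts$annotate <- lapply(gene_lists, nrow)
    stage_log("annotate", length(gene_lists), " gene lists: ",
              paste(names(gene_lists), vapply(gene_lists, nrow, 1L),
                    sep = "=", collapse = ", "))
  })

  # -- enrich -----------------------------------------------------------
  profiles <- resolve_profiles(config$profiles)
  background <- genes$gene_id
  tables <- list()
  with_stage("enrich", {
    for (gl in gene_lists) {
      for (prof in profiles) {
        tab <- run_ora(gl, sets, background, prof)
        key <- paste0(attr(tab, "list_label"), "_", prof$name)
        tables[[key]] <- tab
        write_table(tab[setdiff(names(tab), "overlap_genes")],
                    out(sprintf("enrich_%s.tsv", key)))
      }
    }
    manifest$counts$enrich <- lapply(tables, function(t) sum(t$enriched))
    stage_log("enrich", length(tables), " enrichment tables")
  })

  # -- consensus --------------------------------------------------------
  report <- NULL
  with_stage("consensus", {
    report <- consensus_report(tables, min_methods = config$min_methods)
    consistent <- report$set_id[report$consistent]
    idx <- match(report$set_id, sets$set_id)
    tab3 <- data.frame(
      set_id = report$set_id,
      name = sets$name[idx],
      n_methods = report$n_methods,
      methods = report$methods,
      n_category_genes = sets$n_members[idx],
      consistent = report$consistent,
      stringsAsFactors = FALSE
    )
    write_table(tab3, out("consensus.tsv"))
    jsonlite::write_json(
      list(per_method_sets = attr(report, "per_method_sets"),
           support = attr(report, "support")),
      out("consensus_support.json"), auto_unbox = FALSE, pretty = TRUE)
    manifest$counts$consensus <- list(n_candidates = nrow(report),
                                      n_consistent = length(consistent))
    stage_log("consensus", length(consistent), " consistent categories")
  })

  # -- overlap ----------------------------------------------------------
  with_stage("overlap", {
    consistent <- report$set_id[report$consistent]
    if (length(consistent) >= 2) {
      full <- overlap_matrix(sets, ids = consistent)
      write_overlap_matrix(full, out("overlap_full.tsv"))
      write_table(overlap_percentages(full), out("overlap_full_pct.tsv"))
      first_list <- gene_lists[[1]]
      restr <- overlap_matrix(sets, ids = consistent, restrict_to = first_list)
      write_overlap_matrix(restr, out(sprintf("overlap_%s.tsv",
                                              attr(first_list, "label"))))
      manifest$counts$overlap <- list(n_categories = length(consistent))
      stage_log("overlap", "cross-tabulated ", length(consistent),
                " categories")
    } else {
      manifest$counts$overlap <- list(n_categories = length(consistent))
      stage_log("overlap", "skipped (fewer than 2 consistent categories)")
    }
  })

  manifest$outputs <- sort(unique(c(list.files(config$out_dir),
                                    "manifest.json")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
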