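# The consistency criterion: a category counts as consistently enriched
# when it is enriched in every required gene list (two p-value cutoffs x
# two window schemes) by at least min_methods independent method profiles.

#' Categories enriched by one method in every required gene list
#'
#' For a single method profile, intersects the enriched category sets of
#' its enrichment tables across all required gene lists (e.g. the 0.01,
#' 0.01+-20kb, 0.005 and 0.005+-20kb lists).  An empty enriched set in any
#' list empties the intersection.
#'
#' @param tables list of `enrichment_table`s from [run_ora()], all produced
#'   with the same method profile, one per required list.
#' @param required_lists character vector of list labels that must all be
#'   present; default: the labels of the supplied tables.
#' @return character vector of `set_id`s enriched in every required list.
#' @export
per_method_consistent <- function(tables, required_lists = NULL) {
  labels <- vapply(tables, function(t) attr(t, "list_label"), "")
  if (is.null(required_lists)) required_lists <- labels
  missing <- setdiff(required_lists, labels)
  if (length(missing)) {
    stop("no enrichment table supplied for required list(s): ",
         paste(missing, collapse = ", "))
  }
  methods_seen <- unique(vapply(tables, function(t) attr(t, "config")$name, ""))
  if (length(methods_seen) > 1) {
    stop("tables mix method profiles: ", paste(methods_seen, collapse = ", "))
  }
  use <- tables[match(required_lists, labels)]
  sets <- lapply(use, enriched_ids)
  sort(Reduce(intersect, sets))
}

#' Consensus of per-method consistent sets across method profiles
#'
#' A category is consistent when it appears in the per-method consistent
#' set of at least `min_methods` profiles ("enriched ... by more than one
#' tool" for the default of 2).
#'
#' @param per_method_sets named list (one element per method profile) of
#'   `set_id` vectors as returned by [per_method_consistent()].
#' @param min_methods minimum number of supporting profiles (default 2).
#' @return data.frame with one row per candidate category: `set_id`,
#'   `n_methods`, `methods` (comma-joined supporting profile names) and
#'   `consistent`, sorted by descending support then `set_id`.
#' @export
consensus_across_methods <- function(per_method_sets, min_methods = 2L) {
  if (min_methods < 1) stop("min_methods must be >= 1")
  if (length(per_method_sets) < min_methods) {
    stop("only ", length(per_method_sets), " method set(s) supplied but ",
         min_methods, " required")
  }
  if (is.null(names(per_method_sets)) || any(!nzchar(names(per_method_sets)))) {
    names(per_method_sets) <- paste0("method", seq_along(per_method_sets))
  }
  ids <- sort(unique(unlist(per_method_sets)))
  support <- lapply(ids, function(id) {
    names(per_method_sets)[vapply(per_method_sets, function(s) id %in% s, TRUE)]
  })
  out <- data.frame(
    set_id = ids,
    n_methods = vapply(support, length, 1L),
    methods = vapply(support, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  out$consistent <- out$n_methods >= min_methods
  out <- out[order(-out$n_methods, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full consensus report over a collection of enrichment tables
#'
#' Groups the supplied enrichment tables by method profile, computes each
#' profile's consistent set across the required gene lists, and applies the
#' cross-method consensus rule.  The long support matrix (one row per
#' category x list x method, with the enriched flag) is attached as
#' attribute `support`.
#'
#' @param tables list of `enrichment_table`s covering every (required list,
#'   method profile) combination.
#' @param required_lists list labels that every method must support a
#'   category in; default: all labels present in `tables`.
#' @param min_methods minimum supporting method profiles (default 2).
#' @return the data.frame of [consensus_across_methods()] with attributes
#'   `per_method_sets` and `support`.
#' @export
consensus_report <- function(tables, required_lists = NULL, min_methods = 2L) {
  methods <- unname(vapply(tables, function(t) attr(t, "config")$name, ""))
  labels <- unname(vapply(tables, function(t) attr(t, "list_label"), ""))
  if (is.null(required_lists)) required_lists <- sort(unique(labels))
  per_method <- lapply(split(tables, methods), per_method_consistent,
                       required_lists = required_lists)
  report <- consensus_across_methods(per_method, min_methods = min_methods)

  cand <- report$set_id
  support <- data.frame(set_id = character(), list_label = character(),
                        method = character(), enriched = logical(),
                        stringsAsFactors = FALSE)
  if (length(cand) > 0) {
    support <- do.call(rbind, lapply(seq_along(tables), function(i) {
      t <- tables[[i]]
      idx <- match(cand, t$set_id)
      data.frame(set_id = cand, list_label = labels[i], method = methods[i],
                 enriched = !is.na(idx) & t$enriched[idx],
                 stringsAsFactors = FALSE)
    }))
    rownames(support) <- NULL
  }
  structure(report, per_method_sets = per_method, support = support,
            class = c("consensus_report", "data.frame"))
}
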