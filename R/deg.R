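# Differential-expression status tables and the gene sets derived from them.
#
# Each data set is one experiment's gene -> {up, down, none} map over a
# stated gene universe (e.g. the genes with a unique probe on the array the
# experiment used). The meta-analysis consumes a list of such data sets.

DEG_STATUSES <- c("up", "down", "none")

#' Construct a differential-expression data set
#'
#' @param dataset_id Identifier of the experiment.
#' @param status Named character vector (`up`/`down`/`none`), names = gene
#'   ids. Genes of the universe missing from `status` are implicitly `none`.
#' @param universe Character vector of all genes measured in the experiment.
#' @param timepoint_h Treatment duration in hours (used by the early/late
#'   grouping), `NA` if unknown.
#' @return A `DatasetDEG` object.
#' @export
dataset_deg <- function(dataset_id, status, universe, timepoint_h = NA_real_) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  if (length(status)) {
    if (is.null(names(status))) stop("`status` must be named by gene id")
    if (!all(status %in% DEG_STATUSES)) {
      stop("unknown status value(s): ",
           paste(unique(setdiff(status, DEG_STATUSES)), collapse = ", "))
    }
    if (anyDuplicated(names(status))) {
      dup <- unique(names(status)[duplicated(names(status))])
      agree <- vapply(dup, function(g) {
        length(unique(status[names(status) == g])) == 1L
      }, logical(1L))
      if (!all(agree)) {
        stop("conflicting status for gene(s): ",
             paste(dup[!agree], collapse = ", "))
      }
      status <- status[!duplicated(names(status))]
    }
    if (!all(names(status) %in% universe)) {
      stop("status for gene(s) outside the universe")
    }
  }
  full <- structure(rep("none", length(universe)), names = universe)
  full[names(status)] <- status
  structure(list(dataset_id = as.character(dataset_id), status = full,
                 universe = universe, timepoint_h = as.numeric(timepoint_h)),
            class = "DatasetDEG")
}

#' @export
print.DatasetDEG <- function(x, ...) {
  cat(sprintf("DatasetDEG %s: %d genes (%d up, %d down), %s h\n",
              x$dataset_id, length(x$universe),
              sum(x$status == "up"), sum(x$status == "down"),
              format(x$timepoint_h)))
  invisible(x)
}

#' Genes with a given status in a data set
#'
#' @param ds A `DatasetDEG`.
#' @param status One of `"up"`, `"down"`, `"none"`.
#' @return Character vector of gene ids.
#' @export
deg_genes <- function(ds, status) {
  stopifnot(inherits(ds, "DatasetDEG"), status %in% DEG_STATUSES)
  names(ds$status)[ds$status == status]
}

#' Number of differentially expressed genes in a data set
#' @param ds A `DatasetDEG`.
#' @return Integer count of up plus down genes.
#' @export
n_degs <- function(ds) {
  stopifnot(inherits(ds, "DatasetDEG"))
  sum(ds$status != "none")
}

#' Read a differential-expression status table
#'
#' Expects a TSV with columns `gene_id` and `status` (optionally `lfc`,
#' `adj_p`). Rows for genes outside the supplied universe are dropped with a
#' warning; conflicting duplicate rows are an error.
#'
#' @param path TSV path.
#' @param universe Gene universe; defaults to the genes listed in the file.
#' @param dataset_id Identifier (defaults to the file name).
#' @param timepoint_h Treatment duration in hours.
#' @return A `DatasetDEG`.
#' @export
read_deg_table <- function(path, universe = NULL, dataset_id = NULL,
                           timepoint_h = NA_real_) {
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    if (is.null(universe)) stop("empty table and no universe supplied")
    return(dataset_deg(dataset_id, character(0L), universe, timepoint_h))
  }
  if (!all(c("gene_id", "status") %in% names(tab))) {
    stop("DEG table needs columns gene_id, status")
  }
  if (!all(tab$status %in% DEG_STATUSES)) {
    stop("unknown status value(s) in ", path)
  }
  if (is.null(universe)) universe <- unique(tab$gene_id)
  out <- tab$gene_id %in% universe
  if (!all(out)) {
    warning(sum(!out), " row(s) for genes outside the universe dropped")
    tab <- tab[out, , drop = FALSE]
  }
  dataset_deg(dataset_id, structure(tab$status, names = tab$gene_id),
              universe, timepoint_h)
}

#' Benjamini–Yekutieli adjusted p-values
#'
#' FDR control valid under arbitrary dependence between tests (the
#' correction used to call differential expression here). Thin validating
#' wrapper over [stats::p.adjust()] with `method = "BY"`; input order is
#' preserved.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
by_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("`pvals` must be numeric")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BY")
}

#' Call differential-expression statuses from fold changes and adjusted p
#'
#' A gene is `up` when its adjusted p is below `fdr` and its linear fold
#' change `2^lfc` exceeds `fc_hi`; `down` when adjusted p is below `fdr`
#' and the fold change is below `fc_lo`; `none` otherwise.
#'
#' @param lfc Named numeric vector of log2 fold changes.
#' @param adj_p Named numeric vector of adjusted p-values (same genes).
#' @param fdr FDR threshold (default 0.05).
#' @param fc_hi Upper linear fold-change threshold (default 3/2).
#' @param fc_lo Lower linear fold-change threshold (default 2/3).
#' @return Named character vector of statuses.
#' @export
call_degs <- function(lfc, adj_p, fdr = 0.05, fc_hi = 3 / 2, fc_lo = 2 / 3) {
  if (is.null(names(lfc)) || is.null(names(adj_p))) {
    stop("`lfc` and `adj_p` must be named by gene id")
  }
  if (!setequal(names(lfc), names(adj_p))) {
    stop("`lfc` and `adj_p` must cover the same genes")
  }
  adj_p <- adj_p[names(lfc)]
  fc <- 2^lfc
  status <- rep("none", length(lfc))
  status[adj_p < fdr & fc > fc_hi] <- "up"
  status[adj_p < fdr & fc < fc_lo] <- "down"
  structure(status, names = names(lfc))
}

#' Keep data sets with enough differentially expressed genes
#'
#' @param datasets List of `DatasetDEG`.
#' @param min_degs Minimum `|up| + |down|` (inclusive; default 10).
#' @return Filtered list, order preserved.
#' @export
filter_datasets <- function(datasets, min_degs = 10L) {
  keep <- vapply(datasets, function(d) n_degs(d) >= min_degs, logical(1L))
  datasets[keep]
}

#' Control and positive gene sets across data sets
#'
#' The control set holds genes measured in every data set (intersection of
#' universes) and called `none` everywhere; the positive set holds genes
#' differentially expressed (up or down) in at least `min_hits` data sets.
#' The two sets are disjoint by construction.
#'
#' @param datasets List of `DatasetDEG`.
#' @param min_hits Minimum number of data sets a positive gene must be DE in
#'   (default 3).
#' @return A list with `control` and `positive` character vectors, class
#'   `GeneSets`.
#' @export
build_gene_sets <- function(datasets, min_hits = 3L) {
  stopifnot(length(datasets) > 0L)
  universes <- lapply(datasets, `[[`, "universe")
  common <- Reduce(intersect, universes)
  de_sets <- lapply(datasets, function(d) {
    names(d$status)[d$status != "none"]
  })
  all_de <- unlist(de_sets, use.names = FALSE)
  hits <- table(all_de)
  positive <- names(hits)[hits >= min_hits]
  never_de <- setdiff(common, unique(all_de))
  structure(list(control = sort(never_de), positive = sort(positive)),
            class = "GeneSets")
}

#' @export
print.GeneSets <- function(x, ...) {
  cat(sprintf("GeneSets: %d control, %d positive\n",
              length(x$control), length(x$positive)))
  invisible(x)
}
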