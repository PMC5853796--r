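# End-to-end orchestration: scan -> association -> meta -> permutation,
# with early/late data-set grouping and TSV reporting.

#' Group data sets by treatment duration
#'
#' @param datasets List of `DatasetDEG`.
#' @param rule `"all"`, `"early"` or `"late"`.
#' @param boundary_h Boundary in hours (default 2).
#' @param early_inclusive Is the boundary counted as early (default TRUE,
#'   i.e. early = `<= 2 h`, late = `> 2 h`)?
#' @return Filtered list of data sets; `early` and `late` partition `all`.
#' @export
group_datasets <- function(datasets, rule = c("all", "early", "late"),
                           boundary_h = 2, early_inclusive = TRUE) {
  rule <- match.arg(rule)
  if (rule == "all") return(datasets)
  tp <- vapply(datasets, `[[`, numeric(1L), "timepoint_h")
  if (any(is.na(tp))) stop("early/late grouping needs timepoints for every data set")
  early <- if (early_inclusive) tp <= boundary_h else tp < boundary_h
  if (rule == "early") datasets[early] else datasets[!early]
}

#' Run the hexamer-association pipeline end to end
#'
#' Scans the promoters for canonical hexamer presence, runs the
#' per-dataset association tests and Fisher's-method meta-combination,
#' screens with the Bonferroni-corrected meta p-value, and assigns
#' permutation significance to the screened hexamers. Optionally groups
#' the data sets into early/late treatment subsets first and writes
#' per-stage TSVs plus a run log.
#'
#' @param promoters `promoter_set` or named character vector of sequences.
#' @param datasets List of `DatasetDEG` (must be non-empty after
#'   grouping).
#' @param grouping `"all"`, `"early"` or `"late"`.
#' @param alpha Threshold on Bonferroni-corrected p-values (default
#'   0.005).
#' @param M Number of permutations (default 1000).
#' @param rng_seed Integer seed for the permutation stage.
#' @param respect_mask Treat lowercase letters as masked?
#' @param n_tests Bonferroni family for the meta screen (default hexamers
#'   x statuses).
#' @param perm_method Multiplicity handling at the permutation stage.
#'   `"minp"` (default) assigns each screened hypothesis the Westfall–Young
#'   family-wise adjusted empirical p-value: per permutation the minimum
#'   meta p over the full family (all hexamers x both statuses) is
#'   recorded, and a hypothesis is counted as reached when that minimum is
#'   not greater than its observed meta p. This controls the FWER under
#'   the dependence between overlapping hexamers and between data sets,
#'   and — unlike an explicit Bonferroni factor, whose smallest reachable
#'   corrected value `n_tests / (M + 1)` exceeds any usual `alpha` at desk
#'   scale — remains informative at moderate `M`. `"bonferroni"` uses each
#'   hypothesis's own permutation null multiplied by the full family
#'   factor; it requires `M` on the order of `n_tests / alpha` to be
#'   satisfiable.
#' @param min_degs Data sets with fewer DEGs are dropped (default 10).
#' @param out_dir Optional directory for TSV reports and the run log.
#' @return A list of class `hexmeta_report`: `association`, `permutation`,
#'   `significant`, `datasets_used`, `params`.
#' @export
run_pipeline <- function(promoters, datasets, grouping = "all",
                         alpha = 0.005, M = 1000L, rng_seed = NULL,
                         respect_mask = FALSE, n_tests = NULL,
                         perm_method = c("minp", "bonferroni"),
                         min_degs = 10L, out_dir = NULL) {
  perm_method <- match.arg(perm_method)
  datasets <- group_datasets(datasets, grouping)
  datasets <- filter_datasets(datasets, min_degs)
  if (length(datasets) == 0L) {
    stop("no data sets left after grouping/filtering")
  }
  presence <- presence_matrix(promoters, respect_mask = respect_mask)
  assoc <- run_association(presence, datasets, alpha = alpha,
                           n_tests = n_tests)
  screened <- assoc[assoc$selected, , drop = FALSE]
  if (nrow(screened) > 0L) {
    if (perm_method == "minp") {
      perm <- permutation_test(presence, datasets, screened, M = M,
                               rng_seed = rng_seed, method = "minp",
                               statuses = c("up", "down"), alpha = alpha)
    } else {
      perm <- permutation_test(presence, datasets, screened, M = M,
                               rng_seed = rng_seed, method = "per_hexamer",
                               n_tests = if (is.null(n_tests))
                                 ncol(presence) * 2L else n_tests,
                               alpha = alpha)
    }
    signif_tab <- select_significant(perm, alpha)
  } else {
    perm <- data.frame(hexamer = character(0L), status = character(0L),
                       meta_p = numeric(0L), m = integer(0L), M = integer(0L),
                       perm_p = numeric(0L), bonferroni_perm_p = numeric(0L),
                       selected = logical(0L), stringsAsFactors = FALSE)
    signif_tab <- perm
  }
  report <- structure(list(
    association = assoc, permutation = perm, significant = signif_tab,
    datasets_used = vapply(datasets, `[[`, character(1L), "dataset_id"),
    params = list(grouping = grouping, alpha = alpha, M = M,
                  rng_seed = rng_seed, respect_mask = respect_mask,
                  n_tests_meta = if (is.null(n_tests))
                    ncol(presence) * 2L else n_tests,
                  perm_method = perm_method,
                  n_screened = nrow(screened), min_degs = min_degs)
  ), class = "hexmeta_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.hexmeta_report <- function(x, ...) {
  cat(sprintf(
    "hexameta report: %d data sets (%s), %d meta-screened, %d significant\n",
    length(x$datasets_used), x$params$grouping,
    sum(x$association$selected), nrow(x$significant)))
  if (nrow(x$significant)) {
    utils::head(x$significant, 10L) |> print(row.names = FALSE)
  }
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Emits `association.tsv`, `permutation.tsv`, `significant.tsv` and
#' `run_log.json` (thresholds, multiplicities, seed, data sets used).
#'
#' @param report A `hexmeta_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("association", "permutation", "significant")) {
    utils::write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    c(report$params, list(datasets_used = report$datasets_used,
                          package_version = as.character(utils::packageVersion("hexameta")))),
    file.path(dir, "run_log.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  invisible(dir)
}
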