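# Association of hexamer presence with differential-expression status:
# per-dataset one-sided Fisher exact tests on 2x2 contingency tables,
# Fisher's-method combination across data sets, Bonferroni selection.

#' 2x2 contingency table for presence vs responsiveness
#'
#' Cells: `a` = hexamer-present and responsive, `b` = present and not,
#' `c` = absent and responsive, `d` = absent and not. The four cells sum to
#' the size of the gene universe.
#'
#' @param presence Gene ids whose promoter contains the hexamer.
#' @param deg Gene ids with the responsiveness status under test.
#' @param universe All gene ids of the experiment.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
contingency <- function(presence, deg, universe) {
  universe <- unique(universe)
  if (!all(presence %in% universe) || !all(deg %in% universe)) {
    stop("presence and deg sets must lie inside the universe")
  }
  presence <- unique(presence); deg <- unique(deg)
  a <- length(intersect(presence, deg))
  b <- length(presence) - a
  cc <- length(deg) - a
  d <- length(universe) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' One-sided Fisher exact test for over-representation
#'
#' Exact upper-tail hypergeometric probability `P(X >= a)` given the
#' table's margins, i.e. the probability of seeing at least as many
#' hexamer-present responsive genes by chance. Vectorised over the cells.
#'
#' @param a,b,c,d Cells of the 2x2 table (see [contingency()]); `a` may also
#'   be a named vector as returned by [contingency()].
#' @return Upper-tail p-value(s) in `(0, 1]`.
#' @export
fisher_one_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b) && length(a) == 4L) {
    b <- a[[2L]]; c <- a[[3L]]; d <- a[[4L]]; a <- a[[1L]]
  }
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("negative cell count")
  # margins: a+b present genes, c+d absent, a+c responsive draws
  stats::phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
}

#' Combine p-values with Fisher's method
#'
#' The statistic is `-2 * sum(log(p_i))`, chi-squared with `2k` degrees of
#' freedom when the `p_i` are independent and uniform under the null; the
#' meta p-value is its upper-tail probability.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]` (length `k >= 1`).
#'   Exact zeros are clamped to the smallest positive double with a warning.
#' @return List with `chi2`, `dof` (`= 2k`) and `meta_p`.
#' @export
fisher_method <- function(pvals) {
  if (length(pvals) < 1L || !is.numeric(pvals)) {
    stop("`pvals` must be a non-empty numeric vector")
  }
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]")
  }
  if (any(pvals == 0)) {
    warning("p-value of 0 clamped to the smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  chi2 <- -2 * sum(log(pvals))
  dof <- 2L * length(pvals)
  list(chi2 = chi2, dof = dof,
       meta_p = stats::pchisq(chi2, df = dof, lower.tail = FALSE))
}

#' Bonferroni correction
#'
#' @param p P-value(s).
#' @param n_tests Number of tests in the family.
#' @return `min(1, p * n_tests)`.
#' @export
bonferroni <- function(p, n_tests) {
  if (any(n_tests < 1)) stop("`n_tests` must be >= 1")
  pmin(1, p * n_tests)
}

# Per-dataset upper-tail Fisher p for every feature column of a presence
# matrix, given integer row indices of the universe and of the responsive
# genes within that universe. Vectorised over features.
.dataset_feature_p <- function(presence, uni_idx, deg_idx) {
  n_u <- length(uni_idx)
  if (n_u == 0L) stop("dataset with empty universe")
  if (n_u == nrow(presence)) {
    n_pres <- colSums(presence)
  } else {
    n_pres <- colSums(presence[uni_idx, , drop = FALSE])
  }
  a <- colSums(presence[deg_idx, , drop = FALSE])
  n_deg <- length(deg_idx)
  stats::phyper(a - 1, m = n_pres, n = n_u - n_pres, k = n_deg,
                lower.tail = FALSE)
}

#' Hexamer-by-status association meta-analysis across data sets
#'
#' For every feature (canonical hexamer, or any other binary promoter
#' feature such as a chromatin state) and each status, builds one 2x2
#' contingency table per data set (presence vs status over that data set's
#' universe), computes the one-sided Fisher exact p, combines the
#' per-dataset p-values with Fisher's method, and Bonferroni-corrects the
#' meta p over `n_tests` tests.
#'
#' @param presence Logical matrix genes x features (see
#'   [presence_matrix()]); row names are gene ids.
#' @param datasets Non-empty list of `DatasetDEG`. Universe genes missing
#'   from the presence matrix are dropped from that data set's table.
#' @param statuses Statuses to test (default `c("up", "down")`).
#' @param alpha Selection threshold on the Bonferroni-corrected meta p
#'   (default 0.005, strict).
#' @param n_tests Bonferroni family size; default features x statuses.
#' @return Data.frame with one row per (feature, status): `hexamer`,
#'   `status`, `k`, `chi2`, `dof`, `meta_p`, `bonferroni_p`, `selected`.
#' @export
run_association <- function(presence, datasets, statuses = c("up", "down"),
                            alpha = 0.005, n_tests = NULL) {
  stopifnot(is.matrix(presence), is.logical(presence))
  if (length(datasets) == 0L) stop("`datasets` must be non-empty")
  if (is.null(rownames(presence)) || is.null(colnames(presence))) {
    stop("`presence` needs gene row names and feature column names")
  }
  statuses <- match.arg(statuses, c("up", "down"), several.ok = TRUE)
  if (is.null(n_tests)) n_tests <- ncol(presence) * length(statuses)
  genes <- rownames(presence)
  k <- length(datasets)
  out <- vector("list", length(statuses))
  for (si in seq_along(statuses)) {
    st <- statuses[si]
    logp <- matrix(0, nrow = ncol(presence), ncol = k)
    for (di in seq_len(k)) {
      ds <- datasets[[di]]
      uni <- intersect(ds$universe, genes)
      if (length(uni) == 0L) stop("dataset with empty universe: ", ds$dataset_id)
      uni_idx <- match(uni, genes)
      deg_idx <- match(intersect(deg_genes(ds, st), genes), genes)
      logp[, di] <- log(.dataset_feature_p(presence, uni_idx, deg_idx))
    }
    chi2 <- -2 * rowSums(logp)
    meta_p <- stats::pchisq(chi2, df = 2 * k, lower.tail = FALSE)
    bonf <- bonferroni(meta_p, n_tests)
    out[[si]] <- data.frame(
      hexamer = colnames(presence), status = st, k = k, chi2 = chi2,
      dof = 2L * k, meta_p = meta_p, bonferroni_p = bonf,
      selected = bonf < alpha, stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}
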