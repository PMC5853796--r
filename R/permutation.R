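# Promoter-shuffling permutation test.
#
# Each permutation reassigns promoters to genes by a uniformly random
# bijection (every promoter used exactly once), shared by all hexamers and
# all data sets within that iteration so the correlation structure between
# overlapping hexamers is preserved. The association + meta computation is
# re-run on the permuted assignment; per (hexamer, status), m counts
# permutation statistics <= the observed meta p-value and the empirical
# p-value is (m + 1) / (M + 1). Counters accumulate in a streaming fashion
# so memory is O(features), not O(M).
#
# Two multiplicity treatments are provided. "minp" (Westfall–Young) counts,
# for each hypothesis, the permutations in which the *family minimum* of
# the permuted meta p-values reaches its observed value; the resulting
# p-value is already family-wise adjusted, exploits the dependence between
# overlapping hexamers, and is the default. "per_hexamer" counts against
# each hypothesis's own permutation distribution and leaves the family
# correction to an explicit Bonferroni factor; with the full family factor
# this is only satisfiable for very large M (the smallest reachable
# corrected value is n_tests / (M + 1)).

#' Random promoter-to-gene assignment
#'
#' A uniformly random bijection from genes to promoters (a full
#' permutation; fixed points allowed). Deterministic given the seed.
#'
#' @param gene_ids Character vector of distinct gene ids.
#' @param rng_seed Integer seed, or `NULL` to use the current RNG state.
#' @return Named character vector mapping each gene to the gene whose
#'   promoter it receives.
#' @export
permute_assignment <- function(gene_ids, rng_seed = NULL) {
  if (anyDuplicated(gene_ids)) stop("gene ids must be distinct")
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  structure(sample(gene_ids, length(gene_ids)), names = gene_ids)
}

#' Permutation significance for meta p-values
#'
#' Runs `M` promoter-shuffling permutations, re-runs the full association +
#' meta computation on every permuted assignment (all features in
#' `presence`, all statuses appearing in `observed`, one shared permutation
#' per iteration), and assigns each observed (hexamer, status) meta p-value
#' an empirical p-value `(m + 1) / (M + 1)`, where `m` counts permutation
#' statistics not greater than (`<=`) the observed value.
#'
#' With `method = "minp"` (default) the permutation statistic is the family
#' minimum of the permuted meta p-values (Westfall–Young), so `perm_p` is
#' already a family-wise adjusted p-value and `n_tests` defaults to 1. With
#' `method = "per_hexamer"` each hypothesis is counted against its own
#' permutation distribution and `n_tests` (default `nrow(observed)`)
#' supplies an explicit Bonferroni factor.
#'
#' @param presence Logical matrix genes x features (see
#'   [presence_matrix()]); its full column set defines the family for
#'   `"minp"`.
#' @param datasets List of `DatasetDEG`.
#' @param observed Data.frame from [run_association()] (or a subset of its
#'   rows) holding the (hexamer, status, meta_p) tuples to report.
#' @param M Number of permutations (>= 1). Desk-scale default 1000; raise
#'   towards 1e6 for publication-grade tails.
#' @param rng_seed Integer seed for reproducibility.
#' @param method `"minp"` or `"per_hexamer"` (see above).
#' @param statuses Statuses defining the permuted family (default: those
#'   appearing in `observed`; pass `c("up", "down")` to keep the full
#'   screen family when `observed` covers only one status).
#' @param n_tests Bonferroni factor applied on top of `perm_p`.
#' @param alpha Significance threshold on `bonferroni_perm_p` (default
#'   0.005, strict).
#' @return Data.frame with `hexamer`, `status`, `meta_p`, `m`, `M`,
#'   `perm_p`, `bonferroni_perm_p`, `selected`.
#' @export
permutation_test <- function(presence, datasets, observed, M = 1000L,
                             rng_seed = NULL,
                             method = c("minp", "per_hexamer"),
                             statuses = NULL, n_tests = NULL, alpha = 0.005) {
  stopifnot(is.matrix(presence), is.logical(presence))
  method <- match.arg(method)
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("M must be >= 1")
  if (nrow(observed) == 0L) stop("`observed` is empty")
  if (!all(c("hexamer", "status", "meta_p") %in% names(observed))) {
    stop("`observed` needs columns hexamer, status, meta_p")
  }
  if (!all(observed$hexamer %in% colnames(presence))) {
    stop("observed hexamer(s) absent from the presence matrix")
  }
  if (is.null(n_tests)) {
    n_tests <- if (method == "minp") 1L else nrow(observed)
  }
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))

  genes <- rownames(presence)
  n_genes <- length(genes)
  if (is.null(statuses)) statuses <- unique(observed$status)
  if (!all(observed$status %in% statuses)) {
    stop("`statuses` must cover every status in `observed`")
  }
  # the permuted family: all features for minp, the observed ones otherwise
  feats <- if (method == "minp") colnames(presence) else
    unique(observed$hexamer)
  P <- presence[, feats, drop = FALSE]

  # per (dataset, status) integer row indices
  ds_idx <- lapply(datasets, function(ds) {
    uni <- intersect(ds$universe, genes)
    if (length(uni) == 0L) stop("dataset with empty universe: ", ds$dataset_id)
    list(uni = match(uni, genes),
         deg = lapply(structure(statuses, names = statuses), function(st) {
           match(intersect(deg_genes(ds, st), genes), genes)
         }))
  })
  k <- length(datasets)
  obs_mat <- matrix(NA_real_, nrow = length(feats), ncol = length(statuses),
                    dimnames = list(feats, statuses))
  obs_mat[cbind(match(observed$hexamer, feats),
                match(observed$status, statuses))] <- observed$meta_p
  m_mat <- matrix(0L, nrow = length(feats), ncol = length(statuses),
                  dimnames = dimnames(obs_mat))

  for (it in seq_len(M)) {
    perm <- sample.int(n_genes)   # one shared permutation per iteration
    perm_meta <- matrix(NA_real_, length(feats), length(statuses))
    for (st_i in seq_along(statuses)) {
      logp <- numeric(length(feats))
      for (di in seq_len(k)) {
        ix <- ds_idx[[di]]
        logp <- logp + log(.dataset_feature_p(
          P, perm[ix$uni], perm[ix$deg[[st_i]]]))
      }
      perm_meta[, st_i] <- stats::pchisq(-2 * logp, df = 2 * k,
                                         lower.tail = FALSE)
    }
    if (method == "minp") {
      fam_min <- min(perm_meta)
      hit <- fam_min <= obs_mat
    } else {
      hit <- perm_meta <= obs_mat
    }
    hit[is.na(hit)] <- FALSE
    m_mat <- m_mat + hit
  }

  m <- m_mat[cbind(match(observed$hexamer, feats),
                   match(observed$status, statuses))]
  perm_p <- (m + 1) / (M + 1)
  bonf <- bonferroni(perm_p, n_tests)
  data.frame(
    hexamer = observed$hexamer, status = observed$status,
    meta_p = observed$meta_p, m = as.integer(m), M = M, perm_p = perm_p,
    bonferroni_perm_p = bonf, selected = bonf < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Select permutation-significant results
#'
#' @param results Data.frame from [permutation_test()].
#' @param alpha Threshold on `bonferroni_perm_p` (strict `<`; default
#'   0.005).
#' @return Subset with `bonferroni_perm_p < alpha`, sorted by `perm_p` then
#'   hexamer.
#' @export
select_significant <- function(results, alpha = 0.005) {
  keep <- results[results$bonferroni_perm_p < alpha, , drop = FALSE]
  keep[order(keep$perm_p, keep$hexamer), , drop = FALSE]
}
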