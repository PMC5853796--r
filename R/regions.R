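# Positional hexamer-occupancy enrichment inside peak regions and
# chromatin-state segments, and the chromatin-state-as-feature variant of
# the association analysis.
#
# Occupancy is counted over 6-bp start positions: the number of positions a
# hexamer (canonical class) occupies over a set of sequences, relative to
# the total number of valid positions. Two such proportions (foreground
# region set vs background promoters) are compared with the one-tailed
# Fisher exact test, Bonferroni-corrected over the hexamers tested.

#' Positional occupancy of one hexamer over a sequence set
#'
#' @param seqs Character vector of sequences.
#' @param hexamer A hexamer (canonicalised internally).
#' @param respect_mask Treat lowercase letters as masked (invalid)?
#' @return Named integer vector `c(occupied, total)`.
#' @export
occupancy <- function(seqs, hexamer, respect_mask = FALSE) {
  if (length(seqs) == 0L) return(c(occupied = 0L, total = 0L))
  hc <- hexamer_counts(seqs, respect_mask = respect_mask)
  h <- canonicalize(hexamer)
  c(occupied = sum(hc$counts[, h]), total = sum(hc$total_positions))
}

#' One-tailed two-proportion Fisher test for occupancy enrichment
#'
#' Tests over-representation of the foreground occupancy proportion against
#' the background via the exact hypergeometric upper tail on the 2x2 table
#' `(fg_occ, fg_tot - fg_occ; bg_occ, bg_tot - bg_occ)`.
#'
#' @param fg,bg Length-2 vectors `c(occupied, total)`.
#' @return Upper-tail p-value.
#' @export
enrichment_test <- function(fg, bg) {
  if (fg[[2L]] <= 0 || bg[[2L]] <= 0) stop("zero total positions")
  if (fg[[1L]] > fg[[2L]] || bg[[1L]] > bg[[2L]]) {
    stop("occupied exceeds total")
  }
  fisher_one_sided(fg[[1L]], fg[[2L]] - fg[[1L]],
                   bg[[1L]], bg[[2L]] - bg[[1L]])
}

# Occupancy counts for all canonical hexamers over a sequence set:
# list(occupied = named integer 2080-vector, total = scalar).
.occupancy_all <- function(seqs, respect_mask = FALSE) {
  canon <- enumerate_canonical()$hexamer
  if (length(seqs) == 0L) {
    return(list(occupied = structure(integer(length(canon)), names = canon),
                total = 0L))
  }
  hc <- hexamer_counts(seqs, respect_mask = respect_mask)
  list(occupied = colSums(hc$counts), total = sum(hc$total_positions))
}

# Extract interval sequences from a genome, truncating at chromosome ends.
.interval_seqs <- function(gr, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chrom %in% names(genome))) {
    stop("interval chromosome(s) absent from the genome")
  }
  clen <- Biostrings::width(genome)[match(chrom, names(genome))]
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  if (any(s < 1L) || any(e > clen)) {
    warning("interval(s) beyond chromosome ends truncated")
    s <- pmax(s, 1L); e <- pmin(e, clen)
  }
  keep <- s <= e
  as.character(Biostrings::subseq(genome[chrom[keep]],
                                  start = s[keep], end = e[keep]))
}

#' Hexamer enrichment within peak regions
#'
#' Compares, per hexamer, the positional occupancy across all peak
#' sequences (foreground) with the occupancy across all promoter windows
#' (background), via the one-tailed Fisher exact test with Bonferroni
#' correction over the hexamers tested. Overlapping peaks are merged first
#' so no position is double-counted. Peak sequences are taken from the
#' forward strand; canonical matching makes the strand choice irrelevant.
#'
#' @param peaks A `GRanges` or BED path of peak intervals.
#' @param genome A `DNAStringSet` or FASTA path.
#' @param promoter_bg Background promoters (`promoter_set` or named
#'   character vector of sequences).
#' @param hexamers Hexamers to test (default: all 2080 canonical classes).
#' @param fwer Family-wise error rate threshold (default 0.05, strict).
#' @param respect_mask Treat lowercase letters as masked?
#' @return Data.frame with one row per hexamer: occupancy counts on both
#'   sides, `p`, `fwer_p`, `significant`.
#' @export
peak_enrichment <- function(peaks, genome, promoter_bg, hexamers = NULL,
                            fwer = 0.05, respect_mask = FALSE) {
  if (is.character(peaks)) peaks <- rtracklayer::import(peaks)
  peaks <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
  fg_seqs <- .interval_seqs(peaks, genome)
  fg <- .occupancy_all(fg_seqs, respect_mask)
  bg <- .occupancy_all(promoter_seqs(promoter_bg), respect_mask)
  if (is.null(hexamers)) hexamers <- enumerate_canonical()$hexamer
  hexamers <- canonicalize(hexamers)
  occ_fg <- fg$occupied[hexamers]
  occ_bg <- bg$occupied[hexamers]
  p <- fisher_one_sided(occ_fg, fg$total - occ_fg, occ_bg, bg$total - occ_bg)
  fwer_p <- bonferroni(p, length(hexamers))
  data.frame(
    hexamer = hexamers, region_label = "peaks",
    occupied_fg = as.integer(occ_fg), total_fg = fg$total,
    occupied_bg = as.integer(occ_bg), total_bg = bg$total,
    p = p, fwer_p = fwer_p, significant = fwer_p < fwer,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Intersect promoter windows with a chromatin-state segmentation
#'
#' Splits each promoter into the sub-sequences that fall inside each
#' chromatin state's intervals. Sub-sequences are reported in
#' promoter-strand orientation; their lengths sum to the promoter's
#' coverage by the state map.
#'
#' @param promoters A `promoter_set` with genomic coordinates.
#' @param states A `GRanges` or BED path; the state label is the `name`
#'   column (conventionally `"1"`..`"9"` for a nine-state map).
#' @return Data.frame with `gene_id`, `state`, `chrom`, `start`, `end`
#'   (genomic, 1-based inclusive) and `seq`.
#' @export
state_segments <- function(promoters, states) {
  if (is.character(states)) states <- rtracklayer::import(states)
  lab <- states$name
  if (is.null(lab)) lab <- states$state
  if (is.null(lab)) stop("state intervals need a label (BED name column)")
  pg <- promoters_granges(promoters)
  ov <- GenomicRanges::findOverlaps(pg, states, ignore.strand = TRUE)
  if (length(ov) == 0L) {
    return(data.frame(gene_id = character(0L), state = character(0L),
                      chrom = character(0L), start = integer(0L),
                      end = integer(0L), seq = character(0L),
                      stringsAsFactors = FALSE))
  }
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  istart <- pmax(GenomicRanges::start(pg)[qh], GenomicRanges::start(states)[sh])
  iend <- pmin(GenomicRanges::end(pg)[qh], GenomicRanges::end(states)[sh])
  p_start <- promoters$start[qh]
  p_end <- promoters$end[qh]
  minus <- promoters$strand[qh] == "-"
  # promoter-local (1-based) coordinates along the promoter's own strand
  rel_start <- ifelse(minus, p_end - iend + 1L, istart - p_start + 1L)
  rel_end <- ifelse(minus, p_end - istart + 1L, iend - p_start + 1L)
  seqs <- substring(promoters$seq[qh], rel_start, rel_end)
  data.frame(
    gene_id = promoters$gene_id[qh], state = as.character(lab[sh]),
    chrom = promoters$chrom[qh], start = as.integer(istart),
    end = as.integer(iend), seq = seqs, stringsAsFactors = FALSE
  )
}

#' Per-gene chromatin-state presence matrix
#'
#' A state is present for a gene when its promoter has a non-empty
#' intersection with that state's intervals. The result plugs into
#' [run_association()] in place of the hexamer presence matrix.
#'
#' @param segments Output of [state_segments()].
#' @param gene_ids All gene ids to include as rows (genes without segments
#'   get all-`FALSE` rows).
#' @param states State labels to include as columns (default: those seen).
#' @return Logical matrix genes x states.
#' @export
state_presence <- function(segments, gene_ids, states = NULL) {
  if (is.null(states)) states <- sort(unique(segments$state))
  m <- matrix(FALSE, nrow = length(gene_ids), ncol = length(states),
              dimnames = list(gene_ids, states))
  keep <- segments$gene_id %in% gene_ids & segments$state %in% states
  m[cbind(segments$gene_id[keep], segments$state[keep])] <- TRUE
  m
}

#' Chromatin-state association with responsiveness
#'
#' Runs the association meta-analysis and the permutation test with the
#' chromatin-state indicators in place of the hexamer indicators: per data
#' set, the 2x2 table compares "promoter overlaps state s" with up/down
#' status. The meta screen is Bonferroni-corrected over states x statuses;
#' the permutation stage reports Westfall–Young family-wise adjusted
#' empirical p-values over the same family.
#'
#' @param datasets List of `DatasetDEG`.
#' @param state_pres Logical matrix from [state_presence()].
#' @param M Number of permutations.
#' @param rng_seed Integer seed.
#' @param alpha Selection threshold (default 0.005).
#' @return List with `association` and `permutation` data.frames (column
#'   `hexamer` carries the state label).
#' @export
state_association <- function(datasets, state_pres, M = 1000L,
                              rng_seed = NULL, alpha = 0.005) {
  n_tests <- ncol(state_pres) * 2L
  assoc <- run_association(state_pres, datasets, alpha = alpha,
                           n_tests = n_tests)
  perm <- permutation_test(state_pres, datasets, assoc, M = M,
                           rng_seed = rng_seed, method = "minp",
                           alpha = alpha)
  list(association = assoc, permutation = perm)
}

#' Hexamer enrichment within one chromatin state's promoter segments
#'
#' Two modes. `genomewide`: foreground = all promoter segments of the given
#' state, background = all promoters. `responsive_vs_control`: foreground =
#' the state's segments of the positive (responsive) genes, background =
#' the state's segments of the control genes. One-tailed Fisher exact test
#' on the occupancy proportions; `n_tests` sets the Bonferroni family
#' (canonically hexamers x states).
#'
#' @param hexamers Hexamers to test (canonicalised).
#' @param state State label.
#' @param segments Output of [state_segments()].
#' @param promoter_bg Background promoters (used in `genomewide` mode).
#' @param mode `"genomewide"` or `"responsive_vs_control"`.
#' @param sets `GeneSets` (required in `responsive_vs_control` mode).
#' @param n_tests Bonferroni family size (default `length(hexamers)` x
#'   number of states present in `segments`).
#' @param fwer FWER threshold (default 0.05, strict).
#' @param respect_mask Treat lowercase letters as masked?
#' @return Data.frame with one row per hexamer: counts, `p`, `fwer_p`,
#'   `significant`, `degenerate` (empty foreground).
#' @export
state_hexamer_enrichment <- function(hexamers, state, segments, promoter_bg,
                                     mode = c("genomewide",
                                              "responsive_vs_control"),
                                     sets = NULL, n_tests = NULL,
                                     fwer = 0.05, respect_mask = FALSE) {
  mode <- match.arg(mode)
  hexamers <- canonicalize(hexamers)
  if (is.null(n_tests)) {
    n_tests <- length(hexamers) * max(1L, length(unique(segments$state)))
  }
  seg <- segments[segments$state == state, , drop = FALSE]
  if (mode == "genomewide") {
    fg_seqs <- seg$seq
    bg_seqs <- promoter_seqs(promoter_bg)
  } else {
    if (is.null(sets)) stop("responsive_vs_control mode needs `sets`")
    fg_seqs <- seg$seq[seg$gene_id %in% sets$positive]
    bg_seqs <- seg$seq[seg$gene_id %in% sets$control]
  }
  fg <- .occupancy_all(fg_seqs, respect_mask)
  bg <- .occupancy_all(bg_seqs, respect_mask)
  degenerate <- fg$total == 0L || bg$total == 0L
  if (degenerate) {
    p <- rep(1, length(hexamers))
    occ_fg <- occ_bg <- rep(0L, length(hexamers))
  } else {
    occ_fg <- fg$occupied[hexamers]
    occ_bg <- bg$occupied[hexamers]
    p <- fisher_one_sided(occ_fg, fg$total - occ_fg,
                          occ_bg, bg$total - occ_bg)
  }
  fwer_p <- bonferroni(p, n_tests)
  data.frame(
    hexamer = hexamers, region_label = paste0("state_", state),
    occupied_fg = as.integer(occ_fg), total_fg = fg$total,
    occupied_bg = as.integer(occ_bg), total_bg = bg$total,
    p = p, fwer_p = fwer_p, significant = !degenerate & fwer_p < fwer,
    degenerate = degenerate, stringsAsFactors = FALSE, row.names = NULL
  )
}
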