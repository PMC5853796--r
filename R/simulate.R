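# Synthetic data generator.
#
# Emulates the statistical structure the analysis assumes: a cohort of
# differential-expression data sets with controlled cross-dataset overlap
# of gene statuses, i.i.d. promoter sequences at a chosen GC content with
# motifs planted at controlled foreground/background rates in responsive
# genes, peak intervals centered on planted instances, and block-wise
# chromatin-state segmentations with state-specific composition. Ground
# truth is returned alongside the emitted data so recovery and calibration
# are directly testable.

#' Simulation configuration
#'
#' Defaults describe a desk-scale auxin-response-style cohort: 2000 genes
#' with 1501-bp TSS-anchored windows at 36% GC, three data sets spanning
#' early and late treatment times, ~8% of genes up- and 8% down-regulated
#' per data set, and a 0.7 probability that a gene keeps its latent status
#' in any given data set.
#'
#' @param n_genes Number of genes.
#' @param window_len Promoter window length in bp.
#' @param gc_content Background GC fraction of promoter sequence.
#' @param n_datasets Number of differential-expression data sets.
#' @param timepoints_h Treatment durations in hours, one per data set
#'   (default spreads over 0.5–24 h so early/late grouping is exercised).
#' @param frac_up,frac_down Marginal fractions of up-/down-regulated genes
#'   per data set.
#' @param deg_overlap Probability a gene shows its latent status in a given
#'   data set (the rest of the time its status is redrawn from the
#'   marginal), giving the cross-dataset recurrence of responsive genes.
#' @param planted_motifs `NULL`, or a data.frame with columns `hexamer`,
#'   `target_status` (`up`/`down`), `p_fg`, `p_bg`: each motif is planted
#'   (one instance, random position and orientation) with probability
#'   `p_fg` in genes holding the target status in at least one data set and
#'   `p_bg` otherwise.
#' @param peak_cfg `NULL`, or `list(n_peaks, width, frac_planted)`: peak
#'   intervals of the given width; `frac_planted` of them are centered on
#'   planted motif instances and the rest placed uniformly on the genome.
#' @param state_cfg `NULL`, or `list(mean_block, state_freq, state_gc)`:
#'   promoters are tiled with chromatin-state blocks of geometric-ish
#'   length (mean `mean_block` bp), states drawn from `state_freq` (named
#'   `"1"`..`"9"` or any labels); `state_gc` optionally gives a per-state
#'   GC fraction so specific states carry biased composition.
#' @param seed Integer seed; the whole simulation is deterministic given
#'   it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L, window_len = 1501L,
                       gc_content = 0.36, n_datasets = 3L,
                       timepoints_h = NULL, frac_up = 0.08,
                       frac_down = 0.08, deg_overlap = 0.7,
                       planted_motifs = NULL, peak_cfg = NULL,
                       state_cfg = NULL, seed = 1L) {
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1) {
    stop("frac_up + frac_down must lie in [0, 1]")
  }
  if (gc_content < 0 || gc_content > 1 || deg_overlap < 0 || deg_overlap > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  if (is.null(timepoints_h)) {
    timepoints_h <- rep(c(0.5, 2, 6, 24), length.out = n_datasets)
  }
  if (length(timepoints_h) != n_datasets) {
    stop("timepoints_h must have one entry per data set")
  }
  if (!is.null(planted_motifs)) {
    stopifnot(all(c("hexamer", "target_status", "p_fg", "p_bg") %in%
                    names(planted_motifs)))
    if (any(nchar(planted_motifs$hexamer) > window_len)) {
      stop("motif longer than the promoter window")
    }
    if (any(planted_motifs$p_fg < planted_motifs$p_bg)) {
      stop("p_fg must be >= p_bg for enrichment scenarios")
    }
  }
  structure(list(
    n_genes = as.integer(n_genes), window_len = as.integer(window_len),
    gc_content = gc_content, n_datasets = as.integer(n_datasets),
    timepoints_h = as.numeric(timepoints_h), frac_up = frac_up,
    frac_down = frac_down, deg_overlap = deg_overlap,
    planted_motifs = planted_motifs, peak_cfg = peak_cfg,
    state_cfg = state_cfg, seed = as.integer(seed)
  ), class = "sim_config")
}

.rand_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.rand_seq <- function(n, gc) paste(.rand_bases(n, gc), collapse = "")

# Tile one window with state blocks; returns data.frame(start, end, state)
# in window-local 1-based coordinates.
.tile_states <- function(window_len, state_cfg) {
  mean_block <- state_cfg$mean_block %||% 400
  freq <- state_cfg$state_freq
  labs <- names(freq)
  if (is.null(labs)) labs <- as.character(seq_along(freq))
  starts <- integer(0L); ends <- integer(0L); sts <- character(0L)
  pos <- 1L
  while (pos <= window_len) {
    len <- max(30L, as.integer(round(stats::rexp(1L, rate = 1 / mean_block))))
    end <- min(window_len, pos + len - 1L)
    starts <- c(starts, pos); ends <- c(ends, end)
    sts <- c(sts, sample(labs, 1L, prob = freq))
    pos <- end + 1L
  }
  data.frame(start = starts, end = ends, state = sts,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic cohort
#'
#' Draws latent gene statuses, per-dataset statuses with the configured
#' cross-dataset persistence, promoter sequences (optionally tiled with
#' chromatin-state blocks of state-specific composition), plants motifs in
#' responsive genes, assembles a toy genome with gene models on both
#' strands, and derives peak and state interval sets. Deterministic given
#' `cfg$seed`; when `dir` is given all standard-format files are written
#' (FASTA, GFF3, TSV, BED, truth tables, config JSON) and re-reading them
#' reproduces the in-memory objects.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @return A list with `genome` (`DNAStringSet`), `promoters`
#'   (`promoter_set`), `models` (`GRanges`), `datasets` (list of
#'   `DatasetDEG`), `peaks` (`GRanges` or `NULL`), `states` (`GRanges` or
#'   `NULL`), `truth` (latent statuses, status matrix, planted instances,
#'   state blocks) and `cfg`.
#' @export
simulate_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  L <- cfg$window_len
  gene_ids <- sprintf("g%04d", seq_len(n))

  # latent status and per-dataset statuses (Markov copy of the latent label)
  marg <- c(up = cfg$frac_up, down = cfg$frac_down,
            none = 1 - cfg$frac_up - cfg$frac_down)
  latent <- sample(names(marg), n, replace = TRUE, prob = marg)
  status_mat <- matrix("none", nrow = n, ncol = cfg$n_datasets,
                       dimnames = list(gene_ids, sprintf("ds%02d", seq_len(cfg$n_datasets))))
  for (d in seq_len(cfg$n_datasets)) {
    keep <- stats::runif(n) < cfg$deg_overlap
    fresh <- sample(names(marg), n, replace = TRUE, prob = marg)
    status_mat[, d] <- ifelse(keep, latent, fresh)
  }

  # promoter sequences, optionally with chromatin-state block structure
  blocks <- NULL
  if (is.null(cfg$state_cfg)) {
    big <- .rand_bases(n * L, cfg$gc_content)
    seqs <- vapply(seq_len(n), function(i) {
      paste(big[((i - 1L) * L + 1L):(i * L)], collapse = "")
    }, character(1L))
  } else {
    state_gc <- cfg$state_cfg$state_gc
    blk_list <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      bl <- .tile_states(L, cfg$state_cfg)
      gc_i <- if (is.null(state_gc)) rep(cfg$gc_content, nrow(bl)) else {
        g <- state_gc[bl$state]
        ifelse(is.na(g), cfg$gc_content, g)
      }
      pieces <- vapply(seq_len(nrow(bl)), function(j) {
        .rand_seq(bl$end[j] - bl$start[j] + 1L, gc_i[j])
      }, character(1L))
      seqs[i] <- paste(pieces, collapse = "")
      bl$gene_id <- gene_ids[i]
      blk_list[[i]] <- bl
    }
    blocks <- do.call(rbind, blk_list)
  }

  # plant motifs in foreground genes (target status in >= 1 data set)
  planted <- data.frame(gene_id = character(0L), hexamer = character(0L),
                        offset = integer(0L), orient = character(0L),
                        stringsAsFactors = FALSE)
  if (!is.null(cfg$planted_motifs)) {
    pm <- cfg$planted_motifs
    for (r in seq_len(nrow(pm))) {
      hx <- toupper(pm$hexamer[r])
      is_fg <- rowSums(status_mat == pm$target_status[r]) >= 1L
      p_ins <- ifelse(is_fg, pm$p_fg[r], pm$p_bg[r])
      ins <- stats::runif(n) < p_ins
      for (i in which(ins)) {
        off <- sample.int(L - nchar(hx) + 1L, 1L)
        orient <- sample(c("+", "-"), 1L)
        word <- if (orient == "+") hx else reverse_complement(hx)
        substr(seqs[i], off, off + nchar(hx) - 1L) <- word
        planted <- rbind(planted, data.frame(
          gene_id = gene_ids[i], hexamer = hx, offset = off,
          orient = orient, stringsAsFactors = FALSE))
      }
    }
  }

  # genome assembly: genes alternate between two chromosomes and strands
  body_len <- 60L
  spacer <- 50L
  chrom_of <- rep(c("chr1", "chr2"), length.out = n)
  strand_of <- rep(c("+", "-"), length.out = n)
  cursor <- c(chr1 = 0L, chr2 = 0L)
  pieces <- list(chr1 = list(), chr2 = list())
  p_start <- p_end <- g_start <- g_end <- integer(n)
  for (i in seq_len(n)) {
    ch <- chrom_of[i]
    cur <- cursor[[ch]]
    sp <- .rand_seq(spacer, cfg$gc_content)
    if (strand_of[i] == "+") {
      # spacer | promoter (forward) | TSS = promoter 3' end | body
      p_start[i] <- cur + spacer + 1L
      p_end[i] <- p_start[i] + L - 1L
      g_start[i] <- p_end[i]              # TSS base
      g_end[i] <- g_start[i] + body_len - 1L
      piece <- paste0(sp, seqs[i], .rand_seq(body_len - 1L, cfg$gc_content))
    } else {
      # spacer | body | TSS = gene 3' end in genome coords | promoter (revcomp)
      g_start[i] <- cur + spacer + 1L
      g_end[i] <- g_start[i] + body_len - 1L
      p_start[i] <- g_end[i]              # TSS base
      p_end[i] <- p_start[i] + L - 1L
      piece <- paste0(sp, .rand_seq(body_len - 1L, cfg$gc_content),
                      reverse_complement(seqs[i]))
    }
    pieces[[ch]][[length(pieces[[ch]]) + 1L]] <- piece
    cursor[[ch]] <- max(p_end[i], g_end[i])
  }
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(unlist(pieces$chr1), collapse = ""),
    chr2 = paste(unlist(pieces$chr2), collapse = "")
  ))

  promoters <- promoter_set(gene_id = gene_ids, seq = seqs,
                            chrom = chrom_of, strand = strand_of,
                            start = p_start, end = p_end)
  models <- GenomicRanges::GRanges(
    seqnames = chrom_of,
    ranges = IRanges::IRanges(start = g_start, end = g_end),
    strand = strand_of
  )
  models$type <- "gene"
  models$ID <- gene_ids
  GenomeInfoDb::seqlengths(models) <-
    Biostrings::width(genome)[match(GenomeInfoDb::seqlevels(models),
                                    names(genome))]

  # planted instance genomic coordinates
  if (nrow(planted) > 0L) {
    gi <- match(planted$gene_id, gene_ids)
    plus <- strand_of[gi] == "+"
    w <- nchar(planted$hexamer)
    planted$g_start <- ifelse(plus, p_start[gi] + planted$offset - 1L,
                              p_end[gi] - planted$offset - w + 2L)
    planted$g_end <- planted$g_start + w - 1L
    planted$chrom <- chrom_of[gi]
  }

  # peaks
  peaks <- NULL
  if (!is.null(cfg$peak_cfg)) {
    pc <- cfg$peak_cfg
    wdt <- as.integer(pc$width)
    n_pk <- as.integer(pc$n_peaks)
    n_cent <- min(as.integer(round((pc$frac_planted %||% 0) * n_pk)),
                  if (nrow(planted)) nrow(planted) else 0L)
    centers <- integer(0L); pk_chrom <- character(0L)
    if (n_cent > 0L) {
      sel <- sample.int(nrow(planted), n_cent)
      centers <- as.integer((planted$g_start[sel] + planted$g_end[sel]) %/% 2)
      pk_chrom <- planted$chrom[sel]
    }
    n_rand <- n_pk - n_cent
    if (n_rand > 0L) {
      rc_chrom <- sample(names(genome), n_rand, replace = TRUE)
      clen <- Biostrings::width(genome)[match(rc_chrom, names(genome))]
      rc_center <- as.integer(floor(stats::runif(n_rand) *
                                      (clen - wdt)) + wdt %/% 2 + 1L)
      centers <- c(centers, rc_center)
      pk_chrom <- c(pk_chrom, rc_chrom)
    }
    pk_start <- pmax(1L, centers - wdt %/% 2L)
    peaks <- GenomicRanges::GRanges(
      seqnames = pk_chrom,
      ranges = IRanges::IRanges(start = pk_start, width = wdt)
    )
    GenomeInfoDb::seqlengths(peaks) <-
      Biostrings::width(genome)[match(GenomeInfoDb::seqlevels(peaks),
                                      names(genome))]
    peaks <- GenomicRanges::trim(peaks)
  }

  # chromatin-state intervals in genomic coordinates
  states <- NULL
  if (!is.null(blocks)) {
    gi <- match(blocks$gene_id, gene_ids)
    plus <- strand_of[gi] == "+"
    st_start <- ifelse(plus, p_start[gi] + blocks$start - 1L,
                       p_end[gi] - blocks$end + 1L)
    st_end <- ifelse(plus, p_start[gi] + blocks$end - 1L,
                     p_end[gi] - blocks$start + 1L)
    states <- GenomicRanges::GRanges(
      seqnames = chrom_of[gi],
      ranges = IRanges::IRanges(start = st_start, end = st_end),
      name = blocks$state
    )
  }

  datasets <- lapply(seq_len(cfg$n_datasets), function(d) {
    dataset_deg(colnames(status_mat)[d],
                structure(status_mat[, d], names = gene_ids),
                universe = gene_ids,
                timepoint_h = cfg$timepoints_h[d])
  })

  sim <- list(genome = genome, promoters = promoters, models = models,
              datasets = datasets, peaks = peaks, states = states,
              truth = list(latent = structure(latent, names = gene_ids),
                           status = status_mat, planted = planted,
                           blocks = blocks),
              cfg = cfg)
  if (!is.null(dir)) write_cohort(sim, dir)
  sim
}

#' Write a synthetic cohort to standard-format files
#'
#' Emits `genome.fa`, `promoters.fa`, `models.gff3`, per-dataset DEG TSVs
#' plus `manifest.tsv`, `peaks.bed` / `states.bed` when present,
#' `truth_status.tsv` / `truth_planted.tsv`, and the configuration echo
#' `config.json`.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_promoters_fasta(sim$promoters, file.path(dir, "promoters.fa"))
  rtracklayer::export(sim$models, file.path(dir, "models.gff3"),
                      format = "gff3")
  man <- data.frame(dataset_id = character(0L), path = character(0L),
                    timepoint_h = numeric(0L))
  for (ds in sim$datasets) {
    f <- paste0("deg_", ds$dataset_id, ".tsv")
    utils::write.table(
      data.frame(gene_id = names(ds$status), status = unname(ds$status)),
      file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    man <- rbind(man, data.frame(dataset_id = ds$dataset_id, path = f,
                                 timepoint_h = ds$timepoint_h))
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$peaks)) {
    rtracklayer::export(sim$peaks, file.path(dir, "peaks.bed"),
                        format = "bed")
  }
  if (!is.null(sim$states)) {
    rtracklayer::export(sim$states, file.path(dir, "states.bed"),
                        format = "bed")
  }
  utils::write.table(
    data.frame(gene_id = rownames(sim$truth$status),
               latent = unname(sim$truth$latent), sim$truth$status),
    file.path(dir, "truth_status.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sim$truth$planted, file.path(dir, "truth_planted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$cfg
  cfg$planted_motifs <- if (is.null(cfg$planted_motifs)) NULL else
    as.list(cfg$planted_motifs)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Expected probability that a promoter contains a hexamer
#'
#' Analytic check for the generator: the chance a window of the given
#' length contains the canonical hexamer at least once, combining the
#' planting probability with the background occurrence rate under an
#' i.i.d. base-composition model. The background term uses the
#' independent-windows approximation `1 - (1 - q)^(window_len - 5)`, where
#' `q` is the per-window probability of matching either member of the
#' canonical pair (one member for palindromes).
#'
#' @param p_plant Probability an instance was planted.
#' @param window_len Promoter length in bp.
#' @param hexamer The hexamer (canonicalised).
#' @param gc GC fraction of the composition model.
#' @return Expected presence probability.
#' @export
expected_presence_rate <- function(p_plant, window_len, hexamer, gc = 0.5) {
  h <- canonicalize(hexamer)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  word_p <- function(w) prod(base_p[strsplit(w, "")[[1L]]])
  q <- word_p(h)
  if (!is_palindrome(h)) q <- q + word_p(reverse_complement(h))
  n_win <- max(window_len - HEX_K + 1L, 0L)
  1 - (1 - p_plant) * (1 - q)^n_win
}
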