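# Positional occupancy enrichment in peaks and chromatin-state segments.

test_that("occupancy sums position counts over sequences", {
  expect_equal(occupancy("AAAAAAA", "AAAAAA"),
               c(occupied = 2L, total = 2L))
  expect_equal(occupancy(c("TGTCTCT", "CCCCCCC"), "GAGACA"),
               c(occupied = 1L, total = 4L))
  expect_equal(occupancy(character(0), "AAAAAA"),
               c(occupied = 0L, total = 0L))
  # agrees with scan_sequence totals on random sequences
  set.seed(81)
  seqs <- vapply(1:5, function(i) rand_dna(60), character(1))
  for (h in c("AAAAAA", "ACGTAC", "CACGTG")) {
    per_seq <- vapply(seqs, function(s) {
      pc <- scan_sequence(s)$position_counts
      if (h %in% names(pc)) unname(pc[h]) else 0L
    }, integer(1))
    expect_equal(unname(occupancy(seqs, h)["occupied"]), sum(per_seq))
  }
})

test_that("enrichment_test compares two occupancy proportions one-sidedly", {
  expect_equal(enrichment_test(c(2, 2), c(0, 2)), 1 / 6, tolerance = 1e-12)
  expect_gte(enrichment_test(c(3, 10), c(3, 10)), 0.5)
  expect_equal(enrichment_test(c(0, 50), c(10, 50)), 1.0)
  expect_error(enrichment_test(c(0, 0), c(1, 2)), "zero total")
  # swapped foreground/background: at most one direction is < 0.5
  set.seed(82)
  for (r in 1:10) {
    fg <- c(rbinom(1, 40, 0.3), 40)
    bg <- c(rbinom(1, 60, 0.3), 60)
    p1 <- enrichment_test(fg, bg)
    p2 <- enrichment_test(bg, fg)
    expect_false(p1 < 0.5 && p2 < 0.5)
  }
})

test_that("peak_enrichment flags a hexamer planted under the peaks", {
  sim <- simulate_cohort(sim_config(
    n_genes = 250, window_len = 300, n_datasets = 3,
    planted_motifs = data.frame(hexamer = "TGTCTC", target_status = "up",
                                p_fg = 0.9, p_bg = 0.05),
    peak_cfg = list(n_peaks = 60, width = 80, frac_planted = 0.9),
    seed = 83))
  res <- peak_enrichment(sim$peaks, sim$genome, sim$promoters)
  expect_equal(nrow(res), 2080L)
  hit <- res[res$hexamer == "GAGACA", ]
  expect_true(hit$significant)
  expect_true(all(res$fwer_p >= res$p))
  expect_true(all(res$occupied_fg <= res$total_fg))
})

test_that("a single 6-bp peak equal to a hexamer gives occupancy 1 of 1", {
  genome <- Biostrings::DNAStringSet(c(chr = "AATGTCTCAA"))
  peak <- GenomicRanges::GRanges("chr", IRanges::IRanges(3, 8))
  res <- peak_enrichment(peak, genome, c(g1 = rand_dna(50)),
                         hexamers = "TGTCTC")
  expect_equal(res$occupied_fg, 1L)
  expect_equal(res$total_fg, 1L)
})

test_that("overlapping peaks are merged before counting", {
  genome <- Biostrings::DNAStringSet(c(chr = strrep("A", 40)))
  peaks <- GenomicRanges::GRanges("chr", IRanges::IRanges(c(1, 5), c(10, 14)))
  res <- peak_enrichment(peaks, genome, c(g1 = rand_dna(50)),
                         hexamers = "AAAAAA")
  # merged [1,14]: 9 windows, not 5 + 5 from double counting
  expect_equal(res$total_fg, 9L)
  expect_equal(res$occupied_fg, 9L)
})

test_that("state_segments partitions promoters and preserves orientation", {
  set.seed(84)
  sim <- simulate_cohort(sim_config(
    n_genes = 40, window_len = 200, n_datasets = 2,
    state_cfg = list(mean_block = 60,
                     state_freq = c(`1` = 0.3, `4` = 0.4, `5` = 0.3)),
    seed = 85))
  segs <- state_segments(sim$promoters, sim$states)
  # conservation: per-gene segment lengths sum to the window coverage
  cov <- tapply(nchar(segs$seq), segs$gene_id, sum)
  expect_true(all(cov == sim$cfg$window_len))
  # segment sequences equal the promoter substrings they claim (both strands)
  for (i in sample(nrow(segs), 20)) {
    g <- sim$promoters[sim$promoters$gene_id == segs$gene_id[i], ]
    if (g$strand == "+") {
      rel <- c(segs$start[i] - g$start + 1, segs$end[i] - g$start + 1)
    } else {
      rel <- c(g$end - segs$end[i] + 1, g$end - segs$start[i] + 1)
    }
    expect_equal(segs$seq[i], substr(g$seq, rel[1], rel[2]))
  }
  # ground truth: emitted blocks match recovered segments per gene/state
  expect_equal(sum(nchar(segs$seq)),
               sum(sim$truth$blocks$end - sim$truth$blocks$start + 1))
})

test_that("promoters outside the state map yield no segments", {
  pr <- promoter_set("lone", rand_dna(50), chrom = "chrZ", strand = "+",
                     start = 10L, end = 59L)
  states <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(500, 600),
                                   name = "1")
  segs <- state_segments(pr, states)
  expect_equal(nrow(segs), 0L)
  sp <- state_presence(segs, "lone", states = "1")
  expect_false(any(sp))
})

test_that("state_association finds a state linked to up-regulation", {
  set.seed(86)
  n <- 500
  genes <- sprintf("g%03d", 1:n)
  up <- sample(genes, 80)
  # state 4 covers most up-gene promoters, few others; states 1-3 random
  sp <- cbind(
    `1` = runif(n) < 0.5, `2` = runif(n) < 0.5, `3` = runif(n) < 0.5,
    `4` = runif(n) < ifelse(genes %in% up, 0.9, 0.2)
  )
  rownames(sp) <- genes
  st <- structure(rep("up", length(up)), names = up)
  ds <- tiny_datasets(list(st, st, st), genes)
  res <- state_association(ds, sp, M = 100, rng_seed = 11)
  a4 <- res$association[res$association$hexamer == "4" &
                          res$association$status == "up", ]
  expect_true(a4$selected)
  p4 <- res$permutation[res$permutation$hexamer == "4" &
                          res$permutation$status == "up", ]
  expect_equal(p4$m, 0L)
  # a single state covering everything has no contrast: meta p = 1
  sp_all <- matrix(TRUE, n, 1, dimnames = list(genes, "9"))
  res_all <- run_association(sp_all, ds, n_tests = 2)
  expect_true(all(res_all$meta_p == 1))
})

test_that("state_hexamer_enrichment detects composition bias genome-wide", {
  sim <- simulate_cohort(sim_config(
    n_genes = 150, window_len = 400, n_datasets = 2,
    state_cfg = list(mean_block = 100,
                     state_freq = c(`2` = 0.5, `4` = 0.5),
                     state_gc = c(`2` = 0.5, `4` = 0.1)),
    seed = 87))
  segs <- state_segments(sim$promoters, sim$states)
  res <- state_hexamer_enrichment(c("AAAAAA", "ATATAT", "GCGCGC"), "4",
                                  segs, sim$promoters, mode = "genomewide")
  expect_true(all(res$significant[res$hexamer %in% c("AAAAAA", "ATATAT")]))
  expect_false(res$significant[res$hexamer == "GCGCGC"])
})

test_that("responsive-vs-control mode compares positive and control segments", {
  set.seed(88)
  # two genes' segments of one state; the positive gene's segment is AT-rich
  segs <- data.frame(
    gene_id = c("gpos", "gctl"), state = "4", chrom = "chr1",
    start = c(1L, 101L), end = c(80L, 180L),
    seq = c(paste0(strrep("AT", 30), rand_dna(20)), rand_dna(80)),
    stringsAsFactors = FALSE)
  sets <- structure(list(control = "gctl", positive = "gpos"),
                    class = "GeneSets")
  res <- state_hexamer_enrichment("ATATAT", "4", segs,
                                  promoter_bg = character(0),
                                  mode = "responsive_vs_control",
                                  sets = sets, n_tests = 1)
  expect_lt(res$p, 0.05)
  expect_false(res$degenerate)
  # identical density on both sides is not significant
  segs$seq <- c(segs$seq[2], segs$seq[2])
  res2 <- state_hexamer_enrichment("ATATAT", "4", segs,
                                   promoter_bg = character(0),
                                   mode = "responsive_vs_control",
                                   sets = sets, n_tests = 1)
  expect_false(res2$significant)
  # hexamer absent from both sides gives p = 1
  res3 <- state_hexamer_enrichment("GGGGGG", "4", segs,
                                   promoter_bg = character(0),
                                   mode = "responsive_vs_control",
                                   sets = sets, n_tests = 1)
  expect_equal(res3$p, 1)
})
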