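# Promoter extraction, DEG tables, gene universes and derived gene sets.

test_that("extract_promoters anchors windows at the TSS on either strand", {
  set.seed(51)
  chr <- rand_dna(3000)
  genome <- Biostrings::DNAStringSet(c(toy = chr))
  models <- GenomicRanges::GRanges(
    seqnames = "toy",
    ranges = IRanges::IRanges(start = c(2000, 50, 10), end = c(2200, 100, 40)),
    strand = c("+", "-", "+")
  )
  models$type <- "gene"
  models$ID <- c("plus", "minus", "edge")
  pr <- extract_promoters(genome, models, window_len = 1501L)
  # + strand: [TSS - 1500, TSS], forward sequence
  p <- pr[pr$gene_id == "plus", ]
  expect_equal(c(p$start, p$end), c(500L, 2000L))
  expect_equal(p$seq, substr(chr, 500, 2000))
  expect_false(p$truncated)
  # - strand: TSS at gene end; mirrored window, reverse complement
  m <- pr[pr$gene_id == "minus", ]
  expect_equal(c(m$start, m$end), c(100L, 1600L))
  expect_equal(m$seq, reverse_complement(substr(chr, 100, 1600)))
  # truncation at the chromosome start, flagged
  e <- pr[pr$gene_id == "edge", ]
  expect_equal(c(e$start, e$end), c(1L, 10L))
  expect_true(e$truncated)
  expect_equal(nchar(e$seq), 10L)
})

test_that("extraction is consistent under genome reverse complementation", {
  set.seed(52)
  chr <- rand_dna(800)
  genome <- Biostrings::DNAStringSet(c(c1 = chr))
  models <- GenomicRanges::GRanges("c1", IRanges::IRanges(500, 600), "+")
  models$type <- "gene"; models$ID <- "g"
  # same gene described on the flipped genome with flipped strand/coords
  genome_rc <- Biostrings::DNAStringSet(c(c1 = reverse_complement(chr)))
  models_rc <- GenomicRanges::GRanges("c1", IRanges::IRanges(800 - 600 + 1, 800 - 500 + 1), "-")
  models_rc$type <- "gene"; models_rc$ID <- "g"
  a <- extract_promoters(genome, models, window_len = 101L)
  b <- extract_promoters(genome_rc, models_rc, window_len = 101L)
  expect_equal(a$seq, b$seq)
})

test_that("promoter FASTA round-trip preserves records", {
  set.seed(53)
  pr <- promoter_set(gene_id = c("gA", "gB"),
                     seq = c(rand_dna(40), rand_dna(40)),
                     chrom = c("chr1", "chr2"), strand = c("+", "-"),
                     start = c(10L, 99L), end = c(49L, 138L))
  f <- tempfile(fileext = ".fa")
  write_promoters_fasta(pr, f)
  back <- read_promoters_fasta(f)
  expect_equal(back$gene_id, pr$gene_id)
  expect_equal(back$seq, pr$seq)
  expect_equal(back$chrom, pr$chrom)
  expect_equal(back$start, pr$start)
  expect_equal(back$end, pr$end)
  expect_equal(back$strand, pr$strand)
})

test_that("by_adjust reproduces hand-computed Benjamini–Yekutieli values", {
  expect_equal(by_adjust(0.5), 0.5)
  # n = 2, c(2) = 1.5: 0.01*2*1.5/1 = 0.03, 0.04*2*1.5/2 = 0.06
  expect_equal(by_adjust(c(0.01, 0.04)), c(0.03, 0.06))
  expect_equal(by_adjust(c(0.04, 0.01)), c(0.06, 0.03))
  expect_error(by_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone along sorted inputs, bounded by 1
  set.seed(54)
  p <- sort(runif(50))
  adj <- by_adjust(p)
  expect_false(is.unsorted(adj))
  expect_true(all(adj <= 1))
})

test_that("call_degs applies the FDR and fold-change thresholds", {
  lfc <- c(g1 = 1, g2 = 1, g3 = -1, g4 = 0.2, g5 = -0.2)
  adj <- c(g1 = 0.01, g2 = 0.2, g3 = 0.001, g4 = 0.001, g5 = 0.001)
  st <- call_degs(lfc, adj)
  expect_equal(unname(st[c("g1", "g2", "g3")]), c("up", "none", "down"))
  # |fold change| inside (2/3, 3/2) is never a DEG however small the p
  expect_equal(unname(st[c("g4", "g5")]), c("none", "none"))
  expect_error(call_degs(lfc, adj[-1]), "same genes")
})

test_that("read_deg_table validates statuses, universe and duplicates", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tstatus", "g1\tup", "g2\tdown", "g3\tnone"), f)
  ds <- read_deg_table(f, universe = c("g1", "g2", "g3", "g4"),
                       dataset_id = "t", timepoint_h = 2)
  expect_equal(deg_genes(ds, "up"), "g1")
  expect_equal(deg_genes(ds, "down"), "g2")
  expect_equal(sort(deg_genes(ds, "none")), c("g3", "g4"))
  expect_equal(n_degs(ds), 2L)
  # row outside the universe dropped with a warning
  writeLines(c("gene_id\tstatus", "g1\tup", "gX\tdown"), f)
  expect_warning(ds2 <- read_deg_table(f, universe = c("g1", "g2")),
                 "outside the universe")
  expect_equal(n_degs(ds2), 1L)
  # conflicting duplicate is an error; agreeing duplicate is not
  writeLines(c("gene_id\tstatus", "g1\tup", "g1\tdown"), f)
  expect_error(read_deg_table(f, universe = "g1"), "conflicting")
  writeLines(c("gene_id\tstatus", "g1\tbanana"), f)
  expect_error(read_deg_table(f, universe = "g1"), "unknown status")
  # empty table with an explicit universe is valid
  writeLines("gene_id\tstatus", f)
  ds3 <- read_deg_table(f, universe = c("g1", "g2"))
  expect_equal(n_degs(ds3), 0L)
})

test_that("filter_datasets keeps data sets with at least min_degs DEGs", {
  universe <- sprintf("g%02d", 1:40)
  mk <- function(n_up) {
    structure(rep("up", n_up), names = universe[seq_len(n_up)])
  }
  ds <- tiny_datasets(list(mk(9), mk(10), mk(11)), universe)
  kept <- filter_datasets(ds, min_degs = 10)
  expect_equal(vapply(kept, `[[`, character(1), "dataset_id"),
               c("ds2", "ds3"))
  expect_equal(filter_datasets(list(), 10), list())
})

test_that("control and positive gene sets follow the never-DE / >=3-hits rules", {
  universe <- c("a", "b", "c", "d", "e")
  st <- list(
    c(a = "up", b = "up"),
    c(a = "down", c = "up"),
    c(a = "up"),
    c(b = "down")
  )
  gs <- build_gene_sets(tiny_datasets(st, universe), min_hits = 3)
  expect_equal(gs$positive, "a")            # DE in 3 of 4
  expect_equal(gs$control, c("d", "e"))     # never DE anywhere
  # b (2 hits) and c (1 hit) are in neither set
  expect_false(any(c("b", "c") %in% c(gs$control, gs$positive)))
  expect_length(intersect(gs$control, gs$positive), 0L)
})

test_that("control/positive disjointness holds on random synthetic cohorts", {
  set.seed(55)
  for (r in 1:5) {
    sim <- simulate_cohort(sim_config(n_genes = 120, window_len = 30,
                                      n_datasets = 4, seed = 60 + r))
    gs <- build_gene_sets(sim$datasets)
    expect_length(intersect(gs$control, gs$positive), 0L)
    expect_true(all(vapply(sim$datasets, function(d)
      all(gs$control %in% deg_genes(d, "none")), logical(1))))
  }
})
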