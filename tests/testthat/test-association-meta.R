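# Contingency construction, one-sided Fisher exact tests, Fisher's-method
# combination and the Bonferroni meta screen.

test_that("contingency performs the set arithmetic over the universe", {
  t1 <- contingency(c("g1", "g2"), c("g2", "g3"), paste0("g", 1:4))
  expect_equal(unname(t1), c(1L, 1L, 1L, 1L))
  expect_equal(sum(t1), 4L)
  t2 <- contingency(character(0), c("g1"), paste0("g", 1:4))
  expect_equal(unname(t2[c("a", "b")]), c(0L, 0L))
  u <- paste0("g", 1:6)
  t3 <- contingency(u, u, u)
  expect_equal(unname(t3), c(6L, 0L, 0L, 0L))
  expect_error(contingency("gX", "g1", "g1"), "universe")
})

test_that("fisher_one_sided gives exact upper-tail hypergeometric probabilities", {
  expect_equal(fisher_one_sided(0, 10, 10, 80), 1.0)
  expect_equal(fisher_one_sided(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(fisher_one_sided(5, 5, 5, 85), hyper_tail_brute(5, 5, 5, 85),
               tolerance = 1e-12)
  expect_equal(fisher_one_sided(0, 0, 0, 0), 1.0)
  # agrees with fisher.test's one-sided greater alternative
  tab <- matrix(c(7, 3, 12, 38), nrow = 2, byrow = TRUE)
  expect_equal(fisher_one_sided(7, 3, 12, 38),
               fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_error(fisher_one_sided(-1, 1, 1, 1), "negative")
})

test_that("fisher_method combines p-values into a 2k-dof chi-squared tail", {
  r1 <- fisher_method(c(1, 1))
  expect_equal(r1$chi2, 0)
  expect_equal(r1$dof, 4L)
  expect_equal(r1$meta_p, 1)
  # k = 1 is the identity: the dof-2 survival function is exp(-chi2/2)
  r2 <- fisher_method(0.05)
  expect_equal(r2$chi2, -2 * log(0.05), tolerance = 1e-12)
  expect_equal(r2$meta_p, 0.05, tolerance = 1e-12)
  r3 <- fisher_method(c(0.05, 0.05))
  expect_equal(r3$meta_p, chisq_tail_even(r3$chi2, 4), tolerance = 1e-12)
  expect_equal(r3$meta_p, 0.01747866, tolerance = 1e-6)
  expect_warning(r4 <- fisher_method(c(0.5, 0)), "clamped")
  expect_true(r4$meta_p > 0)
  expect_error(fisher_method(c(0.5, 1.1)), "\\[0, 1\\]")
})

test_that("fisher_method is monotone: lowering any p never raises meta p", {
  set.seed(61)
  for (r in 1:20) {
    p <- runif(sample(2:6, 1), min = 0.01)
    i <- sample(length(p), 1)
    q <- p
    q[i] <- p[i] * runif(1)
    expect_lte(fisher_method(q)$meta_p, fisher_method(p)$meta_p)
  }
})

test_that("bonferroni multiplies and caps at one", {
  expect_equal(bonferroni(0.001, 2080), 1.0)
  expect_equal(bonferroni(1e-6, 2080), 2.08e-3)
  expect_equal(bonferroni(0.5, 1), 0.5)
  expect_error(bonferroni(0.5, 0), ">= 1")
})

test_that("run_association recovers a strongly associated hexamer and respects identities", {
  set.seed(62)
  n <- 600
  genes <- sprintf("g%03d", 1:n)
  up <- sample(genes, 60)
  hex <- "GAGACA"
  canon <- enumerate_canonical()$hexamer
  pres <- matrix(FALSE, n, length(canon), dimnames = list(genes, canon))
  # hexamer present in 90% of up-genes, 10% of background
  p_in <- ifelse(genes %in% up, 0.9, 0.1)
  pres[, hex] <- runif(n) < p_in
  pres[, "ACACAC"] <- runif(n) < 0.3   # an unassociated hexamer
  st <- structure(rep("up", length(up)), names = up)
  ds <- tiny_datasets(list(st, st, st), genes)
  res <- run_association(pres, ds)
  hit <- res[res$hexamer == hex & res$status == "up", ]
  expect_true(hit$selected)
  expect_equal(hit$dof, 6L)
  expect_lt(hit$meta_p, 1e-10)
  miss <- res[res$hexamer == "ACACAC" & res$status == "up", ]
  expect_false(miss$selected)
  # chi2 = -2 sum(log p_i) and bonferroni_p >= meta_p everywhere
  expect_true(all(res$bonferroni_p >= res$meta_p))
  expect_true(all(res$dof == 2L * res$k))
  # single data set: meta p equals that data set's Fisher p
  res1 <- run_association(pres, ds[1], statuses = "up")
  tab <- contingency(genes[pres[, hex]], up, genes)
  expect_equal(res1$meta_p[res1$hexamer == hex],
               unname(fisher_one_sided(tab)), tolerance = 1e-12)
})

test_that("all-none statuses give meta p of exactly one", {
  genes <- sprintf("g%02d", 1:30)
  pres <- presence_matrix(structure(
    vapply(1:30, function(i) rand_dna(40), character(1)), names = genes))
  ds <- tiny_datasets(list(structure(character(0), names = character(0))),
                      genes)
  res <- run_association(pres, ds)
  expect_true(all(res$meta_p == 1))
})

test_that("contingency tables inside run_association conserve the universe", {
  set.seed(63)
  genes <- sprintf("g%02d", 1:50)
  pres <- presence_matrix(structure(
    vapply(1:50, function(i) rand_dna(30), character(1)), names = genes))
  up <- sample(genes, 10)
  ds <- tiny_datasets(list(structure(rep("up", 10), names = up)), genes)
  res <- run_association(pres, ds, statuses = "up")
  # recompute one hexamer's table explicitly: cells must sum to |universe|
  for (h in sample(colnames(pres), 5)) {
    tab <- contingency(genes[pres[, h]], up, genes)
    expect_equal(sum(tab), 50L)
    expect_equal(res$meta_p[res$hexamer == h],
                 unname(fisher_one_sided(tab)), tolerance = 1e-12)
  }
})

test_that("meta p-values are calibrated under a null with independent statuses", {
  # statuses drawn independently of sequence and independently across data
  # sets (deg_overlap = 0) so the chi-squared null of the combination holds.
  # Exact conditional tests are discrete, hence conservative: the rejection
  # fraction must never exceed alpha beyond Monte Carlo tolerance (the
  # direction that matters for error control) and must stay within a factor
  # of a few below it. Presence correlations between overlapping hexamers
  # make the effective number of independent tests smaller than the row
  # count, hence the extra allowance above 3 binomial SEs.
  sim <- simulate_cohort(sim_config(n_genes = 800, window_len = 300,
                                    n_datasets = 3, deg_overlap = 0,
                                    seed = 64))
  res <- run_association(presence_matrix(sim$promoters), sim$datasets)
  alpha <- 0.1
  frac <- mean(res$meta_p <= alpha)
  se <- sqrt(alpha * (1 - alpha) / nrow(res))
  expect_lt(frac, alpha + 3 * se + 0.01)
  expect_gt(frac, alpha / 3)
})
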