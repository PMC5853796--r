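# Shared fixtures and independent oracles, built in code at test time.

# Random DNA string (uniform composition unless probs given).
rand_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Brute-force reverse complement via an explicit lookup loop, independent
# of the package's chartr-based implementation.
rc_brute <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# Brute-force double-strand scanner: counts, for a canonical hexamer, the
# start positions on the given sequence where either the hexamer or its
# reverse complement occurs (N-containing windows skipped).
scan_brute <- function(seq, hexamer) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 6) return(0L)
  fwd <- toupper(hexamer)
  rev <- rc_brute(fwd)
  hits <- 0L
  for (s in seq_len(L - 5L)) {
    w <- substr(seq, s, s + 5L)
    if (grepl("N", w, fixed = TRUE)) next
    if (w == fwd || (fwd != rev && w == rev)) hits <- hits + 1L
  }
  hits
}

# Hypergeometric upper-tail oracle from first principles: enumerate the
# tail of P(X >= a) with binomial coefficients only.
hyper_tail_brute <- function(a, b, c, d) {
  k <- a + c                      # responsive draws
  m <- a + b                      # hexamer-present genes
  n <- a + b + c + d
  xs <- a:min(m, k)
  if (a > min(m, k)) return(0)
  sum(choose(m, xs) * choose(n - m, k - xs)) / choose(n, k)
}

# Closed-form upper tail of the chi-squared distribution with even dof:
# exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!  (dof = 2k).
chisq_tail_even <- function(x, dof) {
  k <- dof / 2
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# A small multi-dataset cohort with hand-controllable statuses.
tiny_datasets <- function(status_list, universe, timepoints = NULL) {
  if (is.null(timepoints)) timepoints <- seq_along(status_list)
  lapply(seq_along(status_list), function(i) {
    dataset_deg(paste0("ds", i), status_list[[i]], universe,
                timepoint_h = timepoints[i])
  })
}
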