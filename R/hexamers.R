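# Canonical hexamer algebra and sequence scanning.
#
# Binding of a double-stranded site is strand-symmetric, so a 6-mer and its
# reverse complement are one unit of analysis. The representative of each
# pair is its lexicographic minimum; 4096 hexamers collapse to 2080 canonical
# classes (2016 complementary pairs + 64 palindromes).

HEX_K <- 6L

.hex_env <- new.env(parent = emptyenv())

#' Reverse complement of a nucleotide string
#'
#' Vectorised over `s`. Case is preserved (lowercase is commonly used for
#' repeat-masked bases); `N`/`n` map to themselves.
#'
#' @param s Character vector of sequences over `A,C,G,T,N` (either case).
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("TGTCTC")  # "GAGACA"
#' @export
reverse_complement <- function(s) {
  if (!is.character(s)) stop("`s` must be a character vector")
  bad <- grepl("[^ACGTNacgtn]", s)
  if (any(bad)) {
    stop("non-nucleotide character in sequence(s): ",
         paste(utils::head(s[bad], 3L), collapse = ", "))
  }
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", s)
  vapply(comp, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# All 4096 uppercase hexamers in sorted order (matches the column order of
# Biostrings::oligonucleotideFrequency(width = 6)).
all_hexamers <- function() {
  if (is.null(.hex_env$all4096)) {
    b <- c("A", "C", "G", "T")
    g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
    # expand.grid varies the first factor fastest; build strings so that the
    # first position is the slowest digit, then sort to be explicit.
    h <- do.call(paste0, g[, HEX_K:1L])
    .hex_env$all4096 <- sort(h)
  }
  .hex_env$all4096
}

.canon_map <- function() {
  if (is.null(.hex_env$canon_map)) {
    h <- all_hexamers()
    rc <- reverse_complement(h)
    cm <- ifelse(h <= rc, h, rc)
    names(cm) <- h
    .hex_env$canon_map <- cm
  }
  .hex_env$canon_map
}

#' Canonical representative of a hexamer
#'
#' Returns the lexicographic minimum of the hexamer and its reverse
#' complement, so that both strands map to the same class. Idempotent.
#'
#' @param h Character vector of hexamers (length-6 strings over `A,C,G,T`;
#'   lowercase accepted and uppercased).
#' @return Character vector of canonical hexamers.
#' @examples
#' canonicalize("TGTCTC")  # "GAGACA"
#' @export
canonicalize <- function(h) {
  if (!is.character(h)) stop("`h` must be a character vector")
  h <- toupper(h)
  if (any(nchar(h) != HEX_K) || any(grepl("[^ACGT]", h))) {
    stop("hexamers must be length-6 strings over A,C,G,T")
  }
  unname(.canon_map()[h])
}

#' Is a hexamer its own reverse complement?
#'
#' @param h Character vector of hexamers.
#' @return Logical vector.
#' @export
is_palindrome <- function(h) {
  if (!is.character(h)) stop("`h` must be a character vector")
  h <- toupper(h)
  h == reverse_complement(h)
}

#' Enumerate all canonical hexamers
#'
#' The 4096 hexamers collapse under reverse-complement equivalence to 2080
#' canonical classes: 2016 complementary pairs plus 64 palindromes.
#'
#' @return A data.frame with columns `hexamer` (sorted canonical
#'   representatives) and `is_palindrome`.
#' @examples
#' nrow(enumerate_canonical())  # 2080
#' @export
enumerate_canonical <- function() {
  if (is.null(.hex_env$canonical)) {
    canon <- sort(unique(unname(.canon_map())))
    .hex_env$canonical <- data.frame(
      hexamer = canon,
      is_palindrome = is_palindrome(canon),
      stringsAsFactors = FALSE
    )
  }
  .hex_env$canonical
}

# Apply the masking convention: respect_mask treats lowercase (soft-masked)
# letters as invalid by rewriting them to N; otherwise they are uppercased
# and scanned like ordinary bases. Any window containing N is invalid.
.apply_mask <- function(seqs, respect_mask) {
  if (respect_mask) {
    toupper(chartr("acgt", "NNNN", seqs))
  } else {
    toupper(seqs)
  }
}

# Number of valid (N-free) 6-mer windows in one uppercase sequence.
.valid_windows <- function(seq) {
  L <- nchar(seq)
  if (L < HEX_K) return(0L)
  n_win <- L - HEX_K + 1L
  if (!grepl("N", seq, fixed = TRUE)) return(n_win)
  bad <- as.integer(strsplit(seq, "", fixed = TRUE)[[1L]] == "N")
  cs <- c(0L, cumsum(bad))
  starts <- seq_len(n_win)
  sum(cs[starts + HEX_K] - cs[starts] == 0L)
}

#' Scan one sequence for canonical hexamer occurrences
#'
#' Slides a 6-bp window over every start position. Windows containing `N`
#' (or soft-masked lowercase letters when `respect_mask = TRUE`) are invalid
#' and excluded from both the per-hexamer counts and the total position
#' count, so occupancy proportions stay comparable between masked and
#' unmasked sequences. Overlapping occurrences are all counted.
#'
#' @param seq A single nucleotide string.
#' @param respect_mask Treat lowercase letters as masked (invalid)?
#' @return A list with `presence` (character vector of canonical hexamers
#'   found at least once), `position_counts` (named integer vector over the
#'   found hexamers) and `total_positions` (number of valid windows).
#' @examples
#' scan_sequence("TGTCTCT")$position_counts  # GAGACA = 1 of 2 windows
#' @export
scan_sequence <- function(seq, respect_mask = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("`seq` must be a single string")
  }
  if (grepl("[^ACGTNacgtn]", seq)) stop("non-nucleotide character in `seq`")
  s <- .apply_mask(seq, respect_mask)
  L <- nchar(s)
  if (L < HEX_K) {
    return(list(presence = character(0L),
                position_counts = structure(integer(0L), names = character(0L)),
                total_positions = 0L))
  }
  starts <- seq_len(L - HEX_K + 1L)
  w <- substring(s, starts, starts + HEX_K - 1L)
  valid <- !grepl("N", w, fixed = TRUE)
  counts <- table(.canon_map()[w[valid]])
  pc <- structure(as.integer(counts), names = names(counts))
  if (length(pc)) pc <- pc[order(names(pc))] else names(pc) <- character(0L)
  list(presence = names(pc), position_counts = pc,
       total_positions = sum(valid))
}

#' Per-sequence canonical hexamer occupancy counts
#'
#' Fast bulk scanner used by the presence and occupancy layers: counts, for
#' every canonical hexamer, the occupied start positions in each sequence,
#' and the number of valid windows per sequence. Windows containing `N`
#' (or masked letters under `respect_mask`) are excluded from both.
#'
#' @param seqs Character vector of sequences (names used as row names).
#' @param respect_mask Treat lowercase letters as masked (invalid)?
#' @return A list with `counts` (integer matrix, sequences x 2080 canonical
#'   hexamers) and `total_positions` (integer vector per sequence).
#' @export
hexamer_counts <- function(seqs, respect_mask = FALSE) {
  if (!is.character(seqs)) stop("`seqs` must be a character vector")
  canon <- enumerate_canonical()
  s <- .apply_mask(seqs, respect_mask)
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) stop("non-nucleotide character in sequence(s)")
  dss <- Biostrings::DNAStringSet(s)
  of <- Biostrings::oligonucleotideFrequency(dss, width = HEX_K, step = 1L)
  # Fold the 4096 columns onto canonical classes: class count = count of the
  # representative plus, for non-palindromes, the count of its partner.
  idx_c <- match(canon$hexamer, colnames(of))
  idx_r <- match(reverse_complement(canon$hexamer), colnames(of))
  counts <- of[, idx_c, drop = FALSE]
  np <- !canon$is_palindrome
  counts[, np] <- counts[, np] + of[, idx_r[np], drop = FALSE]
  colnames(counts) <- canon$hexamer
  rownames(counts) <- names(seqs)
  tot <- pmax(nchar(s) - HEX_K + 1L, 0L)
  has_n <- grepl("N", s, fixed = TRUE)
  if (any(has_n)) {
    tot[has_n] <- vapply(s[has_n], .valid_windows, integer(1L),
                         USE.NAMES = FALSE)
  }
  names(tot) <- names(seqs)
  list(counts = counts, total_positions = tot)
}

#' Hexamer presence matrix over a promoter set
#'
#' One row per gene, one column per canonical hexamer; `TRUE` where the
#' hexamer occurs at least once in the gene's upstream window. This
#' gene-level presence indicator is the unit feature of the association
#' analysis.
#'
#' @param promoters A `promoter_set` (see [extract_promoters()]) or a named
#'   character vector of promoter sequences (names = gene ids).
#' @param respect_mask Treat lowercase letters as masked (invalid)?
#' @return Logical matrix genes x 2080 with gene ids as row names.
#' @export
presence_matrix <- function(promoters, respect_mask = FALSE) {
  seqs <- promoter_seqs(promoters)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("promoter sequences must be named by gene id")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate gene id in promoters")
  hc <- hexamer_counts(seqs, respect_mask = respect_mask)
  hc$counts > 0L
}

# Coerce the accepted promoter representations to a named sequence vector.
promoter_seqs <- function(promoters) {
  if (is.character(promoters)) return(promoters)
  if (is.data.frame(promoters) &&
      all(c("gene_id", "seq") %in% names(promoters))) {
    return(structure(promoters$seq, names = promoters$gene_id))
  }
  stop("`promoters` must be a promoter_set or a named character vector")
}
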