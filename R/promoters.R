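# TSS-anchored upstream windows ("promoters") and their FASTA round-trip.
#
# A promoter here is the [-1500; +1] window relative to the transcription
# start site: a window_len-bp stretch whose 3'-most base is the TSS base,
# reported 5'->3' on the gene's own strand. window_len is a parameter
# (default 1501) because the bracket notation is ambiguous about whether
# the "+1" base adds one transcribed position.

#' Build a promoter set
#'
#' @param gene_id Character vector of unique gene ids.
#' @param seq Character vector of promoter sequences, 5'->3' on the gene's
#'   strand.
#' @param chrom,strand,start,end Optional genomic coordinates of the window
#'   (1-based inclusive, forward-strand coordinates). Needed only for the
#'   interval-based analyses (peaks, chromatin states).
#' @param truncated Logical; window clipped at a chromosome edge?
#' @return A `promoter_set` data.frame.
#' @export
promoter_set <- function(gene_id, seq, chrom = NA_character_,
                         strand = NA_character_, start = NA_integer_,
                         end = NA_integer_, truncated = FALSE) {
  if (anyDuplicated(gene_id)) stop("duplicate gene id")
  if (length(seq) != length(gene_id)) stop("gene_id/seq length mismatch")
  out <- data.frame(
    gene_id = as.character(gene_id), chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(end),
    truncated = truncated, seq = as.character(seq),
    stringsAsFactors = FALSE
  )
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Extract TSS-anchored upstream windows from a genome and gene models
#'
#' For a plus-strand gene with TSS at position `t`, the window is the
#' 1-based inclusive interval `[t - window_len + 1, t]` on the forward
#' strand. For a minus-strand gene the mirrored interval `[t, t +
#' window_len - 1]` is taken and reverse-complemented, so the returned
#' sequence always reads 5'->3' towards the TSS on the gene's strand.
#' Windows running off a chromosome edge are truncated and flagged.
#'
#' @param genome A `DNAStringSet` or path to a FASTA file.
#' @param models A `GRanges` of gene models or path to a GFF3 file (records
#'   with `type == "gene"` are used; TSS = 5' end on the gene's strand).
#' @param window_len Window length in bp (default 1501, i.e. 1500 upstream
#'   bases plus the TSS base).
#' @return A `promoter_set` with genomic coordinates.
#' @export
extract_promoters <- function(genome, models, window_len = 1501L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(models)) models <- rtracklayer::import(models)
  if (!methods::is(models, "GRanges")) stop("`models` must be a GRanges or GFF3 path")
  if (!is.null(models$type) && any(models$type == "gene")) {
    models <- models[models$type == "gene"]
  }
  names(genome) <- sub("\\s.*", "", names(genome))
  ids <- models$ID
  if (is.null(ids)) ids <- models$gene_id
  if (is.null(ids)) ids <- names(models)
  if (is.null(ids) || any(is.na(ids))) stop("gene models must carry gene ids")
  if (anyDuplicated(ids)) stop("duplicate gene id in models")
  str <- as.character(GenomicRanges::strand(models))
  if (any(str == "*")) stop("gene model without strand")
  chrom <- as.character(GenomicRanges::seqnames(models))
  present <- chrom %in% names(genome)
  if (!all(present)) {
    warning(sum(!present), " gene(s) on chromosomes absent from the genome; skipped")
    models <- models[present]; ids <- ids[present]
    str <- str[present]; chrom <- chrom[present]
  }
  clen <- Biostrings::width(genome)[match(chrom, names(genome))]
  tss <- ifelse(str == "+", GenomicRanges::start(models),
                GenomicRanges::end(models))
  w_start <- ifelse(str == "+", tss - window_len + 1L, tss)
  w_end <- ifelse(str == "+", tss, tss + window_len - 1L)
  t_start <- pmax(w_start, 1L)
  t_end <- pmin(w_end, clen)
  truncated <- t_start != w_start | t_end != w_end
  seqs <- as.character(Biostrings::subseq(genome[chrom],
                                          start = t_start, end = t_end))
  minus <- str == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  promoter_set(gene_id = ids, seq = unname(seqs), chrom = chrom,
               strand = str, start = as.integer(t_start),
               end = as.integer(t_end), truncated = truncated)
}

#' Write a promoter set to FASTA
#'
#' The description line is `gene_id chrom:start-end(strand)` so the genomic
#' window survives a round-trip; coordinates are omitted when absent.
#'
#' @param promoters A `promoter_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  dss <- Biostrings::DNAStringSet(promoters$seq)
  coord <- ifelse(
    is.na(promoters$chrom), "",
    paste0(" ", promoters$chrom, ":", promoters$start, "-", promoters$end,
           "(", promoters$strand, ")")
  )
  names(dss) <- paste0(promoters$gene_id, coord)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a promoter set from FASTA
#'
#' The gene id is the first whitespace-separated token of the description
#' line; a second token of the form `chrom:start-end(strand)` (as written by
#' [write_promoters_fasta()]) restores genomic coordinates.
#'
#' @param path FASTA path.
#' @return A `promoter_set`.
#' @export
read_promoters_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  desc <- names(dss)
  id <- sub("\\s.*", "", desc)
  rest <- ifelse(grepl("\\s", desc), sub("^\\S+\\s+", "", desc), "")
  m <- regmatches(rest, regexec("^(\\S+):(\\d+)-(\\d+)\\(([+-])\\)", rest))
  has <- lengths(m) == 5L
  chrom <- ifelse(has, vapply(m, function(x) if (length(x)) x[2L] else NA_character_,
                              character(1L)), NA_character_)
  start <- ifelse(has, as.integer(vapply(m, function(x) if (length(x)) x[3L] else NA_character_,
                                         character(1L))), NA_integer_)
  end <- ifelse(has, as.integer(vapply(m, function(x) if (length(x)) x[4L] else NA_character_,
                                       character(1L))), NA_integer_)
  strand <- ifelse(has, vapply(m, function(x) if (length(x)) x[5L] else NA_character_,
                               character(1L)), NA_character_)
  promoter_set(gene_id = id, seq = as.character(dss), chrom = chrom,
               strand = strand, start = start, end = end)
}

# GRanges view of the promoter windows (needed by the interval analyses).
promoters_granges <- function(promoters) {
  if (any(is.na(promoters$chrom) | is.na(promoters$start))) {
    stop("promoters lack genomic coordinates; this analysis needs them")
  }
  GenomicRanges::GRanges(
    seqnames = promoters$chrom,
    ranges = IRanges::IRanges(start = promoters$start, end = promoters$end),
    strand = promoters$strand,
    gene_id = promoters$gene_id
  )
}
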