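#' Merge fully overlapping read pairs with mismatch masking
#'
#' Read2 is reverse-complemented and compared base by base with Read1; any
#' position where the mates disagree, or where either mate reports N, is
#' masked to N in the merged read. Masking (rather than discarding pairs
#' above some mismatch count) retains the maximum amount of sequence: a
#' sequencing error only survives merging if the same change occurs at the
#' same position in both mates (probability ~ e^2/3 per site).
#'
#' @param r1,r2 character vectors of mate sequences in matching order.
#' @return character vector of merged reads; pairs of unequal length give
#'   `NA` (counted and dropped by [run_consensus()]).
#' @export
merge_pairs <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("merge error: mate vectors differ in length")
  merge_pairs_cpp(as.character(r1), as.character(r2))
}

#' Extract capture barcodes from merged reads
#'
#' The capture barcode is the concatenation of the 5' UMI (first `umi_len`
#' bases), the 3' UMI (last `umi_len` bases) and a 5-base anchor (the first
#' five bases of the insert), 29 informative bases at the defaults. The
#' insert is the merged read with both UMIs stripped.
#'
#' @param merged character vector of merged reads.
#' @param umi_len UMI length (default 12).
#' @param anchor_len anchor length (default 5).
#' @return list with `barcode`, `insert`, `umi5`, `umi3`, `anchor`, and
#'   `too_short` (logical: reads shorter than `2*umi_len + anchor_len + 1`,
#'   which carry no insert and are dropped).
#' @export
extract_barcodes <- function(merged, umi_len = 12L, anchor_len = 5L) {
  len <- nchar(merged)
  too_short <- len <= 2L * umi_len + anchor_len
  umi5 <- substr(merged, 1L, umi_len)
  umi3 <- substr(merged, len - umi_len + 1L, len)
  anchor <- substr(merged, umi_len + 1L, umi_len + anchor_len)
  insert <- substr(merged, umi_len + 1L, len - umi_len)
  list(barcode = paste0(umi5, umi3, anchor), insert = insert,
       umi5 = umi5, umi3 = umi3, anchor = anchor, too_short = too_short)
}

#' Cluster barcodes with mismatch tolerance
#'
#' Greedy clustering in descending-support order: each barcode joins the
#' first established bin whose founding barcode lies within `max_mismatch`
#' (characters compared literally, so an N mismatches any real base), else
#' founds a new bin. The highest-support barcode is taken as the true
#' sequence of its bin, as in standard UMI deduplication practice.
#'
#' @param barcode character vector, one entry per read.
#' @param max_mismatch allowed Hamming distance (default 1).
#' @return list with `bin` (1-based bin id per read), `n_bins`, and
#'   `representative` (founding barcode of each bin).
#' @export
cluster_barcodes <- function(barcode, max_mismatch = 1L) {
  u <- unique(barcode)
  cnt <- tabulate(match(barcode, u), nbins = length(u))
  ord <- order(-cnt, u)  # ties broken lexicographically for determinism
  u <- u[ord]
  res <- cluster_barcodes_cpp(u, as.integer(max_mismatch))
  bin_of_unique <- res$bin
  list(bin = bin_of_unique[match(barcode, u)],
       n_bins = length(res$founder),
       representative = u[res$founder])
}

#' Collapse one capture bin to a consensus read
#'
#' Single-bin convenience wrapper around the collapsing rule; see
#' [run_consensus()] for the full pipeline. Bins with fewer than `min_reads`
#' members are rejected (`NULL`). At each position the most common non-N
#' base is called iff it is observed in at least `agreement` of all members
#' (members reporting N at that position stay in the denominator) and the
#' maximum is unique; otherwise the consensus carries N and alignment is
#' attempted with an unknown base there.
#'
#' @param inserts character vector of member insert sequences (equal length).
#' @param min_reads minimum supporting reads per capture (default 5).
#' @param agreement required agreement fraction (default 0.75).
#' @return list with `seq` and `support`, or `NULL` if rejected.
#' @export
collapse_bin <- function(inserts, min_reads = 5L, agreement = 0.75) {
  res <- collapse_bins_cpp(as.character(inserts),
                           rep(1L, length(inserts)), 1L,
                           as.integer(min_reads), agreement)
  if (is.na(res$consensus[1])) return(NULL)
  list(seq = as.character(res$consensus[1]), support = res$support[1])
}

read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Collapse raw paired-end reads into per-capture consensus reads
#'
#' The core error-elimination pipeline: merge mates with mismatch masking,
#' extract the UMI/anchor barcode, bin reads by barcode with mismatch
#' tolerance, and collapse each bin into one consensus sequence per unique
#' capture. Sequencing errors are removed by merging and by the agreement
#' rule; PCR errors from rounds after the first reach at most ~50\% of a
#' bin's reads and are masked or out-voted; pre-amplification (round-0)
#' errors survive into the consensus and are only removed downstream by the
#' multi-capture support rule.
#'
#' @param r1,r2 character vectors of mate sequences, or paths to FASTQ
#'   files (plain or gzip) in matching order.
#' @param umi_len UMI length (default 12).
#' @param min_reads minimum supporting reads per capture (default 5).
#' @param agreement per-position agreement fraction (default 0.75).
#' @param max_mismatch barcode mismatch tolerance (default 1).
#' @param anchor_len barcode anchor length (default 5).
#' @return object of class `umivar_consensus`: data frame with columns
#'   `barcode`, `seq`, `support`, and a `qc` attribute (total pairs, merge
#'   drops, anchor drops, bins formed/rejected, per-capture coverage).
#' @export
run_consensus <- function(r1, r2, umi_len = 12L, min_reads = 5L,
                          agreement = 0.75, max_mismatch = 1L,
                          anchor_len = 5L) {
  if (length(r1) == 1 && file.exists(r1[1])) r1 <- read_fastq_seqs(r1)
  if (length(r2) == 1 && file.exists(r2[1])) r2 <- read_fastq_seqs(r2)
  if (length(r1) != length(r2)) stop("merge error: mate files differ in read count")
  qc <- list(total_pairs = length(r1))

  merged <- merge_pairs(r1, r2)
  bad <- is.na(merged)
  qc$dropped_length_mismatch <- sum(bad)
  merged <- merged[!bad]

  bc <- extract_barcodes(merged, umi_len, anchor_len)
  qc$dropped_too_short <- sum(bc$too_short)
  keep <- !bc$too_short
  # reads whose anchor carries no information cannot be binned reliably
  all_n_anchor <- keep & !grepl("[ACGT]", bc$anchor)
  qc$dropped_anchor_all_n <- sum(all_n_anchor)
  keep <- keep & !all_n_anchor
  barcode <- bc$barcode[keep]
  insert <- bc$insert[keep]
  # bins mix lengths only if input mixes read lengths; keep the modal length
  lens <- nchar(insert)
  modal <- as.integer(names(which.max(table(lens))))
  qc$dropped_offlength <- sum(lens != modal)
  barcode <- barcode[lens == modal]
  insert <- insert[lens == modal]

  cl <- cluster_barcodes(barcode, max_mismatch)
  qc$total_captures <- cl$n_bins
  col <- collapse_bins_cpp(insert, cl$bin, cl$n_bins,
                           as.integer(min_reads), agreement)
  ok <- !is.na(col$consensus)
  qc$bins_rejected_min_reads <- col$rejected
  qc$n_consensus <- sum(ok)
  qc$total_reads_used <- length(insert)
  qc$mean_support <- if (any(ok)) mean(col$support[ok]) else NA_real_
  qc$capture_coverage <- capture_coverage(length(insert), max(cl$n_bins, 1L))

  out <- data.frame(barcode = cl$representative[ok],
                    seq = as.character(col$consensus[ok]),
                    support = col$support[ok], stringsAsFactors = FALSE)
  structure(out, class = c("umivar_consensus", "data.frame"), qc = qc)
}

#' @export
print.umivar_consensus <- function(x, ...) {
  qc <- attr(x, "qc")
  cat(sprintf("umivar consensus reads: %d (from %d read pairs, %d captures; %.1fx per capture)\n",
              nrow(x), qc$total_pairs, qc$total_captures, qc$capture_coverage))
  cat(sprintf("  bins rejected (<min reads): %d; pairs dropped: %d\n",
              qc$bins_rejected_min_reads,
              qc$dropped_length_mismatch + qc$dropped_too_short + qc$dropped_anchor_all_n))
  invisible(x)
}

#' Write consensus reads as FASTA
#'
#' Headers carry the barcode and the supporting-read count.
#'
#' @param consensus an `umivar_consensus`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensus, path) {
  set <- Biostrings::DNAStringSet(consensus$seq)
  names(set) <- sprintf("%s support=%d", consensus$barcode, consensus$support)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
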