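#' Load a probe panel
#'
#' Reads the definition of the targeted probe panel: the set of ~150 bp
#' genomic regions captured by the assay, each with its plus-strand
#' reference sequence. All downstream alignment, calling and background
#' construction is anchored on these regions.
#'
#' The native format is a tab-separated file with columns `probe_id`,
#' `chrom`, `start`, `end`, `strand`, `region_seq`; coordinates are
#' 1-based inclusive and `region_seq` is always the plus strand
#' (minus-strand probes store the plus-strand sequence of their interval).
#'
#' @param path path to a panel TSV.
#' @param genome_label free-text genome tag stored on the panel.
#' @param umi_len length in bases of the unique molecular identifier at each
#'   end of a capture (default 12).
#' @param sample_index_len length of the per-sample index (metadata only;
#'   demultiplexing is assumed done upstream).
#' @return an object of class `umivar_panel`: a data frame of probes with
#'   attributes `genome_label`, `umi_len`, `sample_index_len`.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("probe_id\tchrom\tstart\tend\tstrand\tregion_seq",
#'              paste("p1", "chr1", 100, 109, "+", "ACGTACGTAC", sep = "\t")),
#'            tsv)
#' load_panel(tsv)
load_panel <- function(path, genome_label = "unspecified", umi_len = 12L,
                       sample_index_len = 16L) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "strand", "region_seq")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel file lacks column(s): ", paste(miss, collapse = ", "))
  panel_from_df(df[need], genome_label, umi_len, sample_index_len)
}

#' Build a probe panel from a data frame
#'
#' Programmatic constructor used by [load_panel()], the BED+FASTA loader and
#' the simulator fixtures. Validates all panel invariants.
#'
#' @param df data frame with columns `probe_id`, `chrom`, `start`, `end`,
#'   `strand`, `region_seq`.
#' @inheritParams load_panel
#' @return an `umivar_panel`.
#' @export
panel_from_df <- function(df, genome_label = "unspecified", umi_len = 12L,
                          sample_index_len = 16L) {
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$region_seq <- toupper(df$region_seq)
  if (anyDuplicated(df$probe_id))
    stop("panel error: duplicate probe_id: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("panel error: strand must be '+' or '-'")
  bad_len <- nchar(df$region_seq) != df$end - df$start + 1L
  if (any(bad_len))
    stop("panel error: region_seq length disagrees with coordinates for probe(s): ",
         paste(df$probe_id[bad_len], collapse = ", "))
  if (any(grepl("[^ACGT]", df$region_seq)))
    stop("panel error: region_seq contains non-ACGT characters")
  if (umi_len <= 0) stop("panel error: umi_len must be positive")
  # reject overlapping intervals per chromosome
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
      stop("panel error: overlapping probe intervals on ", ch)
  }
  rownames(df) <- NULL
  structure(df, class = c("umivar_panel", "data.frame"),
            genome_label = genome_label, umi_len = as.integer(umi_len),
            sample_index_len = as.integer(sample_index_len))
}

#' Load a probe panel from BED + reference FASTA
#'
#' Convenience alias for panels kept as a BED file (0-based half-open,
#' converted to 1-based inclusive on load) plus a FASTA of region sequences
#' named by probe id.
#'
#' @param bed_path BED file with at least chrom, start, end, name columns.
#' @param fasta_path FASTA whose sequence names match the BED name column.
#' @inheritParams load_panel
#' @return an `umivar_panel`.
#' @export
load_panel_bed <- function(bed_path, fasta_path, genome_label = "unspecified",
                           umi_len = 12L, sample_index_len = 16L) {
  bed <- read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("panel error: BED needs chrom,start,end,name columns")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  sn <- as.character(bed[[4]])
  if (!all(sn %in% names(seqs)))
    stop("panel error: BED names missing from FASTA: ",
         paste(setdiff(sn, names(seqs)), collapse = ", "))
  strand <- if (ncol(bed) >= 6) as.character(bed[[6]]) else rep("+", nrow(bed))
  df <- data.frame(probe_id = sn, chrom = as.character(bed[[1]]),
                   start = as.integer(bed[[2]]) + 1L, end = as.integer(bed[[3]]),
                   strand = strand,
                   region_seq = as.character(seqs[sn]),
                   stringsAsFactors = FALSE)
  panel_from_df(df, genome_label, umi_len, sample_index_len)
}

#' Write a probe panel to its TSV format
#'
#' @param panel an `umivar_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.umivar_panel <- function(x, ...) {
  cat(sprintf("umivar probe panel: %d probe(s), genome %s\n", nrow(x),
              attr(x, "genome_label")))
  cat(sprintf("  UMI length %d, sample index length %d\n",
              attr(x, "umi_len"), attr(x, "sample_index_len")))
  print.data.frame(head(as.data.frame(x)[c("probe_id", "chrom", "start", "end",
                                           "strand")], 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more probe(s)\n", nrow(x) - 10L))
  invisible(x)
}

#' Locate a genomic position within the panel
#'
#' @param panel an `umivar_panel`.
#' @param chrom chromosome name.
#' @param pos 1-based genomic position.
#' @return a list with elements `probe_id`, `probe` (row index) and `offset`
#'   (0-based offset within the region sequence), or `NULL` if the position
#'   is not probed.
#' @export
locate_position <- function(panel, chrom, pos) {
  hit <- which(panel$chrom == chrom & panel$start <= pos & panel$end >= pos)
  if (length(hit) == 0) return(NULL)
  hit <- hit[1]  # panel invariant: intervals do not overlap
  list(probe_id = panel$probe_id[hit], probe = hit,
       offset = as.integer(pos - panel$start[hit]))
}

#' Trinucleotide context of a probed position
#'
#' Returns the plus-strand 3-mer centred on the position (5' neighbour,
#' reference base, 3' neighbour). Positions at region edges have no context
#' and raise an error.
#'
#' @inheritParams locate_position
#' @return 3-character string.
#' @export
trinucleotide_context <- function(panel, chrom, pos) {
  loc <- locate_position(panel, chrom, pos)
  if (is.null(loc)) stop("position ", chrom, ":", pos, " is not probed")
  len <- nchar(panel$region_seq[loc$probe])
  if (loc$offset < 1L || loc$offset > len - 2L)
    stop("edge-context error: ", chrom, ":", pos,
         " has no neighbour inside its probe region")
  substr(panel$region_seq[loc$probe], loc$offset, loc$offset + 2L)
}

#' Reference base at a probed position
#'
#' @inheritParams locate_position
#' @return single character, or `NA` if unprobed.
#' @export
ref_base <- function(panel, chrom, pos) {
  loc <- locate_position(panel, chrom, pos)
  if (is.null(loc)) return(NA_character_)
  substr(panel$region_seq[loc$probe], loc$offset + 1L, loc$offset + 1L)
}
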