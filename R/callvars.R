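#' Anchor consensus reads to their probe regions
#'
#' Seed-and-verify placement against the panel: every N-free 20-mer of a
#' consensus read is looked up in an index of all panel-region 20-mers, and
#' each implied placement is verified by full Hamming comparison with N
#' positions excluded. Both orientations are tried and the best placement
#' kept; reads with more than `max_mismatch` mismatches (or no seed hit)
#' are rejected, which also excludes material captured outside the probed
#' regions. For 150 bp amplicons this is exact and deterministic; no
#' external aligner is involved.
#'
#' @param consensus an `umivar_consensus`, or a character vector of
#'   sequences.
#' @param panel an `umivar_panel`.
#' @param max_mismatch mismatch ceiling for accepting a placement
#'   (default 10).
#' @param seed_len seed k-mer length (default 20).
#' @return object of class `umivar_aligned`: data frame with `probe_id`,
#'   `offset` (0-based start in the region), `orientation`, `mismatches`,
#'   `seq` (plus-strand orientation), `support`, `barcode`; rejected reads
#'   are dropped and counted in the `qc` attribute.
#' @export
align_consensus <- function(consensus, panel, max_mismatch = 10L,
                            seed_len = 20L) {
  if (inherits(consensus, "umivar_consensus")) {
    seqs <- consensus$seq
    support <- consensus$support
    barcode <- consensus$barcode
  } else {
    seqs <- as.character(consensus)
    support <- rep(NA_integer_, length(seqs))
    barcode <- rep(NA_character_, length(seqs))
  }
  res <- align_cpp(seqs, panel$region_seq, as.integer(seed_len),
                   as.integer(max_mismatch))
  ok <- res$probe > 0L
  plus <- ifelse(res$orientation[ok] == "reverse", revcomp(seqs[ok]), seqs[ok])
  out <- data.frame(probe_id = panel$probe_id[res$probe[ok]],
                    probe = res$probe[ok], offset = res$offset[ok],
                    orientation = res$orientation[ok],
                    mismatches = res$mismatches[ok], seq = plus,
                    support = support[ok], barcode = barcode[ok],
                    stringsAsFactors = FALSE)
  structure(out, class = c("umivar_aligned", "data.frame"),
            qc = list(n_input = length(seqs), n_aligned = sum(ok),
                      n_rejected = sum(!ok)),
            panel = panel)
}

#' @export
print.umivar_aligned <- function(x, ...) {
  qc <- attr(x, "qc")
  cat(sprintf("umivar aligned consensus: %d placed / %d input (%d rejected)\n",
              qc$n_aligned, qc$n_input, qc$n_rejected))
  invisible(x)
}

#' Build a per-position base pileup from aligned consensus reads
#'
#' Tallies A/C/G/T/N counts per probe position over aligned consensus reads
#' (one capture, one vote). Sequences are tallied in plus-strand space;
#' reverse-orientation placements were already reverse-complemented by
#' [align_consensus()].
#'
#' @param aligned an `umivar_aligned`.
#' @param panel an `umivar_panel` (defaults to the one stored on `aligned`).
#' @return object of class `umivar_pileup`: list of 5 x region-length count
#'   matrices, one per probe, with rows A,C,G,T,N.
#' @export
build_pileup <- function(aligned, panel = attr(aligned, "panel")) {
  mats <- pileup_cpp(aligned$seq, aligned$probe, aligned$offset,
                     nchar(panel$region_seq), nrow(panel))
  names(mats) <- panel$probe_id
  structure(mats, class = "umivar_pileup", panel = panel)
}

#' @export
print.umivar_pileup <- function(x, ...) {
  depth <- vapply(unclass(x), function(m) max(colSums(m)), numeric(1))
  cat(sprintf("umivar pileup over %d probe(s); max capture depth %s\n",
              length(x), paste(depth, collapse = ", ")))
  invisible(x)
}

#' Call per-position substitutions from a capture pileup
#'
#' Every non-reference base observed in at least `min_capture_support`
#' distinct captures is emitted as a call. The variant allele frequency is
#' supporting captures / covering captures, where covering counts only
#' captures reporting a real base (N encodes "unknown" and is excluded from
#' both numerator and denominator). Germline heterozygotes appear at VAF
#' ~0.5 and are retained; they are handled by the background stage or by
#' reporting. Multi-allelic positions yield one call per alternate base.
#'
#' @param pileup an `umivar_pileup`.
#' @param panel an `umivar_panel` (defaults to the one stored on `pileup`).
#' @param min_capture_support minimum distinct captures carrying the
#'   alternate base (default 5).
#' @return object of class `umivar_calls`: data frame with `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `supporting`, `covering`, `vaf`, `context`
#'   (plus-strand trinucleotide, NA at region edges), and `class` (the
#'   pyrimidine-collapsed substitution class, e.g. `"C>T"`).
#' @export
call_variants <- function(pileup, panel = attr(pileup, "panel"),
                          min_capture_support = 5L) {
  out <- list()
  for (p in seq_along(pileup)) {
    m <- pileup[[p]]
    len <- ncol(m)
    refs <- strsplit(panel$region_seq[p], "")[[1]]
    covering <- colSums(m[1:4, , drop = FALSE])
    for (b in 1:4) {
      base <- DNA_BASES[b]
      cnt <- m[b, ]
      hit <- which(cnt >= min_capture_support & refs != base)
      if (!length(hit)) next
      ctx <- ifelse(hit > 1L & hit < len,
                    substr(panel$region_seq[p], hit - 1L, hit + 1L),
                    NA_character_)
      out[[length(out) + 1L]] <- data.frame(
        chrom = panel$chrom[p], pos = panel$start[p] + hit - 1L,
        ref = refs[hit], alt = base,
        supporting = cnt[hit], covering = covering[hit],
        vaf = cnt[hit] / covering[hit], context = ctx,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), supporting = integer(0),
               covering = integer(0), vaf = numeric(0), context = character(0),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls$class <- substitution_class(calls$ref, calls$alt)
  structure(calls, class = c("umivar_calls", "data.frame"), panel = panel)
}

#' @export
print.umivar_calls <- function(x, ...) {
  cat(sprintf("umivar calls: %d substitution(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Pyrimidine-collapsed substitution class
#'
#' Complementary changes (e.g. C>T and G>A) are conventionally reported as
#' one class keyed on the pyrimidine reference base.
#'
#' @param ref,alt character vectors of reference and alternate bases.
#' @return character vector like `"C>T"`.
#' @export
substitution_class <- function(ref, alt) {
  if (!length(ref)) return(character(0))
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, chartr("ACGT", "TGCA", ref), ref)
  a <- ifelse(flip, chartr("ACGT", "TGCA", alt), alt)
  paste0(r, ">", a)
}

#' Pyrimidine-collapsed trinucleotide context class
#'
#' @param context plus-strand 3-mer context.
#' @param ref,alt reference and alternate bases.
#' @return character vector like `"ACG>T"` (context, then alternate on the
#'   pyrimidine strand); NA contexts propagate.
#' @export
context_class <- function(context, ref, alt) {
  if (!length(ref)) return(character(0))
  flip <- ref %in% c("A", "G")
  ctx <- ifelse(flip, revcomp(context), context)
  a <- ifelse(flip, chartr("ACGT", "TGCA", alt), alt)
  ifelse(is.na(context), NA_character_, paste0(ctx, ">", a))
}

#' Write variant calls as a minimal VCF 4.2 file
#'
#' INFO keys: SUP (supporting captures), DPU (covering captures), VAF,
#' CTX (trinucleotide context), and SIG (significance vs background:
#' `positional`, `generic`, or `none`; only present after
#' [filter_variants()]).
#'
#' @param calls an `umivar_calls`.
#' @param panel an `umivar_panel` (for the reference label).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, panel = attr(calls, "panel"), path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=umivar"),
           sprintf("##reference=%s", attr(panel, "genome_label") %||% "unspecified"),
           "##INFO=<ID=SUP,Number=1,Type=Integer,Description=\"Supporting captures\">",
           "##INFO=<ID=DPU,Number=1,Type=Integer,Description=\"Covering captures (non-N)\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
           "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Trinucleotide context\">",
           "##INFO=<ID=SIG,Number=1,Type=String,Description=\"Significance vs background\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  if (nrow(calls)) {
    sig <- if ("significance" %in% names(calls)) calls$significance else NULL
    info <- sprintf("SUP=%d;DPU=%d;VAF=%.6g;CTX=%s", calls$supporting,
                    calls$covering, calls$vaf,
                    ifelse(is.na(calls$context), ".", calls$context))
    if (!is.null(sig)) info <- paste0(info, ";SIG=", sig)
    recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", calls$chrom, calls$pos,
                    calls$ref, calls$alt, info)
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a minimal VCF of substitution calls
#'
#' Parses VCF files written by [write_vcf()] (or any VCF restricted to
#' single-base substitutions with SUP/DPU/VAF INFO keys) back into an
#' `umivar_calls` table, so externally produced calls can enter the
#' background/filtering stages.
#'
#' @param path VCF path.
#' @param panel optional `umivar_panel` to recompute contexts.
#' @return an `umivar_calls` data frame.
#' @export
read_vcf <- function(path, panel = NULL) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln)) {
    calls <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        supporting = integer(0), covering = integer(0),
                        vaf = numeric(0), context = character(0),
                        stringsAsFactors = FALSE)
    calls$class <- character(0)
    return(structure(calls, class = c("umivar_calls", "data.frame"),
                     panel = panel))
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  getinfo <- function(info, key) {
    vapply(strsplit(info, ";", fixed = TRUE), function(kv) {
      hit <- kv[startsWith(kv, paste0(key, "="))]
      if (length(hit)) sub("^[^=]+=", "", hit[1]) else NA_character_
    }, character(1))
  }
  info <- vapply(f, `[`, character(1), 8L)
  calls <- data.frame(
    chrom = vapply(f, `[`, character(1), 1L),
    pos = as.integer(vapply(f, `[`, character(1), 2L)),
    ref = vapply(f, `[`, character(1), 4L),
    alt = vapply(f, `[`, character(1), 5L),
    supporting = as.integer(getinfo(info, "SUP")),
    covering = as.integer(getinfo(info, "DPU")),
    vaf = as.numeric(getinfo(info, "VAF")),
    context = getinfo(info, "CTX"), stringsAsFactors = FALSE)
  calls$context[calls$context == "."] <- NA_character_
  if (!is.null(panel))
    calls$context <- vapply(seq_len(nrow(calls)), function(i)
      tryCatch(trinucleotide_context(panel, calls$chrom[i], calls$pos[i]),
               error = function(e) NA_character_), character(1))
  calls$class <- substitution_class(calls$ref, calls$alt)
  structure(calls, class = c("umivar_calls", "data.frame"), panel = panel)
}
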