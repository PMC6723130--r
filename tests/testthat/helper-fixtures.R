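# Fixture builders and brute-force reference implementations shared across
# the test files. Everything is generated in code; no data files.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# panel of `n` non-overlapping probes with random region sequences
make_panel <- function(n = 1L, len = 150L, chrom = "chr1", gap = 50L,
                       start0 = 1000L) {
  starts <- start0 + (seq_len(n) - 1L) * (len + gap)
  panel_from_df(data.frame(
    probe_id = sprintf("p%02d", seq_len(n)), chrom = chrom,
    start = starts, end = starts + len - 1L, strand = "+",
    region_seq = vapply(seq_len(n), function(i) rand_seq(len), character(1)),
    stringsAsFactors = FALSE))
}

# genomic positions of probe p usable for variants (interior of the
# sequenced insert) whose reference base is `base`
probe_positions <- function(panel, p = 1L, base = NULL) {
  lay_off <- (nchar(panel$region_seq[p]) - 126L) %/% 2L
  off <- seq.int(lay_off + 1L, lay_off + 124L)  # interior of the insert
  refs <- substring(panel$region_seq[p], off + 1L, off + 1L)
  pos <- panel$start[p] + off
  if (!is.null(base)) pos <- pos[refs == base]
  pos
}

other_base <- function(ref) vapply(ref, function(b)
  setdiff(c("A", "C", "G", "T"), b)[1], character(1), USE.NAMES = FALSE)

# ---- brute-force reference implementations ----

bf_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(s, ""), function(x)
    paste(rev(x), collapse = ""), character(1)))
}

bf_merge <- function(r1, r2) {
  a <- strsplit(r1, "")[[1]]
  b <- strsplit(bf_revcomp(r2), "")[[1]]
  paste(ifelse(a == b & a != "N", a, "N"), collapse = "")
}

bf_hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  sum(x != y)
}

# greedy clustering oracle: unique barcodes in descending support order
# (ties lexicographic), each joining the first established founder within
# max_mismatch by literal character comparison
bf_cluster <- function(barcodes, max_mismatch = 1L) {
  u <- unique(barcodes)
  cnt <- tabulate(match(barcodes, u), nbins = length(u))
  u <- u[order(-cnt, u)]
  founders <- character(0)
  bin_of_u <- integer(length(u))
  for (i in seq_along(u)) {
    hit <- 0L
    for (b in seq_along(founders)) {
      if (bf_hamming(u[i], founders[b]) <= max_mismatch) { hit <- b; break }
    }
    if (hit == 0L) { founders <- c(founders, u[i]); hit <- length(founders) }
    bin_of_u[i] <- hit
  }
  list(bin = bin_of_u[match(barcodes, u)], representative = founders)
}

# per-position tally collapse oracle
bf_collapse <- function(inserts, min_reads = 5L, agreement = 0.75) {
  if (length(inserts) < min_reads) return(NULL)
  mat <- do.call(rbind, strsplit(inserts, ""))
  cons <- apply(mat, 2, function(col) {
    tab <- table(factor(col[col != "N"], levels = c("A", "C", "G", "T")))
    top <- max(tab)
    if (top == 0 || sum(tab == top) > 1) return("N")
    if (top / length(col) >= agreement) names(tab)[which.max(tab)] else "N"
  })
  list(seq = paste(cons, collapse = ""), support = length(inserts))
}

# exhaustive sliding-window placement oracle (both orientations, N skipped)
bf_align <- function(query, regions, max_mismatch = 10L) {
  best <- NULL
  for (ori in c("forward", "reverse")) {
    q <- if (ori == "forward") query else bf_revcomp(query)
    qc <- strsplit(q, "")[[1]]
    for (r in seq_along(regions)) {
      rc <- strsplit(regions[r], "")[[1]]
      if (length(qc) > length(rc)) next
      for (s in 0:(length(rc) - length(qc))) {
        seg <- rc[s + seq_along(qc)]
        d <- sum(qc != "N" & qc != seg)
        if (is.null(best) || d < best$mismatches)
          best <- list(probe = r, offset = s, mismatches = d, orientation = ori)
      }
    }
    if (!is.null(best) && best$mismatches == 0) break
  }
  if (is.null(best) || best$mismatches > max_mismatch) return(NULL)
  best
}

bf_pileup <- function(seqs, offsets, region_len) {
  m <- matrix(0L, 5, region_len, dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    for (j in seq_along(ch)) {
      row <- match(ch[j], c("A", "C", "G", "T"), nomatch = 5L)
      m[row, offsets[i] + j] <- m[row, offsets[i] + j] + 1L
    }
  }
  m
}

# construct an umivar_calls table directly (for background-model unit tests)
synthetic_calls <- function(panel, pos, ref, alt, vaf, covering = 10000L) {
  if (!length(pos)) {
    df <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                     alt = character(0), supporting = integer(0),
                     covering = integer(0), vaf = numeric(0),
                     context = character(0), class = character(0),
                     stringsAsFactors = FALSE)
    return(structure(df, class = c("umivar_calls", "data.frame"), panel = panel))
  }
  sup <- as.integer(round(vaf * covering))
  ctx <- vapply(pos, function(p)
    tryCatch(trinucleotide_context(panel, panel$chrom[1], p),
             error = function(e) NA_character_), character(1))
  df <- data.frame(chrom = panel$chrom[1], pos = pos, ref = ref, alt = alt,
                   supporting = sup, covering = covering, vaf = vaf,
                   context = ctx, stringsAsFactors = FALSE)
  df$class <- substitution_class(df$ref, df$alt)
  structure(df, class = c("umivar_calls", "data.frame"), panel = panel)
}

# full small-scale pipeline on a simulated library
sim_calls <- function(panel, cfg, min_capture_support = 5L) {
  s <- simulate_library(panel, cfg)
  cons <- run_consensus(s$r1, s$r2)
  al <- align_consensus(cons, panel)
  call_variants(build_pileup(al, panel), panel,
                min_capture_support = min_capture_support)
}
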