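#' Simulation configuration
#'
#' Parameters of the synthetic library generator. The generator emulates the
#' wet-lab process molecule by molecule: diploid template molecules are
#' captured per probe with a fresh random UMI pair, the single capture copy
#' and subsequent PCR rounds introduce round-indexed substitution errors, and
#' fully overlapping 150 bp read pairs are emitted with independent per-base
#' sequencing errors.
#'
#' @param seed integer seed; every top-level simulation call seeds the R RNG
#'   with it (NULL leaves the RNG state alone).
#' @param captures_per_probe number of captured molecules per probe (scalar
#'   or one value per probe).
#' @param reads_per_capture_mean mean of the Poisson read count per capture
#'   (paper-scale sequencing corresponds to about 30x per capture).
#' @param pcr_cycles number of PCR amplification rounds (default 29).
#' @param pcr_error_rate per-base, per-copy polymerase substitution
#'   probability during PCR.
#' @param seq_error_rate per-base, per-mate sequencing error probability.
#' @param damage_rate per-base probability that a template molecule carries a
#'   pre-amplification lesion (round 0: oxidation/deamination-style damage
#'   present in every read of the capture).
#' @param ct_bias multiplier (>= 1) applied to C>T (and G>A) artifact
#'   substitutions relative to other changes, for PCR and damage errors.
#' @param pcr_pop_cap per-capture strand-pool ceiling; after each PCR round
#'   the pool is uniformly subsampled to this size so that 29 cycles stay
#'   tractable while lineage fractions are preserved in expectation.
#' @param read_len read length of each mate (default 150).
#' @param variants data frame of variants to inject, with columns `chrom`,
#'   `pos`, `ref`, `alt`, `vaf`, and optionally `mode` (one of `"somatic"`:
#'   carriers ~ Binomial(captures, vaf), the default; `"germline"`: carried
#'   by every molecule of the assigned haplotype; `"exact"`: carried by
#'   exactly round(captures * vaf) molecules) and `haplotype` (1 or 2,
#'   default 1).
#' @param hotspots data frame of position-specific damage hotspots with
#'   columns `chrom`, `pos`, `alt`, `rate` (per-molecule probability).
#' @param round1_errors number of forced first-round PCR errors injected at
#'   uniformly chosen (capture, position) sites; each lands on the round-1
#'   copy and so reaches ~50\% of that capture's reads.
#' @param inject data frame of targeted PCR error injections with columns
#'   `capture`, `round`, `chrom`, `pos`, `alt` (used mainly by tests).
#' @return an object of class `umivar_sim_config` (a validated list).
#' @export
sim_config <- function(seed = NULL, captures_per_probe = 1000L,
                       reads_per_capture_mean = 30, pcr_cycles = 29L,
                       pcr_error_rate = 1e-6, seq_error_rate = 1e-3,
                       damage_rate = 2e-5, ct_bias = 8, pcr_pop_cap = 512L,
                       read_len = 150L, variants = NULL, hotspots = NULL,
                       round1_errors = 0L, inject = NULL) {
  cfg <- list(seed = seed, captures_per_probe = as.integer(captures_per_probe),
              reads_per_capture_mean = reads_per_capture_mean,
              pcr_cycles = as.integer(pcr_cycles),
              pcr_error_rate = pcr_error_rate, seq_error_rate = seq_error_rate,
              damage_rate = damage_rate, ct_bias = ct_bias,
              pcr_pop_cap = as.integer(pcr_pop_cap),
              read_len = as.integer(read_len), variants = variants,
              hotspots = hotspots, round1_errors = as.integer(round1_errors),
              inject = inject)
  rates <- c(cfg$pcr_error_rate, cfg$seq_error_rate, cfg$damage_rate)
  if (any(rates < 0 | rates > 1)) stop("error rates must lie in [0, 1]")
  if (any(cfg$captures_per_probe < 1)) stop("captures_per_probe must be >= 1")
  if (cfg$reads_per_capture_mean <= 0) stop("reads_per_capture_mean must be positive")
  if (cfg$ct_bias < 1) stop("ct_bias must be >= 1")
  if (!is.null(variants)) {
    need <- c("chrom", "pos", "ref", "alt", "vaf")
    if (!all(need %in% names(variants)))
      stop("variants needs columns ", paste(need, collapse = ", "))
    if (any(variants$vaf < 0 | variants$vaf > 1)) stop("variant VAFs must lie in [0, 1]")
  }
  structure(cfg, class = "umivar_sim_config")
}

#' Expected heterozygous VAF after a founder-cell bottleneck
#'
#' A culture expanded from `n_founder_cells` cells dilutes any heterozygous
#' mutation private to one founder to an allele frequency of 1 / (2 n) at
#' diploid loci (0.005 after a 100-cell bottleneck).
#'
#' @param n_founder_cells number of founder cells (>= 1).
#' @return expected variant allele frequency.
#' @export
expected_het_vaf <- function(n_founder_cells) {
  if (any(n_founder_cells < 1)) stop("n_founder_cells must be >= 1")
  1 / (2 * n_founder_cells)
}

#' Cell divisions needed to reach a population size
#'
#' `ceiling(log2(n))` divisions grow a single cell to at least `n` cells
#' (about 14 divisions for the 10,000-cell detection limit).
#'
#' @param n_cells target population size (>= 1).
#' @return integer number of divisions.
#' @export
divisions_to_reach <- function(n_cells) {
  if (any(n_cells < 1)) stop("n_cells must be >= 1")
  as.integer(ceiling(log2(n_cells)))
}

# per-probe 0-based offset of the sequenced insert within region_seq
insert_layout <- function(panel, config) {
  umi_len <- attr(panel, "umi_len")
  ins_len <- config$read_len - 2L * umi_len
  if (ins_len < 1L) stop("read_len too short for two UMIs")
  reg_len <- nchar(panel$region_seq)
  if (any(reg_len < ins_len))
    stop("probe region(s) shorter than the sequenced insert (", ins_len, " bp)")
  list(ins_len = ins_len, ins_off = as.integer((reg_len - ins_len) %/% 2L))
}

# weighted substitution choice mirroring the C++ artifact-error model
pick_alt_r <- function(ref, ct_bias) {
  vapply(ref, function(b) {
    alts <- setdiff(DNA_BASES, b)
    w <- rep(1, 3)
    w[alts == "T" & b == "C"] <- ct_bias
    w[alts == "A" & b == "G"] <- ct_bias
    sample(alts, 1, prob = w)
  }, character(1), USE.NAMES = FALSE)
}

sub_str <- function(x, i, pos, alt) {
  for (k in seq_along(i)) substr(x[i[k]], pos[k], pos[k]) <- alt[k]
  x
}

#' Simulate captured template molecules
#'
#' Draws `captures_per_probe` single-molecule captures per probe from a
#' diploid template population (each capture picks haplotype 1 or 2 with
#' probability 1/2 and receives two fresh random UMIs), injects the
#' configured variants into carrier subsets, and applies pre-amplification
#' damage (round-0 errors present in every read of the capture).
#'
#' @param panel an `umivar_panel`.
#' @param config an `umivar_sim_config`.
#' @param .set_seed internal; set `config$seed` before drawing.
#' @return object of class `umivar_molecules`: list with elements `captures`
#'   (one row per capture: probe, haplotype, UMIs), `templates` (insert
#'   sequence of each captured molecule), `truth` (round-0 event table:
#'   variants, damage, hotspot lesions), `layout`, `panel`, `config`.
#' @export
simulate_molecules <- function(panel, config, .set_seed = TRUE) {
  stopifnot(inherits(panel, "umivar_panel"), inherits(config, "umivar_sim_config"))
  if (.set_seed && !is.null(config$seed)) set.seed(config$seed)
  lay <- insert_layout(panel, config)
  npp <- rep_len(config$captures_per_probe, nrow(panel))
  probe_idx <- rep(seq_len(nrow(panel)), npp)
  ncap <- length(probe_idx)
  hap <- rbinom(ncap, 1L, 0.5) + 1L
  umi <- random_dna_cpp(2L * ncap, attr(panel, "umi_len"))

  tmpl_by_probe <- substr(panel$region_seq, lay$ins_off + 1L,
                          lay$ins_off + lay$ins_len)
  templates <- tmpl_by_probe[probe_idx]

  ev <- list()
  add_ev <- function(cap, probe, off, ref, alt, origin) {
    data.frame(capture = cap, probe_id = panel$probe_id[probe],
               chrom = panel$chrom[probe],
               pos = panel$start[probe] + lay$ins_off[probe] + off,
               offset = off, ref = ref, alt = alt, origin = origin,
               round = 0L, stringsAsFactors = FALSE)
  }

  vs <- config$variants
  if (!is.null(vs) && nrow(vs)) {
    vs$mode <- if ("mode" %in% names(vs)) vs$mode else "somatic"
    vs$haplotype <- if ("haplotype" %in% names(vs)) vs$haplotype else 1L
    for (v in seq_len(nrow(vs))) {
      loc <- locate_position(panel, vs$chrom[v], vs$pos[v])
      if (is.null(loc))
        stop("variant spec error: ", vs$chrom[v], ":", vs$pos[v], " is not probed")
      io <- loc$offset - lay$ins_off[loc$probe]
      if (io < 0L || io >= lay$ins_len)
        stop("variant spec error: ", vs$chrom[v], ":", vs$pos[v],
             " lies outside the sequenced insert of probe ", loc$probe_id)
      rb <- substr(panel$region_seq[loc$probe], loc$offset + 1L, loc$offset + 1L)
      if (rb != vs$ref[v])
        stop("variant spec error: stated ref ", vs$ref[v], " disagrees with panel (",
             rb, ") at ", vs$chrom[v], ":", vs$pos[v])
      idx_p <- which(probe_idx == loc$probe)
      idx_h <- idx_p[hap[idx_p] == vs$haplotype[v]]
      carriers <- switch(vs$mode[v],
        germline = idx_h,
        exact = {
          k <- round(length(idx_p) * vs$vaf[v])
          if (k > length(idx_h)) k <- length(idx_h)
          if (k > 0) sample(idx_h, k) else integer(0)
        },
        somatic = {
          k <- rbinom(1L, length(idx_p), vs$vaf[v])
          if (k > length(idx_h)) k <- length(idx_h)
          if (k > 0) sample(idx_h, k) else integer(0)
        },
        stop("variant spec error: unknown mode ", vs$mode[v]))
      if (length(carriers)) {
        templates <- sub_str(templates, carriers, rep(io + 1L, length(carriers)),
                             rep(vs$alt[v], length(carriers)))
        ev[[length(ev) + 1L]] <- add_ev(carriers, loc$probe, io,
                                        vs$ref[v], vs$alt[v], "variant")
      }
    }
  }

  if (config$damage_rate > 0) {
    k <- rbinom(ncap, lay$ins_len, config$damage_rate)
    hit <- which(k > 0)
    for (i in hit) {
      off <- sample.int(lay$ins_len, k[i], replace = FALSE) - 1L
      ref <- vapply(off, function(o) substr(templates[i], o + 1L, o + 1L),
                    character(1))
      alt <- pick_alt_r(ref, config$ct_bias)
      templates <- sub_str(templates, rep(i, k[i]), off + 1L, alt)
      ev[[length(ev) + 1L]] <- add_ev(rep(i, k[i]), probe_idx[i], off, ref,
                                      alt, "damage")
    }
  }

  hs <- config$hotspots
  if (!is.null(hs) && nrow(hs)) {
    for (h in seq_len(nrow(hs))) {
      loc <- locate_position(panel, hs$chrom[h], hs$pos[h])
      if (is.null(loc))
        stop("hotspot spec error: ", hs$chrom[h], ":", hs$pos[h], " is not probed")
      io <- loc$offset - lay$ins_off[loc$probe]
      if (io < 0L || io >= lay$ins_len)
        stop("hotspot spec error: position outside the sequenced insert")
      idx_p <- which(probe_idx == loc$probe)
      carriers <- idx_p[runif(length(idx_p)) < hs$rate[h]]
      if (length(carriers)) {
        ref <- vapply(carriers, function(i) substr(templates[i], io + 1L, io + 1L),
                      character(1))
        templates <- sub_str(templates, carriers, rep(io + 1L, length(carriers)),
                             rep(hs$alt[h], length(carriers)))
        ev[[length(ev) + 1L]] <- add_ev(carriers, loc$probe, io, ref,
                                        hs$alt[h], "hotspot")
      }
    }
  }

  truth <- if (length(ev)) do.call(rbind, ev) else
    data.frame(capture = integer(0), probe_id = character(0),
               chrom = character(0), pos = integer(0), offset = integer(0),
               ref = character(0), alt = character(0), origin = character(0),
               round = integer(0), stringsAsFactors = FALSE)

  structure(list(
    captures = data.frame(capture = seq_len(ncap), probe = probe_idx,
                          probe_id = panel$probe_id[probe_idx],
                          haplotype = hap,
                          umi5 = umi[seq_len(ncap)],
                          umi3 = umi[ncap + seq_len(ncap)],
                          stringsAsFactors = FALSE),
    templates = templates, truth = truth, layout = lay,
    panel = panel, config = config), class = "umivar_molecules")
}

#' @export
print.umivar_molecules <- function(x, ...) {
  cat(sprintf("umivar simulated molecules: %d captures over %d probe(s); %d round-0 event(s)\n",
              nrow(x$captures), nrow(x$panel), nrow(x$truth)))
  invisible(x)
}

# assemble forced PCR injections (targeted + random first-round errors)
build_injections <- function(molecules) {
  cfg <- molecules$config
  panel <- molecules$panel
  lay <- molecules$layout
  out <- data.frame(capture = integer(0), round = integer(0),
                    offset = integer(0), alt = character(0),
                    stringsAsFactors = FALSE)
  inj <- cfg$inject
  if (!is.null(inj) && nrow(inj)) {
    off <- integer(nrow(inj))
    for (k in seq_len(nrow(inj))) {
      loc <- locate_position(panel, inj$chrom[k], inj$pos[k])
      if (is.null(loc)) stop("injection outside panel: ", inj$chrom[k], ":", inj$pos[k])
      io <- loc$offset - lay$ins_off[loc$probe]
      if (io < 0L || io >= lay$ins_len)
        stop("injection outside the sequenced insert")
      off[k] <- io
    }
    out <- rbind(out, data.frame(capture = as.integer(inj$capture),
                                 round = as.integer(inj$round), offset = off,
                                 alt = inj$alt, stringsAsFactors = FALSE))
  }
  if (cfg$round1_errors > 0) {
    ncap <- nrow(molecules$captures)
    n <- cfg$round1_errors
    if (n > ncap) stop("round1_errors exceeds the number of captures")
    caps <- sample.int(ncap, n, replace = FALSE)
    offs <- sample.int(lay$ins_len, n, replace = TRUE) - 1L
    ref <- vapply(seq_len(n), function(i)
      substr(molecules$templates[caps[i]], offs[i] + 1L, offs[i] + 1L),
      character(1))
    alt <- pick_alt_r(ref, cfg$ct_bias)
    out <- rbind(out, data.frame(capture = caps, round = 1L, offset = offs,
                                 alt = alt, stringsAsFactors = FALSE))
  }
  out
}

# map insert-space PCR error records to genomic coordinates
pcr_truth_frame <- function(molecules, capture, round, offset, ref, alt) {
  if (!length(capture))
    return(data.frame(capture = integer(0), probe_id = character(0),
                      chrom = character(0), pos = integer(0),
                      offset = integer(0), ref = character(0),
                      alt = character(0), origin = character(0),
                      round = integer(0), stringsAsFactors = FALSE))
  probe <- molecules$captures$probe[capture]
  data.frame(capture = capture,
             probe_id = molecules$panel$probe_id[probe],
             chrom = molecules$panel$chrom[probe],
             pos = molecules$panel$start[probe] +
               molecules$layout$ins_off[probe] + offset,
             offset = offset, ref = ref, alt = alt,
             origin = "pcr", round = round, stringsAsFactors = FALSE)
}

#' Amplify captured molecules by PCR (round-resolved error process)
#'
#' Runs the branching amplification process for every capture: the template
#' is copied once in round 1 (round-1 errors reach ~50\% of the final pool),
#' then the pool doubles each round with per-copy error probability
#' `1-(1-pcr_error_rate)^L`, capped at `pcr_pop_cap` strands by uniform
#' subsampling. A round-k error is carried by a fraction `2^-k` of the final
#' pool under perfect doubling. Intended for module-scale work and tests;
#' [simulate_library()] fuses amplification and read emission for large runs.
#'
#' @param molecules an `umivar_molecules`.
#' @param .set_seed internal; seed the RNG from the stored config.
#' @return object of class `umivar_pool`: per-capture strand pools
#'   (`data.frame(seq, count)`) plus the PCR error truth table.
#' @export
simulate_pcr <- function(molecules, .set_seed = FALSE) {
  stopifnot(inherits(molecules, "umivar_molecules"))
  cfg <- molecules$config
  if (.set_seed && !is.null(cfg$seed)) set.seed(cfg$seed)
  inj <- build_injections(molecules)
  ncap <- nrow(molecules$captures)
  pools <- vector("list", ncap)
  errs <- vector("list", ncap)
  for (i in seq_len(ncap)) {
    ii <- inj[inj$capture == i, , drop = FALSE]
    res <- sim_pcr_pool_cpp(molecules$templates[i], cfg$pcr_cycles,
                            cfg$pcr_error_rate, cfg$ct_bias, cfg$pcr_pop_cap,
                            ii$round, ii$offset, ii$alt)
    pools[[i]] <- data.frame(seq = res$seq, count = res$count,
                             stringsAsFactors = FALSE)
    if (length(res$err_round))
      errs[[i]] <- pcr_truth_frame(molecules, rep(i, length(res$err_round)),
                                   res$err_round, res$err_pos, res$err_ref,
                                   res$err_alt)
  }
  errs <- errs[!vapply(errs, is.null, logical(1))]
  truth_pcr <- if (length(errs)) do.call(rbind, errs) else
    pcr_truth_frame(molecules, integer(0), integer(0), integer(0),
                    character(0), character(0))
  structure(list(pools = pools, truth_pcr = truth_pcr, molecules = molecules),
            class = "umivar_pool")
}

#' Fraction of a strand pool carrying a given substitution
#'
#' @param pool an `umivar_pool`.
#' @param capture capture index.
#' @param offset 0-based offset within the insert.
#' @param alt alternate base.
#' @return fraction of final strands with `alt` at `offset`.
#' @export
pool_fraction <- function(pool, capture, offset, alt) {
  p <- pool$pools[[capture]]
  base <- substr(p$seq, offset + 1L, offset + 1L)
  sum(p$count[base == alt]) / sum(p$count)
}

#' Emit paired-end reads from amplified strand pools
#'
#' Each capture yields Poisson(`reads_per_capture_mean`) reads; every read
#' samples one strand from the capture's pool, is framed as
#' `UMI5 + insert + UMI3`, and both mates (Read2 = reverse complement)
#' receive independent per-base sequencing errors. Qualities written later by
#' [write_fastq()] are constant placeholders; the pipeline never uses them.
#'
#' @param pool an `umivar_pool`.
#' @param .set_seed internal; seed the RNG from the stored config.
#' @return object of class `umivar_reads`: `r1`, `r2` (character vectors),
#'   `capture` (originating capture of each pair), `seq_errors` (truth table
#'   of sequencing errors: read, mate, 1-based position in the mate).
#' @export
simulate_reads <- function(pool, .set_seed = FALSE) {
  stopifnot(inherits(pool, "umivar_pool"))
  mol <- pool$molecules
  cfg <- mol$config
  if (.set_seed && !is.null(cfg$seed)) set.seed(cfg$seed)
  ncap <- length(pool$pools)
  r1 <- list(); r2 <- list(); capv <- list(); serr <- list()
  L <- cfg$read_len
  nemitted <- 0L
  for (i in seq_len(ncap)) {
    nr <- rpois(1L, cfg$reads_per_capture_mean)
    if (nr == 0) next
    p <- pool$pools[[i]]
    pick <- sample.int(nrow(p), nr, replace = TRUE, prob = p$count)
    mols <- paste0(mol$captures$umi5[i], p$seq[pick], mol$captures$umi3[i])
    m2 <- revcomp(mols)
    for (j in seq_len(nr)) {
      for (mate in 1:2) {
        ne <- rbinom(1L, L, cfg$seq_error_rate)
        if (ne > 0) {
          posn <- sample.int(L, ne)
          cur <- vapply(posn, function(pp) substr(if (mate == 1) mols[j] else m2[j], pp, pp),
                        character(1))
          nb <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
          if (mate == 1) mols <- sub_str(mols, rep(j, ne), posn, nb)
          else m2 <- sub_str(m2, rep(j, ne), posn, nb)
          serr[[length(serr) + 1L]] <- data.frame(
            capture = i, read = nemitted + j, mate = mate, pos = posn,
            stringsAsFactors = FALSE)
        }
      }
    }
    nemitted <- nemitted + nr
    r1[[length(r1) + 1L]] <- mols
    r2[[length(r2) + 1L]] <- m2
    capv[[length(capv) + 1L]] <- rep(i, nr)
  }
  structure(list(
    r1 = unlist(r1) %||% character(0), r2 = unlist(r2) %||% character(0),
    capture = unlist(capv) %||% integer(0),
    seq_errors = if (length(serr)) do.call(rbind, serr) else NULL),
    class = "umivar_reads")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete barcoded amplicon library
#'
#' One-call generator: captures molecules, amplifies them and emits paired
#' reads using a fused fast path. Fixed seed implies byte-identical output.
#'
#' @inheritParams simulate_molecules
#' @return object of class `umivar_sim`: list with `r1`, `r2`, `capture`
#'   (per read pair), `molecules` (the `umivar_molecules`, including the
#'   round-0 truth), `truth_pcr` (round-resolved PCR error truth),
#'   `n_reads` per capture, and `config`.
#' @export
simulate_library <- function(panel, config, .set_seed = TRUE) {
  if (.set_seed && !is.null(config$seed)) set.seed(config$seed)
  mol <- simulate_molecules(panel, config, .set_seed = FALSE)
  inj <- build_injections(mol)
  res <- sim_emit_cpp(mol$templates, mol$captures$umi5, mol$captures$umi3,
                      inj$capture, inj$round, inj$offset, inj$alt,
                      config$pcr_cycles, config$pcr_error_rate, config$ct_bias,
                      config$pcr_pop_cap, config$reads_per_capture_mean,
                      config$seq_error_rate)
  truth_pcr <- pcr_truth_frame(mol, res$err_capture, res$err_round,
                               res$err_pos, res$err_ref, res$err_alt)
  structure(list(r1 = res$r1, r2 = res$r2, capture = res$capture,
                 molecules = mol, truth_pcr = truth_pcr,
                 n_reads = res$n_reads, config = config),
            class = "umivar_sim")
}

#' @export
print.umivar_sim <- function(x, ...) {
  cat(sprintf("umivar simulated library: %d read pairs from %d captures (%d probes)\n",
              length(x$r1), nrow(x$molecules$captures), nrow(x$molecules$panel)))
  cat(sprintf("  round-0 events: %d; PCR errors: %d\n",
              nrow(x$molecules$truth), nrow(x$truth_pcr)))
  invisible(x)
}

#' Write simulated reads as paired FASTQ
#'
#' Standard 4-line FASTQ with constant placeholder qualities; `.gz` suffixes
#' are compressed transparently.
#'
#' @param sim an `umivar_sim` or `umivar_reads` object.
#' @param r1_path,r2_path output paths for the two mate files.
#' @return invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq <- function(sim, r1_path, r2_path) {
  ids <- sprintf("@cap%d:%d", sim$capture, seq_along(sim$r1))
  wr <- function(seqs, suffix, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeLines(as.vector(rbind(paste0(ids, suffix), seqs, "+",
                               strrep("I", nchar(seqs)))), con)
  }
  wr(sim$r1, "/1", r1_path)
  wr(sim$r2, "/2", r2_path)
  invisible(c(r1_path, r2_path))
}

#' Write the simulation ground truth as TSV
#'
#' @param sim an `umivar_sim`.
#' @param path output path; two files are written, `<path>.captures.tsv`
#'   and `<path>.events.tsv` (round-0 template events and PCR errors).
#' @return invisibly, the two paths.
#' @export
write_sim_truth <- function(sim, path) {
  p1 <- paste0(path, ".captures.tsv")
  p2 <- paste0(path, ".events.tsv")
  write.table(sim$molecules$captures, p1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(rbind(sim$molecules$truth, sim$truth_pcr), p2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
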