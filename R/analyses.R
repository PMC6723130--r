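#' Phase consensus reads by a heterozygous SNP
#'
#' Partitions the aligned consensus reads covering a heterozygous SNP into
#' the two allele bins (reference vs alternate base at the SNP; reads with
#' N there are excluded) and recomputes every other variant's VAF within
#' each bin. A genuine somatic variant resident on one haplotype
#' concentrates in that allele's bin (~2x the pooled VAF, ~0 in the other);
#' ex-vivo artifacts associate equally with both alleles. Equality of
#' association is assessed per variant by a two-proportion test with
#' Benjamini-Hochberg correction across variants.
#'
#' @param aligned an `umivar_aligned`.
#' @param snp list or one-row data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param panel an `umivar_panel` (defaults to the one stored on `aligned`).
#' @param min_capture_support captures required on the minor allele for the
#'   site to count as heterozygous, and per-variant support threshold
#'   (default 5).
#' @return object of class `umivar_phase`: list with `snp`, bin depths, and
#'   `variants` (per variant: VAF in the ref-allele bin `vaf_a`, in the
#'   alt-allele bin `vaf_b`, pooled VAF over the partitioned reads, the
#'   two-proportion p-value and its BH-adjusted value).
#' @export
phase_by_het_snp <- function(aligned, snp, panel = attr(aligned, "panel"),
                             min_capture_support = 5L) {
  loc <- locate_position(panel, snp$chrom, snp$pos)
  if (is.null(loc)) stop("phasing error: SNP position is not probed")
  cover <- aligned$probe == loc$probe &
    aligned$offset <= loc$offset &
    aligned$offset + nchar(aligned$seq) > loc$offset
  sub <- aligned[cover, , drop = FALSE]
  base_at <- substr(sub$seq, loc$offset - sub$offset + 1L,
                    loc$offset - sub$offset + 1L)
  in_a <- base_at == snp$ref
  in_b <- base_at == snp$alt
  if (sum(in_b) < min_capture_support || sum(in_a) < min_capture_support)
    stop("phasing error: site is not heterozygous at the required support (",
         sum(in_a), " ref / ", sum(in_b), " alt captures)")

  bin_calls <- function(idx) {
    pile <- build_pileup(structure(sub[idx, , drop = FALSE],
                                   class = c("umivar_aligned", "data.frame")),
                         panel)
    call_variants(pile, panel, min_capture_support = 1L)
  }
  calls_a <- bin_calls(in_a)
  calls_b <- bin_calls(in_b)
  pooled <- call_variants(build_pileup(
    structure(sub[in_a | in_b, , drop = FALSE],
              class = c("umivar_aligned", "data.frame")), panel),
    panel, min_capture_support = min_capture_support)
  pooled <- pooled[!(pooled$pos == snp$pos & pooled$alt == snp$alt), ,
                   drop = FALSE]
  if (nrow(pooled)) {
    ida <- key_id(calls_a$chrom, calls_a$pos, calls_a$ref, calls_a$alt)
    idb <- key_id(calls_b$chrom, calls_b$pos, calls_b$ref, calls_b$alt)
    idp <- key_id(pooled$chrom, pooled$pos, pooled$ref, pooled$alt)
    ma <- match(idp, ida)
    mb <- match(idp, idb)
    sup_a <- ifelse(is.na(ma), 0L, calls_a$supporting[ma])
    sup_b <- ifelse(is.na(mb), 0L, calls_b$supporting[mb])
    cov_a <- ifelse(is.na(ma), NA_integer_, calls_a$covering[ma])
    cov_b <- ifelse(is.na(mb), NA_integer_, calls_b$covering[mb])
    # covering depth at the position even when the bin lacks the call
    for (i in which(is.na(cov_a))) {
      lc <- locate_position(panel, pooled$chrom[i], pooled$pos[i])
      pa <- build_pileup(structure(sub[in_a, , drop = FALSE],
                                   class = c("umivar_aligned", "data.frame")), panel)
      cov_a[i] <- sum(pa[[lc$probe]][1:4, lc$offset + 1L])
    }
    for (i in which(is.na(cov_b))) {
      lc <- locate_position(panel, pooled$chrom[i], pooled$pos[i])
      pb <- build_pileup(structure(sub[in_b, , drop = FALSE],
                                   class = c("umivar_aligned", "data.frame")), panel)
      cov_b[i] <- sum(pb[[lc$probe]][1:4, lc$offset + 1L])
    }
    pval <- vapply(seq_len(nrow(pooled)), function(i) {
      if (cov_a[i] == 0 || cov_b[i] == 0) return(NA_real_)
      suppressWarnings(stats::prop.test(c(sup_a[i], sup_b[i]),
                                        c(cov_a[i], cov_b[i]))$p.value)
    }, numeric(1))
    variants <- data.frame(pooled[c("chrom", "pos", "ref", "alt")],
                           sup_a = sup_a, cov_a = cov_a,
                           vaf_a = ifelse(cov_a > 0, sup_a / cov_a, 0),
                           sup_b = sup_b, cov_b = cov_b,
                           vaf_b = ifelse(cov_b > 0, sup_b / cov_b, 0),
                           vaf_pooled = pooled$vaf,
                           p_value = pval,
                           p_adj = p.adjust(pval, "BH"),
                           stringsAsFactors = FALSE)
  } else {
    variants <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           sup_a = integer(0), cov_a = integer(0),
                           vaf_a = numeric(0), sup_b = integer(0),
                           cov_b = integer(0), vaf_b = numeric(0),
                           vaf_pooled = numeric(0), p_value = numeric(0),
                           p_adj = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(snp = snp, n_a = sum(in_a), n_b = sum(in_b),
                 n_excluded = sum(!in_a & !in_b), variants = variants),
            class = "umivar_phase")
}

#' @export
print.umivar_phase <- function(x, ...) {
  cat(sprintf("umivar phasing at %s:%d %s>%s: %d ref-allele / %d alt-allele captures (%d excluded)\n",
              x$snp$chrom, x$snp$pos, x$snp$ref, x$snp$alt, x$n_a, x$n_b,
              x$n_excluded))
  cat(sprintf("  %d variant(s) phased\n", nrow(x$variants)))
  invisible(x)
}

#' Error correction by linked heterozygous SNPs
#'
#' When several heterozygous SNPs in one probe region sit on the same
#' haplotype, only consensus reads carrying all of the alternate alleles or
#' none of them are consistent with the two real haplotypes; reads with a
#' partial set carry at least one library-preparation or residual error and
#' are eliminated. Reports per-SNP VAFs before and after filtering.
#'
#' @param aligned an `umivar_aligned`.
#' @param snps data frame of phased SNPs (columns `chrom`, `pos`, `ref`,
#'   `alt`), all on one haplotype within a single probe region (>= 2 SNPs).
#' @param panel an `umivar_panel`.
#' @return object of class `umivar_linked`: `retained` (filtered
#'   `umivar_aligned`), `n_discarded`, `discarded` (row indices into the
#'   covering subset), and `snp_vafs` (per SNP: before/after VAF).
#' @export
linked_snp_filter <- function(aligned, snps, panel = attr(aligned, "panel")) {
  if (nrow(snps) < 2L) stop("linked filter error: at least 2 phased SNPs required")
  locs <- lapply(seq_len(nrow(snps)), function(i)
    locate_position(panel, snps$chrom[i], snps$pos[i]))
  if (any(vapply(locs, is.null, logical(1))))
    stop("linked filter error: SNP outside the panel")
  probes <- vapply(locs, `[[`, numeric(1), "probe")
  if (length(unique(probes)) != 1L)
    stop("linked filter error: SNPs span multiple probes")
  probe <- probes[1]
  offs <- vapply(locs, `[[`, numeric(1), "offset")

  cover <- aligned$probe == probe &
    aligned$offset <= min(offs) &
    aligned$offset + nchar(aligned$seq) > max(offs)
  sub <- aligned[cover, , drop = FALSE]
  bases <- vapply(seq_along(offs), function(k)
    substr(sub$seq, offs[k] - sub$offset + 1L, offs[k] - sub$offset + 1L),
    character(nrow(sub)))
  if (nrow(sub) == 1L) bases <- matrix(bases, nrow = 1L)
  is_alt <- bases == matrix(snps$alt, nrow(sub), nrow(snps), byrow = TRUE)
  is_ref <- bases == matrix(snps$ref, nrow(sub), nrow(snps), byrow = TRUE)
  all_alt <- rowSums(is_alt) == nrow(snps)
  all_ref <- rowSums(is_ref) == nrow(snps)
  keep <- all_alt | all_ref

  vaf_at <- function(d, k) {
    b <- substr(d$seq, offs[k] - d$offset + 1L, offs[k] - d$offset + 1L)
    sum(b == snps$alt[k]) / max(1L, sum(b %in% DNA_BASES))
  }
  snp_vafs <- data.frame(snps[c("chrom", "pos", "ref", "alt")],
                         vaf_before = vapply(seq_along(offs), function(k)
                           vaf_at(sub, k), numeric(1)),
                         vaf_after = vapply(seq_along(offs), function(k)
                           vaf_at(sub[keep, , drop = FALSE], k), numeric(1)),
                         stringsAsFactors = FALSE)
  retained <- structure(rbind(aligned[!cover, , drop = FALSE],
                              sub[keep, , drop = FALSE]),
                        class = c("umivar_aligned", "data.frame"),
                        panel = panel)
  structure(list(retained = retained, n_covering = nrow(sub),
                 n_discarded = sum(!keep),
                 discarded = sub[!keep, , drop = FALSE],
                 snp_vafs = snp_vafs),
            class = "umivar_linked")
}

#' @export
print.umivar_linked <- function(x, ...) {
  cat(sprintf("umivar linked-SNP filter: %d of %d covering reads discarded\n",
              x$n_discarded, x$n_covering))
  print(x$snp_vafs, row.names = FALSE)
  invisible(x)
}

#' Evaluate a dilution series
#'
#' A heterozygous variant serially diluted into negative DNA is expected at
#' VAF = dilution / 2 (an undiluted het sits at 0.5; a 1/5,000 dilution at
#' 1/10,000). For each dilution point the observed VAF (0 if the variant
#' was not called) and its significance against the background model are
#' reported.
#'
#' @param call_sets list of `umivar_calls`, one per dilution point.
#' @param spiked list with `chrom`, `pos`, `ref`, `alt` of the diluted
#'   variant.
#' @param dilutions numeric vector of nominal dilution fractions (1 =
#'   undiluted), same length as `call_sets`.
#' @param model an `umivar_background`.
#' @param alpha confidence mass for significance (default the model's).
#' @return data frame of class `umivar_dilution`: per point the nominal
#'   dilution, `expected_vaf` (= dilution/2), `observed_vaf`, and
#'   `detected` (significant vs background).
#' @export
evaluate_dilution <- function(call_sets, spiked, dilutions, model,
                              alpha = NULL) {
  stopifnot(length(call_sets) == length(dilutions))
  id <- key_id(spiked$chrom, spiked$pos, spiked$ref, spiked$alt)
  obs <- numeric(length(dilutions))
  det <- logical(length(dilutions))
  for (i in seq_along(call_sets)) {
    cc <- filter_variants(call_sets[[i]], model, alpha = alpha)
    m <- match(id, key_id(cc$chrom, cc$pos, cc$ref, cc$alt))
    if (!is.na(m)) {
      obs[i] <- cc$vaf[m]
      det[i] <- cc$significant[m]
    }
  }
  structure(data.frame(nominal_dilution = dilutions,
                       expected_vaf = dilutions / 2,
                       observed_vaf = obs, detected = det),
            class = c("umivar_dilution", "data.frame"))
}

#' Track variants across longitudinal samples
#'
#' Builds per-variant VAF trajectories over ordered timepoints: the union
#' of keys significant at any timepoint is tracked at every timepoint (VAF
#' 0 when uncalled, with a separate coverage flag), and keys that are not
#' significant at baseline but become so later are flagged emergent.
#'
#' @param call_sets list (ordered by timepoint) of `umivar_calls`.
#' @param model an `umivar_background`.
#' @param alpha confidence mass (default the model's).
#' @param pileups optional list of `umivar_pileup` matching `call_sets`,
#'   used to mark whether an uncalled position was covered.
#' @return object of class `umivar_track`: data frame `trajectories` (one
#'   row per variant x timepoint: vaf, significant, covered, plus an
#'   `emergent` flag per variant).
#' @export
track_variants <- function(call_sets, model, alpha = NULL, pileups = NULL) {
  if (length(call_sets) < 2L) stop("tracking needs at least 2 timepoints")
  flagged <- lapply(call_sets, filter_variants, model = model, alpha = alpha)
  keys <- unique(do.call(rbind, lapply(flagged, function(cc)
    cc[cc$significant, c("chrom", "pos", "ref", "alt"), drop = FALSE])))
  if (!nrow(keys))
    return(structure(list(trajectories = data.frame(), n_timepoints =
                            length(call_sets)), class = "umivar_track"))
  rownames(keys) <- NULL
  kid <- key_id(keys$chrom, keys$pos, keys$ref, keys$alt)
  rows <- list()
  for (t in seq_along(flagged)) {
    cc <- flagged[[t]]
    m <- match(kid, key_id(cc$chrom, cc$pos, cc$ref, cc$alt))
    covered <- rep(NA, length(kid))
    if (!is.null(pileups)) {
      covered <- vapply(seq_along(kid), function(i) {
        loc <- locate_position(attr(call_sets[[t]], "panel") %||%
                                 attr(pileups[[t]], "panel"),
                               keys$chrom[i], keys$pos[i])
        if (is.null(loc)) return(FALSE)
        sum(pileups[[t]][[loc$probe]][1:4, loc$offset + 1L]) > 0
      }, logical(1))
    }
    covered[!is.na(m)] <- TRUE
    rows[[t]] <- data.frame(keys, timepoint = t,
                            vaf = ifelse(is.na(m), 0, cc$vaf[m]),
                            significant = !is.na(m) & cc$significant[m],
                            covered = covered, stringsAsFactors = FALSE)
  }
  traj <- do.call(rbind, rows)
  sig_mat <- matrix(traj$significant, nrow = nrow(keys))
  emergent <- !sig_mat[, 1] & rowSums(sig_mat[, -1, drop = FALSE]) > 0
  traj$emergent <- rep(emergent, length(call_sets))
  structure(list(trajectories = traj, n_timepoints = length(call_sets),
                 emergent = keys[emergent, , drop = FALSE]),
            class = "umivar_track")
}

#' @export
print.umivar_track <- function(x, ...) {
  nk <- if (nrow(x$trajectories)) nrow(x$trajectories) / x$n_timepoints else 0
  cat(sprintf("umivar variant tracking: %d variant(s) over %d timepoints; %d emergent\n",
              nk, x$n_timepoints,
              if (is.null(x$emergent)) 0L else nrow(x$emergent)))
  invisible(x)
}
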