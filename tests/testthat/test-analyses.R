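# simulate one sample and return its aligned consensus set
sim_aligned <- function(panel, cfg) {
  s <- simulate_library(panel, cfg)
  list(aligned = align_consensus(run_consensus(s$r1, s$r2), panel), sim = s)
}

test_that("phasing concentrates a haplotype-resident variant in its allele bin", {
  set.seed(91)
  panel <- make_panel(1)
  posS <- probe_positions(panel)[30]
  posV <- probe_positions(panel)[80]
  refS <- ref_base(panel, "chr1", posS); altS <- other_base(refS)
  refV <- ref_base(panel, "chr1", posV); altV <- other_base(refV)
  cfg <- sim_config(seed = 92, captures_per_probe = 2000L,
                    reads_per_capture_mean = 8, damage_rate = 0,
                    variants = data.frame(
                      chrom = "chr1", pos = c(posS, posV),
                      ref = c(refS, refV), alt = c(altS, altV),
                      vaf = c(0.5, 0.05), mode = c("germline", "exact"),
                      haplotype = 1L))
  al <- sim_aligned(panel, cfg)$aligned
  ph <- phase_by_het_snp(al, list(chrom = "chr1", pos = posS, ref = refS,
                                  alt = altS), panel)
  v <- ph$variants[ph$variants$pos == posV & ph$variants$alt == altV, ]
  expect_equal(nrow(v), 1L)
  # bin B carries the SNP alternate allele = haplotype 1 = the variant's home
  expect_gt(v$vaf_b, 1.5 * v$vaf_pooled)
  expect_lt(v$vaf_a, 0.2 * v$vaf_b)
  # phasing conservation identity, exact on counts
  expect_equal((v$sup_a + v$sup_b) / (v$cov_a + v$cov_b), v$vaf_pooled,
               tolerance = 1e-9)
  for (i in seq_len(nrow(ph$variants))) {
    w <- ph$variants[i, ]
    expect_equal((w$sup_a + w$sup_b) / (w$cov_a + w$cov_b), w$vaf_pooled,
                 tolerance = 1e-9)
  }
})

test_that("ex-vivo artifacts associate equally with both alleles", {
  set.seed(93)
  panel <- make_panel(1)
  posS <- probe_positions(panel)[30]
  refS <- ref_base(panel, "chr1", posS); altS <- other_base(refS)
  cfg <- sim_config(seed = 94, captures_per_probe = 3000L,
                    reads_per_capture_mean = 8, damage_rate = 2e-3,
                    variants = data.frame(chrom = "chr1", pos = posS,
                                          ref = refS, alt = altS, vaf = 0.5,
                                          mode = "germline", haplotype = 1L))
  al <- sim_aligned(panel, cfg)$aligned
  ph <- phase_by_het_snp(al, list(chrom = "chr1", pos = posS, ref = refS,
                                  alt = altS), panel)
  expect_gt(nrow(ph$variants), 3)
  # after BH control no artifact shows a significant allele bias
  expect_true(all(ph$variants$p_adj > 0.05, na.rm = TRUE))
})

test_that("a site without minor-allele captures cannot be used for phasing", {
  set.seed(95)
  panel <- make_panel(1)
  posS <- probe_positions(panel)[30]
  refS <- ref_base(panel, "chr1", posS)
  cfg <- sim_config(seed = 96, captures_per_probe = 200L, damage_rate = 0,
                    reads_per_capture_mean = 8)
  al <- sim_aligned(panel, cfg)$aligned
  expect_error(phase_by_het_snp(al, list(chrom = "chr1", pos = posS,
                                         ref = refS,
                                         alt = other_base(refS)), panel),
               "not heterozygous")
})

test_that("linked-SNP filtering removes exactly the haplotype-inconsistent reads", {
  set.seed(97)
  panel <- make_panel(1)
  posn <- probe_positions(panel)[c(20, 60, 100)]
  ref <- vapply(posn, function(p) ref_base(panel, "chr1", p), character(1))
  alt <- other_base(ref)
  snps <- data.frame(chrom = "chr1", pos = posn, ref = ref, alt = alt)
  cfg <- sim_config(seed = 98, captures_per_probe = 2500L,
                    reads_per_capture_mean = 8, damage_rate = 0,
                    variants = data.frame(chrom = "chr1", pos = posn,
                                          ref = ref, alt = alt, vaf = 0.5,
                                          mode = "germline", haplotype = 1L),
                    # contamination: the first SNP's alternate arising on
                    # haplotype-2 molecules as a pre-amplification artifact
                    hotspots = data.frame(chrom = "chr1", pos = posn[1],
                                          alt = alt[1], rate = 0.02))
  res <- sim_aligned(panel, cfg)
  al <- res$aligned
  lf <- linked_snp_filter(al, snps, panel)
  expect_gt(lf$n_discarded, 0)

  # retained reads carry all three alternates or none
  offs <- posn - panel$start[1]
  ret <- lf$retained
  cover <- ret$probe == 1L & ret$offset <= min(offs) &
    ret$offset + nchar(ret$seq) > max(offs)
  bases <- sapply(seq_along(offs), function(k)
    substr(ret$seq[cover], offs[k] - ret$offset[cover] + 1L,
           offs[k] - ret$offset[cover] + 1L))
  nalt <- rowSums(bases == matrix(alt, sum(cover), 3, byrow = TRUE))
  nref <- rowSums(bases == matrix(ref, sum(cover), 3, byrow = TRUE))
  expect_true(all(nalt == 3L | nref == 3L))

  # the contaminated SNP's VAF drops toward the true haplotype fraction
  expect_lt(lf$snp_vafs$vaf_after[1], lf$snp_vafs$vaf_before[1])

  # every discarded read traces to a recorded artifact (or an unresolved N)
  # in its capture at one of the SNP positions
  sim <- res$sim
  umis <- paste0(sim$molecules$captures$umi5, sim$molecules$captures$umi3)
  truth <- rbind(sim$molecules$truth[c("capture", "pos", "ref", "alt")],
                 sim$truth_pcr[c("capture", "pos", "ref", "alt")])
  truth <- truth[truth$pos %in% posn & truth$ref != truth$alt, ]
  disc <- lf$discarded
  for (i in seq_len(nrow(disc))) {
    cap <- match(substr(disc$barcode[i], 1, 24), umis)
    b <- vapply(seq_along(offs), function(k)
      substr(disc$seq[i], offs[k] - disc$offset[i] + 1L,
             offs[k] - disc$offset[i] + 1L), character(1))
    explained <- (!is.na(cap) && any(truth$capture == cap)) || any(b == "N")
    expect_true(explained)
  }
})

test_that("dilution-series recovery is linear down to rare frequencies", {
  set.seed(99)
  panel <- make_panel(1)
  pos <- probe_positions(panel)[50]
  ref <- ref_base(panel, "chr1", pos); alt <- other_base(ref)
  dil <- c(1, 1 / 5, 1 / 25, 1 / 125, 1 / 625)
  call_sets <- lapply(seq_along(dil), function(i) {
    cfg <- sim_config(seed = 990 + i, captures_per_probe = 10000L,
                      reads_per_capture_mean = 8,
                      variants = data.frame(chrom = "chr1", pos = pos,
                                            ref = ref, alt = alt,
                                            vaf = dil[i] / 2, mode = "exact"))
    sim_calls(panel, cfg)
  })
  ctl <- lapply(1:2, function(i)
    sim_calls(panel, sim_config(seed = 996 + i, captures_per_probe = 10000L,
                                reads_per_capture_mean = 8)))
  bg <- fit_background(ctl, panel)
  dp <- evaluate_dilution(call_sets, list(chrom = "chr1", pos = pos,
                                          ref = ref, alt = alt), dil, bg)
  expect_equal(dp$expected_vaf[1], 0.5)           # undiluted heterozygote
  expect_equal(dp$expected_vaf[dil == 1 / 625], 8e-4)
  expect_true(all(dp$detected))
  fit <- lm(log10(observed_vaf) ~ log10(expected_vaf), data = dp)
  expect_lt(abs(unname(coef(fit)[2]) - 1), 0.1)
  expect_lt(max(abs(log10(dp$observed_vaf / dp$expected_vaf))), 0.15)
})

test_that("variant tracking flags emergent clones and holds constant ones flat", {
  set.seed(101)
  panel <- make_panel(1)
  pos <- probe_positions(panel)[c(20, 70)]
  ref <- vapply(pos, function(p) ref_base(panel, "chr1", p), character(1))
  alt <- other_base(ref)
  # timepoints: constant 5% clone at key 1; key 2 emerges at t3
  mk <- function(vafs) synthetic_calls(panel, pos[vafs > 0], ref[vafs > 0],
                                       alt[vafs > 0], vafs[vafs > 0])
  sets <- list(mk(c(0.05, 0)), mk(c(0.05, 0)), mk(c(0.05, 0.02)))
  ctl <- lapply(1:2, function(i) synthetic_calls(panel, integer(0),
                                                 character(0), character(0),
                                                 numeric(0)))
  bg <- fit_background(ctl, panel)
  for (s in sets) attr(s, "panel") <- panel
  tr <- track_variants(sets, bg)
  traj <- tr$trajectories
  k1 <- traj[traj$pos == pos[1], ]
  expect_equal(k1$vaf, rep(0.05, 3))
  expect_false(any(k1$emergent))
  k2 <- traj[traj$pos == pos[2], ]
  expect_equal(k2$vaf, c(0, 0, 0.02))
  expect_true(all(k2$emergent))
  expect_equal(nrow(tr$emergent), 1L)

  # a simulated selective sweep is recovered as a monotone trajectory
  sweep_sets <- lapply(c(0, 0.01, 0.2), function(v) {
    cfg <- sim_config(seed = 1010 + round(v * 1000),
                      captures_per_probe = 5000L, reads_per_capture_mean = 8,
                      variants = if (v > 0)
                        data.frame(chrom = "chr1", pos = pos[1], ref = ref[1],
                                   alt = alt[1], vaf = v, mode = "exact")
                      else NULL)
    sim_calls(panel, cfg)
  })
  tr2 <- track_variants(sweep_sets, bg)
  t2 <- tr2$trajectories
  kv <- t2[t2$pos == pos[1] & t2$alt == alt[1], ]
  expect_equal(nrow(kv), 3L)
  expect_true(all(diff(kv$vaf) > 0))
  expect_equal(kv$vaf[1], 0)
  expect_true(all(kv$emergent))
})
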