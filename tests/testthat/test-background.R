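# shared small simulation: damage-driven background libraries
damage_calls <- function(panel, seed, damage = 2e-3, ct_bias = 8,
                         captures = 3000L, variants = NULL, hotspots = NULL) {
  cfg <- sim_config(seed = seed, captures_per_probe = captures,
                    reads_per_capture_mean = 8, damage_rate = damage,
                    ct_bias = ct_bias, variants = variants,
                    hotspots = hotspots)
  sim_calls(panel, cfg)
}

test_that("alpha helpers and t interval endpoints match frozen references", {
  expect_equal(alpha_from_nines(1), 0.9)
  expect_equal(alpha_from_nines(15), 0.999999999999999)
  # textbook t interval for control VAFs [0.001,0.002,0.0015,0.0012,0.0008]
  v <- c(0.001, 0.002, 0.0015, 0.0012, 0.0008)
  ep <- ci_endpoints(mean(v), sd(v), 4L, 0.99)
  expect_equal(ep$high, 0.003459511914, tolerance = 1e-9)
  expect_equal(ep$low, 0)  # floored: mean - 4.604 sd < 0
  # df=4, loc 0.001, scale 5e-4, alpha .95: loc +- 2.776445 scale
  ep2 <- ci_endpoints(0.001, 5e-4, 4L, 0.95)
  expect_equal(ep2$high, 0.002388222553, tolerance = 1e-9)
  expect_equal(ep2$low, 0)
  # zero scale collapses to the location at any alpha
  ep3 <- ci_endpoints(0.001, 0, 4L, 0.999999)
  expect_equal(ep3$low, 0.001)
  expect_equal(ep3$high, 0.001)
  expect_error(ci_endpoints(0.001, 5e-4, 4L, 1), "strictly between")
})

test_that("interval nesting: larger alpha strictly contains smaller", {
  set.seed(71)
  for (i in 1:20) {
    loc <- runif(1, 0, 0.01)
    sc <- runif(1, 1e-5, 1e-3)
    df <- sample(2:9, 1)
    a1 <- runif(1, 0.5, 0.9)
    a2 <- runif(1, 0.91, 0.9999)
    e1 <- ci_endpoints(loc, sc, df, a1)
    e2 <- ci_endpoints(loc, sc, df, a2)
    expect_lt(e1$high, e2$high)
    expect_gte(e1$low, e2$low)
  }
})

test_that("positional fitting zero-fills absent controls and drops outliers", {
  set.seed(72)
  panel <- make_panel(1)
  pos <- probe_positions(panel)[c(10, 30)]
  ref <- vapply(pos, function(p) ref_base(panel, "chr1", p), character(1))
  alt <- other_base(ref)
  # key 1 in all five controls at the same VAF; key 2 in one control only
  ctl <- lapply(1:5, function(i) {
    if (i == 1) synthetic_calls(panel, pos, ref, alt, c(0.001, 0.002))
    else synthetic_calls(panel, pos[1], ref[1], alt[1], 0.001)
  })
  bg0 <- fit_background(ctl, panel, alpha = 0.99, outlier_drop = 0L)
  k1 <- bg0$positions[bg0$positions$pos == pos[1], ]
  expect_equal(k1$n, 5L)
  expect_equal(k1$location, 0.001)
  expect_equal(k1$scale, 0)           # identical VAFs: degenerate interval
  expect_equal(k1$low, 0.001)
  expect_equal(k1$high, 0.001)
  k2 <- bg0$positions[bg0$positions$pos == pos[2], ]
  expect_equal(k2$location, mean(c(0.002, 0, 0, 0, 0)))  # zero-filled
  # outlier drop removes the single non-zero observation of key 2
  bg1 <- fit_background(ctl, panel, alpha = 0.99, outlier_drop = 1L)
  k2d <- bg1$positions[bg1$positions$pos == pos[2], ]
  expect_equal(k2d$location, 0)
  expect_equal(k2d$n, 4L)
  # keys never seen in controls stay out of the positional table
  expect_false(any(bg0$positions$pos == pos[1] & bg0$positions$alt == "N"))
  expect_error(fit_background(ctl[1], panel), "insufficient controls")
})

test_that("the generic model has at most 96 collapsed context classes", {
  set.seed(73)
  panel <- make_panel(4)
  ctl <- lapply(1:3, function(i)
    synthetic_calls(panel, probe_positions(panel)[5 + i],
                    ref_base(panel, "chr1", probe_positions(panel)[5 + i]),
                    other_base(ref_base(panel, "chr1",
                                        probe_positions(panel)[5 + i])), 1e-3))
  bg <- fit_background(ctl, panel)
  expect_lte(nrow(bg$generic), 96L)
  expect_true(all(grepl("^[ACGT]{3}>[ACGT]$", bg$generic$class)))
  # collapsed classes are keyed on the pyrimidine strand
  centers <- substr(bg$generic$class, 2, 2)
  expect_true(all(centers %in% c("C", "T")))
})

test_that("C>T-biased damage raises C>T class locations above T>G", {
  set.seed(74)
  panel <- make_panel(1)
  ctl <- lapply(1:2, function(i) damage_calls(panel, seed = 740 + i))
  bg <- fit_background(ctl, panel)
  g <- bg$generic
  sub_of <- paste0(substr(g$class, 2, 2), ">", substr(g$class, 5, 5))
  ct <- g$location[sub_of == "C>T"]
  tg <- g$location[sub_of == "T>G"]
  expect_gt(mean(ct), mean(tg))
})

test_that("significance filtering uses positional keys first, then the fallback", {
  set.seed(75)
  panel <- make_panel(1)
  pos <- probe_positions(panel)[c(10, 30)]
  ref <- vapply(pos, function(p) ref_base(panel, "chr1", p), character(1))
  alt <- other_base(ref)
  ctl <- lapply(1:5, function(i)
    synthetic_calls(panel, pos[1], ref[1], alt[1],
                    0.001 + 0.0002 * i))
  bg <- fit_background(ctl, panel, alpha = 0.99, outlier_drop = 0L)
  test_calls <- synthetic_calls(panel, pos, ref, alt, c(0.01, 0.01))
  fc <- filter_variants(test_calls, bg)
  expect_equal(fc$significance, c("positional", "generic"))
  expect_true(all(fc$significant))
  # below the positional high endpoint: not significant
  low_call <- synthetic_calls(panel, pos[1], ref[1], alt[1], 0.0015)
  expect_false(filter_variants(low_call, bg)$significant)
})

test_that("significant-call counts decrease monotonically over an alpha sweep", {
  set.seed(76)
  panel <- make_panel(1)
  ctl <- lapply(1:5, function(i) damage_calls(panel, seed = 760 + i))
  test_calls <- damage_calls(panel, seed = 766)
  bg <- fit_background(ctl, panel)
  alphas <- alpha_from_nines(1:15)
  counts <- vapply(alphas, function(a)
    attr(filter_variants(test_calls, bg, alpha = a), "filter_counts")$n_significant,
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("each control filtered against a leave-one-out background loses its calls as alpha grows", {
  set.seed(77)
  panel <- make_panel(1)
  ctl <- lapply(1:5, function(i) damage_calls(panel, seed = 770 + i))
  # outlier_drop 0: dropping the top VAF of a key seen in a single control
  # would collapse it to a zero-scale point mass that never widens with alpha
  bgs <- lapply(1:5, function(i) fit_background(ctl[-i], panel,
                                                outlier_drop = 0L))
  resid <- function(a) sum(vapply(1:5, function(i)
    attr(filter_variants(ctl[[i]], bgs[[i]], alpha = a),
         "filter_counts")$n_significant, numeric(1)))
  rr <- vapply(alpha_from_nines(1:15), resid, numeric(1))
  expect_true(all(diff(rr) <= 0))
  # residuals shrink substantially; calls of classes the other controls never
  # exhibited stay flagged at any stringency (no spread to widen)
  expect_lte(rr[15], rr[1] / 2)
})

test_that("positional filtering beats the generic model under position-specific error", {
  set.seed(78)
  panel <- make_panel(4)
  # two damage hotspots per probe, spread over contexts, C>T type
  hot <- unlist(lapply(1:4, function(p) {
    cp <- probe_positions(panel, p, base = "C")
    cp[c(5, length(cp) - 4)]
  }))
  hotspots <- data.frame(chrom = "chr1", pos = hot, alt = "T",
                         rate = c(0.03, 0.01, 0.005, rep(0.002, 5)))
  tpos <- probe_positions(panel, 2, base = "T")[7]
  spike <- data.frame(chrom = "chr1", pos = tpos, ref = "T", alt = "G",
                      vaf = 5e-3, mode = "exact")
  ctl <- lapply(1:5, function(i)
    damage_calls(panel, seed = 780 + i, damage = 1e-5, captures = 3000L,
                 hotspots = hotspots))
  test_calls <- damage_calls(panel, seed = 786, damage = 1e-5,
                             captures = 3000L, hotspots = hotspots,
                             variants = spike)
  bg_pos <- fit_background(ctl, panel, kind = "positional")
  bg_gen <- fit_background(ctl, panel, kind = "generic")
  a <- 0.999
  fp <- function(fc) sum(fc$significant & fc$pos %in% hot & fc$alt == "T")
  tp <- function(fc) sum(fc$significant & fc$pos == tpos & fc$alt == "G")
  fc_pos <- filter_variants(test_calls, bg_pos, alpha = a)
  fc_gen <- filter_variants(test_calls, bg_gen, alpha = a)
  expect_lt(fp(fc_pos), fp(fc_gen))   # fewer false positives
  expect_gte(tp(fc_pos), tp(fc_gen))  # no fewer true positives
  expect_equal(tp(fc_pos), 1L)
})

test_that("spectra are normalized and reflect the injected substitution bias", {
  set.seed(79)
  panel <- make_panel(1)
  # a single C>T call: spectrum is 100% C>T
  cpos <- probe_positions(panel, base = "C")[1]
  one <- synthetic_calls(panel, cpos, "C", "T", 0.01)
  sp1 <- mutation_spectrum(one)
  expect_equal(unname(sp1$classes["C>T"]), 1)
  # uniform damage: six classes near 1/6 each
  unif <- damage_calls(panel, seed = 790, damage = 6e-3, ct_bias = 1)
  spu <- mutation_spectrum(unif)
  expect_equal(sum(spu$classes), 1, tolerance = 1e-9)
  expect_equal(length(spu$classes), 6L)
  n <- nrow(unif)
  for (cl in names(spu$classes))
    expect_lt(abs(spu$classes[[cl]] - 1 / 6),
              4 * sqrt(1 / 6 * 5 / 6 / n) + 0.02)
  # C>T-biased damage: C>T is the plurality class
  bias <- damage_calls(panel, seed = 791, damage = 6e-3, ct_bias = 8)
  spb <- mutation_spectrum(bias)
  expect_equal(names(which.max(spb$classes)), "C>T")
  # the bias suppresses the other changes from the same pyrimidine
  getcl <- function(cl) if (cl %in% names(spb$classes)) spb$classes[[cl]] else 0
  expect_gt(spb$classes[["C>T"]], 4 * getcl("C>A"))
  expect_gt(spb$classes[["C>T"]], 4 * getcl("C>G"))
  expect_equal(sum(spb$contexts), 1, tolerance = 1e-9)
})

test_that("background models survive serialization", {
  set.seed(80)
  panel <- make_panel(1)
  pos <- probe_positions(panel)[c(10, 30)]
  ref <- vapply(pos, function(p) ref_base(panel, "chr1", p), character(1))
  ctl <- lapply(1:4, function(i)
    synthetic_calls(panel, pos, ref, other_base(ref),
                    c(0.001, 0.002) * i / 2))
  bg <- fit_background(ctl, panel, alpha = 0.999)
  d <- withr::local_tempdir()
  write_background(bg, file.path(d, "bg"))
  back <- read_background(file.path(d, "bg"))
  expect_equal(back$alpha, bg$alpha)
  expect_equal(back$kind, bg$kind)
  expect_equal(back$positions$location, bg$positions$location)
  expect_equal(back$generic$high, bg$generic$high)
  # a reloaded model filters identically
  calls <- synthetic_calls(panel, pos[1], ref[1], other_base(ref[1]), 0.02)
  expect_equal(filter_variants(calls, back)$significant,
               filter_variants(calls, bg)$significant)
})
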