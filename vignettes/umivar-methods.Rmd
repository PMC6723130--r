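---
title: "umivar: consensus calling and background filtering for ultra-rare variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{umivar: consensus calling and background filtering for ultra-rare variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umivar)
```

## The problem

Somatic mutations present in a fraction of 1/1,000 to 1/10,000 of the cells
of a sample — nascent clonal expansions, minimal residual disease after
leukemia therapy — sit far below the raw error floor of Illumina sequencing.
Three error processes dominate a targeted amplicon library: per-base
sequencing errors (~10^-3^), polymerase errors during PCR amplification, and
chemical damage to the template DNA incurred before or during the first
round of amplification (oxidation, deamination), which is carried by every
subsequent copy of that molecule and is indistinguishable from a real
variant within its capture.

`umivar` implements a two-layer defence. First, molecule-level consensus:
every captured template strand carries a 12-bp unique molecular identifier
(UMI) at each end, reads are paired-end sequenced with complete overlap, and
all reads from one capture are collapsed into a single consensus sequence.
Second, an empirical background model: the variant allele frequencies (VAFs)
that *control* samples exhibit at every probed position, for every
substitution, are modelled as Student's t distributions, and a test-sample
call is only accepted when its VAF rises above the alpha-confidence envelope
of the matching background distribution.

## The consensus layer

1. **Mate merging.** Read 2 is reverse-complemented and compared to Read 1
   base by base; any disagreement (or N) is masked to N rather than the pair
   being discarded. A sequencing error survives merging only if the *same*
   change hits the *same* position in both mates (probability ≈ e²/3 per
   site — about 3×10^-8^ at e = 10^-3^).
2. **Barcoding.** Each merged read is keyed by its 5′ UMI + 3′ UMI + the
   first five insert bases (29 informative characters). Reads join bins
   greedily in descending-support order, tolerating one barcode mismatch
   (an N compares as a mismatch against any real base).
3. **Collapsing.** A bin with fewer than `min_reads = 5` members is
   discarded. At each position the most common non-N base is emitted only
   if it is supported by at least `agreement = 0.75` of *all* members; ties
   and weaker majorities yield N, and alignment proceeds with the unknown
   base.

The thresholds interlock with the PCR error arithmetic: an error arising in
amplification round *k* ≥ 1 of a capture is carried by ~2^-k^ of its reads
(50% for round 1, 25% for round 2, ...), so every post-round-0 polymerase
error falls below the 75% agreement bar and is masked or out-voted.
Template-damage (round-0) errors are present in ~100% of the bin and
*survive* consensus by design — no collapsing scheme can remove them. They
are eliminated by the next layer: a substitution must be observed in at
least `min_capture_support = 5` independent captures to be called at all,
and independent single-molecule lesions recurring five times at the same
(position, alternate) key are exponentially unlikely across a multi-probe
panel.

## The background model

For control samples 1..n and every (position, substitution) key observed in
any control, the control VAFs v₁..vₙ (zero-filled where a control lacks the
call, so absence counts as evidence of a low error rate and the degrees of
freedom stay constant) define a location-scale t distribution:

* df = n − 1, location = mean(v), scale = sd(v);
* the central interval holding probability mass α is
  location ± t₍(1+α)/2, df₎ · scale, floored at 0;
* a test call is **significant** iff its VAF exceeds the *high* endpoint.
  The low endpoint is computed and stored for diagnostics but plays no role
  in calling — there is no "below background" test.

Two cleaning steps precede fitting: control VAFs above
`germline_vaf_ceiling = 0.25` are removed (germline heterozygotes are not
background), and the `outlier_drop = 1` highest remaining values per key are
removed so that any true mutations present in a control do not inflate its
background.

Keys the positional table has never seen are governed by a **generic
fallback**: control VAFs pooled by pyrimidine-collapsed (trinucleotide
context, alternate) class — at most 96 classes — across every probed
position, zero-filled the same way. Calls flagged through the fallback carry
a distinct `significance = "generic"` label. A context-only model
(`kind = "generic"`) is available for comparison; on simulations with
position-heterogeneous error rates the positional model yields strictly
fewer false positives at equal alpha, which is the package's motivating
property.

Stringency is conveniently swept as a count of trailing nines
(`alpha_from_nines(1)` = 0.9 ... `alpha_from_nines(15)` = fifteen nines);
significant-call counts are non-increasing along the sweep because the
t intervals are nested.

### Numerical and degenerate-case choices

* Identical control VAFs give scale 0: the interval collapses to the
  location at every alpha. A key reduced to all zeros (e.g. a key seen in
  one control whose single value is then outlier-dropped) therefore flags
  *any* observation at *any* alpha. This is a real property of the
  estimator, not a bug: the model has seen nothing at that key and has no
  spread to widen. The practical consequence, visible in the leave-one-out
  analysis below, is a residual floor of calls from classes the other
  controls never exhibited. When sweeping alpha on sparse backgrounds,
  `outlier_drop = 0` avoids manufacturing such point masses.
* The agreement denominator includes N-bearing members (conservative: an
  uncertain member weakens, never strengthens, a base call).
* Consensus ties (e.g. 5A/5G of 10) give N regardless of the threshold.
* The confidence interval is central (two-sided) with only the high
  endpoint used for calling; a one-sided bound at the same alpha would be
  slightly tighter, and the stored parameters allow either to be derived.
* Alignment is seed-and-verify: every N-free 20-mer of a consensus read is
  looked up in a k-mer index of the panel (both orientations), and implied
  placements are verified by Hamming comparison with N excluded, accepting
  at most 10 mismatches. For a panel of ~150 bp known amplicons this is
  exact, deterministic and dependency-free. A read whose mismatches are
  spread so that no 20-mer window is clean (>6 well-spread errors) is
  rejected and QC-counted, as is anything captured outside the panel.
* N bases never support reference or alternate and leave the VAF
  denominator entirely.

## The simulator

`simulate_library()` emulates the library preparation molecule by molecule:

* diploid templates: each capture draws haplotype 1 or 2 with probability
  ½ and receives two fresh random 12-mers as UMIs;
* injected variants: `somatic` carriers are Binomial(captures, VAF) within
  the assigned haplotype; `germline` variants are carried by every molecule
  of their haplotype (so multiple SNPs on one haplotype are genuinely
  linked, which the linked-SNP filter requires); `exact` spikes carry
  round(captures × VAF) molecules and are used by the sensitivity and
  dilution benchmarks so that detection measures the pipeline rather than
  the binomial draw on a handful of carriers;
* pre-amplification damage: each template base is hit with probability
  `damage_rate` (default 2×10^-5^), with optional per-position hotspots;
  damaged bases appear in every read of the capture;
* PCR: the template is copied once (round 1), then the pool doubles for
  `pcr_cycles = 29` rounds with per-base, per-copy error probability
  `pcr_error_rate` (default 10^-6^), so a round-k error reaches 2^-k^ of
  the pool; after each round the pool is subsampled uniformly to
  `pcr_pop_cap = 512` strands, which keeps 29 cycles tractable while
  preserving lineage fractions in expectation;
* C>T bias: artifact substitutions at C (and G) are weighted toward C>T
  (G>A) by `ct_bias = 8`, giving the C>T-dominated spectra characteristic
  of amplicon background;
* reads: Poisson(`reads_per_capture_mean`) fully overlapping 150 bp pairs
  per capture, independent per-base sequencing errors at
  `seq_error_rate = 10^-3` per mate, constant placeholder qualities (the
  pipeline never reads quality scores).

Every molecule, round-resolved PCR error and injected lesion is recorded,
so tests can trace any output base to its cause. Fixed seed gives
byte-identical FASTQ.

What the simulator does **not** emulate — and what passing tests therefore
do not establish about real libraries: probe-to-probe capture-efficiency
variation (real panels show several-fold spread), indel errors, quality
degradation along the read, strand-asymmetric damage chemistry, barcode
collisions from non-uniform UMI synthesis, and epigenomic context effects
beyond the trinucleotide. Real backgrounds are also far denser than the
default desk-scale damage rate produces; position-specific structure is
emulated explicitly through hotspots where tests need it.

## Study sizes used by the tests and the acceptance script

Chosen once as desk-scale versions of the method's operating point: the
spike-detection study uses one probe with 50,000 captures at ~10 reads per
capture (~500k read pairs) and ten control libraries of 20,000 captures
each — background resolution is capture-limited, and 20,000 captures bound
a control's VAF granularity at 2.5×10^-4^ while keeping the eleven-sample
study inside a few minutes. The first-round-error study uses the method's
native geometry, 32 probes and ~30,000 captures total, because 400 errors
concentrated on a single probe's ~378 keys would recur five-fold by
birthday collision and no support rule could remove them; spread over the
~12,000 keys of a 32-probe panel, recurrence is vanishingly rare, which is
precisely the argument for the ≥5-capture rule. The dilution series spans
1 to 1/625 of a heterozygote at 10,000 captures per point.

## Known limitations

* Indels are neither simulated nor background-filtered; substitutions only.
* The generic fallback pools over all probed positions including the ~12%
  of each region outside the sequenced insert, slightly diluting class
  locations toward zero (conservative in the significance direction).
* Keys whose background is a point mass at zero are flagged at every
  alpha (see above); with 5–10 controls this concerns sporadic,
  weakly-recurrent artifacts.
* Detection at VAF 10^-4^ requires ≥5 carrier molecules among the captures
  and a per-position background location well below 10^-4^; at positions
  with a high background the same spike is correctly reported as
  not-significant.
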