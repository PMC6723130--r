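#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// ---------- small utilities ----------

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_str(as<std::string>(x[i]));
  }
  return out;
}

// Random DNA strings drawn from the R RNG (deterministic under set.seed()).
// [[Rcpp::export]]
CharacterVector random_dna_cpp(int n, int len) {
  static const char* bases = "ACGT";
  CharacterVector out(n);
  std::string s(len, 'A');
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < len; ++j)
      s[j] = bases[(int)(unif_rand() * 4.0) & 3];
    out[i] = s;
  }
  return out;
}

// Hamming distance; positions where either sequence is 'N' are skipped when
// ignore_n is true, otherwise compared literally.
// [[Rcpp::export]]
int hamming_cpp(std::string a, std::string b, bool ignore_n = false) {
  if (a.size() != b.size()) stop("sequences differ in length");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    if (ignore_n && (a[i] == 'N' || b[i] == 'N')) continue;
    if (a[i] != b[i]) ++d;
  }
  return d;
}

// ---------- PCR branching process ----------

// A strand lineage class: mutations relative to the capture template,
// applied in order of occurrence.
struct MutClass {
  std::vector<int>  pos;
  std::vector<char> alt;
  int count;
};

struct ErrRec { int round; int pos; char ref; char alt; };

static inline char class_base_at(const std::string& tmpl, const MutClass& cl, int p) {
  char b = tmpl[p];
  for (size_t i = 0; i < cl.pos.size(); ++i)
    if (cl.pos[i] == p) b = cl.alt[i];
  return b;
}

// Pick a substitution for base `ref`: C->T and G->A receive weight ct_bias,
// all other substitutions weight 1.
static inline char pick_alt(char ref, double ct_bias) {
  static const char* bases = "ACGT";
  double w[4], tot = 0.0;
  for (int i = 0; i < 4; ++i) {
    if (bases[i] == ref) { w[i] = 0.0; continue; }
    w[i] = 1.0;
    if ((ref == 'C' && bases[i] == 'T') || (ref == 'G' && bases[i] == 'A'))
      w[i] = ct_bias;
    tot += w[i];
  }
  double u = unif_rand() * tot;
  for (int i = 0; i < 4; ++i) {
    u -= w[i];
    if (u <= 0.0 && w[i] > 0.0) return bases[i];
  }
  return ref == 'A' ? 'C' : 'A'; // unreachable
}

// Core branching process for one capture.
//
// Pool model: the captured template strand (round-0 mutations already baked
// into `tmpl` by the caller) is copied once in round 1; the copy acquires
// round-1 errors. Rounds 2..cycles double the pool, each copy mutating with
// per-copy probability 1-(1-rate)^L. A round-k error therefore ends up in a
// fraction 2^-k of the final pool under perfect doubling. The pool is capped
// by uniform (multivariate hypergeometric) subsampling after each round.
static void run_pcr(const std::string& tmpl, int cycles, double rate,
                    double ct_bias, int cap,
                    const std::vector<ErrRec>& inject,
                    std::vector<MutClass>& classes,
                    std::vector<ErrRec>& errors) {
  const int L = (int)tmpl.size();
  const double p_err = 1.0 - std::pow(1.0 - rate, (double)L);
  classes.clear();
  classes.push_back(MutClass{{}, {}, 1});

  // round 1: single copy of the template
  {
    MutClass b{{}, {}, 1};
    int m = (int)R::rbinom(L, rate);
    for (int j = 0; j < m; ++j) {
      int p = (int)(unif_rand() * L); if (p >= L) p = L - 1;
      char ref = class_base_at(tmpl, b, p);
      char alt = pick_alt(ref, ct_bias);
      b.pos.push_back(p); b.alt.push_back(alt);
      errors.push_back(ErrRec{1, p, ref, alt});
    }
    for (size_t k = 0; k < inject.size(); ++k) {
      if (inject[k].round != 1) continue;
      char ref = class_base_at(tmpl, b, inject[k].pos);
      b.pos.push_back(inject[k].pos); b.alt.push_back(inject[k].alt);
      errors.push_back(ErrRec{1, inject[k].pos, ref, inject[k].alt});
    }
    if (b.pos.empty()) classes[0].count = 2; else classes.push_back(b);
  }

  std::vector<int> precnt;
  for (int r = 2; r <= cycles; ++r) {
    size_t ncls = classes.size();
    precnt.resize(ncls);
    long total = 0;
    for (size_t i = 0; i < ncls; ++i) { precnt[i] = classes[i].count; total += precnt[i]; }

    for (size_t i = 0; i < ncls; ++i) {
      int n = precnt[i];
      int m = (p_err > 0.0 && n > 0) ? (int)R::rbinom(n, p_err) : 0;
      classes[i].count += n - m;
      for (int j = 0; j < m; ++j) {
        MutClass nc = classes[i]; nc.count = 1;
        int p = (int)(unif_rand() * L); if (p >= L) p = L - 1;
        char ref = class_base_at(tmpl, nc, p);
        char alt = pick_alt(ref, ct_bias);
        nc.pos.push_back(p); nc.alt.push_back(alt);
        errors.push_back(ErrRec{r, p, ref, alt});
        classes.push_back(nc);
      }
    }
    // forced injections created during this round: one randomly chosen copy
    for (size_t k = 0; k < inject.size(); ++k) {
      if (inject[k].round != r) continue;
      double u = unif_rand() * (double)total;
      size_t idx = 0;
      for (size_t i = 0; i < ncls; ++i) { u -= precnt[i]; if (u <= 0.0) { idx = i; break; } }
      if (classes[idx].count > precnt[idx]) classes[idx].count -= 1;
      MutClass nc = classes[idx]; nc.count = 1;
      char ref = class_base_at(tmpl, nc, inject[k].pos);
      nc.pos.push_back(inject[k].pos); nc.alt.push_back(inject[k].alt);
      errors.push_back(ErrRec{r, inject[k].pos, ref, inject[k].alt});
      classes.push_back(nc);
    }

    long newtot = 0;
    for (size_t i = 0; i < classes.size(); ++i) newtot += classes[i].count;
    if (cap > 0 && newtot > cap) {
      long rem_pop = newtot; int rem_draw = cap;
      for (size_t i = 0; i < classes.size(); ++i) {
        int ci = classes[i].count;
        int take = (rem_draw <= 0) ? 0 :
          (int)R::rhyper((double)ci, (double)(rem_pop - ci), (double)rem_draw);
        classes[i].count = take;
        rem_draw -= take; rem_pop -= ci;
      }
      // drop extinct lineages
      std::vector<MutClass> keep;
      for (size_t i = 0; i < classes.size(); ++i)
        if (classes[i].count > 0) keep.push_back(classes[i]);
      classes.swap(keep);
    }
  }
}

static std::string class_seq(const std::string& tmpl, const MutClass& cl) {
  std::string s = tmpl;
  for (size_t i = 0; i < cl.pos.size(); ++i) s[cl.pos[i]] = cl.alt[i];
  return s;
}

// PCR pool for a single capture; exposed for the module-level simulate_pcr()
// and for deterministic branching tests.
// [[Rcpp::export]]
List sim_pcr_pool_cpp(std::string tmpl, int cycles, double pcr_error_rate,
                      double ct_bias, int cap,
                      IntegerVector inj_round, IntegerVector inj_pos,
                      CharacterVector inj_alt) {
  std::vector<ErrRec> inject;
  for (int k = 0; k < inj_round.size(); ++k)
    inject.push_back(ErrRec{inj_round[k], inj_pos[k], 'N',
                            as<std::string>(inj_alt[k])[0]});
  std::vector<MutClass> classes;
  std::vector<ErrRec> errors;
  run_pcr(tmpl, cycles, pcr_error_rate, ct_bias, cap, inject, classes, errors);

  int nc = (int)classes.size();
  CharacterVector seqs(nc); IntegerVector counts(nc);
  for (int i = 0; i < nc; ++i) {
    seqs[i] = class_seq(tmpl, classes[i]);
    counts[i] = classes[i].count;
  }
  int ne = (int)errors.size();
  IntegerVector er(ne), ep(ne); CharacterVector eref(ne), ealt(ne);
  for (int i = 0; i < ne; ++i) {
    er[i] = errors[i].round; ep[i] = errors[i].pos;
    eref[i] = std::string(1, errors[i].ref); ealt[i] = std::string(1, errors[i].alt);
  }
  return List::create(_["seq"] = seqs, _["count"] = counts,
                      _["err_round"] = er, _["err_pos"] = ep,
                      _["err_ref"] = eref, _["err_alt"] = ealt);
}

static void apply_seq_errors(std::string& s, double rate) {
  if (rate <= 0.0) return;
  static const char* bases = "ACGT";
  int L = (int)s.size();
  int m = (int)R::rbinom(L, rate);
  for (int j = 0; j < m; ++j) {
    int p = (int)(unif_rand() * L); if (p >= L) p = L - 1;
    char cur = s[p];
    char nb;
    do { nb = bases[(int)(unif_rand() * 4.0) & 3]; } while (nb == cur);
    s[p] = nb;
  }
}

// Fused PCR + read emission over all captures (the fast path used by
// simulate_library()). Templates carry round-0 mutations already.
// [[Rcpp::export]]
List sim_emit_cpp(CharacterVector templates, CharacterVector umi5,
                  CharacterVector umi3,
                  IntegerVector inj_capture, IntegerVector inj_round,
                  IntegerVector inj_pos, CharacterVector inj_alt,
                  int cycles, double pcr_error_rate, double ct_bias, int cap,
                  double reads_mean, double seq_error_rate) {
  int ncap = templates.size();

  // group forced injections by capture (1-based capture ids)
  std::vector<std::vector<ErrRec>> inj(ncap);
  for (int k = 0; k < inj_capture.size(); ++k)
    inj[inj_capture[k] - 1].push_back(
      ErrRec{inj_round[k], inj_pos[k], 'N', as<std::string>(inj_alt[k])[0]});

  std::vector<std::string> r1, r2;
  std::vector<int> read_cap;
  std::vector<int> e_cap, e_round, e_pos;
  std::vector<char> e_ref, e_alt;
  std::vector<int> nreads_per_cap(ncap);

  std::vector<MutClass> classes;
  std::vector<ErrRec> errors;
  for (int c = 0; c < ncap; ++c) {
    std::string tmpl = as<std::string>(templates[c]);
    errors.clear();
    run_pcr(tmpl, cycles, pcr_error_rate, ct_bias, cap, inj[c], classes, errors);
    for (size_t i = 0; i < errors.size(); ++i) {
      e_cap.push_back(c + 1); e_round.push_back(errors[i].round);
      e_pos.push_back(errors[i].pos); e_ref.push_back(errors[i].ref);
      e_alt.push_back(errors[i].alt);
    }
    long total = 0;
    for (size_t i = 0; i < classes.size(); ++i) total += classes[i].count;
    int nr = (int)R::rpois(reads_mean);
    nreads_per_cap[c] = nr;
    if (nr == 0 || total == 0) continue;

    std::string u5 = as<std::string>(umi5[c]);
    std::string u3 = as<std::string>(umi3[c]);
    std::vector<std::string> cache(classes.size());
    for (int j = 0; j < nr; ++j) {
      double u = unif_rand() * (double)total;
      size_t idx = 0;
      for (size_t i = 0; i < classes.size(); ++i) { u -= classes[i].count; if (u <= 0.0) { idx = i; break; } }
      if (cache[idx].empty()) cache[idx] = u5 + class_seq(tmpl, classes[idx]) + u3;
      std::string m1 = cache[idx];
      std::string m2 = revcomp_str(m1);
      apply_seq_errors(m1, seq_error_rate);
      apply_seq_errors(m2, seq_error_rate);
      r1.push_back(m1); r2.push_back(m2);
      read_cap.push_back(c + 1);
    }
    if ((c & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  int nr = (int)r1.size(), ne = (int)e_cap.size();
  CharacterVector R1(nr), R2(nr); IntegerVector RC(nr);
  for (int i = 0; i < nr; ++i) { R1[i] = r1[i]; R2[i] = r2[i]; RC[i] = read_cap[i]; }
  IntegerVector EC(ne), ER(ne), EP(ne); CharacterVector EF(ne), EA(ne);
  for (int i = 0; i < ne; ++i) {
    EC[i] = e_cap[i]; ER[i] = e_round[i]; EP[i] = e_pos[i];
    EF[i] = std::string(1, e_ref[i]); EA[i] = std::string(1, e_alt[i]);
  }
  return List::create(_["r1"] = R1, _["r2"] = R2, _["capture"] = RC,
                      _["err_capture"] = EC, _["err_round"] = ER,
                      _["err_pos"] = EP, _["err_ref"] = EF, _["err_alt"] = EA,
                      _["n_reads"] = wrap(nreads_per_cap));
}

// ---------- consensus ----------

// Position-wise merge of a read pair: Read2 is reverse-complemented and
// compared to Read1; disagreement or N in either mate masks the base to N.
// Pairs of unequal length yield NA.
// [[Rcpp::export]]
CharacterVector merge_pairs_cpp(CharacterVector r1, CharacterVector r2) {
  int n = r1.size();
  if (r2.size() != n) stop("mate vectors differ in length");
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(r1[i]);
    std::string b = as<std::string>(r2[i]);
    if (a.size() != b.size()) { out[i] = NA_STRING; continue; }
    int L = (int)a.size();
    std::string m(L, 'N');
    for (int j = 0; j < L; ++j) {
      char x = a[j], y = comp_base(b[L - 1 - j]);
      m[j] = (x == y && x != 'N') ? x : 'N';
    }
    out[i] = m;
  }
  return out;
}

// Greedy mismatch-tolerant barcode clustering. `barcodes` must be unique
// strings sorted by descending support (ties broken deterministically by the
// caller); each barcode joins the earliest-established bin whose founding
// barcode lies within `max_mismatch` (literal character comparison, so an N
// mismatches any real base), else founds a new bin. Returns 1-based bin ids
// and, per bin, the index of the founding barcode.
// [[Rcpp::export]]
List cluster_barcodes_cpp(CharacterVector barcodes, int max_mismatch) {
  int n = barcodes.size();
  IntegerVector bin(n);
  std::vector<int> founder;
  if (n == 0) return List::create(_["bin"] = bin, _["founder"] = IntegerVector(0));

  std::vector<std::string> bc(n);
  for (int i = 0; i < n; ++i) bc[i] = as<std::string>(barcodes[i]);
  const int L = (int)bc[0].size();

  if (max_mismatch == 1) {
    static const char alphabet[] = "ACGTN";
    std::unordered_map<std::string, int> rep2bin;
    rep2bin.reserve(n * 2);
    for (int i = 0; i < n; ++i) {
      if ((int)bc[i].size() != L) stop("barcodes differ in length");
      int best = -1;
      auto hit = rep2bin.find(bc[i]);
      if (hit != rep2bin.end()) best = hit->second;
      std::string q = bc[i];
      for (int p = 0; p < L && best != 0; ++p) {
        char orig = q[p];
        for (int a = 0; a < 5; ++a) {
          if (alphabet[a] == orig) continue;
          q[p] = alphabet[a];
          auto h = rep2bin.find(q);
          if (h != rep2bin.end() && (best < 0 || h->second < best)) best = h->second;
        }
        q[p] = orig;
      }
      if (best < 0) {
        best = (int)founder.size();
        founder.push_back(i + 1);
        rep2bin.emplace(bc[i], best);
      }
      bin[i] = best + 1;
    }
  } else {
    // general Hamming threshold, founding-order scan with early exit
    for (int i = 0; i < n; ++i) {
      if ((int)bc[i].size() != L) stop("barcodes differ in length");
      int best = -1;
      for (size_t b = 0; b < founder.size(); ++b) {
        const std::string& r = bc[founder[b] - 1];
        int d = 0;
        for (int j = 0; j < L && d <= max_mismatch; ++j)
          if (bc[i][j] != r[j]) ++d;
        if (d <= max_mismatch) { best = (int)b; break; }
      }
      if (best < 0) { best = (int)founder.size(); founder.push_back(i + 1); }
      bin[i] = best + 1;
    }
  }
  return List::create(_["bin"] = bin, _["founder"] = wrap(founder));
}

// Collapse capture bins to consensus sequences. Bins with fewer than
// min_reads members are rejected (NA consensus). At each position the most
// common non-N base is emitted iff its count is at least `agreement` of all
// members (N-bearing members included in the denominator) and the maximum is
// unique; otherwise N.
// [[Rcpp::export]]
List collapse_bins_cpp(CharacterVector inserts, IntegerVector bin, int nbins,
                       int min_reads, double agreement) {
  int n = inserts.size();
  std::vector<int> size(nbins, 0);
  for (int i = 0; i < n; ++i) size[bin[i] - 1]++;
  std::vector<std::vector<int>> members(nbins);
  for (int b = 0; b < nbins; ++b) members[b].reserve(size[b]);
  for (int i = 0; i < n; ++i) members[bin[i] - 1].push_back(i);

  CharacterVector consensus(nbins);
  IntegerVector support(nbins);
  int rejected = 0;
  std::vector<std::string> seqs(n);
  for (int i = 0; i < n; ++i) seqs[i] = as<std::string>(inserts[i]);

  for (int b = 0; b < nbins; ++b) {
    int sz = size[b];
    support[b] = sz;
    if (sz < min_reads) { consensus[b] = NA_STRING; rejected++; continue; }
    int L = (int)seqs[members[b][0]].size();
    std::string cons(L, 'N');
    std::vector<int> cnt(5);
    for (int p = 0; p < L; ++p) {
      cnt.assign(5, 0);
      for (int k = 0; k < sz; ++k) {
        char c = seqs[members[b][k]][p];
        switch (c) {
        case 'A': cnt[0]++; break; case 'C': cnt[1]++; break;
        case 'G': cnt[2]++; break; case 'T': cnt[3]++; break;
        default:  cnt[4]++; break;
        }
      }
      int top = -1, topc = 0; bool tie = false;
      for (int a = 0; a < 4; ++a) {
        if (cnt[a] > topc) { topc = cnt[a]; top = a; tie = false; }
        else if (cnt[a] == topc && cnt[a] > 0) tie = true;
      }
      if (top >= 0 && !tie && (double)topc >= agreement * (double)sz)
        cons[p] = "ACGT"[top];
    }
    consensus[b] = cons;
  }
  return List::create(_["consensus"] = consensus, _["support"] = support,
                      _["rejected"] = rejected);
}

// ---------- anchored alignment & pileup ----------

// Seed-and-verify placement of consensus reads against the probe panel:
// every N-free k-mer of the query is looked up in an index of all panel
// region k-mers; implied placements are verified by Hamming comparison with
// N positions excluded. Both orientations are tried; the best placement
// (fewest mismatches; forward preferred on ties) is kept if its mismatch
// count is within max_mismatch. Returns 0 in `probe` for rejected queries.
// [[Rcpp::export]]
List align_cpp(CharacterVector queries, CharacterVector regions,
               int k = 20, int max_mismatch = 10) {
  int nreg = regions.size();
  std::vector<std::string> reg(nreg);
  for (int i = 0; i < nreg; ++i) reg[i] = as<std::string>(regions[i]);

  std::unordered_map<std::string, std::vector<long>> index;
  for (int r = 0; r < nreg; ++r) {
    int M = (int)reg[r].size();
    for (int o = 0; o + k <= M; ++o)
      index[reg[r].substr(o, k)].push_back(((long)r << 20) | (long)o);
  }

  int nq = queries.size();
  IntegerVector probe(nq), offset(nq), mism(nq);
  CharacterVector orient(nq);

  for (int i = 0; i < nq; ++i) {
    std::string fwd = as<std::string>(queries[i]);
    int best_mm = max_mismatch + 1, best_r = -1, best_o = 0; bool best_rev = false;
    for (int ori = 0; ori < 2; ++ori) {
      std::string q = (ori == 0) ? fwd : revcomp_str(fwd);
      int Lq = (int)q.size();
      if (Lq < k) continue;
      std::vector<std::pair<int,int>> seen; // candidate (region, start)
      for (int j = 0; j + k <= Lq; ++j) {
        // skip windows containing N
        bool hasN = false; int lastN = -1;
        for (int t = j + k - 1; t >= j; --t)
          if (q[t] == 'N') { hasN = true; lastN = t; break; }
        if (hasN) { j = lastN; continue; } // loop ++ moves past the N
        auto h = index.find(q.substr(j, k));
        if (h == index.end()) continue;
        for (size_t v = 0; v < h->second.size(); ++v) {
          int r = (int)(h->second[v] >> 20);
          int o = (int)(h->second[v] & 0xFFFFF);
          int start = o - j;
          if (start < 0 || start + Lq > (int)reg[r].size()) continue;
          bool dup = false;
          for (size_t s = 0; s < seen.size(); ++s)
            if (seen[s].first == r && seen[s].second == start) { dup = true; break; }
          if (dup) continue;
          seen.push_back(std::make_pair(r, start));
          int d = 0;
          for (int t = 0; t < Lq && d < best_mm; ++t) {
            if (q[t] == 'N') continue;
            if (q[t] != reg[r][start + t]) ++d;
          }
          if (d < best_mm) { best_mm = d; best_r = r; best_o = start; best_rev = (ori == 1); }
        }
      }
      if (best_mm == 0) break; // cannot improve
    }
    if (best_r < 0 || best_mm > max_mismatch) {
      probe[i] = 0; offset[i] = NA_INTEGER; mism[i] = NA_INTEGER; orient[i] = NA_STRING;
    } else {
      probe[i] = best_r + 1; offset[i] = best_o; mism[i] = best_mm;
      orient[i] = best_rev ? "reverse" : "forward";
    }
  }
  return List::create(_["probe"] = probe, _["offset"] = offset,
                      _["mismatches"] = mism, _["orientation"] = orient);
}

// Per-probe base tallies over aligned consensus reads (sequences already in
// plus-strand orientation). Returns one 5 x region_length matrix per probe
// with rows A,C,G,T,N.
// [[Rcpp::export]]
List pileup_cpp(CharacterVector seqs, IntegerVector probe, IntegerVector offset,
                IntegerVector region_len, int nprobes) {
  std::vector<IntegerMatrix> mats;
  for (int p = 0; p < nprobes; ++p) mats.push_back(IntegerMatrix(5, region_len[p]));
  int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    int p = probe[i] - 1;
    if (p < 0) continue;
    std::string s = as<std::string>(seqs[i]);
    int o = offset[i];
    IntegerMatrix& m = mats[p];
    for (int j = 0; j < (int)s.size(); ++j) {
      int row;
      switch (s[j]) {
      case 'A': row = 0; break; case 'C': row = 1; break;
      case 'G': row = 2; break; case 'T': row = 3; break;
      default:  row = 4; break;
      }
      m(row, o + j)++;
    }
  }
  List out(nprobes);
  for (int p = 0; p < nprobes; ++p) {
    rownames(mats[p]) = CharacterVector::create("A", "C", "G", "T", "N");
    out[p] = mats[p];
  }
  return out;
}
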