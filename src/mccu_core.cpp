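#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode A/C/G/T; returns false if any other character is present
static inline bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    uint64_t b;
    switch (s[i]) {
      case 'A': case 'a': b = 0; break;
      case 'C': case 'c': b = 1; break;
      case 'G': case 'g': b = 2; break;
      case 'T': case 't': b = 3; break;
      default: return false;
    }
    v = (v << 2) | b;
  }
  out = v;
  return true;
}

static inline uint64_t revcomp_kmer(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (v & 3));
    v >>= 2;
  }
  return r;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector r1, CharacterVector r2,
                     CharacterVector q1, CharacterVector q2,
                     int min_overlap, double max_mismatch_rate) {
  int n = r1.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector merged(n);
  IntegerVector overlap_len(n);
  std::string s2, t2;
  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(r1[i]);
    std::string t1 = as<std::string>(q1[i]);
    std::string raw2 = as<std::string>(r2[i]);
    std::string rawq2 = as<std::string>(q2[i]);
    int n1 = (int)s1.size(), n2 = (int)raw2.size();
    // reverse complement R2 (and reverse its qualities)
    s2.assign(n2, 'N'); t2.assign(n2, '!');
    for (int j = 0; j < n2; ++j) {
      s2[j] = comp_base(raw2[n2 - 1 - j]);
      t2[j] = rawq2[n2 - 1 - j];
    }
    int best_o = -1, best_mm = 0;
    double best_score = -1e18;
    int omax = std::min(n1, n2);
    for (int o = min_overlap; o <= omax; ++o) {
      // suffix of s1 (length o) vs prefix of s2 (length o)
      int mm = 0;
      int off = n1 - o;
      int allow = (int)std::floor(max_mismatch_rate * o);
      for (int j = 0; j < o; ++j) {
        if (s1[off + j] != s2[j]) { if (++mm > allow) break; }
      }
      if (mm > allow) continue;
      double score = (double)o - 5.0 * mm;
      if (score > best_score || (score == best_score && o > best_o)) {
        best_score = score; best_o = o; best_mm = mm;
      }
    }
    if (best_o >= min_overlap) {
      int o = best_o, off = n1 - o;
      std::string ms = s1.substr(0, off);
      std::string mq = t1.substr(0, off);
      ms.reserve(n1 + n2 - o); mq.reserve(n1 + n2 - o);
      for (int j = 0; j < o; ++j) {
        if (s1[off + j] == s2[j] || t1[off + j] >= t2[j]) {
          ms.push_back(s1[off + j]);
          mq.push_back(std::max(t1[off + j], t2[j]));
        } else {
          ms.push_back(s2[j]);
          mq.push_back(t2[j]);
        }
      }
      ms.append(s2.substr(o)); mq.append(t2.substr(o));
      mseq[i] = ms; mqual[i] = mq;
      merged[i] = true; overlap_len[i] = o;
      (void)best_mm;
    } else {
      mseq[i] = s1; mqual[i] = t1;  // caller keeps R2 separately
      merged[i] = false; overlap_len[i] = 0;
    }
  }
  return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                      _["merged"] = merged, _["overlap"] = overlap_len);
}

struct SubHit { int rs, re, gs, ge, mm; bool fwd, ambig; };

// Map reads to a reference by maximal exact k-mer diagonal runs, merging
// runs across <= max_mm mismatches; junction micro-homology is assigned to
// the upstream (left-in-read) sub-read.
// [[Rcpp::export]]
DataFrame cpp_map_subreads(CharacterVector reads, std::string ref, int k,
                           int min_subread, int max_mm) {
  int L = (int)ref.size();
  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve((size_t)std::max(1, L - k + 1) * 2);
  for (int p = 0; p + k <= L; ++p) {
    uint64_t v;
    if (encode_kmer(ref.c_str() + p, k, v)) idx[v].push_back(p);
  }
  std::vector<int> out_read, out_rs, out_re, out_gs, out_ge, out_mm;
  std::vector<int> out_strand, out_ambig;
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    int n = (int)rd.size();
    if (n < k) continue;
    // hit at read pos i: (strand, diag); diag = p - i (+), p + i (-)
    // keep at most one hit per (i, strand) per diagonal continuation:
    // collect all, then chain greedily
    std::vector<SubHit> runs;
    // current runs keyed by (fwd, diag) -> index in runs of open run
    // simple approach: for each i, extend matching open run else open new
    std::unordered_map<int64_t, int> open; // key: diag*2 + fwd, value: run idx
    for (int i = 0; i + k <= n; ++i) {
      uint64_t v;
      if (!encode_kmer(rd.c_str() + i, k, v)) continue;
      uint64_t rv = revcomp_kmer(v, k);
      for (int strand = 0; strand < 2; ++strand) {
        uint64_t key = strand == 0 ? v : rv;
        auto it = idx.find(key);
        if (it == idx.end()) continue;
        for (int p : it->second) {
          int64_t diag = strand == 0 ? (int64_t)p - i : (int64_t)p + i;
          int64_t okey = diag * 2 + (strand == 0 ? 1 : 0);
          auto oit = open.find(okey);
          if (oit != open.end() && runs[oit->second].re >= i) {
            SubHit& h = runs[oit->second];
            h.re = i + k;  // extend (contiguous or overlapping k-mers)
          } else {
            SubHit h;
            h.rs = i; h.re = i + k; h.mm = 0;
            h.fwd = (strand == 0); h.ambig = false;
            h.gs = (int)diag; // store diag temporarily in gs
            runs.push_back(h);
            open[okey] = (int)runs.size() - 1;
          }
        }
      }
    }
    if (runs.empty()) continue;
    // merge runs on the same (strand, diag) across small mismatch gaps
    std::sort(runs.begin(), runs.end(), [](const SubHit& a, const SubHit& b) {
      if (a.fwd != b.fwd) return a.fwd > b.fwd;
      if (a.gs != b.gs) return a.gs < b.gs;
      return a.rs < b.rs;
    });
    std::vector<SubHit> merged;
    for (auto& h : runs) {
      if (!merged.empty()) {
        SubHit& m = merged.back();
        if (m.fwd == h.fwd && m.gs == h.gs && h.rs > m.re - k &&
            h.rs <= m.re + (max_mm + 1) * k) {
          // count true mismatches between read[m.re, h.rs) and reference
          int mm = 0;
          bool ok = true;
          for (int j = m.re; j < h.rs && ok; ++j) {
            int gp = m.fwd ? (m.gs + j) : (m.gs + k - 1 - j);
            if (gp < 0 || gp >= L) { ok = false; break; }
            char rb = rd[j];
            char gb = m.fwd ? ref[gp] : comp_base(ref[gp]);
            if (toupper(rb) != toupper(gb)) ++mm;
          }
          if (ok && m.mm + mm <= max_mm) {
            m.re = std::max(m.re, h.re);
            m.mm += mm;
            continue;
          }
        }
      }
      merged.push_back(h);
    }
    // order by read interval, drop runs contained in longer ones
    std::sort(merged.begin(), merged.end(), [](const SubHit& a, const SubHit& b) {
      if (a.rs != b.rs) return a.rs < b.rs;
      return (a.re - a.rs) > (b.re - b.rs);
    });
    std::vector<SubHit> kept;
    for (auto& h : merged) {
      bool contained = false;
      for (auto& o : kept)
        if (h.rs >= o.rs && h.re <= o.re) { contained = true; break; }
      if (!contained) kept.push_back(h);
    }
    // resolve read-interval overlaps: ambiguous bases go upstream
    for (size_t j = 1; j < kept.size(); ++j) {
      if (kept[j].rs < kept[j - 1].re) {
        kept[j].ambig = true;
        kept[j - 1].ambig = true;
        kept[j].rs = kept[j - 1].re;
      }
    }
    for (auto& h : kept) {
      int len = h.re - h.rs;
      if (len < min_subread) continue;
      int gs, ge;
      if (h.fwd) { gs = h.gs + h.rs; ge = h.gs + h.re; }
      else { gs = h.gs + k - h.re; ge = h.gs + k - h.rs; }
      if (gs < 0 || ge > L) continue;
      out_read.push_back(ri + 1);
      out_rs.push_back(h.rs); out_re.push_back(h.re);
      out_gs.push_back(gs); out_ge.push_back(ge);
      out_strand.push_back(h.fwd ? 1 : -1);
      out_mm.push_back(h.mm);
      out_ambig.push_back(h.ambig ? 1 : 0);
    }
  }
  return DataFrame::create(
    _["read"] = out_read, _["read_start"] = out_rs, _["read_end"] = out_re,
    _["genome_start"] = out_gs, _["genome_end"] = out_ge,
    _["strand"] = out_strand, _["mismatches"] = out_mm,
    _["ambiguous"] = out_ambig);
}

// Sample ligation-partner cut sites. For event e with first cut a[e] under
// phase ph[e], draw b from  w[b,ph] * decay(|b-a|) * pair factors.
// w: L x nphase cut-weight matrix. ndr_id/ctcf_id are 0 outside the
// feature and a positive interval id inside; the NDR and CTCF pair
// factors apply only to pairs spanning two *different* features
// (punctate contacts between NDRs / between CTCF sites).
// [[Rcpp::export]]
IntegerVector cpp_sample_partners(IntegerVector a, IntegerVector phase,
                                  NumericMatrix w, IntegerVector domain,
                                  IntegerVector ndr_id, IntegerVector ctcf_id,
                                  LogicalMatrix is_linker,
                                  double within_domain_factor,
                                  double ndr_pair_factor,
                                  double ctcf_pair_factor,
                                  double linker_periodic_factor,
                                  double decay_exponent, int min_dist) {
  int L = w.nrow();
  int n = a.size();
  std::vector<double> decay(L + 1);
  for (int d = 0; d <= L; ++d)
    decay[d] = std::pow((double)std::max(d, min_dist), -decay_exponent);
  IntegerVector b(n);
  std::vector<double> cum(L);
  GetRNGstate();
  for (int e = 0; e < n; ++e) {
    int ai = a[e], ph = phase[e];
    int a_ndr = ndr_id[ai], a_ctcf = ctcf_id[ai];
    bool a_lnk = is_linker(ai, ph);
    int a_dom = domain[ai];
    double tot = 0.0;
    for (int j = 0; j < L; ++j) {
      double wj = w(j, ph);
      if (wj > 0.0 && j != ai) {
        double f = wj * decay[std::abs(j - ai)];
        if (domain[j] == a_dom) f *= within_domain_factor;
        if (a_ndr > 0 && ndr_id[j] > 0 && ndr_id[j] != a_ndr)
          f *= ndr_pair_factor;
        if (a_ctcf > 0 && ctcf_id[j] > 0 && ctcf_id[j] != a_ctcf)
          f *= ctcf_pair_factor;
        if (a_lnk && is_linker(j, ph)) f *= linker_periodic_factor;
        tot += f;
        cum[j] = tot;
      } else {
        cum[j] = tot;
      }
    }
    if (tot <= 0.0) { b[e] = NA_INTEGER; continue; }
    double u = unif_rand() * tot;
    int lo = 0, hi = L - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    b[e] = lo;
  }
  PutRNGstate();
  return b;
}

// Sample the far (non-ligated) end of a fragment: a weighted cut site at
// distance [dmin, dmax] from pos on the given side (-1 left, +1 right),
// falling back to the nearest available cut beyond dmin.
// [[Rcpp::export]]
IntegerVector cpp_sample_frag_ends(IntegerVector pos, IntegerVector side,
                                   IntegerVector phase, NumericMatrix w,
                                   int dmin, int dmax) {
  int L = w.nrow();
  int n = pos.size();
  IntegerVector out(n);
  GetRNGstate();
  for (int e = 0; e < n; ++e) {
    int p = pos[e], s = side[e], ph = phase[e];
    int lo, hi;
    if (s > 0) { lo = p + dmin; hi = std::min(p + dmax, L - 1); }
    else { lo = std::max(p - dmax, 0); hi = p - dmin; }
    double tot = 0.0;
    for (int j = lo; j <= hi; ++j) if (j >= 0 && j < L) tot += w(j, ph);
    int pick = NA_INTEGER;
    if (tot > 0.0) {
      double u = unif_rand() * tot, acc = 0.0;
      for (int j = lo; j <= hi; ++j) {
        if (j < 0 || j >= L) continue;
        acc += w(j, ph);
        if (acc >= u) { pick = j; break; }
      }
    } else {
      // nearest weighted cut beyond dmin in the chosen direction
      if (s > 0) {
        for (int j = p + dmin; j < L; ++j) if (w(j, ph) > 0) { pick = j; break; }
      } else {
        for (int j = p - dmin; j >= 0; --j) if (w(j, ph) > 0) { pick = j; break; }
      }
      if (pick == NA_INTEGER) pick = s > 0 ? std::min(p + dmin, L - 1)
                                           : std::max(p - dmin, 0);
    }
    out[e] = pick;
  }
  PutRNGstate();
  return out;
}
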