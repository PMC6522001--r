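#include <Rcpp.h>
using namespace Rcpp;

// Log-odds scan of a set of encoded sequences with a set of PWMs.
// seqs: list of integer vectors, codes 1..4 (A,C,G,T), NA for N.
// loms_fwd / loms_rev: per motif, 4 x L log-odds matrices (reverse
// complement pre-computed in R). cutoffs: per-motif score cutoff.
// Windows containing an N are skipped. Minus-strand hits are reported in
// plus-strand coordinates at the same window start.
// [[Rcpp::export]]
DataFrame scan_core(List seqs, List loms_fwd, List loms_rev,
                    NumericVector cutoffs, bool both_strands) {
  const int n_seq = seqs.size();
  const int n_mot = loms_fwd.size();
  std::vector<int> out_seq, out_mot, out_start, out_strand;
  std::vector<double> out_score;

  // flatten matrices column-major and precompute suffix maxima for
  // lookahead pruning (abandon a window once even a perfect remaining
  // match cannot reach the cutoff)
  std::vector<std::vector<double> > F(n_mot), R(n_mot), sufF(n_mot), sufR(n_mot);
  std::vector<int> Ls(n_mot);
  for (int m = 0; m < n_mot; ++m) {
    NumericMatrix fwd = loms_fwd[m], rev = loms_rev[m];
    const int L = fwd.ncol();
    Ls[m] = L;
    F[m].resize(4 * L); R[m].resize(4 * L);
    for (int i = 0; i < L; ++i)
      for (int b = 0; b < 4; ++b) {
        F[m][4 * i + b] = fwd(b, i);
        R[m][4 * i + b] = rev(b, i);
      }
    sufF[m].assign(L + 1, 0.0); sufR[m].assign(L + 1, 0.0);
    for (int i = L - 1; i >= 0; --i) {
      double mf = F[m][4 * i], mr = R[m][4 * i];
      for (int b = 1; b < 4; ++b) {
        mf = std::max(mf, F[m][4 * i + b]);
        mr = std::max(mr, R[m][4 * i + b]);
      }
      sufF[m][i] = sufF[m][i + 1] + mf;
      sufR[m][i] = sufR[m][i + 1] + mr;
    }
  }

  for (int s = 0; s < n_seq; ++s) {
    IntegerVector sv = seqs[s];
    const int len = sv.size();
    const int *sp = INTEGER(sv);
    for (int m = 0; m < n_mot; ++m) {
      const int L = Ls[m];
      if (len < L) continue;
      const double cut = cutoffs[m];
      const double *f = F[m].data(), *r = R[m].data();
      const double *sf = sufF[m].data(), *sr = sufR[m].data();
      for (int p = 0; p + L <= len; ++p) {
        bool has_n = false, live_f = true, live_r = both_strands;
        double sc_f = 0.0, sc_r = 0.0;
        for (int i = 0; i < L; ++i) {
          int b = sp[p + i];
          if (b == NA_INTEGER) { has_n = true; break; }
          const int o = 4 * i + (b - 1);
          if (live_f) {
            sc_f += f[o];
            if (sc_f + sf[i + 1] < cut) live_f = false;
          }
          if (live_r) {
            sc_r += r[o];
            if (sc_r + sr[i + 1] < cut) live_r = false;
          }
          if (!live_f && !live_r) break;
        }
        if (has_n) continue;
        if (live_f && sc_f >= cut) {
          out_seq.push_back(s + 1); out_mot.push_back(m + 1);
          out_start.push_back(p);   out_strand.push_back(1);
          out_score.push_back(sc_f);
        }
        if (live_r && sc_r >= cut) {
          out_seq.push_back(s + 1); out_mot.push_back(m + 1);
          out_start.push_back(p);   out_strand.push_back(2);
          out_score.push_back(sc_r);
        }
      }
    }
  }
  return DataFrame::create(_["seq_idx"] = out_seq, _["motif_idx"] = out_mot,
                           _["start"] = out_start, _["strand_idx"] = out_strand,
                           _["score"] = out_score);
}

// Altschul-Erickson dinucleotide-preserving shuffle of one encoded
// sequence (codes 1..4, no NA). Preserves the multiset of adjacent base
// pairs and both terminal bases. Uses R's RNG (seedable via set.seed()).
// [[Rcpp::export]]
IntegerVector dinuc_shuffle_core(IntegerVector seq) {
  const int n = seq.size();
  if (n < 2) return clone(seq);

  // Edge lists of the dinucleotide multigraph.
  std::vector<std::vector<int> > edges(4);
  for (int i = 0; i + 1 < n; ++i) edges[seq[i] - 1].push_back(seq[i + 1] - 1);
  const int s1 = seq[0] - 1, sf = seq[n - 1] - 1;

  // Pick a random last-exit edge for every non-terminal vertex such that
  // following last edges from any vertex with out-edges reaches sf.
  std::vector<int> last(4, -1);
  for (int iter = 0; ; ++iter) {
    if (iter > 10000) stop("dinucleotide shuffle failed to find an Eulerian ordering");
    for (int v = 0; v < 4; ++v) {
      last[v] = -1;
      if (v != sf && !edges[v].empty()) {
        int k = (int)(unif_rand() * edges[v].size());
        if (k >= (int)edges[v].size()) k = edges[v].size() - 1;
        last[v] = edges[v][k];
      }
    }
    bool ok = true;
    for (int v = 0; v < 4 && ok; ++v) {
      if (v == sf || edges[v].empty()) continue;
      int u = v;
      for (int step = 0; step < 8; ++step) {
        if (u == sf) break;
        u = last[u];
        if (u < 0) break;
      }
      if (u != sf) ok = false;
    }
    if (ok) break;
  }

  // Permute each vertex's edges, forcing the chosen last edge to the end.
  std::vector<std::vector<int> > ordered(4);
  for (int v = 0; v < 4; ++v) {
    std::vector<int> e = edges[v];
    if (last[v] >= 0) {
      // remove one instance of last[v]
      for (size_t i = 0; i < e.size(); ++i)
        if (e[i] == last[v]) { e.erase(e.begin() + i); break; }
    }
    // Fisher-Yates
    for (int i = (int)e.size() - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(e[i], e[j]);
    }
    if (last[v] >= 0) e.push_back(last[v]);
    ordered[v] = e;
  }

  // Walk the Eulerian path.
  IntegerVector out(n);
  std::vector<size_t> pos(4, 0);
  int v = s1;
  out[0] = v + 1;
  for (int i = 1; i < n; ++i) {
    int w = ordered[v][pos[v]++];
    out[i] = w + 1;
    v = w;
  }
  return out;
}

// Count qualifying site pairs. Sites must be sorted by (seq, start).
// gap = start(downstream) - end(upstream); a pair qualifies iff gap is in
// [d_min, d_max], or gap < 0 when allow_overlap. Returns a K x K count
// matrix with the count of each unordered motif pair stored at
// [min(a,b), max(a,b)] (1-based motif indices in, 0-based matrix out).
// [[Rcpp::export]]
IntegerMatrix pair_count_core(IntegerVector seq, IntegerVector start,
                              IntegerVector end, IntegerVector motif, int K,
                              int d_min, int d_max, bool allow_overlap,
                              bool allow_homodimer) {
  const int n = seq.size();
  IntegerMatrix C(K, K);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (seq[j] != seq[i]) break;
      int gap = start[j] - end[i];
      if (gap > d_max) {
        // starts are sorted, so gap only grows with j unless site i is
        // unusually long; end[i] is fixed here, so the break is exact
        break;
      }
      bool ok = (gap >= d_min) || (allow_overlap && gap < 0);
      if (!ok) continue;
      int a = motif[i], b = motif[j];
      if (a == b && !allow_homodimer) continue;
      int lo = std::min(a, b) - 1, hi = std::max(a, b) - 1;
      C(lo, hi)++;
    }
  }
  return C;
}
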