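#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Integer-grid PWM scores for every window of every sequence.
// seqs: n x L integer codes 0..3, -1 for N/padding.
// scores: 4 x w integer matrix (log-odds rounded to the score grid).
// Returns n x (L - w + 1) integer matrix; NA for windows containing N.
// [[Rcpp::export]]
IntegerMatrix score_windows_cpp(IntegerMatrix seqs, IntegerMatrix scores) {
  const int n = seqs.nrow(), L = seqs.ncol(), w = scores.ncol();
  const int noff = L - w + 1;
  if (noff < 1) return IntegerMatrix(n, 0);
  IntegerMatrix out(n, noff);
  std::vector<int> row(L), sc(4 * w);
  for (int i = 0; i < w; ++i)
    for (int c = 0; c < 4; ++c) sc[c + 4 * i] = scores(c, i);
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < L; ++j) row[j] = seqs(s, j);
    for (int o = 0; o < noff; ++o) {
      int acc = 0;
      bool ok = true;
      const int* word = row.data() + o;
      for (int i = 0; i < w; ++i) {
        if (word[i] < 0) { ok = false; break; }
        acc += sc[word[i] + 4 * i];
      }
      out(s, o) = ok ? acc : NA_INTEGER;
    }
  }
  return out;
}

// Dense open convolution of two probability vectors (direct algorithm;
// lengths are kept small by re-binning upstream).
// [[Rcpp::export]]
NumericVector conv_dense_cpp(NumericVector a, NumericVector b) {
  const int na = a.size(), nb = b.size();
  NumericVector out(na + nb - 1);
  for (int i = 0; i < na; ++i) {
    const double ai = a[i];
    if (ai == 0.0) continue;
    for (int j = 0; j < nb; ++j) out[i + j] += ai * b[j];
  }
  return out;
}

// Exact distribution of the integer-grid PWM score of an i.i.d. background
// word: column-by-column convolution. Returns the support lower bound and
// the probability vector.
// [[Rcpp::export]]
List score_dist_cpp(IntegerMatrix Si, NumericVector bg) {
  const int w = Si.ncol();
  std::vector<double> p(1, 1.0);
  long cur_lo = 0;
  for (int j = 0; j < w; ++j) {
    int smin = Si(0, j), smax = Si(0, j);
    for (int c = 1; c < 4; ++c) {
      smin = std::min(smin, Si(c, j));
      smax = std::max(smax, Si(c, j));
    }
    const long new_lo = cur_lo + smin;
    const long new_hi = cur_lo + (long)p.size() - 1 + smax;
    std::vector<double> np(new_hi - new_lo + 1, 0.0);
    for (int c = 0; c < 4; ++c) {
      const long sh = cur_lo + Si(c, j) - new_lo;
      const double b = bg[c];
      for (size_t k = 0; k < p.size(); ++k) np[k + sh] += b * p[k];
    }
    p.swap(np);
    cur_lo = new_lo;
  }
  return List::create(_["lo"] = (double)cur_lo,
                      _["probs"] = NumericVector(p.begin(), p.end()));
}

// ZOOPS (zero-or-one occurrence per sequence) EM for PWM refinement.
//
// Mixture per sequence: "no site" with prior (1 - gamma), or a site at one
// admissible offset x strand with prior gamma * pos_prior[o] / 2. Windows
// containing N are inadmissible. Sequences may be weighted (ChIP-enrichment
// prioritization); weights scale each sequence's contribution to the
// sufficient statistics.
//
// seqs: n x L codes (0..3, -1 = N/pad); lens: true length of each sequence.
// theta0: 4 x w column-stochastic start matrix. pos_prior_type: 0 = uniform,
// 1 = centered (triangular peak at the sequence midpoint).
// Returns theta, gamma, iteration count and the observed-data log-likelihood
// trace (one entry per iteration, non-decreasing).
// [[Rcpp::export]]
List zoops_em_cpp(IntegerMatrix seqs, IntegerVector lens, NumericMatrix theta0,
                  NumericVector bg, int pos_prior_type,
                  NumericVector seq_weights, double gamma0, double pseudo,
                  double tol, int max_iter) {
  const int n = seqs.nrow(), w = theta0.ncol();
  NumericMatrix theta(clone(theta0));
  double gamma = gamma0;
  std::vector<double> ll_trace;
  int iter = 0;

  std::vector<double> log_bg(4);
  for (int b = 0; b < 4; ++b) log_bg[b] = std::log(bg[b]);

  // transpose once: contiguous per-sequence codes, plus window validity
  std::vector<int> codes;
  std::vector<size_t> seq_off(n + 1, 0);
  for (int s = 0; s < n; ++s) seq_off[s + 1] = seq_off[s] + lens[s];
  codes.resize(seq_off[n]);
  for (int s = 0; s < n; ++s)
    for (int j = 0; j < lens[s]; ++j) codes[seq_off[s] + j] = seqs(s, j);
  std::vector<unsigned char> valid(seq_off[n], 0); // valid window start?
  std::vector<double> log_prior;                   // per (s, o), flattened
  log_prior.resize(seq_off[n], 0.0);
  for (int s = 0; s < n; ++s) {
    const int Ls = lens[s], noff = Ls - w + 1;
    const int* sq = codes.data() + seq_off[s];
    int run = 0; // count of non-N in current window tail
    for (int j = Ls - 1; j >= 0; --j) {
      run = (sq[j] < 0) ? 0 : run + 1;
      if (j < noff) valid[seq_off[s] + j] = (run >= w);
    }
    if (noff >= 1) {
      double* pr = log_prior.data() + seq_off[s];
      if (pos_prior_type == 1) {
        const double mid = 0.5 * (noff - 1);
        double tot = 0.0;
        for (int o = 0; o < noff; ++o) tot += 1.0 + mid - std::fabs(o - mid);
        for (int o = 0; o < noff; ++o)
          pr[o] = std::log((1.0 + mid - std::fabs(o - mid)) / tot);
      } else {
        for (int o = 0; o < noff; ++o) pr[o] = -std::log((double)noff);
      }
    }
  }

  // nucleotide-triple codes (c1 + 4*c2 + 16*c3), built once: one 64-entry
  // table lookup then covers three PWM columns in the inner loops
  const int G3 = w / 3, rem = w - 3 * G3;
  std::vector<int> tri(seq_off[n], 0);
  for (int s = 0; s < n; ++s) {
    const int Ls = lens[s];
    const int* sq = codes.data() + seq_off[s];
    int* tr = tri.data() + seq_off[s];
    for (int j = 0; j + 2 < Ls; ++j) {
      const int c1 = sq[j] < 0 ? 0 : sq[j];
      const int c2 = sq[j + 1] < 0 ? 0 : sq[j + 1];
      const int c3 = sq[j + 2] < 0 ? 0 : sq[j + 2];
      tr[j] = c1 + 4 * c2 + 16 * c3;
    }
  }

  std::vector<double> lodds; // scratch, 2 * max noff
  int max_noff = 1;
  for (int s = 0; s < n; ++s)
    if (lens[s] - w + 1 > max_noff) max_noff = lens[s] - w + 1;
  lodds.resize(2 * max_noff);

  std::vector<double> tp3(G3 * 64), tm3(G3 * 64);
  std::vector<double> hp3(G3 * 64), hm3(G3 * 64);
  std::vector<double> hp1(rem * 4), hm1(rem * 4);

  for (iter = 1; iter <= max_iter; ++iter) {
    // per-iteration log-odds tables for both strands
    std::vector<double> lp(4 * w), lm(4 * w); // [c + 4*i]
    for (int i = 0; i < w; ++i)
      for (int c = 0; c < 4; ++c) {
        lp[c + 4 * i] = std::log(theta(c, i)) - log_bg[c];
        lm[c + 4 * i] = std::log(theta(3 - c, w - 1 - i)) - log_bg[c];
      }
    for (int g = 0; g < G3; ++g)
      for (int t = 0; t < 64; ++t) {
        const int c1 = t & 3, c2 = (t >> 2) & 3, c3 = (t >> 4) & 3;
        tp3[g * 64 + t] = lp[c1 + 4 * (3 * g)] + lp[c2 + 4 * (3 * g + 1)] +
                          lp[c3 + 4 * (3 * g + 2)];
        tm3[g * 64 + t] = lm[c1 + 4 * (3 * g)] + lm[c2 + 4 * (3 * g + 1)] +
                          lm[c3 + 4 * (3 * g + 2)];
      }
    std::fill(hp3.begin(), hp3.end(), 0.0);
    std::fill(hm3.begin(), hm3.end(), 0.0);
    std::fill(hp1.begin(), hp1.end(), 0.0);
    std::fill(hm1.begin(), hm1.end(), 0.0);

    double g_num = 0.0, g_den = 0.0, ll = 0.0;

    for (int s = 0; s < n; ++s) {
      const int Ls = lens[s];
      const double ws = seq_weights[s];
      const int noff = Ls - w + 1;
      if (noff < 1) { g_den += ws; continue; }
      const int* sq = codes.data() + seq_off[s];
      const int* tr = tri.data() + seq_off[s];
      const unsigned char* vd = valid.data() + seq_off[s];
      const double* pr = log_prior.data() + seq_off[s];
      const double lg = std::log(gamma * 0.5);

      double best = std::log1p(-gamma); // "no site" term
      for (int o = 0; o < noff; ++o) {
        if (!vd[o]) { lodds[o] = lodds[noff + o] = R_NegInf; continue; }
        double ap = 0.0, am = 0.0;
        for (int g = 0; g < G3; ++g) {
          const int t = tr[o + 3 * g];
          ap += tp3[g * 64 + t];
          am += tm3[g * 64 + t];
        }
        for (int i = 3 * G3; i < w; ++i) {
          const int c = sq[o + i];
          ap += lp[c + 4 * i];
          am += lm[c + 4 * i];
        }
        const double lpr = lg + pr[o];
        lodds[o] = ap + lpr;
        lodds[noff + o] = am + lpr;
        if (lodds[o] > best) best = lodds[o];
        if (lodds[noff + o] > best) best = lodds[noff + o];
      }
      const double l0 = std::log1p(-gamma);
      double tot = std::exp(l0 - best);
      for (int k = 0; k < 2 * noff; ++k)
        if (lodds[k] > R_NegInf) tot += std::exp(lodds[k] - best);
      ll += ws * (best + std::log(tot)); // + background ll, constant in theta
      const double p0 = std::exp(l0 - best) / tot;
      g_num += ws * (1.0 - p0);
      g_den += ws;

      // accumulate posterior mass into per-triple histograms
      const double inv_tot = 1.0 / tot;
      for (int o = 0; o < noff; ++o) {
        if (!vd[o]) continue;
        const double pp = std::exp(lodds[o] - best) * inv_tot * ws;
        const double pm = std::exp(lodds[noff + o] - best) * inv_tot * ws;
        if (pp + pm <= 1e-14) continue;
        for (int g = 0; g < G3; ++g) {
          const int t = tr[o + 3 * g];
          hp3[g * 64 + t] += pp;
          hm3[g * 64 + t] += pm;
        }
        for (int i = 3 * G3; i < w; ++i) {
          const int c = sq[o + i];
          hp1[(i - 3 * G3) * 4 + c] += pp;
          hm1[(i - 3 * G3) * 4 + c] += pm;
        }
      }
    }
    ll_trace.push_back(ll);

    // unpack histograms into posterior-weighted letter counts
    NumericMatrix counts(4, w);
    for (int g = 0; g < G3; ++g)
      for (int t = 0; t < 64; ++t) {
        const int c1 = t & 3, c2 = (t >> 2) & 3, c3 = (t >> 4) & 3;
        const double vp = hp3[g * 64 + t], vm = hm3[g * 64 + t];
        if (vp > 0) {
          counts(c1, 3 * g) += vp;
          counts(c2, 3 * g + 1) += vp;
          counts(c3, 3 * g + 2) += vp;
        }
        if (vm > 0) { // minus strand: complement base, mirrored column
          counts(3 - c1, w - 1 - 3 * g) += vm;
          counts(3 - c2, w - 1 - (3 * g + 1)) += vm;
          counts(3 - c3, w - 1 - (3 * g + 2)) += vm;
        }
      }
    for (int i = 3 * G3; i < w; ++i)
      for (int c = 0; c < 4; ++c) {
        counts(c, i) += hp1[(i - 3 * G3) * 4 + c];
        counts(3 - c, w - 1 - i) += hm1[(i - 3 * G3) * 4 + c];
      }

    // M-step
    const double g_new = g_den > 0 ? std::min(std::max(g_num / g_den, 1e-6),
                                              1.0 - 1e-6) : gamma;
    double max_delta = 0.0;
    for (int i = 0; i < w; ++i) {
      double colsum = 0.0;
      for (int c = 0; c < 4; ++c) colsum += counts(c, i) + pseudo;
      for (int c = 0; c < 4; ++c) {
        const double v = (counts(c, i) + pseudo) / colsum;
        max_delta = std::max(max_delta, std::fabs(v - theta(c, i)));
        theta(c, i) = v;
      }
    }
    max_delta = std::max(max_delta, std::fabs(g_new - gamma));
    gamma = g_new;
    if (max_delta < tol) break;
  }

  return List::create(_["theta"] = theta, _["gamma"] = gamma,
                      _["n_iter"] = std::min(iter, max_iter),
                      _["loglik"] = NumericVector(ll_trace.begin(),
                                                  ll_trace.end()));
}
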