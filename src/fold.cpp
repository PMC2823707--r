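// Secondary-structure engine: McCaskill-style partition function, mfe
// folding with traceback, and an intermolecular-only dimer partition
// function.  Energy model (shared with the R enumeration oracle):
// nearest-neighbor stacks, length-dependent hairpin/bulge/internal loop
// penalties, linear multiloops, Watson-Crick pairs only, minimum hairpin
// loop of 3, interior loops capped at `maxloop` unpaired bases total.
// All energy tables arrive from R already evaluated at the working
// temperature; sequences arrive as 0-based integer codes.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

static const double INF_E = 1e9;

struct Model {
  std::vector<int> s;            // base codes 0..3
  std::vector<bool> blocked;     // bases forbidden to pair
  NumericMatrix pairG;           // 4x4: 0 if pair allowed, INF otherwise
  NumericMatrix stackG;          // 4x4 keyed by s[i], s[i+1]
  NumericVector hairpinG;        // index size-1
  NumericVector bulgeG;          // index size-1
  NumericVector internalG;       // index size-1
  double mla, mlb, mlc, RT;
  int maxloop;
  int n;

  bool can_pair(int i, int j) const {
    if (blocked[i] || blocked[j]) return false;
    return pairG(s[i], s[j]) < INF_E / 2;
  }
  double hairpin(int size) const { return hairpinG[size - 1]; }
  // energy of the two-loop closed by (i,j) with inner pair (k,l)
  double two_loop(int i, int j, int k, int l) const {
    int s1 = k - i - 1, s2 = j - l - 1;
    if (s1 == 0 && s2 == 0) return stackG(s[i], s[i + 1]);
    if (s1 == 0 || s2 == 0) return bulgeG[s1 + s2 - 1];
    return internalG[s1 + s2 - 1];
  }
};

// ---------------------------------------------------------------------------
// Partition function.  Returns ln Z.

// [[Rcpp::export]]
double fold_partition_cpp(IntegerVector seq, LogicalVector blocked,
                          NumericMatrix pairG, NumericMatrix stackG,
                          NumericVector hairpinG, NumericVector bulgeG,
                          NumericVector internalG,
                          double mla, double mlb, double mlc,
                          double RT, int maxloop) {
  Model m;
  m.s = as<std::vector<int>>(seq);
  m.blocked = as<std::vector<bool>>(blocked);
  m.pairG = pairG; m.stackG = stackG;
  m.hairpinG = hairpinG; m.bulgeG = bulgeG; m.internalG = internalG;
  m.mla = mla; m.mlb = mlb; m.mlc = mlc; m.RT = RT; m.maxloop = maxloop;
  m.n = m.s.size();
  const int n = m.n;
  if (n < 5) return 0.0;

  // Boltzmann weight tables: no exp() in the inner loops.
  std::vector<double> whair(n + 1, 0.0);
  for (int sz = 3; sz <= n - 2; ++sz)
    whair[sz] = std::exp(-hairpinG[sz - 1] / RT);
  std::vector<double> wbul(maxloop + 1, 0.0), wint(maxloop + 1, 0.0);
  for (int sz = 1; sz <= maxloop; ++sz) {
    wbul[sz] = std::exp(-bulgeG[sz - 1] / RT);
    wint[sz] = std::exp(-internalG[sz - 1] / RT);
  }
  double wstk[4][4];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      wstk[a][b] = std::exp(-stackG(a, b) / RT);
  std::vector<double> powc(n + 1, 1.0);
  for (int d = 1; d <= n; ++d) powc[d] = powc[d - 1] * std::exp(-mlc / RT);
  const double wb = std::exp(-mlb / RT);
  const double wclose = std::exp(-(mla + mlb) / RT);

  std::vector<double> Qb(n * (size_t)n, 0.0), Qm(n * (size_t)n, 0.0),
      Qm1(n * (size_t)n, 0.0);
  auto ix = [n](int i, int j) { return (size_t)i * n + j; };

  for (int d = 4; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // Qb
      if (m.can_pair(i, j)) {
        double q = whair[j - i - 1];
        int kmax = std::min(i + m.maxloop + 1, j - 5);
        for (int k = i + 1; k <= kmax; ++k) {
          int g1 = k - i - 1;
          int lmin = std::max(k + 4, j - 1 - (m.maxloop - g1));
          const double* qrow = &Qb[ix(k, 0)];
          for (int l = lmin; l <= j - 1; ++l) {
            double qb = qrow[l];
            if (qb > 0.0) {
              int g2 = j - l - 1;
              double w;
              if (g1 == 0 && g2 == 0) w = wstk[m.s[i]][m.s[i + 1]];
              else if (g1 == 0 || g2 == 0) w = wbul[g1 + g2];
              else w = wint[g1 + g2];
              q += qb * w;
            }
          }
        }
        // multiloop: closing pair + >= 2 branches inside
        double qml = 0.0;
        const double* qmrow = &Qm[ix(i + 1, 0)];
        for (int k = i + 2; k <= j - 2; ++k) {
          double q1 = Qm1[ix(k, j - 1)];
          if (q1 > 0.0) qml += qmrow[k - 1] * q1;
        }
        q += qml * wclose;
        Qb[ix(i, j)] = q;
      }
      // Qm1: one branch starting at i, trailing bases unpaired
      Qm1[ix(i, j)] = powc[1] * Qm1[ix(i, j - 1)] + Qb[ix(i, j)] * wb;
      // Qm: >= 1 branch in [i, j]
      {
        double q = 0.0;
        const double* qmrow = &Qm[ix(i, 0)];
        for (int k = i; k <= j - 4; ++k) {
          double q1 = Qm1[ix(k, j)];
          if (q1 > 0.0) {
            double left = powc[k - i];
            if (k > i) left += qmrow[k - 1];
            q += q1 * left;
          }
        }
        Qm[ix(i, j)] = q;
      }
    }
  }

  // exterior loop
  std::vector<double> Qe(n + 1, 1.0);
  for (int j = 0; j < n; ++j) {
    double q = Qe[j];  // j unpaired
    for (int k = 0; k <= j - 4; ++k) {
      double qb = Qb[ix(k, j)];
      if (qb > 0.0) q += Qe[k] * qb;
    }
    Qe[j + 1] = q;
  }
  return std::log(Qe[n]);
}

// ---------------------------------------------------------------------------
// MFE folding with traceback.

struct MfeTables {
  std::vector<double> Vb, Wm, Wm1;
  std::vector<double> We;
  int n;
  size_t ix(int i, int j) const { return (size_t)i * n + j; }
};

static void mfe_fill(const Model& m, MfeTables& t) {
  const int n = m.n;
  t.n = n;
  t.Vb.assign((size_t)n * n, INF_E);
  t.Wm.assign((size_t)n * n, INF_E);
  t.Wm1.assign((size_t)n * n, INF_E);
  for (int d = 4; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      if (m.can_pair(i, j)) {
        double e = m.hairpin(j - i - 1);
        int kmax = std::min(i + m.maxloop + 1, j - 5);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + 4, j - 1 - (m.maxloop - (k - i - 1)));
          for (int l = lmin; l <= j - 1; ++l) {
            double vb = t.Vb[t.ix(k, l)];
            if (vb < INF_E / 2)
              e = std::min(e, vb + m.two_loop(i, j, k, l));
          }
        }
        for (int k = i + 2; k <= j - 2; ++k) {
          double w1 = t.Wm1[t.ix(k, j - 1)], wm = t.Wm[t.ix(i + 1, k - 1)];
          if (w1 < INF_E / 2 && wm < INF_E / 2)
            e = std::min(e, wm + w1 + m.mla + m.mlb);
        }
        t.Vb[t.ix(i, j)] = e;
      }
      {
        double e = INF_E;
        for (int l = i + 4; l <= j; ++l) {
          double vb = t.Vb[t.ix(i, l)];
          if (vb < INF_E / 2)
            e = std::min(e, vb + m.mlb + m.mlc * (j - l));
        }
        t.Wm1[t.ix(i, j)] = e;
      }
      {
        double e = INF_E;
        for (int k = i; k <= j - 4; ++k) {
          double w1 = t.Wm1[t.ix(k, j)];
          if (w1 < INF_E / 2) {
            double left = m.mlc * (k - i);
            if (k > i) left = std::min(left, t.Wm[t.ix(i, k - 1)]);
            e = std::min(e, w1 + left);
          }
        }
        t.Wm[t.ix(i, j)] = e;
      }
    }
  }
  t.We.assign(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    double e = t.We[j];
    for (int k = 0; k <= j - 4; ++k) {
      double vb = t.Vb[t.ix(k, j)];
      if (vb < INF_E / 2) e = std::min(e, t.We[k] + vb);
    }
    t.We[j + 1] = e;
  }
}

static void trace_vb(const Model& m, const MfeTables& t, int i, int j,
                     std::string& db);

static void trace_wm1(const Model& m, const MfeTables& t, int i, int j,
                      std::string& db) {
  double e = t.Wm1[t.ix(i, j)];
  for (int l = i + 4; l <= j; ++l) {
    double vb = t.Vb[t.ix(i, l)];
    if (vb < INF_E / 2 && std::abs(vb + m.mlb + m.mlc * (j - l) - e) < 1e-9) {
      trace_vb(m, t, i, l, db);
      return;
    }
  }
}

static void trace_wm(const Model& m, const MfeTables& t, int i, int j,
                     std::string& db) {
  double e = t.Wm[t.ix(i, j)];
  for (int k = i; k <= j - 4; ++k) {
    double w1 = t.Wm1[t.ix(k, j)];
    if (w1 >= INF_E / 2) continue;
    if (std::abs(w1 + m.mlc * (k - i) - e) < 1e-9) {
      trace_wm1(m, t, k, j, db);
      return;
    }
    if (k > i && t.Wm[t.ix(i, k - 1)] < INF_E / 2 &&
        std::abs(w1 + t.Wm[t.ix(i, k - 1)] - e) < 1e-9) {
      trace_wm(m, t, i, k - 1, db);
      trace_wm1(m, t, k, j, db);
      return;
    }
  }
}

static void trace_vb(const Model& m, const MfeTables& t, int i, int j,
                     std::string& db) {
  db[i] = '('; db[j] = ')';
  double e = t.Vb[t.ix(i, j)];
  if (std::abs(m.hairpin(j - i - 1) - e) < 1e-9) return;
  int kmax = std::min(i + m.maxloop + 1, j - 5);
  for (int k = i + 1; k <= kmax; ++k) {
    int lmin = std::max(k + 4, j - 1 - (m.maxloop - (k - i - 1)));
    for (int l = lmin; l <= j - 1; ++l) {
      double vb = t.Vb[t.ix(k, l)];
      if (vb < INF_E / 2 && std::abs(vb + m.two_loop(i, j, k, l) - e) < 1e-9) {
        trace_vb(m, t, k, l, db);
        return;
      }
    }
  }
  for (int k = i + 2; k <= j - 2; ++k) {
    double w1 = t.Wm1[t.ix(k, j - 1)], wm = t.Wm[t.ix(i + 1, k - 1)];
    if (w1 < INF_E / 2 && wm < INF_E / 2 &&
        std::abs(wm + w1 + m.mla + m.mlb - e) < 1e-9) {
      trace_wm(m, t, i + 1, k - 1, db);
      trace_wm1(m, t, k, j - 1, db);
      return;
    }
  }
}

// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector seq, LogicalVector blocked,
                  NumericMatrix pairG, NumericMatrix stackG,
                  NumericVector hairpinG, NumericVector bulgeG,
                  NumericVector internalG,
                  double mla, double mlb, double mlc,
                  double RT, int maxloop) {
  Model m;
  m.s = as<std::vector<int>>(seq);
  m.blocked = as<std::vector<bool>>(blocked);
  m.pairG = pairG; m.stackG = stackG;
  m.hairpinG = hairpinG; m.bulgeG = bulgeG; m.internalG = internalG;
  m.mla = mla; m.mlb = mlb; m.mlc = mlc; m.RT = RT; m.maxloop = maxloop;
  m.n = m.s.size();
  const int n = m.n;
  std::string db(n, '.');
  if (n < 5)
    return List::create(_["mfe"] = 0.0, _["structure"] = db);
  MfeTables t;
  mfe_fill(m, t);
  double mfe = t.We[n];
  if (mfe >= -1e-12)
    return List::create(_["mfe"] = 0.0, _["structure"] = std::string(n, '.'));
  // traceback of the exterior loop
  int j = n - 1;
  while (j >= 4) {
    if (std::abs(t.We[j] - t.We[j + 1]) < 1e-12) { --j; continue; }
    bool found = false;
    for (int k = 0; k <= j - 4; ++k) {
      double vb = t.Vb[t.ix(k, j)];
      if (vb < INF_E / 2 && std::abs(t.We[k] + vb - t.We[j + 1]) < 1e-9) {
        trace_vb(m, t, k, j, db);
        j = k - 1;
        found = true;
        break;
      }
    }
    if (!found) --j;
  }
  return List::create(_["mfe"] = mfe, _["structure"] = db);
}

// ---------------------------------------------------------------------------
// Intermolecular-only duplex partition function (RNAduplex-style).
// A and B both 5'->3'; pair (i, j) joins A[i] with B[j]; coexisting pairs
// satisfy i < i'  <=>  j > j' (antiparallel duplex).  Loops between
// consecutive pairs use the bulge/internal tables; adjacent pairs stack
// with the key A[i]A[i+1].  Each non-empty structure pays the duplex
// initiation energy once.  Returns ln of (1 + sum over non-empty
// structures), i.e. the open state contributes weight 1.

// [[Rcpp::export]]
double dimer_partition_cpp(IntegerVector seqA, IntegerVector seqB,
                           NumericMatrix pairG, NumericMatrix stackG,
                           NumericVector bulgeG, NumericVector internalG,
                           double initG, double RT, int maxloop) {
  std::vector<int> a = as<std::vector<int>>(seqA);
  std::vector<int> b = as<std::vector<int>>(seqB);
  int na = a.size(), nb = b.size();
  std::vector<double> Qd((size_t)na * nb, 0.0);
  auto ix = [nb](int i, int j) { return (size_t)i * nb + j; };
  const double winit = std::exp(-initG / RT);
  double total = 0.0;
  for (int i = 0; i < na; ++i) {
    for (int j = nb - 1; j >= 0; --j) {
      if (pairG(a[i], b[j]) >= INF_E / 2) continue;
      double q = winit;  // (i, j) is the only/first pair
      int ipmin = std::max(0, i - 1 - maxloop);
      for (int ip = ipmin; ip < i; ++ip) {
        int g1 = i - ip - 1;
        int jpmax = std::min(nb - 1, j + 1 + (maxloop - g1));
        for (int jp = j + 1; jp <= jpmax; ++jp) {
          double qd = Qd[ix(ip, jp)];
          if (qd <= 0.0) continue;
          int g2 = jp - j - 1;
          double e;
          if (g1 == 0 && g2 == 0) e = stackG(a[ip], a[i]);
          else if (g1 == 0 || g2 == 0) e = bulgeG[g1 + g2 - 1];
          else e = internalG[g1 + g2 - 1];
          q += qd * std::exp(-e / RT);
        }
      }
      Qd[ix(i, j)] = q;
      total += q;
    }
  }
  return std::log1p(total);
}
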