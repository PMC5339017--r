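// Nearest-neighbour RNA secondary-structure engine: minimum-free-energy
// folding (Zuker-style dynamic programming) and a McCaskill-style partition
// function for base-pair probabilities.
//
// Energy model (37 C, kcal/mol stored as integer centi-kcal):
//   - Watson-Crick + GU stacking (Turner-2004-style 6x6 table, symmetric in
//     the helix-reversal sense)
//   - hairpin / bulge / internal loop length-dependent initiation with
//     Jacobson-Stockmayer log extrapolation (1.75 RT ln)
//   - internal-loop asymmetry (Ninio) 0.6 kcal/nt capped at 3.0
//   - 0.5 kcal terminal penalty for AU/GU helix-closing pairs
//   - affine multiloop model (3.4 close + 0.4 per branch, free unpaired)
//   - no dangling ends / terminal mismatch bonuses: predictions are slightly
//     less negative than mismatch-aware engines but orderings are preserved
// Pseudoknots are not modelled; minimum hairpin loop is 3 nt.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>
#include <stack>
using namespace Rcpp;

static const int INF = 10000000;
static const int MAXLOOP = 30;
static const int ML_CLOSE = 340;
static const int ML_BRANCH = 40;
static const int AU_PEN = 50;
static const double RT_CENTI = 61.633; // kT at 310.15 K in centi-kcal/mol

// pair types: 0 CG, 1 GC, 2 GU, 3 UG, 4 AU, 5 UA
static const int stack37[6][6] = {
  {-240, -330, -210, -140, -210, -210},
  {-330, -340, -250, -150, -220, -240},
  {-210, -250,  130,  -50, -140, -130},
  {-140, -150,  -50,   30,  -60, -100},
  {-210, -220, -140,  -60, -110,  -90},
  {-210, -240, -130, -100,  -90, -130}
};

static int enc(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3;
  }
  return -1;
}

static int ptype(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  return -1;
}

static int au_pen(int t) { return (t >= 2) ? AU_PEN : 0; }

static int hairpinE(int n) {
  static const int h[7] = {540, 560, 570, 540, 600, 550, 640};
  if (n < 3) return INF;
  if (n <= 9) return h[n - 3];
  return (int)lround(640.0 + 107.856 * std::log((double)n / 9.0));
}

static int bulgeE(int n) {
  static const int b[6] = {380, 280, 320, 360, 400, 440};
  if (n < 1) return INF;
  if (n <= 6) return b[n - 1];
  return (int)lround(440.0 + 107.856 * std::log((double)n / 6.0));
}

static int internalE(int n) {
  static const int il[3] = {110, 200, 200};
  if (n == 2) return 150;
  if (n == 3) return 220;
  if (n <= 6) return il[n - 4];
  return (int)lround(200.0 + 107.856 * std::log((double)n / 6.0));
}

static int ninio(int d) { int v = 60 * d; return v > 300 ? 300 : v; }

// energy of the loop closed by (i,j) with inner pair (k,l); types precomputed
static int loop_energy(int u1, int u2, int tij, int tkl, int stack_term) {
  if (u1 == 0 && u2 == 0) return stack_term;
  if (u1 == 0 || u2 == 0) {
    int u = u1 + u2;
    int e = bulgeE(u);
    if (u == 1) e += stack_term;          // helix stacking continues across
    else e += au_pen(tij) + au_pen(tkl);
    return e;
  }
  return internalE(u1 + u2) + ninio(std::abs(u1 - u2)) +
         au_pen(tij) + au_pen(tkl);
}

struct FoldDP {
  int n;
  std::vector<int> s;
  std::vector<std::vector<int> > V, M;
  std::vector<int> W;

  explicit FoldDP(const std::string& seq) {
    n = (int)seq.size();
    s.resize(n);
    for (int i = 0; i < n; ++i) {
      s[i] = enc(seq[i]);
      if (s[i] < 0) stop("non-RNA character in sequence");
    }
    V.assign(n, std::vector<int>(n, INF));
    M.assign(n, std::vector<int>(n, INF));
    fill();
  }

  int pt(int i, int j) const { return ptype(s[i], s[j]); }

  int vmulti(int i, int j, int t, int* arg = 0) const {
    int best = INF;
    for (int h = i + 1; h < j - 1; ++h) {
      if (M[i + 1][h] >= INF || M[h + 1][j - 1] >= INF) continue;
      int e = ML_CLOSE + ML_BRANCH + au_pen(t) + M[i + 1][h] + M[h + 1][j - 1];
      if (e < best) { best = e; if (arg) *arg = h; }
    }
    return best;
  }

  void fill() {
    for (int span = 4; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        int t = pt(i, j);
        if (t >= 0) {
          int best = hairpinE(j - i - 1) + au_pen(t);
          int kmax = std::min(j - 5, i + MAXLOOP + 1);
          for (int k = i + 1; k <= kmax; ++k) {
            int lmin = std::max(k + 4, j - 1 - (MAXLOOP - (k - i - 1)));
            for (int l = j - 1; l >= lmin; --l) {
              if (V[k][l] >= INF) continue;
              int tin = ptype(s[l], s[k]);         // reversed for stack lookup
              int tkl = ptype(s[k], s[l]);
              int e = loop_energy(k - i - 1, j - l - 1, t, tkl,
                                  stack37[t][tin]) + V[k][l];
              if (e < best) best = e;
            }
          }
          int em = vmulti(i, j, t);
          if (em < best) best = em;
          V[i][j] = best;
        }
        // M: first branch starts at i, or i unpaired (unpaired cost 0)
        int best = (i + 1 <= j) ? M[i + 1][j] : INF;
        for (int k = i + 4; k <= j; ++k) {
          if (V[i][k] >= INF) continue;
          int e = V[i][k] + ML_BRANCH + au_pen(pt(i, k));
          if (k < j && M[k + 1][j] < 0) e += M[k + 1][j];
          if (e < best) best = e;
        }
        M[i][j] = best;
      }
    }
    W.assign(n + 1, 0);
    for (int j = 1; j <= n; ++j) {
      W[j] = W[j - 1];
      for (int k = 1; k <= j - 4; ++k) {
        if (V[k - 1][j - 1] >= INF) continue;
        int e = W[k - 1] + V[k - 1][j - 1] + au_pen(pt(k - 1, j - 1));
        if (e < W[j]) W[j] = e;
      }
    }
  }

  std::string traceback() const {
    std::string db(n, '.');
    std::stack<std::vector<int> > st; // {state, i, j}: 0 = V, 1 = M
    // external
    {
      int j = n;
      while (j > 0) {
        if (W[j] == W[j - 1]) { --j; continue; }
        bool found = false;
        for (int k = 1; k <= j - 4 && !found; ++k) {
          if (V[k - 1][j - 1] < INF &&
              W[j] == W[k - 1] + V[k - 1][j - 1] + au_pen(pt(k - 1, j - 1))) {
            st.push({0, k - 1, j - 1});
            j = k - 1;
            found = true;
          }
        }
        if (!found) { --j; } // defensive; should not happen
      }
    }
    while (!st.empty()) {
      std::vector<int> fr = st.top(); st.pop();
      int i = fr[1], j = fr[2];
      if (fr[0] == 0) {
        db[i] = '('; db[j] = ')';
        int t = pt(i, j);
        if (V[i][j] == hairpinE(j - i - 1) + au_pen(t)) continue;
        bool found = false;
        int kmax = std::min(j - 5, i + MAXLOOP + 1);
        for (int k = i + 1; k <= kmax && !found; ++k) {
          int lmin = std::max(k + 4, j - 1 - (MAXLOOP - (k - i - 1)));
          for (int l = j - 1; l >= lmin && !found; --l) {
            if (V[k][l] >= INF) continue;
            int tin = ptype(s[l], s[k]);
            int tkl = ptype(s[k], s[l]);
            if (V[i][j] == loop_energy(k - i - 1, j - l - 1, t, tkl,
                                       stack37[t][tin]) + V[k][l]) {
              st.push({0, k, l});
              found = true;
            }
          }
        }
        if (!found) {
          int h = -1;
          if (V[i][j] == vmulti(i, j, t, &h) && h >= 0) {
            st.push({1, i + 1, h});
            st.push({1, h + 1, j - 1});
          }
        }
      } else { // M
        if (i > j) continue;
        if (i + 1 <= j && M[i][j] == M[i + 1][j]) {
          st.push({1, i + 1, j});
          continue;
        }
        for (int k = i + 4; k <= j; ++k) {
          if (V[i][k] >= INF) continue;
          int e = V[i][k] + ML_BRANCH + au_pen(pt(i, k));
          int rest = (k < j && M[k + 1][j] < 0) ? M[k + 1][j] : 0;
          if (M[i][j] == e + rest) {
            st.push({0, i, k});
            if (rest != 0) st.push({1, k + 1, j});
            break;
          }
        }
      }
    }
    return db;
  }
};

// [[Rcpp::export(name = ".c_fold_mfe")]]
List c_fold_mfe(std::string seq) {
  int n = (int)seq.size();
  if (n == 0) stop("empty sequence");
  FoldDP dp(seq);
  int e = dp.W[n];
  std::string db(n, '.');
  double mfe = 0.0;
  if (e < 0) {
    db = dp.traceback();
    mfe = e / 100.0;
  }
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}

// [[Rcpp::export(name = ".c_pair_probs")]]
NumericMatrix c_pair_probs(std::string seq) {
  int n = (int)seq.size();
  if (n == 0) stop("empty sequence");
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = enc(seq[i]);
    if (s[i] < 0) stop("non-RNA character in sequence");
  }
  std::vector<std::vector<double> > Qb(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double> > Qm(n, std::vector<double>(n, 0.0));
  // Qm1[i][j]: exactly one branch, starting at i, ending at l <= j, the
  // remainder unpaired — anchors multiloop decompositions uniquely
  std::vector<std::vector<double> > Qm1(n, std::vector<double>(n, 0.0));
  const double beta = 1.0 / RT_CENTI;
  // inside
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int t = ptype(s[i], s[j]);
      if (t >= 0) {
        double q = std::exp(-beta * (hairpinE(j - i - 1) + au_pen(t)));
        int kmax = std::min(j - 5, i + MAXLOOP + 1);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + 4, j - 1 - (MAXLOOP - (k - i - 1)));
          for (int l = j - 1; l >= lmin; --l) {
            if (Qb[k][l] == 0.0) continue;
            int tin = ptype(s[l], s[k]);
            int tkl = ptype(s[k], s[l]);
            q += Qb[k][l] * std::exp(-beta * loop_energy(k - i - 1, j - l - 1,
                                                         t, tkl, stack37[t][tin]));
          }
        }
        // multiloop: split at the start h of the last branch (unique)
        for (int h = i + 2; h < j; ++h) {
          if (Qm[i + 1][h - 1] == 0.0 || Qm1[h][j - 1] == 0.0) continue;
          q += Qm[i + 1][h - 1] * Qm1[h][j - 1] *
               std::exp(-beta * (ML_CLOSE + ML_BRANCH + au_pen(t)));
        }
        Qb[i][j] = q;
      }
      double q1 = 0.0;
      for (int l = i + 4; l <= j; ++l) {
        if (Qb[i][l] == 0.0) continue;
        q1 += Qb[i][l] * std::exp(-beta * (ML_BRANCH + au_pen(ptype(s[i], s[l]))));
      }
      Qm1[i][j] = q1;
      // Qm: decompose by the start/end of the first branch (unique)
      double qm = (i + 1 <= j) ? Qm[i + 1][j] : 0.0; // i unpaired (cost 0)
      for (int k = i + 4; k <= j; ++k) {
        if (Qb[i][k] == 0.0) continue;
        double br = Qb[i][k] *
          std::exp(-beta * (ML_BRANCH + au_pen(ptype(s[i], s[k]))));
        qm += br * (1.0 + ((k < j) ? Qm[k + 1][j] : 0.0));
      }
      Qm[i][j] = qm;
    }
  }
  // external prefix / suffix
  std::vector<double> Qf(n + 1, 1.0), Qr(n + 2, 1.0);
  for (int j = 1; j <= n; ++j) {
    Qf[j] = Qf[j - 1];
    for (int k = 1; k <= j - 4; ++k) {
      if (Qb[k - 1][j - 1] == 0.0) continue;
      Qf[j] += Qf[k - 1] * Qb[k - 1][j - 1] *
               std::exp(-beta * au_pen(ptype(s[k - 1], s[j - 1])));
    }
  }
  for (int i = n; i >= 1; --i) {
    Qr[i] = Qr[i + 1];
    for (int l = i + 4; l <= n; ++l) {
      if (Qb[i - 1][l - 1] == 0.0) continue;
      Qr[i] += Qb[i - 1][l - 1] * Qr[l + 1] *
               std::exp(-beta * au_pen(ptype(s[i - 1], s[l - 1])));
    }
  }
  double Qtot = Qf[n];
  // outside
  std::vector<std::vector<double> > Ob(n, std::vector<double>(n, 0.0));
  for (int span = n - 1; span >= 4; --span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (Qb[i][j] == 0.0) continue;
      int t = ptype(s[i], s[j]);
      double o = Qf[i] * Qr[j + 2] * std::exp(-beta * au_pen(t));
      // enclosed by an outer pair (p,q) through a two-loop
      for (int p = std::max(0, i - MAXLOOP - 1); p < i; ++p) {
        int qmax = std::min(n - 1, j + 1 + (MAXLOOP - (i - p - 1)));
        for (int q = j + 1; q <= qmax; ++q) {
          if (Ob[p][q] == 0.0) continue;
          int tpq = ptype(s[p], s[q]);
          if (tpq < 0) continue;
          int tin = ptype(s[j], s[i]);
          o += Ob[p][q] * std::exp(-beta * loop_energy(i - p - 1, q - j - 1,
                                                       tpq, t, stack37[tpq][tin]));
        }
      }
      // branch of a multiloop closed by (p,q)
      double brf = std::exp(-beta * (ML_BRANCH + au_pen(t)));
      for (int p = 0; p < i; ++p) {
        for (int q = j + 1; q < n; ++q) {
          if (Ob[p][q] == 0.0) continue;
          int tpq = ptype(s[p], s[q]);
          if (tpq < 0) continue;
          double qmL = (p + 1 <= i - 1) ? Qm[p + 1][i - 1] : 0.0;
          double qmR = (j + 1 <= q - 1) ? Qm[j + 1][q - 1] : 0.0;
          double fill = (1.0 + qmL) * (1.0 + qmR) - 1.0;
          if (fill <= 0.0) continue;
          o += Ob[p][q] *
               std::exp(-beta * (ML_CLOSE + ML_BRANCH + au_pen(tpq))) *
               brf * fill;
        }
      }
      Ob[i][j] = o;
    }
  }
  NumericMatrix P(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 4; j < n; ++j) {
      if (Qb[i][j] == 0.0) continue;
      double p = Qb[i][j] * Ob[i][j] / Qtot;
      if (p < 0) p = 0; if (p > 1) p = 1;
      P(i, j) = p; P(j, i) = p;
    }
  }
  return P;
}
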