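#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Pair codes: AU=0, UA=1, GC=2, CG=3, GU=4, UG=5, none=-1.
// Bases coded A=0, C=1, G=2, U=3.

static inline int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 3 && b == 0) return 1;  // UA
  if (a == 2 && b == 1) return 2;  // GC
  if (a == 1 && b == 2) return 3;  // CG
  if (a == 2 && b == 3) return 4;  // GU
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

static const double INF = 1e9;
static const int MAXLOOP = 30;   // max unpaired bases in a bulge/internal loop
static const int MINHP   = 3;    // minimal hairpin loop length

struct Params {
  std::vector<double> stack;  // 6x6, row-major [p*6+q]
  double hp_a, hp_b;          // hairpin: a + b*(L-3)
  double bu_a, bu_b;          // bulge:   a + b*(L-1)
  double in_a, in_b;          // internal:a + b*(L-2)
  double ml_close, ml_branch, ml_unpaired;
  double hairpin(int L) const { return hp_a + hp_b * (L - MINHP); }
  double bulge(int L) const { return bu_a + bu_b * (L - 1); }
  double internal_(int L) const { return in_a + in_b * (L - 2); }
  double looppen(int l1, int l2) const {
    if (l1 == 0 && l2 == 0) return INF;       // that's a stack, handled apart
    if (l1 == 0 || l2 == 0) return bulge(l1 + l2);
    return internal_(l1 + l2);
  }
};

// Fill V, WM matrices. V[i][j]: MFE of [i..j] with (i,j) paired.
// WM[i][j]: MFE of [i..j] as part of a multiloop interior, >=1 branch.
static void fill_matrices(const std::vector<int>& s, const Params& P,
                          std::vector<std::vector<double> >& V,
                          std::vector<std::vector<double> >& WM) {
  int n = (int)s.size();
  V.assign(n, std::vector<double>(n, INF));
  WM.assign(n, std::vector<double>(n, INF));
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int pij = pair_code(s[i], s[j]);
      if (pij >= 0 && j - i - 1 >= MINHP) {
        double best = P.hairpin(j - i - 1);
        // stack
        int pin = pair_code(s[i + 1], s[j - 1]);
        if (pin >= 0 && V[i + 1][j - 1] < INF / 2) {
          double e = V[i + 1][j - 1] + P.stack[pij * 6 + pin];
          if (e < best) best = e;
        }
        // bulge / internal loops
        for (int k = i + 1; k <= j - 1; ++k) {
          int l1 = k - i - 1;
          if (l1 > MAXLOOP) break;
          for (int l = j - 1; l > k; --l) {
            int l2 = j - l - 1;
            if (l1 + l2 == 0) continue;
            if (l1 + l2 > MAXLOOP) break;
            if (pair_code(s[k], s[l]) < 0) continue;
            if (V[k][l] >= INF / 2) continue;
            double e = V[k][l] + P.looppen(l1, l2);
            if (e < best) best = e;
          }
        }
        // multiloop closure: >=2 branches inside
        for (int k = i + 1; k < j - 1; ++k) {
          if (WM[i + 1][k] < INF / 2 && WM[k + 1][j - 1] < INF / 2) {
            double e = P.ml_close + WM[i + 1][k] + WM[k + 1][j - 1];
            if (e < best) best = e;
          }
        }
        V[i][j] = best;
      }
      // WM
      double w = INF;
      if (pij >= 0 && V[i][j] < INF / 2) w = V[i][j] + P.ml_branch;
      if (WM[i + 1].size() && j > i && WM[i + 1][j] < INF / 2)
        w = std::min(w, WM[i + 1][j] + P.ml_unpaired);
      if (j - 1 >= i && WM[i][j - 1] < INF / 2)
        w = std::min(w, WM[i][j - 1] + P.ml_unpaired);
      for (int k = i + 1; k < j; ++k) {
        if (WM[i][k] < INF / 2 && WM[k + 1][j] < INF / 2)
          w = std::min(w, WM[i][k] + WM[k + 1][j]);
      }
      WM[i][j] = w;
    }
  }
}

// Exterior loop: W[j] = MFE of prefix [0..j]; unpaired-first tie break
static void fill_exterior(const std::vector<int>& s, const Params& P,
                          const std::vector<std::vector<double> >& V,
                          std::vector<double>& W) {
  int n = (int)s.size();
  W.assign(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    double best = W[j - 1];  // base j-1 (0-based) unpaired
    for (int i = 1; i <= j; ++i) {
      double vij = V[i - 1][j - 1];
      if (vij < INF / 2) {
        double e = W[i - 1] + vij;
        if (e < best) best = e;  // strict: ties keep fewer pairs
      }
    }
    W[j] = best;
  }
}

struct Seg { int i, j, state; };  // state 0=W-suffix(use W over [0..j], anchored via split), 1=V, 2=WM

// traceback writes '(' ')' into db
static void traceback(const std::vector<int>& s, const Params& P,
                      const std::vector<std::vector<double> >& V,
                      const std::vector<std::vector<double> >& WM,
                      const std::vector<double>& W, std::string& db) {
  int n = (int)s.size();
  const double EPS = 1e-7;
  std::vector<Seg> stk;
  // exterior: walk j from n down
  {
    int j = n;
    while (j > 0) {
      if (std::abs(W[j] - W[j - 1]) < EPS) { --j; continue; }
      bool found = false;
      for (int i = 1; i <= j && !found; ++i) {
        double vij = V[i - 1][j - 1];
        if (vij < INF / 2 && std::abs(W[j] - (W[i - 1] + vij)) < EPS) {
          Seg sg; sg.i = i - 1; sg.j = j - 1; sg.state = 1; stk.push_back(sg);
          j = i - 1; found = true;
        }
      }
      if (!found) --j;  // defensive
    }
  }
  while (!stk.empty()) {
    Seg sg = stk.back(); stk.pop_back();
    int i = sg.i, j = sg.j;
    if (sg.state == 1) {
      db[i] = '('; db[j] = ')';
      int pij = pair_code(s[i], s[j]);
      double v = V[i][j];
      if (std::abs(v - P.hairpin(j - i - 1)) < EPS) continue;
      int pin = pair_code(s[i + 1], s[j - 1]);
      if (pin >= 0 && V[i + 1][j - 1] < INF / 2 &&
          std::abs(v - (V[i + 1][j - 1] + P.stack[pij * 6 + pin])) < EPS) {
        Seg nx; nx.i = i + 1; nx.j = j - 1; nx.state = 1; stk.push_back(nx);
        continue;
      }
      bool done = false;
      for (int k = i + 1; k <= j - 1 && !done; ++k) {
        int l1 = k - i - 1;
        if (l1 > MAXLOOP) break;
        for (int l = j - 1; l > k; --l) {
          int l2 = j - l - 1;
          if (l1 + l2 == 0) continue;
          if (l1 + l2 > MAXLOOP) break;
          if (pair_code(s[k], s[l]) < 0 || V[k][l] >= INF / 2) continue;
          if (std::abs(v - (V[k][l] + P.looppen(l1, l2))) < EPS) {
            Seg nx; nx.i = k; nx.j = l; nx.state = 1; stk.push_back(nx);
            done = true; break;
          }
        }
      }
      if (done) continue;
      for (int k = i + 1; k < j - 1; ++k) {
        if (WM[i + 1][k] < INF / 2 && WM[k + 1][j - 1] < INF / 2 &&
            std::abs(v - (P.ml_close + WM[i + 1][k] + WM[k + 1][j - 1])) < EPS) {
          Seg a; a.i = i + 1; a.j = k; a.state = 2; stk.push_back(a);
          Seg b; b.i = k + 1; b.j = j - 1; b.state = 2; stk.push_back(b);
          break;
        }
      }
    } else if (sg.state == 2) {
      double w = WM[i][j];
      int pij = pair_code(s[i], s[j]);
      if (pij >= 0 && V[i][j] < INF / 2 &&
          std::abs(w - (V[i][j] + P.ml_branch)) < EPS) {
        Seg nx; nx.i = i; nx.j = j; nx.state = 1; stk.push_back(nx);
        continue;
      }
      if (i + 1 <= j && WM[i + 1][j] < INF / 2 &&
          std::abs(w - (WM[i + 1][j] + P.ml_unpaired)) < EPS) {
        Seg nx; nx.i = i + 1; nx.j = j; nx.state = 2; stk.push_back(nx);
        continue;
      }
      if (j - 1 >= i && WM[i][j - 1] < INF / 2 &&
          std::abs(w - (WM[i][j - 1] + P.ml_unpaired)) < EPS) {
        Seg nx; nx.i = i; nx.j = j - 1; nx.state = 2; stk.push_back(nx);
        continue;
      }
      for (int k = i + 1; k < j; ++k) {
        if (WM[i][k] < INF / 2 && WM[k + 1][j] < INF / 2 &&
            std::abs(w - (WM[i][k] + WM[k + 1][j])) < EPS) {
          Seg a; a.i = i; a.j = k; a.state = 2; stk.push_back(a);
          Seg b; b.i = k + 1; b.j = j; b.state = 2; stk.push_back(b);
          break;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq_codes, NumericMatrix stack_mat,
                  NumericVector loop_params) {
  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  int n = (int)s.size();
  Params P;
  P.stack.resize(36);
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) P.stack[a * 6 + b] = stack_mat(a, b);
  P.hp_a = loop_params["hairpin_a"];    P.hp_b = loop_params["hairpin_b"];
  P.bu_a = loop_params["bulge_a"];      P.bu_b = loop_params["bulge_b"];
  P.in_a = loop_params["internal_a"];   P.in_b = loop_params["internal_b"];
  P.ml_close = loop_params["multi_close"];
  P.ml_branch = loop_params["multi_branch"];
  P.ml_unpaired = loop_params["multi_unpaired"];

  std::string db(n, '.');
  if (n < MINHP + 2) {
    return List::create(_["mfe"] = 0.0, _["structure"] = db);
  }
  std::vector<std::vector<double> > V, WM;
  std::vector<double> W;
  fill_matrices(s, P, V, WM);
  fill_exterior(s, P, V, W);
  double mfe = W[n];
  if (mfe < 0) traceback(s, P, V, WM, W, db);
  else mfe = 0.0;  // open chain preferred at ties / positive optimum
  return List::create(_["mfe"] = mfe, _["structure"] = db);
}
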