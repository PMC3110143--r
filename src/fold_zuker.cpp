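// Simplified nearest-neighbour MFE folder (Zuker-style dynamic programme).
//
// Nested structures only, canonical + GU pairs, stacking energies with
// hairpin/bulge/internal-loop size penalties and an affine multiloop cost.
// Energies are whole-model simplifications (Turner-like magnitudes, dcal/mol
// integers); the folder is a self-contained in-process backend behind the
// same contract as the external one: same sequence in, same dot-bracket out.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstring>

using namespace Rcpp;

static const int INF = 1000000;
static const int MAXLOOP = 30;
static const int ML_CLOSE = 340;   // multiloop closing penalty
static const int ML_BRANCH = 40;   // per-branch penalty

// pair type order: CG GC GU UG AU UA
static int pair_type(char a, char b) {
  if (a == 'C' && b == 'G') return 0;
  if (a == 'G' && b == 'C') return 1;
  if (a == 'G' && b == 'U') return 2;
  if (a == 'U' && b == 'G') return 3;
  if (a == 'A' && b == 'U') return 4;
  if (a == 'U' && b == 'A') return 5;
  return -1;
}

static const int STACK[6][6] = {
  {-240, -330, -210, -140, -210, -210},
  {-330, -340, -250, -150, -220, -240},
  {-210, -250,  130,  -50, -140, -130},
  {-140, -150,  -50,   30,  -60, -100},
  {-210, -220, -140,  -60, -110,  -90},
  {-210, -240, -130, -100,  -90, -130}
};

static int hairpin_E(int n) {
  static const int tab[10] = {0, 0, 0, 540, 560, 570, 540, 600, 550, 640};
  if (n < 3) return INF;
  if (n <= 9) return tab[n];
  return 640 + (int)(107.856 * std::log((double)n / 9.0));
}

static int bulge_E(int n) {
  static const int tab[7] = {0, 380, 280, 320, 360, 400, 440};
  if (n <= 6) return tab[n];
  return 440 + (int)(107.856 * std::log((double)n / 6.0));
}

static int internal_E(int n1, int n2) {
  static const int tab[7] = {0, 0, 150, 160, 170, 200, 200};
  int n = n1 + n2;
  int e = (n <= 6) ? tab[n] : 200 + (int)(107.856 * std::log((double)n / 6.0));
  int asym = 50 * std::abs(n1 - n2);
  if (asym > 300) asym = 300;
  return e + asym;
}

struct Fold {
  int n;
  std::vector<char> s;           // 1-based
  std::vector<int> V, WM, WM1;   // (n+2)*(n+2), 1-based
  std::vector<int> W;            // 0..n

  int &at(std::vector<int> &m, int i, int j) { return m[(size_t)i * (n + 2) + j]; }

  int loop_energy(int i, int j, int k, int l) {
    int pt2 = pair_type(s[k], s[l]);
    if (pt2 < 0) return INF;
    int n1 = k - i - 1, n2 = j - l - 1;
    if (n1 == 0 && n2 == 0) {
      int pt1 = pair_type(s[i], s[j]);
      return STACK[pt1][pt2];
    }
    if (n1 == 0 || n2 == 0) return bulge_E(n1 + n2);
    return internal_E(n1, n2);
  }

  void run(const std::string &seq) {
    n = (int)seq.size();
    s.assign(n + 2, 'N');
    for (int i = 1; i <= n; ++i) s[i] = seq[i - 1];
    V.assign((size_t)(n + 2) * (n + 2), INF);
    WM.assign((size_t)(n + 2) * (n + 2), INF);
    WM1.assign((size_t)(n + 2) * (n + 2), INF);
    W.assign(n + 1, 0);

    for (int d = 4; d < n; ++d) {
      for (int i = 1; i + d <= n; ++i) {
        int j = i + d;
        int pt = pair_type(s[i], s[j]);
        int v = INF;
        if (pt >= 0) {
          v = hairpin_E(j - i - 1);
          // stacking / bulge / internal loops
          int kmax = std::min(i + MAXLOOP + 1, j - 4);
          for (int k = i + 1; k <= kmax; ++k) {
            int n1 = k - i - 1;
            int lmin = std::max(k + 4, j - 1 - (MAXLOOP - n1));
            for (int l = lmin; l < j; ++l) {
              int vin = at(V, k, l);
              if (vin >= INF) continue;
              int e = loop_energy(i, j, k, l);
              if (e < INF && vin + e < v) v = vin + e;
            }
          }
          // multiloop closure: >= 2 branches inside
          for (int k = i + 2; k <= j - 2; ++k) {
            int a = at(WM, i + 1, k - 1), b = at(WM1, k, j - 1);
            if (a < INF && b < INF && a + b + ML_CLOSE + ML_BRANCH < v)
              v = a + b + ML_CLOSE + ML_BRANCH;
          }
        }
        at(V, i, j) = v;

        // WM1: one branch starting at i, ending anywhere <= j
        int wm1 = at(WM1, i, j - 1);
        if (v < INF && v + ML_BRANCH < wm1) wm1 = v + ML_BRANCH;
        at(WM1, i, j) = wm1;

        // WM: >= 1 branch within [i, j]
        int wm = std::min(at(WM, i + 1, j), at(WM, i, j - 1));
        if (v < INF && v + ML_BRANCH < wm) wm = v + ML_BRANCH;
        for (int k = i + 1; k <= j - 4; ++k) {
          int a = at(WM, i, k - 1), b = at(V, k, j);
          if (a < INF && b < INF && a + b + ML_BRANCH < wm)
            wm = a + b + ML_BRANCH;
        }
        at(WM, i, j) = wm;
      }
      // short spans keep INF defaults; WM/WM1 for d < 4 stay INF
    }
    for (int j = 1; j <= n; ++j) {
      int w = W[j - 1];
      for (int i = 1; i + 4 <= j; ++i) {
        int v = at(V, i, j);
        if (v < INF && W[i - 1] + v < w) w = W[i - 1] + v;
      }
      W[j] = w;
    }
  }

  void traceback(std::vector<int> &pairs) {
    pairs.assign(n + 1, 0);
    // states: 0 = V(i,j), 1 = WM(i,j)
    std::vector<std::array<int, 3>> stack;
    // external loop
    {
      int j = n;
      while (j > 0) {
        if (W[j] == W[j - 1]) { --j; continue; }
        bool found = false;
        for (int i = 1; i + 4 <= j; ++i) {
          int v = at(V, i, j);
          if (v < INF && W[i - 1] + v == W[j]) {
            stack.push_back({0, i, j});
            j = i - 1;
            found = true;
            break;
          }
        }
        if (!found) break; // defensive; should not happen
      }
    }
    while (!stack.empty()) {
      auto st = stack.back();
      stack.pop_back();
      int i = st[1], j = st[2];
      if (st[0] == 0) { // V(i,j): i pairs j
        pairs[i] = j;
        pairs[j] = i;
        int v = at(V, i, j);
        if (v == hairpin_E(j - i - 1)) continue;
        bool found = false;
        int kmax = std::min(i + MAXLOOP + 1, j - 4);
        for (int k = i + 1; k <= kmax && !found; ++k) {
          int n1 = k - i - 1;
          int lmin = std::max(k + 4, j - 1 - (MAXLOOP - n1));
          for (int l = lmin; l < j; ++l) {
            int vin = at(V, k, l);
            if (vin >= INF) continue;
            int e = loop_energy(i, j, k, l);
            if (e < INF && vin + e == v) {
              stack.push_back({0, k, l});
              found = true;
              break;
            }
          }
        }
        if (found) continue;
        for (int k = i + 2; k <= j - 2 && !found; ++k) {
          int a = at(WM, i + 1, k - 1), b = at(WM1, k, j - 1);
          if (a < INF && b < INF && a + b + ML_CLOSE + ML_BRANCH == v) {
            stack.push_back({1, i + 1, k - 1});
            // resolve WM1(k, j-1): branch V(k, l)
            for (int l = j - 1; l >= k + 4; --l) {
              if (at(V, k, l) < INF &&
                  at(V, k, l) + ML_BRANCH == at(WM1, k, j - 1)) {
                stack.push_back({0, k, l});
                break;
              }
            }
            found = true;
          }
        }
      } else { // WM(i,j)
        int wm = at(WM, i, j);
        if (wm >= INF) continue;
        if (at(WM, i + 1, j) == wm) { stack.push_back({1, i + 1, j}); continue; }
        if (at(WM, i, j - 1) == wm) { stack.push_back({1, i, j - 1}); continue; }
        if (at(V, i, j) < INF && at(V, i, j) + ML_BRANCH == wm) {
          stack.push_back({0, i, j});
          continue;
        }
        for (int k = i + 1; k <= j - 4; ++k) {
          int a = at(WM, i, k - 1), b = at(V, k, j);
          if (a < INF && b < INF && a + b + ML_BRANCH == wm) {
            stack.push_back({1, i, k - 1});
            stack.push_back({0, k, j});
            break;
          }
        }
      }
    }
  }
};

// [[Rcpp::export]]
List fold_zuker_cpp(std::string seq) {
  Fold f;
  f.run(seq);
  std::vector<int> pairs;
  f.traceback(pairs);
  std::string db(seq.size(), '.');
  for (int i = 1; i <= f.n; ++i) {
    if (pairs[i] > i) db[i - 1] = '(';
    else if (pairs[i] > 0 && pairs[i] < i) db[i - 1] = ')';
  }
  double mfe = f.W[f.n] / 100.0;
  return List::create(_["dotbracket"] = db, _["mfe"] = mfe);
}
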