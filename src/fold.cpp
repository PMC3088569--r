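// Minimum-free-energy folding of nested RNA secondary structures.
//
// Zuker-style dynamic programme over the nearest-neighbour model defined in
// R/energy.R; the parameter tables are passed in from R so both sides share
// one definition. Energies are integers in 10 cal/mol units.
//
//   V[i][j]  : MFE of i..j given (i,j) paired
//   M[i][j]  : MFE of i..j containing >= 1 multiloop branch
//              (branch cost ml_branch, unpaired cost ml_unpaired)
//   Ext[i][j]: MFE of i..j as an exterior (free) segment
//
// Ext is filled for every (i,j), so the MFE of any subwindow is a table
// lookup — the precursor scan exploits this to score all candidate
// subwindows from one fill.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const int INF = 100000000;

struct Params {
  int stack[7][7];
  std::vector<int> hairpin, bulge, internal_;
  int ninio, ninio_max, ml_close, ml_branch, ml_unpaired;
  int min_hairpin, max_interior;
};

static int pair_type_tab[5][5];

static void init_pair_types() {
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b) pair_type_tab[a][b] = 0;
  pair_type_tab[2][3] = 1; // CG
  pair_type_tab[3][2] = 2; // GC
  pair_type_tab[3][4] = 3; // GU
  pair_type_tab[4][3] = 4; // UG
  pair_type_tab[1][4] = 5; // AU
  pair_type_tab[4][1] = 6; // UA
}

static Params read_params(const List& par) {
  Params p;
  IntegerMatrix st = par["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) p.stack[a + 1][b + 1] = st(a, b);
  IntegerVector h = par["hairpin"], bu = par["bulge"], in = par["internal"];
  p.hairpin.assign(h.begin(), h.end());
  p.bulge.assign(bu.begin(), bu.end());
  p.internal_.assign(in.begin(), in.end());
  p.ninio = as<int>(par["ninio"]);
  p.ninio_max = as<int>(par["ninio_max"]);
  p.ml_close = as<int>(par["ml_close"]);
  p.ml_branch = as<int>(par["ml_branch"]);
  p.ml_unpaired = as<int>(par["ml_unpaired"]);
  p.min_hairpin = as<int>(par["min_hairpin"]);
  p.max_interior = as<int>(par["max_interior"]);
  return p;
}

struct Tables {
  int n;
  std::vector<int> V, M, Ext;
  std::vector<int> code;
  int at(const std::vector<int>& t, int i, int j) const { return t[i * n + j]; }
};

static inline int ptype(const std::vector<int>& code, int i, int j) {
  return pair_type_tab[code[i]][code[j]];
}

// interior-loop (incl. stack / bulge) penalty between closing (i,j) and
// inner (k,l); returns INF when the loop violates the interior cap
static inline int loop_energy(const Params& p, const std::vector<int>& code,
                              int i, int j, int k, int l) {
  int n1 = k - i - 1, n2 = j - l - 1;
  if (n1 + n2 > p.max_interior) return INF;
  if (n1 == 0 && n2 == 0)
    return p.stack[ptype(code, i, j)][ptype(code, k, l)];
  if (n1 == 0 || n2 == 0) return p.bulge[n1 + n2 - 1];
  int asym = p.ninio * std::abs(n1 - n2);
  if (asym > p.ninio_max) asym = p.ninio_max;
  return p.internal_[n1 + n2 - 1] + asym;
}

static void fill_tables(Tables& T, const Params& p) {
  const int n = T.n;
  const std::vector<int>& code = T.code;
  T.V.assign((size_t)n * n, INF);
  T.M.assign((size_t)n * n, INF);
  T.Ext.assign((size_t)n * n, 0);
  std::vector<int>& V = T.V;
  std::vector<int>& M = T.M;
  std::vector<int>& Ext = T.Ext;

  for (int span = p.min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // --- V ---
      if (ptype(code, i, j) != 0) {
        int best = INF;
        int hsize = j - i - 1;
        if (hsize >= p.min_hairpin && hsize <= (int)p.hairpin.size())
          best = p.hairpin[hsize - 1];
        int kmax = std::min(i + 1 + p.max_interior, j - 2);
        for (int k = i + 1; k <= kmax; ++k) {
          int n1 = k - i - 1;
          int lmin = std::max(k + p.min_hairpin + 1,
                              j - 1 - (p.max_interior - n1));
          for (int l = j - 1; l >= lmin; --l) {
            if (V[(size_t)k * n + l] >= INF) continue;
            int e = loop_energy(p, code, i, j, k, l);
            if (e >= INF) continue;
            e += V[(size_t)k * n + l];
            if (e < best) best = e;
          }
        }
        // multiloop closed by (i,j): two or more branches inside
        for (int k = i + 2; k <= j - 2; ++k) {
          int left = M[(size_t)(i + 1) * n + (k - 1)];
          int right = M[(size_t)k * n + (j - 1)];
          if (left >= INF || right >= INF) continue;
          int e = p.ml_close + p.ml_branch + left + right;
          if (e < best) best = e;
        }
        V[(size_t)i * n + j] = best;
      }
      // --- M ---
      {
        int best = INF;
        if (span >= 1) {
          int down = M[(size_t)(i + 1) * n + j];
          if (down < INF) {
            int e = down + p.ml_unpaired;
            if (e < best) best = e;
          }
        }
        for (int l = i + p.min_hairpin + 1; l <= j; ++l) {
          int v = V[(size_t)i * n + l];
          if (v >= INF) continue;
          int e1 = v + p.ml_branch + p.ml_unpaired * (j - l);
          if (e1 < best) best = e1;
          if (l + 1 <= j) {
            int rest = M[(size_t)(l + 1) * n + j];
            if (rest < INF) {
              int e2 = v + p.ml_branch + rest;
              if (e2 < best) best = e2;
            }
          }
        }
        M[(size_t)i * n + j] = best;
      }
      // --- Ext ---
      {
        int best = Ext[(size_t)(i + 1) * n + j]; // i unpaired (0 when i+1>j)
        if (i + 1 > j) best = 0;
        for (int l = i + p.min_hairpin + 1; l <= j; ++l) {
          int v = V[(size_t)i * n + l];
          if (v >= INF) continue;
          int rest = (l + 1 <= j) ? Ext[(size_t)(l + 1) * n + j] : 0;
          int e = v + rest;
          if (e < best) best = e;
        }
        Ext[(size_t)i * n + j] = best;
      }
    }
  }
}

// ---- traceback (deterministic preference: pair as early/left as possible)

static void tb_V(const Tables& T, const Params& p, int i, int j,
                 std::vector<int>& partner);

static void tb_M(const Tables& T, const Params& p, int i, int j,
                 std::vector<int>& partner) {
  const int n = T.n;
  while (i <= j) {
    int cur = T.M[(size_t)i * n + j];
    bool advanced = false;
    for (int l = i + p.min_hairpin + 1; l <= j; ++l) {
      int v = T.V[(size_t)i * n + l];
      if (v >= INF) continue;
      if (v + p.ml_branch + p.ml_unpaired * (j - l) == cur) {
        tb_V(T, p, i, l, partner);
        return;
      }
      if (l + 1 <= j && T.M[(size_t)(l + 1) * n + j] < INF &&
          v + p.ml_branch + T.M[(size_t)(l + 1) * n + j] == cur) {
        tb_V(T, p, i, l, partner);
        i = l + 1;
        advanced = true;
        break;
      }
    }
    if (advanced) continue;
    // i unpaired
    ++i;
  }
}

static void tb_V(const Tables& T, const Params& p, int i, int j,
                 std::vector<int>& partner) {
  const int n = T.n;
  const std::vector<int>& code = T.code;
  partner[i] = j;
  partner[j] = i;
  int cur = T.V[(size_t)i * n + j];
  int kmax = std::min(i + 1 + p.max_interior, j - 2);
  for (int k = i + 1; k <= kmax; ++k) {
    int n1 = k - i - 1;
    int lmin = std::max(k + p.min_hairpin + 1, j - 1 - (p.max_interior - n1));
    for (int l = j - 1; l >= lmin; --l) {
      if (T.V[(size_t)k * n + l] >= INF) continue;
      int e = loop_energy(p, code, i, j, k, l);
      if (e >= INF) continue;
      if (e + T.V[(size_t)k * n + l] == cur) {
        tb_V(T, p, k, l, partner);
        return;
      }
    }
  }
  for (int k = i + 2; k <= j - 2; ++k) {
    int left = T.M[(size_t)(i + 1) * n + (k - 1)];
    int right = T.M[(size_t)k * n + (j - 1)];
    if (left >= INF || right >= INF) continue;
    if (p.ml_close + p.ml_branch + left + right == cur) {
      tb_M(T, p, i + 1, k - 1, partner);
      tb_M(T, p, k, j - 1, partner);
      return;
    }
  }
  // hairpin: nothing further to trace
}

static void tb_ext(const Tables& T, const Params& p, int i, int j,
                   std::vector<int>& partner) {
  const int n = T.n;
  while (i <= j) {
    int cur = T.Ext[(size_t)i * n + j];
    bool paired = false;
    for (int l = i + p.min_hairpin + 1; l <= j; ++l) {
      int v = T.V[(size_t)i * n + l];
      if (v >= INF) continue;
      int rest = (l + 1 <= j) ? T.Ext[(size_t)(l + 1) * n + j] : 0;
      if (v + rest == cur) {
        tb_V(T, p, i, l, partner);
        i = l + 1;
        paired = true;
        break;
      }
    }
    if (!paired) ++i;
  }
}

static Tables make_tables(const IntegerVector& seq_code, const List& par,
                          Params& p) {
  init_pair_types();
  p = read_params(par);
  Tables T;
  T.n = seq_code.size();
  T.code.assign(seq_code.begin(), seq_code.end());
  fill_tables(T, p);
  return T;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq_code, List par) {
  Params p;
  Tables T = make_tables(seq_code, par, p);
  int n = T.n;
  std::vector<int> partner(n, -1);
  for (int i = 0; i < n; ++i) partner[i] = -1;
  int mfe = (n >= 2) ? T.Ext[0 * (size_t)n + (n - 1)] : 0;
  if (n >= 2) tb_ext(T, p, 0, n - 1, partner);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = partner[i] >= 0 ? partner[i] + 1 : 0;
  return List::create(_["energy"] = mfe, _["partner"] = out);
}

// [[Rcpp::export(name = ".scan_mfe_cpp")]]
IntegerMatrix scan_mfe_cpp(IntegerVector seq_code, List par,
                           int len_min, int len_max, int lo, int hi) {
  // lo/hi: 1-based bounds of the region every subwindow must contain
  Params p;
  Tables T = make_tables(seq_code, par, p);
  int n = T.n;
  std::vector<int> starts, lens, energies;
  for (int s = 1; s <= lo; ++s) {
    for (int L = len_min; L <= len_max; ++L) {
      int e = s + L - 1;
      if (e > n) break;
      if (e < hi) continue;
      int mfe = T.Ext[(size_t)(s - 1) * n + (e - 1)];
      starts.push_back(s);
      lens.push_back(L);
      energies.push_back(mfe);
    }
  }
  IntegerMatrix out(starts.size(), 3);
  for (size_t r = 0; r < starts.size(); ++r) {
    out(r, 0) = starts[r];
    out(r, 1) = lens[r];
    out(r, 2) = energies[r];
  }
  colnames(out) = CharacterVector::create("start", "len", "energy");
  return out;
}
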