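#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand under a simple
// nearest-neighbour model (kcal/mol, model-relative):
//   * pair energies: G-C -3.0, A-U -2.0, G-U -1.0
//   * stacking bonus -1.0 when a pair sits directly on another pair
//   * helix initiation penalty +4.0 per maximal helix (suppresses the
//     1-2 bp helices that would otherwise litter random sequence)
//   * +0.5 per unpaired base inside an internal, bulge or multibranch
//     loop (hairpin loops and the exterior are free)
//   * hairpin loops of at least 3 nt (a pair i..j needs j - i >= 4)
//   * nested structures only (no pseudoknots); N and masked bases never pair
// The empty structure scores 0, so the MFE is always <= 0.
//
// Bases are encoded upstream as integers: A=0, C=1, G=2, U/T=3, other=4.

static const double INF = std::numeric_limits<double>::infinity();
static const double STACK_BONUS = -1.0;
static const double HELIX_INIT = 4.0;
static const double LOOP_BASE = 0.5;
static const int MIN_HAIRPIN = 3;

static inline double pair_energy(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3.0; // G-C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2.0; // A-U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -1.0; // G-U
  return INF;
}

class Folder {
public:
  const std::vector<int> &s;
  const std::vector<bool> &masked;
  int n;
  // V(i,j): best energy of [i,j] with i paired to j, excluding the
  // initiation of the helix (i,j) belongs to (added where the helix is
  // opened). M(i,j): best energy of [i,j] in loop context (each unpaired
  // base costs LOOP_BASE). W(i,j): exterior context (unpaired free).
  std::vector<double> V, W, M;

  Folder(const std::vector<int> &seq, const std::vector<bool> &msk)
    : s(seq), masked(msk), n((int)seq.size()),
      V((size_t)seq.size() * seq.size(), INF),
      W((size_t)seq.size() * seq.size(), 0.0),
      M((size_t)seq.size() * seq.size(), 0.0) {}

  inline bool can_pair(int i, int j) const {
    if (j - i <= MIN_HAIRPIN) return false;
    if (masked[i] || masked[j]) return false;
    if (s[i] > 3 || s[j] > 3) return false;
    return pair_energy(s[i], s[j]) < 0;
  }
  inline double &v(int i, int j) { return V[(size_t)i * n + j]; }
  inline double &w(int i, int j) { return W[(size_t)i * n + j]; }
  inline double &m(int i, int j) { return M[(size_t)i * n + j]; }
  inline double wat(int i, int j) { return (i > j || j < 0 || i >= n) ? 0.0 : w(i, j); }
  inline double mat(int i, int j) {
    return (i > j || j < 0 || i >= n) ? 0.0 : m(i, j);
  }

  void run() {
    for (int i = 0; i < n; ++i) m(i, i) = LOOP_BASE;
    for (int span = 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        if (span > MIN_HAIRPIN && can_pair(i, j)) {
          double best = 0.0; // hairpin closure: loop bases free
          if (can_pair(i + 1, j - 1)) {
            double st = v(i + 1, j - 1) + STACK_BONUS; // helix continues
            if (st < best) best = st;
          }
          // internal/bulge/multibranch loop: interior in loop context
          double inner = mat(i + 1, j - 1);
          if (inner < best) best = inner;
          v(i, j) = pair_energy(s[i], s[j]) + best;
        }
        // loop context: unpaired bases cost LOOP_BASE
        double bm = mat(i, j - 1) + LOOP_BASE;
        for (int k = i; k <= j - MIN_HAIRPIN - 1; ++k) {
          if (!can_pair(k, j)) continue;
          double cand = mat(i, k - 1) + v(k, j) + HELIX_INIT;
          if (cand < bm) bm = cand;
        }
        m(i, j) = bm;
        // exterior context: unpaired bases free
        double best = wat(i, j - 1);
        for (int k = i; k <= j - MIN_HAIRPIN - 1; ++k) {
          if (!can_pair(k, j)) continue;
          double cand = wat(i, k - 1) + v(k, j) + HELIX_INIT;
          if (cand < best) best = cand;
        }
        w(i, j) = best;
      }
    }
  }

  // Deterministic traceback; ties resolved in a fixed branch order.
  // ctx: 0 = exterior (W), 1 = paired (V), 2 = loop (M).
  void trace(std::vector<int> &partner) {
    struct Frame { int i, j, ctx; };
    std::vector<Frame> stack;
    if (n > MIN_HAIRPIN + 1) stack.push_back({0, n - 1, 0});
    const double eps = 1e-9;
    while (!stack.empty()) {
      Frame fr = stack.back();
      stack.pop_back();
      int i = fr.i, j = fr.j;
      if (j < i) continue;
      if (fr.ctx == 1) {
        partner[i] = j;
        partner[j] = i;
        double rest = v(i, j) - pair_energy(s[i], s[j]);
        if (std::abs(rest) < eps) continue; // hairpin
        if (can_pair(i + 1, j - 1) &&
            std::abs(v(i + 1, j - 1) + STACK_BONUS - rest) < eps) {
          stack.push_back({i + 1, j - 1, 1});
          continue;
        }
        stack.push_back({i + 1, j - 1, 2});
        continue;
      }
      bool ext = fr.ctx == 0;
      double target = ext ? w(i, j) : m(i, j);
      if (ext && target >= -eps) continue; // open chain
      double drop = ext ? wat(i, j - 1) : mat(i, j - 1) + LOOP_BASE;
      if (std::abs(drop - target) < eps) {
        stack.push_back({i, j - 1, fr.ctx});
        continue;
      }
      for (int k = i; k <= j - MIN_HAIRPIN - 1; ++k) {
        if (!can_pair(k, j)) continue;
        double left = ext ? wat(i, k - 1) : mat(i, k - 1);
        if (std::abs(left + v(k, j) + HELIX_INIT - target) < eps) {
          if (k > i) stack.push_back({i, k - 1, fr.ctx});
          stack.push_back({k, j, 1});
          break;
        }
      }
    }
  }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq, LogicalVector mask) {
  int n = seq.size();
  if (n == 0) stop("empty sequence");
  if (n > 4000) stop("sequence longer than 4000 nt not supported by the built-in folder");
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<bool> msk(n);
  for (int i = 0; i < n; ++i) msk[i] = mask[i];
  std::vector<int> partner(n, -1);
  double energy = 0.0;
  if (n > MIN_HAIRPIN + 1) {
    Folder f(s, msk);
    f.run();
    energy = f.w(0, n - 1);
    f.trace(partner);
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = partner[i] + 1; // 1-based, 0 = unpaired
  return List::create(_["pairs"] = out, _["energy"] = energy);
}

// Energy of a given (valid, nested) structure under the same model:
// pair energies, stacking bonuses, one initiation per maximal helix (a
// pair opens a helix when (i-1, j+1) is not also a pair), and LOOP_BASE
// per unpaired base whose innermost enclosing pair closes a non-hairpin
// loop (hairpin-loop and exterior bases are free).
// [[Rcpp::export(name = ".structure_energy_cpp")]]
double structure_energy_cpp(IntegerVector seq, IntegerVector pairs) {
  int n = seq.size();
  double e = 0.0;
  std::vector<int> paired_before(n + 1, 0);
  for (int i = 0; i < n; ++i)
    paired_before[i + 1] = paired_before[i] + (pairs[i] > 0 ? 1 : 0);
  for (int i = 0; i < n; ++i) {
    int j = pairs[i] - 1;
    if (j <= i) continue;
    double pe = pair_energy(seq[i], seq[j]);
    if (pe == INF) stop("structure contains a non-canonical pair");
    e += pe;
    bool stacked_inner = (i + 1 < n) && (pairs[i + 1] - 1 == j - 1) && (j - 1 > i + 1);
    if (stacked_inner) e += STACK_BONUS;
    bool opens = (i == 0) || (j + 1 >= n) || (pairs[i - 1] - 1 != j + 1);
    if (opens) e += HELIX_INIT;
  }
  // loop-context unpaired bases
  std::vector<std::pair<int, int>> enclosing;
  for (int x = 0; x < n; ++x) {
    int p = pairs[x] - 1;
    if (p > x) {
      enclosing.push_back({x, p});
    } else if (p >= 0 && p < x) {
      enclosing.pop_back();
    } else if (!enclosing.empty()) {
      int a = enclosing.back().first, b = enclosing.back().second;
      if (paired_before[b] - paired_before[a + 1] > 0) e += LOOP_BASE;
    }
  }
  return e;
}
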