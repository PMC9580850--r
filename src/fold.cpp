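#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

// Simplified nearest-neighbor minimum-free-energy folder for single-stranded
// DNA templates/amplicons. Model:
//   * Watson-Crick pairs plus G.T wobble; N never pairs.
//   * Structures are non-crossing sets of helices; only helices of at least
//     `minHelix` consecutive stacked pairs contribute energy (shorter runs
//     are not allowed to form).
//   * Energy = sum of stack free energies within helices (dH - T*dS from the
//     unified nearest-neighbor table for Watson-Crick stacks; a fixed weak
//     term for any stack involving a wobble pair) + an entropic hairpin-loop
//     penalty for loops of length >= `minLoop` + a fixed entropic penalty
//     for every helix whose inner region contains further structure
//     (interior/bulge/multi-branch closing).
//   * Reported delta G is min(0, MFE): a fold is only reported when it is
//     stabilising, so deltaG == 0 iff no pairs.

static const double R_GAS = 1.9872; // cal / (mol K)

// Unified NN stack dH (kcal/mol) and dS (cal/mol/K), indexed by the
// 5'->3' dinucleotide on one strand (A=0, C=1, G=2, T=3; idx = 4*x1 + x2).
static const double STACK_DH[16] = {
  /*AA*/ -7.9, /*AC*/ -8.4, /*AG*/ -7.8, /*AT*/ -7.2,
  /*CA*/ -8.5, /*CC*/ -8.0, /*CG*/ -10.6, /*CT*/ -7.8,
  /*GA*/ -8.2, /*GC*/ -9.8, /*GG*/ -8.0, /*GT*/ -8.4,
  /*TA*/ -7.2, /*TC*/ -8.2, /*TG*/ -8.5, /*TT*/ -7.9
};
static const double STACK_DS[16] = {
  /*AA*/ -22.2, /*AC*/ -22.4, /*AG*/ -21.0, /*AT*/ -20.4,
  /*CA*/ -22.7, /*CC*/ -19.9, /*CG*/ -27.2, /*CT*/ -21.0,
  /*GA*/ -22.2, /*GC*/ -24.4, /*GG*/ -19.9, /*GT*/ -22.4,
  /*TA*/ -21.3, /*TC*/ -22.2, /*TG*/ -22.7, /*TT*/ -22.2
};

// any stack involving a G.T wobble pair
static const double WOBBLE_DH = -4.0;   // kcal/mol
static const double WOBBLE_DS = -11.5;  // cal/mol/K

static const double BIG = 1e18;
static const double EPS = 1e-6;

static inline int enc(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4; // N and anything else: never pairs
  }
}

static inline bool canPair(int a, int b) {
  if (a > 3 || b > 3) return false;
  return (a + b == 3) || (a + b == 5); // WC (A+T, C+G) or G.T wobble
}

static inline bool isWobble(int a, int b) { return a + b == 5; }

struct FoldModel {
  double tK;       // temperature in Kelvin
  int minHelix;    // minimum pairs per helix
  int minLoop;     // minimum hairpin loop length

  // stack between outer pair (xo, yo) and inner pair (xi, yi);
  // xo/xi on the 5' side of the helix
  double stackG(int xo, int yo, int xi, int yi) const {
    if (isWobble(xo, yo) || isWobble(xi, yi))
      return WOBBLE_DH - tK * WOBBLE_DS / 1000.0;
    int idx = 4 * xo + xi;
    return STACK_DH[idx] - tK * STACK_DS[idx] / 1000.0;
  }

  // entropic hairpin-loop penalty, kcal/mol, Jacobson-Stockmayer growth
  double hairpinG(int L) const {
    double s = 11.29 + 1.75 * R_GAS * std::log((double)L / 3.0);
    return tK * s / 1000.0;
  }

  // entropic penalty for closing an interior/bulge/multi-branch region
  // (any helix whose inner region contains further structure)
  double interiorG() const { return tK * 12.0 / 1000.0; }
};

class Folder {
public:
  Folder(const std::string &seq, const FoldModel &model)
    : m(model), n((int)seq.size()) {
    s.resize(n);
    for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
    W.assign((size_t)n * n, 0.0);
    Wne.assign((size_t)n * n, BIG);
    C.assign((size_t)n * n, BIG);
    fill();
  }

  double mfe() const {
    if (n == 0) return 0.0;
    return getW(0, n - 1);
  }

  std::string traceback() {
    db.assign(n, '.');
    if (n > 0 && mfe() < -EPS) tbWne(0, n - 1);
    return std::string(db.begin(), db.end());
  }

private:
  FoldModel m;
  int n;
  std::vector<int> s;
  std::vector<double> W, Wne, C;
  std::vector<char> db;

  inline double &at(std::vector<double> &v, int i, int j) {
    return v[(size_t)i * n + j];
  }
  inline double cat(const std::vector<double> &v, int i, int j) const {
    return v[(size_t)i * n + j];
  }
  inline double getW(int i, int j) const {
    if (i > j) return 0.0;
    return cat(W, i, j);
  }
  inline double getWne(int i, int j) const {
    if (i > j) return BIG;
    return cat(Wne, i, j);
  }

  // minimal span that can hold one helix + hairpin loop
  inline int minSpan() const { return 2 * m.minHelix + m.minLoop; }

  // energy of helix of k pairs closing (i, j) plus optimal inner region;
  // writes nothing, used both to fill C and to trace back
  double helixBest(int i, int j, int *bestK) const {
    double best = BIG;
    double stackAcc = 0.0;
    int kBest = -1;
    for (int k = 1;; ++k) {
      int a = i + k - 1, b = j - k + 1;
      if (a >= b) break;
      if (!canPair(s[a], s[b])) break;
      if (k >= 2) stackAcc += m.stackG(s[a - 1], s[b + 1], s[a], s[b]);
      if (k >= m.minHelix) {
        int p = i + k, q = j - k;
        int L = q - p + 1;
        double inner = BIG;
        if (L >= m.minLoop) inner = m.hairpinG(L);
        if (p <= q) {
          double wi = getWne(p, q);
          if (wi < BIG / 2 && wi + m.interiorG() < inner)
            inner = wi + m.interiorG();
        }
        if (inner < BIG / 2 && stackAcc + inner < best - EPS) {
          best = stackAcc + inner;
          kBest = k;
        }
      }
    }
    if (bestK) *bestK = kBest;
    return best;
  }

  void fill() {
    for (int span = minSpan(); span <= n; ++span) {
      for (int i = 0; i + span - 1 < n; ++i) {
        int j = i + span - 1;
        at(C, i, j) = helixBest(i, j, nullptr);
        double w = getWne(i + 1, j);
        for (int b = i + minSpan() - 1; b <= j; ++b) {
          double c = cat(C, i, b);
          if (c < BIG / 2) {
            double cand = c + getW(b + 1, j);
            if (cand < w) w = cand;
          }
        }
        at(Wne, i, j) = w;
        at(W, i, j) = (w < 0.0) ? w : 0.0;
      }
    }
    // W defaults to 0 (empty structure) for spans below minSpan
  }

  void tbW(int i, int j) {
    if (i > j) return;
    if (getW(i, j) >= -EPS) return; // empty structure
    tbWne(i, j);
  }

  void tbWne(int i, int j) {
    double target = getWne(i, j);
    if (target >= BIG / 2) return;
    if (std::fabs(getWne(i + 1, j) - target) < EPS) {
      tbWne(i + 1, j);
      return;
    }
    for (int b = i + minSpan() - 1; b <= j; ++b) {
      double c = cat(C, i, b);
      if (c < BIG / 2 && std::fabs(c + getW(b + 1, j) - target) < EPS) {
        tbC(i, b);
        tbW(b + 1, j);
        return;
      }
    }
  }

  void tbC(int i, int j) {
    double target = cat(C, i, j);
    double stackAcc = 0.0;
    for (int k = 1;; ++k) {
      int a = i + k - 1, b = j - k + 1;
      if (a >= b) break;
      if (!canPair(s[a], s[b])) break;
      if (k >= 2) stackAcc += m.stackG(s[a - 1], s[b + 1], s[a], s[b]);
      if (k >= m.minHelix) {
        int p = i + k, q = j - k;
        int L = q - p + 1;
        bool hairpinOk = (L >= m.minLoop) &&
          std::fabs(stackAcc + m.hairpinG(L) - target) < EPS;
        bool innerOk = (p <= q) && getWne(p, q) < BIG / 2 &&
          std::fabs(stackAcc + getWne(p, q) + m.interiorG() - target) < EPS;
        if (hairpinOk || innerOk) {
          for (int t = 0; t < k; ++t) {
            db[i + t] = '(';
            db[j - t] = ')';
          }
          if (!hairpinOk) tbWne(p, q);
          return;
        }
      }
    }
  }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, double temperatureC,
                  int minHelix = 3, int minLoop = 3) {
  FoldModel model;
  model.tK = temperatureC + 273.15;
  model.minHelix = minHelix;
  model.minLoop = minLoop;
  Folder f(seq, model);
  double dg = f.mfe();
  if (dg >= -EPS) {
    return List::create(_["delta_g"] = 0.0,
                        _["structure"] = std::string(seq.size(), '.'));
  }
  std::string db = f.traceback();
  return List::create(_["delta_g"] = dg, _["structure"] = db);
}
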