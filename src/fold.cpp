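#include <Rcpp.h>
using namespace Rcpp;

// Built-in stacking energy model for nested RNA secondary structures.
//
// A structure's energy is the sum of contributions of adjacent stacked
// pairs (i,j),(i+1,j-1): e[0] if both pairs are G-C, e[1] if exactly one
// is G-C, e[2] otherwise. Unpaired bases are free. Lone pairs (helices of
// length 1) can be forbidden (noLP). Hairpin loops must hold >= min_loop
// unpaired bases; this is folded into the `allowed` pair matrix built on
// the R side (together with user constraints).
//
// Grammar used by both the MFE and the partition-function recursions
// (Cp = pair that may still receive an outward stack; CF = fully valid
// pair, i.e. under noLP the outer pair of a helix, which must stack
// inward; F = any valid structure on an interval; Mno = F without the
// closing pair of the interval):
//
//   F(i,j)  -> F(i,j-1)                          [j unpaired]
//   F(i,j)  -> F(i,k-1) CF(k,j)                  [j paired with k]
//   CF(i,j) -> s(i,j) Cp(i+1,j-1)                [noLP on]
//   CF(i,j) -> Cp(i,j)                           [noLP off]
//   Cp(i,j) -> s(i,j) Cp(i+1,j-1)                [stack continues]
//   Cp(i,j) -> F(i+1,j-2)                        [j-1 unpaired inside]
//   Cp(i,j) -> F(i+1,k-1) CF(k,j-1)              [j-1 paired inside]
//
// Base-pair probabilities come from the matching outside pass.

static const double INF = 1e18;

struct Model {
  IntegerVector seq;   // 0=A 1=C 2=G 3=U
  LogicalMatrix allowed;
  LogicalVector mustpair;
  bool noLP;
  double e_gc, e_mix, e_other;
  int n;

  bool isGC(int i, int j) const {
    int a = seq[i], b = seq[j];
    return (a == 1 && b == 2) || (a == 2 && b == 1);
  }
  // stack energy between outer pair (i,j) and inner pair (i+1,j-1)
  double stackE(int i, int j) const {
    bool g1 = isGC(i, j), g2 = isGC(i + 1, j - 1);
    if (g1 && g2) return e_gc;
    if (g1 || g2) return e_mix;
    return e_other;
  }
};

static inline double getM(const NumericMatrix &M, int i, int j, double empty) {
  if (j < i) return empty;
  return M(i, j);
}

// ---------------------------------------------------------------- MFE ----

static void tb_F(const Model &m, const NumericMatrix &F,
                 const NumericMatrix &CF, const NumericMatrix &CP,
                 int i, int j, IntegerVector &pt);

static void tb_CP(const Model &m, const NumericMatrix &F,
                  const NumericMatrix &CF, const NumericMatrix &CP,
                  int i, int j, IntegerVector &pt) {
  const double eps = 1e-6;
  pt[i] = j; pt[j] = i;
  double v = CP(i, j);
  // stack branch first (keeps helices contiguous)
  if (j - i >= 2 && m.allowed(i + 1, j - 1) && CP(i + 1, j - 1) < INF / 2 &&
      std::abs(m.stackE(i, j) + CP(i + 1, j - 1) - v) < eps) {
    tb_CP(m, F, CF, CP, i + 1, j - 1, pt);
    return;
  }
  if (!m.mustpair[j - 1] &&
      std::abs(getM(F, i + 1, j - 2, 0.0) - v) < eps) {
    tb_F(m, F, CF, CP, i + 1, j - 2, pt);
    return;
  }
  for (int k = i + 2; k <= j - 2; ++k) {
    if (CF(k, j - 1) < INF / 2 &&
        std::abs(getM(F, i + 1, k - 1, 0.0) + CF(k, j - 1) - v) < eps) {
      tb_F(m, F, CF, CP, i + 1, k - 1, pt);
      // CF expansion
      if (m.noLP) {
        pt[k] = j - 1; pt[j - 1] = k;
        tb_CP(m, F, CF, CP, k + 1, j - 2, pt);
      } else {
        tb_CP(m, F, CF, CP, k, j - 1, pt);
      }
      return;
    }
  }
  stop("MFE traceback failed (Cp)");
}

static void tb_F(const Model &m, const NumericMatrix &F,
                 const NumericMatrix &CF, const NumericMatrix &CP,
                 int i, int j, IntegerVector &pt) {
  const double eps = 1e-6;
  if (j < i) return;
  double v = F(i, j);
  for (int k = i; k <= j; ++k) {
    if (CF(k, j) < INF / 2 &&
        std::abs(getM(F, i, k - 1, 0.0) + CF(k, j) - v) < eps) {
      tb_F(m, F, CF, CP, i, k - 1, pt);
      if (m.noLP) {
        pt[k] = j; pt[j] = k;
        tb_CP(m, F, CF, CP, k + 1, j - 1, pt);
      } else {
        tb_CP(m, F, CF, CP, k, j, pt);
      }
      return;
    }
  }
  if (!m.mustpair[j] && std::abs(getM(F, i, j - 1, 0.0) - v) < eps) {
    tb_F(m, F, CF, CP, i, j - 1, pt);
    return;
  }
  stop("MFE traceback failed (F)");
}

// [[Rcpp::export]]
List mfe_cpp(IntegerVector seq, LogicalMatrix allowed, LogicalVector mustpair,
             bool noLP, NumericVector energies) {
  Model m{seq, allowed, mustpair, noLP,
          energies[0], energies[1], energies[2], (int)seq.size()};
  int n = m.n;
  NumericMatrix F(n, n), CF(n, n), CP(n, n);
  std::fill(CF.begin(), CF.end(), INF);
  std::fill(CP.begin(), CP.end(), INF);
  std::fill(F.begin(), F.end(), INF);

  for (int d = 0; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // Cp / CF
      if (d >= 2 && m.allowed(i, j)) {
        double cp = INF;
        if (m.allowed(i + 1, j - 1) && CP(i + 1, j - 1) < INF / 2)
          cp = std::min(cp, m.stackE(i, j) + CP(i + 1, j - 1));
        if (!m.mustpair[j - 1]) {
          double f = getM(F, i + 1, j - 2, 0.0);
          if (f < INF / 2) cp = std::min(cp, f);
        }
        for (int k = i + 2; k <= j - 2; ++k) {
          if (CF(k, j - 1) < INF / 2) {
            double f = getM(F, i + 1, k - 1, 0.0);
            if (f < INF / 2) cp = std::min(cp, f + CF(k, j - 1));
          }
        }
        CP(i, j) = cp;
        if (noLP) {
          if (m.allowed(i + 1, j - 1) && CP(i + 1, j - 1) < INF / 2)
            CF(i, j) = m.stackE(i, j) + CP(i + 1, j - 1);
        } else {
          CF(i, j) = cp;
        }
      }
      // F
      double f = INF;
      if (!m.mustpair[j]) {
        double f0 = getM(F, i, j - 1, 0.0);
        if (f0 < INF / 2) f = f0;
      }
      for (int k = i; k <= j; ++k) {
        if (CF(k, j) < INF / 2) {
          double f0 = getM(F, i, k - 1, 0.0);
          if (f0 < INF / 2) f = std::min(f, f0 + CF(k, j));
        }
      }
      F(i, j) = f;
    }
  }

  double mfe = (n > 0) ? F(0, n - 1) : 0.0;
  if (mfe > INF / 2)
    stop("constraints are infeasible: no valid structure exists");
  IntegerVector pt(n, -1);
  if (n > 0) tb_F(m, F, CF, CP, 0, n - 1, pt);
  return List::create(_["energy"] = mfe, _["pairs"] = pt);
}

// --------------------------------------------- partition function --------

// [[Rcpp::export]]
List pf_cpp(IntegerVector seq, LogicalMatrix allowed, LogicalVector mustpair,
            bool noLP, NumericVector energies, double kT) {
  Model m{seq, allowed, mustpair, noLP,
          energies[0], energies[1], energies[2], (int)seq.size()};
  int n = m.n;
  NumericMatrix ZF(n, n), ZCF(n, n), ZCP(n, n);

  for (int d = 0; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      if (d >= 2 && m.allowed(i, j)) {
        double w = std::exp(-m.stackE(i, j) / kT);
        double z = 0.0;
        if (m.allowed(i + 1, j - 1))
          z += w * ZCP(i + 1, j - 1);
        if (!m.mustpair[j - 1]) z += getM(ZF, i + 1, j - 2, 1.0);
        for (int k = i + 2; k <= j - 2; ++k)
          z += getM(ZF, i + 1, k - 1, 1.0) * ZCF(k, j - 1);
        ZCP(i, j) = z;
        ZCF(i, j) = noLP
          ? (m.allowed(i + 1, j - 1) ? w * ZCP(i + 1, j - 1) : 0.0)
          : z;
      }
      double z = m.mustpair[j] ? 0.0 : getM(ZF, i, j - 1, 1.0);
      for (int k = i; k <= j; ++k)
        z += getM(ZF, i, k - 1, 1.0) * ZCF(k, j);
      ZF(i, j) = z;
    }
  }
  double Z = (n > 0) ? ZF(0, n - 1) : 1.0;
  if (!R_finite(Z))
    stop("partition function overflow; fold a shorter window");
  if (Z <= 0) stop("constraints are infeasible: no valid structure exists");

  // outside pass
  NumericMatrix OF(n, n), OCF(n, n), OCP(n, n);
  OF(0, n - 1) = 1.0;
  for (int d = n - 1; d >= 0; --d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // distribute OF(i,j)
      double of = OF(i, j);
      if (of > 0.0) {
        if (!m.mustpair[j] && j - 1 >= i) OF(i, j - 1) += of;
        for (int k = i; k <= j; ++k)
          if (ZCF(k, j) > 0.0) {
            OCF(k, j) += of * getM(ZF, i, k - 1, 1.0);
            if (k - 1 >= i) OF(i, k - 1) += of * ZCF(k, j);
          }
      }
      // distribute OCF(i,j)
      double ocf = OCF(i, j);
      if (ocf > 0.0 && d >= 2 && m.allowed(i, j)) {
        if (noLP) {
          if (m.allowed(i + 1, j - 1))
            OCP(i + 1, j - 1) += ocf * std::exp(-m.stackE(i, j) / kT);
        } else {
          OCP(i, j) += ocf;
        }
      }
      // distribute OCP(i,j)
      double ocp = OCP(i, j);
      if (ocp > 0.0 && d >= 2 && m.allowed(i, j)) {
        double w = std::exp(-m.stackE(i, j) / kT);
        if (m.allowed(i + 1, j - 1)) OCP(i + 1, j - 1) += ocp * w;
        if (!m.mustpair[j - 1] && j - 2 >= i + 1) OF(i + 1, j - 2) += ocp;
        for (int k = i + 2; k <= j - 2; ++k) {
          if (ZCF(k, j - 1) > 0.0) {
            if (k - 1 >= i + 1) OF(i + 1, k - 1) += ocp * ZCF(k, j - 1);
            OCF(k, j - 1) += ocp * getM(ZF, i + 1, k - 1, 1.0);
          }
        }
      }
    }
  }

  NumericMatrix P(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      // with noLP a pair is emitted either as a helix-outer pair (CF) or
      // as a stack continuation (Cp); without noLP everything funnels
      // through Cp via the CF -> Cp unit rule
      double p = noLP ? OCF(i, j) * ZCF(i, j) + OCP(i, j) * ZCP(i, j)
                      : OCP(i, j) * ZCP(i, j);
      p /= Z;
      if (p > 1.0 && p < 1.0 + 1e-9) p = 1.0;
      P(i, j) = p;
      P(j, i) = p;
    }
  }
  return List::create(_["Z"] = Z, _["bp_prob"] = P);
}
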