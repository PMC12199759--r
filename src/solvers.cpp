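// Fixed-point iteration kernels for the mean-field self-consistent
// equations. The R wrappers collapse the degree distribution to the vectors
// passed here; all binomial sums are evaluated in closed form with explicit
// corrections for the s < m leading terms (m is small), so one iteration is
// O(#degrees * m).
#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp01(double v) {
  return v < 0 ? 0 : (v > 1 ? 1 : v);
}

// 0/0 -> 0 convention for conditional probabilities whose conditioning
// event has probability below 1e-14.
static inline double safe_div(double num, double den) {
  if (den < 1e-14) return 0;
  return clamp01(num / den);
}

// Stage 1: link-level pair (x, y). nn[j] is the number of conditioning
// trials for degree class j (k-1 for undirected, kin for directed), w[j]
// its edge-end weight, ch(s, j) = choose(nn[j], s) for s = 0..m-1.
// [[Rcpp::export]]
List stage1_loop(NumericVector nn, NumericVector w, NumericMatrix ch,
                 double q, int m, double x0, double y0, double tol,
                 double max_iter) {
  int nk = nn.size();
  double x = x0, y = y0, res = R_PosInf;
  double iter = 0;
  while (iter < max_iter) {
    double xn = 0, yn = 0;
    double r = safe_div(y, x);
    for (int j = 0; j < nk; ++j) {
      double n1 = nn[j];
      double py = std::pow(1 - y, n1);
      xn += w[j] * (1 - py);
      double corrA = 0, corrB = 0;
      for (int s = 0; s < m; ++s) {
        if (s > n1 + 0.5) break;
        double F = ch(s, j) * std::pow(x, s) * std::pow(1 - x, n1 - s);
        corrA += F;
        corrB += F * std::pow(1 - r, s);
      }
      double A = corrA > 1 ? 0 : 1 - corrA;
      double B = py - corrB; if (B < 0) B = 0;
      double AB = A - B; if (AB < 0) AB = 0;
      yn += w[j] * (q * A + (1 - q) * AB);
    }
    xn = clamp01(q + (1 - q) * xn);
    yn = clamp01(yn);
    res = std::max(std::fabs(xn - x), std::fabs(yn - y));
    x = xn; y = yn; iter += 1;
    if (res < tol) break;
  }
  return List::create(_["x"] = x, _["y"] = y,
                      _["iterations"] = iter, _["residual"] = res);
}

// Stage 2, undirected: triple (alpha, beta, gamma) with the stage-1 pair
// (x, y) frozen. Fm(s, j) = dbinom(s, nn[j], x) precomputed in R.
// [[Rcpp::export]]
List stage2_und_loop(NumericVector nn, NumericVector w, NumericMatrix Fm,
                     double x, double y, double q, int m,
                     double a0, double b0, double g0, double tol,
                     double max_iter) {
  int nk = nn.size();
  double al = a0, be = b0, ga = g0, res = R_PosInf;
  double iter = 0;
  while (iter < max_iter) {
    double r = safe_div(y, x);
    double rb = safe_div(be, x);
    double Rr = safe_div(x - y - be + ga, x);
    double D = 1 - safe_div(al - be, 1 - x);
    double ub = 1 - rb;
    double aln = 0, ben = 0, gan = 0;
    for (int j = 0; j < nk; ++j) {
      double n1 = nn[j];
      double full_bD = std::pow(x * ub + (1 - x) * D, n1);
      double full_RD = std::pow(x * Rr + (1 - x) * D, n1);
      double full_r = std::pow(1 - y, n1);
      double C1 = 0, C2 = 0, C3 = 0, C4 = 0;
      double C1b = 0, C2b = 0, C3b = 0, C4b = 0, CFb = 0, CRb = 0;
      for (int s = 0; s < m; ++s) {
        double F = Fm(s, j);
        double e = n1 - s; if (e < 0) e = 0;
        double Ds = std::pow(D, e);
        double us = std::pow(ub, s), Rs = std::pow(Rr, s);
        if (s <= m - 2) {
          C1 += F * us; C2 += F * us * Ds;
          C3 += F * Rs; C4 += F * Rs * Ds;
        }
        C1b += F * us; C2b += F * us * Ds;
        C3b += F * Rs; C4b += F * Rs * Ds;
        CFb += F; CRb += F * std::pow(1 - r, s);
      }
      aln += w[j] * (1 - C1 - full_bD + C2);
      ben += w[j] * (1 - full_r - C1 - full_bD + C2 + C3 + full_RD - C4);
      double g_q = (1 - CFb) - (full_bD - C2b);
      double g_nq = (1 - CFb) - (full_r - CRb) - (full_bD - C2b) +
        (full_RD - C4b);
      gan += w[j] * (q * g_q + (1 - q) * g_nq);
    }
    aln = clamp01(aln);
    ben = clamp01(q * aln + (1 - q) * ben);
    gan = clamp01(gan);
    res = std::max(std::fabs(aln - al),
                   std::max(std::fabs(ben - be), std::fabs(gan - ga)));
    al = aln; be = ben; ga = gan; iter += 1;
    if (res < tol) break;
  }
  return List::create(_["alpha"] = al, _["beta"] = be, _["gamma"] = ga,
                      _["iterations"] = iter, _["residual"] = res);
}

// Stage 2, directed: pair (x_inf, y_inf) with (x, y) frozen.
// Fm(s, j) = dbinom(s, kin[j], x).
// [[Rcpp::export]]
List stage2_dir_loop(NumericVector kin, NumericVector w, NumericMatrix Fm,
                     double x, double y, double q, int m,
                     double xi0, double yi0, double tol, double max_iter) {
  int nk = kin.size();
  double xi = xi0, yi = yi0, res = R_PosInf;
  double iter = 0;
  while (iter < max_iter) {
    double r = safe_div(y, x);
    double rxi = safe_div(xi, x);
    double ryi = safe_div(yi, x);
    double uH = clamp01(1 - r - rxi + ryi);
    double xin = 0, yin = 0;
    for (int j = 0; j < nk; ++j) {
      double k = kin[j];
      double full_xi = std::pow(1 - xi, k);
      double full_y = std::pow(1 - y, k);
      double full_H = std::pow(clamp01(1 - y - xi + yi), k);
      double A = 0, Cxi = 0, Cr = 0, CH = 0;
      for (int s = 0; s < m; ++s) {
        double F = Fm(s, j);
        A += F;
        Cxi += F * std::pow(1 - rxi, s);
        Cr += F * std::pow(1 - r, s);
        CH += F * std::pow(uH, s);
      }
      double tail1 = 1 - A; if (tail1 < 0) tail1 = 0;
      double tail_xi = full_xi - Cxi; if (tail_xi < 0) tail_xi = 0;
      double tail_r = full_y - Cr; if (tail_r < 0) tail_r = 0;
      double tail_H = full_H - CH; if (tail_H < 0) tail_H = 0;
      xin += w[j] * (q * (1 - full_xi) +
                     (1 - q) * (1 - full_y - full_xi + full_H));
      double hy = tail1 - tail_r - tail_xi + tail_H; if (hy < 0) hy = 0;
      yin += w[j] * (q * (tail1 - tail_xi) + (1 - q) * hy);
    }
    xin = clamp01(xin);
    yin = clamp01(yin);
    res = std::max(std::fabs(xin - xi), std::fabs(yin - yi));
    xi = xin; yi = yin; iter += 1;
    if (res < tol) break;
  }
  return List::create(_["x_inf"] = xi, _["y_inf"] = yi,
                      _["iterations"] = iter, _["residual"] = res);
}
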