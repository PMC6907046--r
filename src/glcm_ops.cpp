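// Fast path for sliding-window GLCM texture maps: for each window and each
// (distance, direction) pair, count co-occurrences, optionally symmetrise,
// normalise, and compute the 14 Haralick features. Mirrors the R chain
// computeGLCM -> symmetrizeGLCM -> normalizeGLCM -> haralickFeatures
// (equivalence is asserted in the test suite).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double xlogx(double v) { return v > 0 ? v * std::log(v) : 0.0; }

// features out: length-14 vector; P is a Q x Q probability matrix
static void haralick14(const arma::mat& P, arma::vec& f) {
  const int Q = P.n_rows;
  arma::vec px = arma::sum(P, 1);      // row marginals (source level)
  arma::rowvec py = arma::sum(P, 0);   // col marginals (target level)
  double mux = 0, muy = 0;
  for (int i = 0; i < Q; ++i) { mux += i * px(i); muy += i * py(i); }
  double vx = 0, vy = 0;
  for (int i = 0; i < Q; ++i) {
    vx += (i - mux) * (i - mux) * px(i);
    vy += (i - muy) * (i - muy) * py(i);
  }
  const double sdx = std::sqrt(vx), sdy = std::sqrt(vy);

  double asm_ = 0, contrast = 0, corrNum = 0, var4 = 0, idm = 0, ent = 0;
  arma::vec pxy(2 * Q - 1, arma::fill::zeros), pxmy(Q, arma::fill::zeros);
  for (int j = 0; j < Q; ++j)
    for (int i = 0; i < Q; ++i) {
      const double p = P(i, j);
      if (p == 0) continue;
      asm_ += p * p;
      const int dij = i - j;
      contrast += dij * dij * p;
      corrNum += (double)i * j * p;
      var4 += (i - mux) * (i - mux) * p;
      idm += p / (1.0 + dij * dij);
      ent -= p * std::log(p);
      pxy(i + j) += p;
      pxmy(std::abs(dij)) += p;
    }
  const double corr = (sdx > 0 && sdy > 0) ? (corrNum - mux * muy) / (sdx * sdy) : 0.0;

  double sumAvg = 0, sumVar = 0, sumEnt = 0;
  for (int k = 0; k < 2 * Q - 1; ++k) sumAvg += k * pxy(k);
  for (int k = 0; k < 2 * Q - 1; ++k) {
    sumVar += (k - sumAvg) * (k - sumAvg) * pxy(k);
    sumEnt -= xlogx(pxy(k));
  }
  double mud = 0, diffVar = 0, diffEnt = 0;
  for (int k = 0; k < Q; ++k) mud += k * pxmy(k);
  for (int k = 0; k < Q; ++k) {
    diffVar += (k - mud) * (k - mud) * pxmy(k);
    diffEnt -= xlogx(pxmy(k));
  }

  double HXY1 = 0, HXY2 = 0, HX = 0, HY = 0;
  for (int i = 0; i < Q; ++i) { HX -= xlogx(px(i)); HY -= xlogx(py(i)); }
  for (int j = 0; j < Q; ++j)
    for (int i = 0; i < Q; ++i) {
      const double m = px(i) * py(j);
      if (m > 0) {
        if (P(i, j) > 0) HXY1 -= P(i, j) * std::log(m);
        HXY2 -= m * std::log(m);
      }
    }
  const double HXY = ent;
  const double mx = std::max(HX, HY);
  const double imc1 = mx > 0 ? (HXY - HXY1) / mx : 0.0;
  const double imc2 = std::sqrt(std::max(1.0 - std::exp(-2.0 * (HXY2 - HXY)), 0.0));

  // MCC: second-largest eigenvalue of the conditional-transition matrix on
  // the support of both marginals
  double mcc = 0.0;
  std::vector<int> s;
  for (int i = 0; i < Q; ++i) if (px(i) > 0 && py(i) > 0) s.push_back(i);
  const int ns = (int)s.size();
  if (ns >= 2) {
    arma::mat M(ns, ns);
    for (int a = 0; a < ns; ++a)
      for (int b = 0; b < ns; ++b) {
        double acc = 0;
        for (int k = 0; k < ns; ++k)
          acc += P(s[a], s[k]) * P(s[b], s[k]) / (px(s[a]) * py(s[k]));
        M(a, b) = acc;
      }
    arma::cx_vec ev;
    if (arma::eig_gen(ev, M)) {
      arma::vec re = arma::sort(arma::real(ev), "descend");
      mcc = std::sqrt(std::max(re(1), 0.0));
    }
  }

  f(0) = asm_; f(1) = contrast; f(2) = corr; f(3) = var4; f(4) = idm;
  f(5) = sumAvg; f(6) = sumVar; f(7) = sumEnt; f(8) = ent; f(9) = diffVar;
  f(10) = diffEnt; f(11) = imc1; f(12) = imc2; f(13) = mcc;
}

// qimg: integer levels 0..Q-1; rows0/cols0: 0-based window top-left grid;
// win: window side (or -1 for the full image); offs: 2 x ndir matrix of
// (row, col) unit offsets; returns rows of
// [win, row, col, d, theta, f1..f14] with 1-based row/col, skipping
// combinations with no in-bounds pairs.
// [[Rcpp::export(name = ".texture_map_cpp")]]
NumericMatrix texture_map_cpp(const IntegerMatrix& qimg,
                              const IntegerVector& rows0,
                              const IntegerVector& cols0, int win,
                              const IntegerVector& dists,
                              const IntegerMatrix& offs,
                              const NumericVector& thetas, int Q,
                              bool symmetric) {
  const int H = qimg.nrow(), W = qimg.ncol();
  const int wh = win > 0 ? win : H, ww = win > 0 ? win : W;
  const int nWin = rows0.size() * cols0.size();
  const int nCombo = dists.size() * thetas.size();
  NumericMatrix out(nWin * nCombo, 19);
  arma::mat counts(Q, Q);
  arma::mat P(Q, Q);
  arma::vec f(14);
  int outRow = 0, wid = 0;
  for (int ri = 0; ri < rows0.size(); ++ri)
    for (int ci = 0; ci < cols0.size(); ++ci) {
      ++wid;
      const int r0 = rows0[ri], c0 = cols0[ci];
      for (int di = 0; di < dists.size(); ++di)
        for (int ti = 0; ti < thetas.size(); ++ti) {
          const int dr = offs(0, ti) * dists[di];
          const int dc = offs(1, ti) * dists[di];
          counts.zeros();
          double tot = 0;
          for (int j = 0; j < ww; ++j) {
            const int jt = j + dc;
            if (jt < 0 || jt >= ww) continue;
            for (int i = 0; i < wh; ++i) {
              const int it = i + dr;
              if (it < 0 || it >= wh) continue;
              const int a = qimg(r0 + i, c0 + j);
              const int b = qimg(r0 + it, c0 + jt);
              counts(a, b) += 1.0;
              tot += 1.0;
            }
          }
          if (tot == 0) continue;
          if (symmetric) { counts += counts.t(); tot *= 2.0; }
          P = counts / tot;
          haralick14(P, f);
          out(outRow, 0) = wid;
          out(outRow, 1) = r0 + 1;
          out(outRow, 2) = c0 + 1;
          out(outRow, 3) = dists[di];
          out(outRow, 4) = thetas[ti];
          for (int q = 0; q < 14; ++q) out(outRow, 5 + q) = f(q);
          ++outRow;
        }
    }
  return out(Range(0, std::max(outRow - 1, 0)), Range(0, 18));
}
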