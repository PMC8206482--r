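#include <Rcpp.h>
using namespace Rcpp;

// Gauss-Legendre abscissae/weights used by Genz's bivariate normal algorithm
static const double GL_X[3][10] = {
  {0.9324695142031521, 0.6612093864662645, 0.2386191860831969,
   0, 0, 0, 0, 0, 0, 0},
  {0.9815606342467192, 0.9041172563704749, 0.7699026741943047,
   0.5873179542866175, 0.3678314989981802, 0.1252334085114689,
   0, 0, 0, 0},
  {0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
   0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
   0.5108670019508271, 0.3737060887154195, 0.2277858511416451,
   0.07652652113349734}
};
static const double GL_W[3][10] = {
  {0.1713244923791704, 0.3607615730481386, 0.4679139345726910,
   0, 0, 0, 0, 0, 0, 0},
  {0.04717533638651183, 0.1069393259953184, 0.1600783285433462,
   0.2031674267230659, 0.2334925365383548, 0.2491470458134028,
   0, 0, 0, 0},
  {0.01761400713915212, 0.04060142980038694, 0.06267204833410907,
   0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
   0.1316886384491766, 0.1420961093183820, 0.1491729864726037,
   0.1527533871307258}
};

static inline double phi_lower(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// Genz (2004) numerical computation of P(X > dh, Y > dk) for a standard
// bivariate normal with correlation r; single-precision-grade accuracy ~1e-15.
static double bvnd(double dh, double dk, double r) {
  const double twopi = 6.283185307179586;
  int ng, lg;
  double ar = std::fabs(r);
  if (ar < 0.3)       { ng = 0; lg = 3; }
  else if (ar < 0.75) { ng = 1; lg = 6; }
  else                { ng = 2; lg = 10; }
  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  if (ar < 0.925) {
    if (ar > 0.0) {
      double hs = (h * h + k * k) / 2.0, asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * GL_X[ng][i] + 1.0) / 2.0);
          bvn += GL_W[ng][i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * twopi);
    }
    bvn += phi_lower(-h) * phi_lower(-k);
  } else {
    if (r < 0.0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(twopi) * phi_lower(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a = a / 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * GL_X[ng][i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          asr = -(bs / xs + hk) / 2.0;
          if (asr > -100.0)
            bvn += a * GL_W[ng][i] * std::exp(asr) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0.0) {
      bvn += phi_lower(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phi_lower(k) - phi_lower(h);
    }
  }
  return bvn;
}

// Phi2(h, k, rho) = P(X <= h, Y <= k); tolerates infinite bounds.
static double phi2(double h, double k, double rho) {
  if (h == R_NegInf || k == R_NegInf) return 0.0;
  bool hinf = (h == R_PosInf), kinf = (k == R_PosInf);
  if (hinf && kinf) return 1.0;
  if (hinf) return phi_lower(k);
  if (kinf) return phi_lower(h);
  double p = bvnd(-h, -k, rho);
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export]]
NumericVector bvn_cdf_cpp(NumericVector h, NumericVector k, double rho) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = phi2(h[i], k[i], rho);
  return out;
}

// Negative log-likelihood of a two-way ordinal table under the bivariate
// normal model with fixed thresholds ta, tb (interior cutpoints) and free rho.
// [[Rcpp::export]]
double polychoric_nll_cpp(double rho, NumericVector ta, NumericVector tb,
                          NumericMatrix counts) {
  int ra = ta.size() + 1, rb = tb.size() + 1;
  std::vector<double> A(ra + 1), B(rb + 1);
  A[0] = R_NegInf; A[ra] = R_PosInf;
  for (int i = 0; i < ra - 1; i++) A[i + 1] = ta[i];
  B[0] = R_NegInf; B[rb] = R_PosInf;
  for (int j = 0; j < rb - 1; j++) B[j + 1] = tb[j];
  // cumulative CDF grid
  std::vector<double> F((ra + 1) * (rb + 1));
  for (int i = 0; i <= ra; i++)
    for (int j = 0; j <= rb; j++)
      F[i * (rb + 1) + j] = phi2(A[i], B[j], rho);
  double nll = 0.0;
  for (int i = 0; i < ra; i++) {
    for (int j = 0; j < rb; j++) {
      double nij = counts(i, j);
      if (nij > 0.0) {
        double pij = F[(i + 1) * (rb + 1) + (j + 1)] -
                     F[i * (rb + 1) + (j + 1)] -
                     F[(i + 1) * (rb + 1) + j] + F[i * (rb + 1) + j];
        if (pij < 1e-12) pij = 1e-12;
        nll -= nij * std::log(pij);
      }
    }
  }
  return nll;
}

// Per-observation influence scores of the polychoric/polyserial estimates.
// Column p holds s_n / mean(s^2) where s_n is the rho-score of observation n
// for moment p (pairs in column-major upper-triangle order, then the k
// item-criterion moments when z is non-empty). Used to estimate the
// asymptotic covariance of the correlation vector for robust test
// statistics: Gamma = crossprod(out) / n^2.
// [[Rcpp::export]]
NumericMatrix pair_scores_cpp(IntegerMatrix resp, NumericMatrix thresholds,
                              NumericMatrix corr, NumericVector z) {
  int n = resp.nrow(), k = resp.ncol();
  int nc = thresholds.ncol() + 1;
  bool has_crit = z.size() > 0;
  int npair = k * (k - 1) / 2;
  int ncol_out = npair + (has_crit ? k : 0);
  NumericMatrix out(n, ncol_out);
  const double h = 1e-5;
  std::vector<double> A(nc + 1), B(nc + 1), lp(nc * nc), lm(nc * nc);
  auto cell_logp = [&](const std::vector<double>& a,
                       const std::vector<double>& b, double r,
                       std::vector<double>& lg) {
    std::vector<double> F((nc + 1) * (nc + 1));
    for (int i = 0; i <= nc; i++)
      for (int j = 0; j <= nc; j++)
        F[i * (nc + 1) + j] = phi2(a[i], b[j], r);
    for (int i = 0; i < nc; i++)
      for (int j = 0; j < nc; j++) {
        double p = F[(i + 1) * (nc + 1) + j + 1] - F[i * (nc + 1) + j + 1] -
                   F[(i + 1) * (nc + 1) + j] + F[i * (nc + 1) + j];
        lg[i * nc + j] = std::log(std::max(p, 1e-12));
      }
  };
  int col = 0;
  for (int j = 1; j < k; j++) {
    for (int i = 0; i < j; i++, col++) {
      double rho = corr(i, j);
      A[0] = R_NegInf; A[nc] = R_PosInf;
      B[0] = R_NegInf; B[nc] = R_PosInf;
      for (int c = 0; c < nc - 1; c++) {
        A[c + 1] = thresholds(i, c);
        B[c + 1] = thresholds(j, c);
      }
      cell_logp(A, B, rho + h, lp);
      cell_logp(A, B, rho - h, lm);
      double ss = 0.0;
      for (int m = 0; m < n; m++) {
        double s = (lp[(resp(m, i) - 1) * nc + resp(m, j) - 1] -
                    lm[(resp(m, i) - 1) * nc + resp(m, j) - 1]) / (2 * h);
        out(m, col) = s;
        ss += s * s;
      }
      ss /= n;
      if (ss > 1e-12) for (int m = 0; m < n; m++) out(m, col) /= ss;
    }
  }
  if (has_crit) {
    for (int i = 0; i < k; i++) {
      double rho = corr(i, k);
      A[0] = R_NegInf; A[nc] = R_PosInf;
      for (int c = 0; c < nc - 1; c++) A[c + 1] = thresholds(i, c);
      double ss = 0.0;
      for (int m = 0; m < n; m++) {
        double s = 0.0;
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          double r = rho + sgn * h, sd = std::sqrt(1 - r * r);
          int y = resp(m, i);
          double hi = A[y] == R_PosInf ? 1.0 :
            phi_lower((A[y] - r * z[m]) / sd);
          double lo = A[y - 1] == R_NegInf ? 0.0 :
            phi_lower((A[y - 1] - r * z[m]) / sd);
          s += sgn * std::log(std::max(hi - lo, 1e-12));
        }
        s /= 2 * h;
        out(m, npair + i) = s;
        ss += s * s;
      }
      ss /= n;
      if (ss > 1e-12) for (int m = 0; m < n; m++) out(m, npair + i) /= ss;
    }
  }
  return out;
}

// Accumulate response-pattern log-likelihoods over quadrature nodes.
// resp: N x k matrix of categories 1..C; logp: array dim (Q, C, k) of
// log P(category | node). Returns N x Q matrix of summed log-likelihoods.
// [[Rcpp::export]]
NumericMatrix ll_accum_cpp(IntegerMatrix resp, NumericVector logp) {
  IntegerVector dims = logp.attr("dim");
  int Q = dims[0], C = dims[1], k = dims[2];
  int N = resp.nrow();
  if (resp.ncol() != k) stop("response/probability dimension mismatch");
  NumericMatrix out(N, Q);
  const double* lp = logp.begin();
  for (int i = 0; i < k; i++) {
    const double* lpi = lp + (size_t)i * Q * C;
    for (int n = 0; n < N; n++) {
      int c = resp(n, i) - 1;
      if (c < 0 || c >= C) stop("response category out of range");
      const double* col = lpi + (size_t)c * Q;
      double* row = &out(n, 0);
      for (int q = 0; q < Q; q++) row[(size_t)q * N] += col[q];
    }
  }
  return out;
}
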