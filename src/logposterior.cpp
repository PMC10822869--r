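#include <Rcpp.h>
using namespace Rcpp;

// Unconstrained-scale unnormalized log posterior and analytic gradient of
// the trial-level binomial accuracy model.
//
// theta layout (n24 intercepts, n18 slope slots):
//   alpha[0..n24)                    intercept log-odds
//   u[0..n18)                        log of the RT penalty (beta_rt = exp(u))
//   beta_trial[0..n18)
// and, when includeSpq:
//   direct  CP, IN, DI               3 blocks of n18
//   rt_mod  CP, IN, DI               3 blocks of n18
//   tr_mod  CP, IN, DI               3 blocks of n18
//
// The returned value includes the log-Jacobian of the exp transform
// (sum of u), so HMC on theta targets the half-normal-constrained model.
// priorSd = (alpha, beta_rt, beta_trial, spq_direct, spq_mod).
// [[Rcpp::export]]
List lpGradCpp(NumericVector theta, IntegerVector correct,
               IntegerVector c24, IntegerVector c18,
               NumericVector xrt, NumericVector xtr,
               NumericMatrix z, LogicalVector hasSpq,
               int n24, int n18, bool includeSpq,
               NumericVector priorSd) {
  const int n = correct.size();
  const int npar = theta.size();
  const int expect = n24 + 2 * n18 + (includeSpq ? 9 * n18 : 0);
  if (npar != expect) stop("theta has %d entries, expected %d", npar, expect);

  const int oU = n24, oTr = n24 + n18;
  const int oD = n24 + 2 * n18;          // direct CP block
  const int oMR = oD + 3 * n18;          // rt moderation CP block
  const int oMT = oMR + 3 * n18;         // trial moderation CP block

  std::vector<double> b(n18);
  for (int k = 0; k < n18; ++k) b[k] = std::exp(theta[oU + k]);

  NumericVector grad(npar);
  double lp = 0.0;

  for (int i = 0; i < n; ++i) {
    const int a = c24[i], s = c18[i];
    double zc = 0, zi = 0, zd = 0, direct = 0, mrt = 0, mtr = 0;
    if (includeSpq && hasSpq[i]) {
      zc = z(i, 0); zi = z(i, 1); zd = z(i, 2);
      direct = theta[oD + s] * zc + theta[oD + n18 + s] * zi +
               theta[oD + 2 * n18 + s] * zd;
      mrt = theta[oMR + s] * zc + theta[oMR + n18 + s] * zi +
            theta[oMR + 2 * n18 + s] * zd;
      mtr = theta[oMT + s] * zc + theta[oMT + n18 + s] * zi +
            theta[oMT + 2 * n18 + s] * zd;
    }
    const double brt_eff = b[s] * (1.0 + mrt);
    const double btr = theta[oTr + s];
    const double btr_eff = btr * (1.0 + mtr);
    const double eta = theta[a] + brt_eff * xrt[i] + btr_eff * xtr[i] +
                       direct;
    const double sgn = correct[i] ? 1.0 : -1.0;
    lp += -std::log1p(std::exp(-sgn * eta));
    const double p = 1.0 / (1.0 + std::exp(-eta));
    const double r = (correct[i] ? 1.0 : 0.0) - p;  // d loglik / d eta

    grad[a] += r;
    grad[oU + s] += r * brt_eff * xrt[i];           // d eta/du = b(1+mrt)x
    grad[oTr + s] += r * (1.0 + mtr) * xtr[i];
    if (includeSpq && hasSpq[i]) {
      grad[oD + s] += r * zc;
      grad[oD + n18 + s] += r * zi;
      grad[oD + 2 * n18 + s] += r * zd;
      const double grt = r * b[s] * xrt[i];
      grad[oMR + s] += grt * zc;
      grad[oMR + n18 + s] += grt * zi;
      grad[oMR + 2 * n18 + s] += grt * zd;
      const double gtr = r * btr * xtr[i];
      grad[oMT + s] += gtr * zc;
      grad[oMT + n18 + s] += gtr * zi;
      grad[oMT + 2 * n18 + s] += gtr * zd;
    }
  }

  const double HALFLOG2PI = 0.9189385332046727;
  const double sdA = priorSd[0], sdB = priorSd[1], sdT = priorSd[2],
               sdD = priorSd[3], sdM = priorSd[4];

  for (int k = 0; k < n24; ++k) {
    lp += -HALFLOG2PI - std::log(sdA) -
          0.5 * theta[k] * theta[k] / (sdA * sdA);
    grad[k] += -theta[k] / (sdA * sdA);
  }
  for (int k = 0; k < n18; ++k) {
    // half-normal prior on b plus log-Jacobian u of b = exp(u)
    lp += M_LN2 - HALFLOG2PI - std::log(sdB) -
          0.5 * b[k] * b[k] / (sdB * sdB) + theta[oU + k];
    grad[oU + k] += 1.0 - b[k] * b[k] / (sdB * sdB);
    lp += -HALFLOG2PI - std::log(sdT) -
          0.5 * theta[oTr + k] * theta[oTr + k] / (sdT * sdT);
    grad[oTr + k] += -theta[oTr + k] / (sdT * sdT);
  }
  if (includeSpq) {
    for (int j = oD; j < oD + 3 * n18; ++j) {
      lp += -HALFLOG2PI - std::log(sdD) -
            0.5 * theta[j] * theta[j] / (sdD * sdD);
      grad[j] += -theta[j] / (sdD * sdD);
    }
    for (int j = oMR; j < oMT + 3 * n18; ++j) {
      lp += -HALFLOG2PI - std::log(sdM) -
            0.5 * theta[j] * theta[j] / (sdM * sdM);
      grad[j] += -theta[j] / (sdM * sdM);
    }
  }

  return List::create(Named("lp") = lp, Named("grad") = grad);
}
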