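#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Beta-binomial log-likelihood of one variant across samples, with the mean
// fixed at the pooled VAF. The lchoose(nr, nv) term is constant in rho and is
// omitted (it does not affect the grid argmax).
static double bb_loglik(const std::vector<int>& nv, const std::vector<int>& nr,
                        double mu, double rho) {
  double a = mu * (1.0 - rho) / rho;
  double b = (1.0 - mu) * (1.0 - rho) / rho;
  double lab = R::lbeta(a, b);
  double ll = 0.0;
  for (size_t j = 0; j < nv.size(); ++j) {
    if (nr[j] <= 0) continue;
    ll += R::lbeta(nv[j] + a, nr[j] - nv[j] + b) - lab;
  }
  return ll;
}

// Grid maximum-likelihood estimate of the beta-binomial overdispersion rho for
// each variant (row), holding the mean at the pooled VAF sum(nv)/sum(nr).
// [[Rcpp::export]]
List bb_rho_grid_cpp(IntegerMatrix NV, IntegerMatrix NR, NumericVector rho_grid) {
  int m = NV.nrow(), n = NV.ncol(), g = rho_grid.size();
  NumericVector rho_hat(m);
  LogicalVector degenerate(m);
  IntegerVector informative(m);
  std::vector<int> nv(n), nr(n);
  for (int i = 0; i < m; ++i) {
    double sv = 0, sr = 0;
    int ninf = 0;
    for (int j = 0; j < n; ++j) {
      nv[j] = NV(i, j);
      nr[j] = NR(i, j);
      if (nr[j] > 0) { ++ninf; sv += nv[j]; sr += nr[j]; }
    }
    informative[i] = ninf;
    if (ninf < 2) {               // single usable sample: rho undefined
      rho_hat[i] = NA_REAL;
      degenerate[i] = true;
      continue;
    }
    if (sv <= 0 || sv >= sr) {    // pooled VAF at 0 or 1: boundary, flagged
      rho_hat[i] = rho_grid[0];
      degenerate[i] = true;
      continue;
    }
    double mu = sv / sr;
    // coarse-to-fine search: the profile log-likelihood in log10(rho) is
    // smooth (7-point likelihoods cannot form peaks narrower than the
    // coarse step); evaluate every 8th grid point, then refine around the
    // best and any near-tied coarse point
    std::vector<double> ll_cache(g, NA_REAL);
    auto eval = [&](int k) {
      if (!ISNA(ll_cache[k])) return ll_cache[k];
      ll_cache[k] = bb_loglik(nv, nr, mu, rho_grid[k]);
      return ll_cache[k];
    };
    const int step = 8;
    double best = R_NegInf;
    int bi = 0;
    std::vector<int> coarse;
    for (int k = 0; k < g; k += step) coarse.push_back(k);
    if (coarse.back() != g - 1) coarse.push_back(g - 1);
    for (int k : coarse) {
      double ll = eval(k);
      if (ll > best) { best = ll; bi = k; }
    }
    double coarse_best = best;
    for (int k : coarse) {
      if (eval(k) < coarse_best - 0.5) continue;  // refine near-ties too
      for (int j = std::max(0, k - step + 1);
           j <= std::min(g - 1, k + step - 1); ++j) {
        double ll = eval(j);
        if (ll > best) { best = ll; bi = j; }
      }
    }
    rho_hat[i] = rho_grid[bi];
    degenerate[i] = false;
  }
  return List::create(_["rho"] = rho_hat,
                      _["degenerate"] = degenerate,
                      _["n_informative"] = informative);
}

// ---- truncated binomial mixture -------------------------------------------

// P(X >= min_reads | n, p) under the binomial (upper tail, no cancellation).
static double trunc_tail(int n, double p, int min_reads) {
  if (min_reads <= 0) return 1.0;
  double s = R::pbinom(min_reads - 1, n, p, 0, 0);
  return (s < 1e-300) ? 1e-300 : s;
}

// log P(X >= min_reads | n, p)
static double log_trunc_tail(int n, double p, int min_reads) {
  if (min_reads <= 0) return 0.0;
  double ls = R::pbinom(min_reads - 1, n, p, 0, 1);
  return (ls < -690.0) ? -690.0 : ls;
}

struct MStepData {
  double A, B;                        // sum r*nv, sum r*(nr-nv)
  const std::vector<int>* depths;     // unique depths
  const std::vector<double>* W;       // sum of responsibilities per unique depth
  int min_reads;
};

// Weighted score of the truncated binomial log-likelihood in p:
//   g(p) = A/p - B/(1-p) - sum_u W_u * u * dbinom(mr-1; u-1, p) / S_u(p)
// using d/dp P(X <= k; n, p) = -n * dbinom(k; n-1, p).
static double mstep_score(double p, const MStepData& d) {
  double g = d.A / p - d.B / (1.0 - p);
  if (d.min_reads > 0) {
    for (size_t u = 0; u < d.depths->size(); ++u) {
      int n = (*d.depths)[u];
      double w = (*d.W)[u];
      if (w <= 0 || n < 1) continue;
      double S = trunc_tail(n, p, d.min_reads);
      g -= w * n * R::dbinom(d.min_reads - 1, n - 1, p, 0) / S;
    }
  }
  return g;
}

// Safeguarded Newton/bisection root of the score on (eps, 1-eps).
static double mstep_solve(double p_start, const MStepData& d) {
  const double eps = 1e-6;
  double lo = eps, hi = 1.0 - eps;
  double glo = mstep_score(lo, d);
  if (glo <= 0) return lo;
  double ghi = mstep_score(hi, d);
  if (ghi >= 0) return hi;
  double p = std::min(std::max(p_start, lo + eps), hi - eps);
  for (int it = 0; it < 40; ++it) {
    double g = mstep_score(p, d);
    if (std::fabs(g) < 1e-7 * (d.A + d.B + 1.0)) return p;
    if (g > 0) lo = p; else hi = p;
    // secant/Newton step via numeric derivative, fall back to bisection
    double h = 1e-6 * std::max(p, 1e-3);
    double gp = (mstep_score(p + h, d) - g) / h;
    double pn = (gp < 0) ? p - g / gp : -1.0;
    if (!(pn > lo && pn < hi)) pn = 0.5 * (lo + hi);
    if (std::fabs(pn - p) < 1e-9) return pn;
    p = pn;
  }
  return p;
}

// One EM run for a K-component binomial mixture truncated at min_reads
// variant-supporting reads. Returns peaks, weights, the log-likelihood trace
// (non-decreasing up to numerical tolerance) and a convergence flag.
// [[Rcpp::export]]
List tbmix_em_cpp(IntegerVector nv, IntegerVector nr, NumericVector p0,
                  NumericVector w0, int min_reads, int max_iter, double tol) {
  int n = nv.size(), K = p0.size();
  std::vector<double> p(p0.begin(), p0.end()), w(w0.begin(), w0.end());

  // unique depths and index of each observation's depth
  std::map<int, int> dindex;
  std::vector<int> depths;
  std::vector<int> di(n);
  for (int i = 0; i < n; ++i) {
    auto it = dindex.find(nr[i]);
    if (it == dindex.end()) {
      dindex[nr[i]] = depths.size();
      di[i] = depths.size();
      depths.push_back(nr[i]);
    } else di[i] = it->second;
  }
  int U = depths.size();

  // lchoose(nr, nv) is constant over iterations and components
  std::vector<double> lch(n);
  for (int i = 0; i < n; ++i) lch[i] = R::lchoose(nr[i], nv[i]);

  std::vector<double> logS(U * K), lw(K), resp(n * K);
  std::vector<double> trace;
  trace.reserve(max_iter);
  double ll_prev = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int k = 0; k < K; ++k) {
      lw[k] = std::log(std::max(w[k], 1e-300));
      for (int u = 0; u < U; ++u)
        logS[u * K + k] = log_trunc_tail(depths[u], p[k], min_reads);
    }
    // E-step and observed-data log-likelihood
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double lpk = std::log(std::max(p[k], 1e-300));
        double lqk = std::log(std::max(1.0 - p[k], 1e-300));
        double lf = lw[k] + lch[i] + nv[i] * lpk + (nr[i] - nv[i]) * lqk -
                    logS[di[i] * K + k];
        resp[i * K + k] = lf;
        if (lf > mx) mx = lf;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(resp[i * K + k] - mx);
      double lse = mx + std::log(s);
      ll += lse;
      for (int k = 0; k < K; ++k)
        resp[i * K + k] = std::exp(resp[i * K + k] - lse);
    }
    trace.push_back(ll);
    if (iter > 1 && std::fabs(ll - ll_prev) < tol) { converged = true; break; }
    ll_prev = ll;

    // M-step
    std::vector<double> W(U);
    for (int k = 0; k < K; ++k) {
      double A = 0.0, B = 0.0, sw = 0.0;
      std::fill(W.begin(), W.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        double r = resp[i * K + k];
        sw += r;
        A += r * nv[i];
        B += r * (nr[i] - nv[i]);
        W[di[i]] += r;
      }
      w[k] = sw / n;
      if (sw > 1e-12 && A > 0 && B > 0) {
        MStepData d{A, B, &depths, &W, min_reads};
        p[k] = (min_reads > 0) ? mstep_solve(p[k], d) : A / (A + B);
      } else if (A <= 0) p[k] = 1e-6;
      else if (B <= 0) p[k] = 1.0 - 1e-6;
    }
  }

  return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                      _["w"] = NumericVector(w.begin(), w.end()),
                      _["loglik"] = trace.empty() ? NA_REAL : trace.back(),
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["niter"] = std::min(iter, max_iter),
                      _["converged"] = converged);
}
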