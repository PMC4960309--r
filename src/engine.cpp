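// Core recursions for MAP spike inference on a discretized state grid.
//
// State layout: the "calcium-like" dimension (calcium alone, or calcium x
// bound-probe for the hill_rise model) is flattened to S rows; baseline
// occupies nb columns.  All passes share precomputed interpolation
// operators W_k (S x S), one per candidate jump (spike count or calcium
// event amplitude), mapping a grid function of the time-(t+1) state to its
// value at the deterministic child of each time-t state.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// dense-or-sparse interpolation operator
struct InterpOp {
  bool sp;
  mat D;
  sp_mat S;
  sp_mat St;  // transpose, for row access / adjoint
  mat mult(const mat& x) const { return sp ? mat(S * x) : D * x; }
  mat tmult(const mat& x) const { return sp ? mat(St * x) : D.t() * x; }
};

static std::vector<InterpOp> asOps(Rcpp::List W) {
  std::vector<InterpOp> ops(W.size());
  for (int k = 0; k < W.size(); ++k) {
    SEXP w = W[k];
    if (Rf_isMatrix(w)) {
      ops[k].sp = false;
      ops[k].D = Rcpp::as<mat>(w);
    } else {
      ops[k].sp = true;
      ops[k].S = Rcpp::as<sp_mat>(w);
      ops[k].St = ops[k].S.t();
    }
  }
  return ops;
}

static inline double logEmisVal(double y, double pred, double sigma) {
  double z = (y - pred) / sigma;
  return -0.5 * z * z - std::log(sigma) - 0.918938533204672742; // log(sqrt(2pi))
}

// vertex refinement of a parabola through (-1,q1),(0,q2),(1,q3) (unit
// spacing); returns refined offset in [-1,1] and value; falls back to the
// middle point when the fit is not concave.
static inline void quadRefine(double q1, double q2, double q3,
                              double& off, double& val) {
  double a = 0.5 * (q1 + q3) - q2;
  double b = 0.5 * (q3 - q1);
  off = 0.0; val = q2;
  if (a < 0) {
    double x = -b / (2 * a);
    if (x < -1) x = -1; else if (x > 1) x = 1;
    double v = q2 + b * x + a * x * x;
    if (v > q2) { off = x; val = v; }
  }
}

// Backward Viterbi pass.  Returns the cube of conditional best
// log-probabilities m_t(x) (S x nb x T).
// [[Rcpp::export(name = ".backwardPass")]]
arma::cube backwardPass(const arma::vec& y, const arma::mat& pred,
                        Rcpp::List W, const arma::vec& logJump,
                        const arma::vec& bValues, double etaSqDt,
                        double sigma, int bWindow, bool refineJump) {
  const uword T = y.n_elem, S = pred.n_rows, nb = pred.n_cols;
  const int K = logJump.n_elem;
  std::vector<InterpOp> ops = asOps(W);
  const bool bdyn = (etaSqDt > 0) && (nb > 1);
  const int hw = bWindow / 2;
  // log-density of a baseline step of d grid units (uniform spacing)
  const double h = nb > 1 ? bValues(1) - bValues(0) : 1.0;
  vec lgB(2 * (hw + 1) + 1);
  if (bdyn) {
    for (int d = -(hw + 1); d <= hw + 1; ++d)
      lgB(d + hw + 1) = -0.5 * (d * h) * (d * h) / etaSqDt
        - 0.5 * std::log(2 * M_PI * etaSqDt);
  }
  cube m(S, nb, T);
  // terminal slice: emission only
  for (uword j = 0; j < nb; ++j)
    for (uword s = 0; s < S; ++s)
      m(s, j, T - 1) = logEmisVal(y(T - 1), pred(s, j), sigma);
  std::vector<mat> Mn(K);
  for (uword tt = T - 1; tt >= 1; --tt) {
    const uword t = tt - 1;          // filling slice t from slice t+1
    for (int k = 0; k < K; ++k) Mn[k] = ops[k].mult(m.slice(tt));
    std::vector<double> qk(K);
    for (uword j = 0; j < nb; ++j) {
      for (uword s = 0; s < S; ++s) {
        double best = -datum::inf;
        int kb = -1;
        for (int k = 0; k < K; ++k) {
          double q;
          if (!bdyn) {
            q = Mn[k](s, j);
          } else {
            int lo = std::max<int>(0, (int)j - hw);
            int hi = std::min<int>(nb - 1, (int)j + hw);
            int jb = lo;
            double qb = -datum::inf;
            for (int jp = lo; jp <= hi; ++jp) {
              double v = Mn[k](s, jp) + lgB(jp - (int)j + hw + 1);
              if (v > qb) { qb = v; jb = jp; }
            }
            q = qb;
            if (jb > 0 && jb < (int)nb - 1) {
              double q1 = Mn[k](s, jb - 1) + lgB(jb - 1 - (int)j + hw + 1);
              double q3 = Mn[k](s, jb + 1) + lgB(jb + 1 - (int)j + hw + 1);
              double off, val;
              quadRefine(q1, qb, q3, off, val);
              q = val;
            }
          }
          qk[k] = q;
          double tot = logJump(k) + q;
          if (tot > best) { best = tot; kb = k; }
        }
        // continuous-amplitude mode: quadratic refinement across the
        // (log-spaced) amplitude candidates; candidate 0 is "no event"
        if (refineJump && kb >= 2 && kb <= K - 2) {
          double off, val;
          quadRefine(qk[kb - 1], qk[kb], qk[kb + 1], off, val);
          double tot = logJump(kb) + val;
          if (tot > best) best = tot;
        }
        m(s, j, t) = logEmisVal(y(t), pred(s, j), sigma) + best;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return m;
}

// local cubic interpolation weights at x on ascending grid g; fills up to 4
// (index, weight) pairs, returns count.  Linear near the edges, clamped
// outside the grid.
static int interpWeights(const vec& g, double x, uword* idx, double* w) {
  const uword n = g.n_elem;
  if (x <= g(0)) { idx[0] = 0; w[0] = 1; return 1; }
  if (x >= g(n - 1)) { idx[0] = n - 1; w[0] = 1; return 1; }
  uword i1 = 0;                      // g(i1) <= x < g(i1+1)
  { uword lo = 0, hi = n - 1;
    while (hi - lo > 1) { uword mid = (lo + hi) / 2;
      if (g(mid) <= x) lo = mid; else hi = mid; }
    i1 = lo; }
  if (i1 == 0 || i1 == n - 2) {      // linear at edges
    double u = (x - g(i1)) / (g(i1 + 1) - g(i1));
    idx[0] = i1; w[0] = 1 - u; idx[1] = i1 + 1; w[1] = u;
    return 2;
  }
  // 4-point Lagrange on i1-1 .. i1+2
  double xs[4] = {g(i1 - 1), g(i1), g(i1 + 1), g(i1 + 2)};
  for (int a = 0; a < 4; ++a) {
    double L = 1;
    for (int b = 0; b < 4; ++b)
      if (b != a) L *= (x - xs[b]) / (xs[a] - xs[b]);
    idx[a] = i1 - 1 + a; w[a] = L;
  }
  return 4;
}

// probe response g(c) (normalized, g(0)=0, g(1)=1)
static double probeG(double c, int probe, double gamma, double p2,
                     double p3, double nHill, double c0) {
  switch (probe) {
  case 0: return c;                                        // linear
  case 1: return (1 + gamma) * c / (1 + gamma * c);        // saturating
  case 2: return (1 - p2 - p3) * c + p2 * c * c + p3 * c * c * c;
  default: {                                               // hill
    double q = std::pow(c0 + 1 / gamma, nHill);
    double h0 = std::pow(c0, nHill);  h0 = h0 / (h0 + q);
    double h1 = std::pow(c0 + 1, nHill); h1 = h1 / (h1 + q);
    double hc = std::pow(c0 + c, nHill); hc = hc / (hc + q);
    return (hc - h0) / (h1 - h0);
  }
  }
}

// Forward collecting sweep.  Re-derives the optimal decisions at the
// (generally off-grid) running state by local interpolation of the stored
// m_t tables, and evaluates the exact log posterior of the decoded path.
// [[Rcpp::export(name = ".forwardCollect")]]
Rcpp::List forwardCollect(const arma::cube& m, const arma::vec& y,
                          const arma::vec& cValues, const arma::vec& pValues,
                          const arma::vec& bValues, const arma::vec& jump,
                          const arma::vec& logJump, double etaSqDt,
                          double sigma, int bWindow, double decay,
                          double relax, int probe, double A, double gamma,
                          double p2, double p3, double nHill, double c0,
                          int c1mode, bool refineJump) {
  const uword T = y.n_elem, S = m.n_rows, nb = m.n_cols;
  const uword nc = cValues.n_elem;
  const uword np = pValues.n_elem;       // 0 unless hill_rise
  const bool has_p = np > 0;
  const int K = jump.n_elem;
  const bool bdyn = (etaSqDt > 0) && (nb > 1);
  const int hw = bWindow / 2;
  const double h = nb > 1 ? bValues(1) - bValues(0) : 1.0;
  const double cmax = cValues(nc - 1);

  // start at the argmax of m_1 (uniform initial priors), restricted to the
  // resting state when c1mode == 1
  uword s0 = 0, j0 = 0;
  { double best = -datum::inf;
    for (uword j = 0; j < nb; ++j) {
      if (c1mode == 1) {
        if (m(0, j, 0) > best) { best = m(0, j, 0); s0 = 0; j0 = j; }
      } else {
        for (uword s = 0; s < S; ++s)
          if (m(s, j, 0) > best) { best = m(s, j, 0); s0 = s; j0 = j; }
      }
    } }
  double cc = cValues(s0 % nc);
  double pp = has_p ? pValues(s0 / nc) : 0.0;
  double bb = bValues(j0);
  int jgrid = (int)j0;                  // current baseline grid index (no-drift case)

  vec cpath(T), bpath(T), ppath(has_p ? T : 1);
  ivec counts(T, fill::zeros);
  vec jumps(T, fill::zeros);
  cpath(0) = cc; bpath(0) = bb; if (has_p) ppath(0) = pp;
  double resp0 = has_p ? pp : probeG(cc, probe, gamma, p2, p3, nHill, c0);
  double logpost = logEmisVal(y(0), bb * (1 + A * resp0), sigma);

  uword cidx[4]; double cw[4];
  for (uword t = 1; t < T; ++t) {
    // per-candidate interpolated row of m_t over baseline columns
    double pnew = has_p
      ? pp + relax * (probeG(cc, probe, gamma, p2, p3, nHill, c0) - pp) : 0.0;
    uword pidx[2]; double pw[2]; int npp = 1;
    if (has_p) {
      if (pnew <= pValues(0)) { pidx[0] = 0; pw[0] = 1; }
      else if (pnew >= pValues(np - 1)) { pidx[0] = np - 1; pw[0] = 1; }
      else {
        uword lo = 0, hi = np - 1;
        while (hi - lo > 1) { uword mid = (lo + hi) / 2;
          if (pValues(mid) <= pnew) lo = mid; else hi = mid; }
        double u = (pnew - pValues(lo)) / (pValues(lo + 1) - pValues(lo));
        pidx[0] = lo; pw[0] = 1 - u; pidx[1] = lo + 1; pw[1] = u; npp = 2;
      }
    } else { pidx[0] = 0; pw[0] = 1; }

    int bestK = -1; double bestScore = -datum::inf;
    double bestB = bb; int bestJ = jgrid;
    std::vector<double> scoreK(K, -datum::inf);
    for (int k = 0; k < K; ++k) {
      double cnew = std::min(decay * cc + jump(k), cmax);
      int ni = interpWeights(cValues, cnew, cidx, cw);
      // v(j') = m_t(child, j')
      vec v(nb, fill::zeros);
      for (int a = 0; a < ni; ++a)
        for (int b = 0; b < npp; ++b) {
          uword s = cidx[a] + nc * pidx[b];
          for (uword j = 0; j < nb; ++j)
            v(j) += cw[a] * pw[b] * m(s, j, t);
        }
      double score, Bcand = bb; int Jcand = jgrid;
      if (!bdyn) {
        score = v(jgrid);
      } else {
        int jc = (int)std::lround((bb - bValues(0)) / h);
        jc = std::min(std::max(jc, 0), (int)nb - 1);
        int lo = std::max(0, jc - hw), hi = std::min((int)nb - 1, jc + hw);
        int jb = lo; double qb = -datum::inf;
        auto lg = [&](int jp) {
          double d = bValues(jp) - bb;
          return -0.5 * d * d / etaSqDt - 0.5 * std::log(2 * M_PI * etaSqDt);
        };
        for (int jp = lo; jp <= hi; ++jp) {
          double q = v(jp) + lg(jp);
          if (q > qb) { qb = q; jb = jp; }
        }
        score = qb; Bcand = bValues(jb); Jcand = jb;
        if (jb > 0 && jb < (int)nb - 1) {
          double off, val;
          quadRefine(v(jb - 1) + lg(jb - 1), qb, v(jb + 1) + lg(jb + 1),
                     off, val);
          if (val > score) { score = val; Bcand = bValues(jb) + off * h; }
        }
      }
      scoreK[k] = score;
      if (logJump(k) + score > bestScore) {
        bestScore = logJump(k) + score; bestK = k; bestB = Bcand;
        bestJ = Jcand;
      }
    }
    double jumpUsed = jump(bestK);
    if (refineJump && bestK >= 2 && bestK <= K - 2) {
      double off, val;
      quadRefine(scoreK[bestK - 1], scoreK[bestK], scoreK[bestK + 1],
                 off, val);
      // candidates are log-spaced in amplitude
      double dlog = std::log(jump(bestK + 1)) - std::log(jump(bestK));
      jumpUsed = std::exp(std::log(jump(bestK)) + off * dlog);
    }
    double dB = bestB - bb;
    cc = std::min(decay * cc + jumpUsed, cmax);
    pp = pnew; bb = bestB; jgrid = bestJ;
    cpath(t) = cc; bpath(t) = bb; if (has_p) ppath(t) = pp;
    counts(t) = (int)std::lround(jumpUsed);
    jumps(t) = jumpUsed;
    double resp = has_p ? pp : probeG(cc, probe, gamma, p2, p3, nHill, c0);
    logpost += logJump(bestK) + logEmisVal(y(t), bb * (1 + A * resp), sigma);
    if (bdyn)
      logpost += -0.5 * dB * dB / etaSqDt
        - 0.5 * std::log(2 * M_PI * etaSqDt);
  }
  return Rcpp::List::create(
    Rcpp::Named("counts") = counts, Rcpp::Named("jumps") = jumps,
    Rcpp::Named("calcium") = cpath, Rcpp::Named("baseline") = bpath,
    Rcpp::Named("bound") = has_p ? ppath : vec(),
    Rcpp::Named("logPosterior") = logpost);
}

// Forward-backward smoothing (sums replacing maxima).  Computes the beta
// cube p(y_t..y_T | x_t) (each slice normalized to max 1), streams the
// filtering pass alpha, and accumulates per-bin posterior spike-count
// probabilities.  G is the row-stochastic baseline transition kernel.
// [[Rcpp::export(name = ".sumPass")]]
Rcpp::List sumPass(const arma::vec& y, const arma::mat& pred, Rcpp::List W,
                   const arma::vec& pois, const arma::mat& G, double sigma,
                   int c1mode, bool keepAlpha) {
  const uword T = y.n_elem, S = pred.n_rows, nb = pred.n_cols;
  const int K = pois.n_elem;
  std::vector<InterpOp> ops = asOps(W);

  auto emis = [&](uword t, double& shift) {
    mat le(S, nb);
    for (uword j = 0; j < nb; ++j)
      for (uword s = 0; s < S; ++s)
        le(s, j) = logEmisVal(y(t), pred(s, j), sigma);
    shift = le.max();
    return mat(exp(le - shift));
  };

  // backward pass: beta cube
  cube beta(S, nb, T);
  double shift;
  beta.slice(T - 1) = emis(T - 1, shift);
  beta.slice(T - 1) /= beta.slice(T - 1).max();
  for (uword tt = T - 1; tt >= 1; --tt) {
    const uword t = tt - 1;
    mat acc(S, nb, fill::zeros);
    for (int k = 0; k < K; ++k)
      acc += pois(k) * (ops[k].mult(beta.slice(tt)) * G.t());
    mat E = emis(t, shift);
    mat b = E % acc;
    double mx = b.max();
    beta.slice(t) = (mx > 0) ? mat(b / mx) : b;
    Rcpp::checkUserInterrupt();
  }

  // forward pass: stream alpha, accumulate spike marginals
  cube alphaCube;
  if (keepAlpha) alphaCube.set_size(S, nb, T);
  mat marg(T, K, fill::zeros);
  marg(0, 0) = 1.0;                      // bin 1 carries no spikes
  double logEvid = 0;
  mat prior(S, nb, fill::zeros);
  if (c1mode == 1) prior.row(0) += 1.0 / nb;
  else prior.fill(1.0 / (S * nb));
  mat E = emis(0, shift);
  mat alpha = prior % E;
  double z = accu(alpha);
  if (z <= 0) Rcpp::stop("numerical underflow in the filtering pass");
  alpha /= z;
  logEvid += std::log(z) + shift;
  if (keepAlpha) alphaCube.slice(0) = alpha;
  for (uword t = 1; t < T; ++t) {
    mat X = alpha * G;                   // baseline step applied forward
    mat acc(S, nb, fill::zeros);
    for (int k = 0; k < K; ++k) {
      mat Vk = ops[k].mult(beta.slice(t));     // beta at the child states
      double w = pois(k) * accu(X % Vk);
      marg(t, k) = std::max(w, 0.0);
      acc += pois(k) * ops[k].tmult(X);
    }
    double rs = accu(marg.row(t));
    if (rs > 0) marg.row(t) /= rs;
    else marg(t, 0) = 1.0;
    // NB: the adjoint spline spread can carry small negative side lobes;
    // they must be kept (not clipped) for the pairing with beta to stay
    // exact -- only the final marginals are clamped.
    E = emis(t, shift);
    alpha = E % acc;
    z = accu(alpha);
    if (z <= 0) Rcpp::stop("numerical underflow in the filtering pass");
    alpha /= z;
    logEvid += std::log(z) + shift;
    if (keepAlpha) alphaCube.slice(t) = alpha;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("marginals") = marg, Rcpp::Named("logEvidence") = logEvid,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("alpha") = keepAlpha ? Rcpp::wrap(alphaCube) : R_NilValue);
}

static uword sampleIndex(const vec& w, double u) {
  double tot = accu(w);
  double acc = 0;
  for (uword i = 0; i < w.n_elem; ++i) {
    acc += w(i);
    if (u * tot <= acc) return i;
  }
  return w.n_elem - 1;
}

// Ancestral sampling of spike trains from the posterior: draw x_1 from
// prior x beta_1, then step forward drawing (n_t, x_t) with weights
// pois(n) W_n[s, s'] G[j, j'] beta_t(s', j').  Requires dense operators.
// [[Rcpp::export(name = ".samplePass")]]
Rcpp::List samplePass(const arma::cube& beta, Rcpp::List W,
                      const arma::vec& pois, const arma::mat& G,
                      int c1mode, int nSamples, bool keepPaths) {
  const uword T = beta.n_slices, S = beta.n_rows, nb = beta.n_cols;
  const int K = pois.n_elem;
  std::vector<mat> Wd(K);
  for (int k = 0; k < K; ++k) {
    if (!Rf_isMatrix(SEXP(W[k])))
      Rcpp::stop("posterior sampling requires dense interpolation operators");
    Wd[k] = Rcpp::as<mat>(W[k]);
    Wd[k].transform([](double v) { return v < 0 ? 0.0 : v; });
  }
  Rcpp::RNGScope scope;
  imat counts(T, nSamples, fill::zeros);
  mat cIdx, bIdx;
  if (keepPaths) { cIdx.set_size(T, nSamples); bIdx.set_size(T, nSamples); }

  // initial distribution
  mat w0 = beta.slice(0);
  if (c1mode == 1) {
    mat m0(S, nb, fill::zeros);
    m0.row(0) = w0.row(0);
    w0 = m0;
  }
  vec w0v = vectorise(w0);
  uvec sCur(nSamples), jCur(nSamples);
  for (int r = 0; r < nSamples; ++r) {
    uword i0 = sampleIndex(w0v, R::unif_rand());
    sCur(r) = i0 % S; jCur(r) = i0 / S;
    if (keepPaths) { cIdx(0, r) = (double)sCur(r); bIdx(0, r) = (double)jCur(r); }
  }
  // step all samples forward together so the per-time weight matrices
  // V_k = W_k beta_t and U_k = V_k G^T are computed once per frame
  std::vector<mat> Vk(K), Uk(K);
  for (uword t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      Vk[k] = Wd[k] * beta.slice(t);
      Vk[k].transform([](double v) { return v < 0 ? 0.0 : v; });
      Uk[k] = Vk[k] * G.t();
    }
    for (int r = 0; r < nSamples; ++r) {
      uword s = sCur(r), j = jCur(r);
      vec wn(K);
      for (int k = 0; k < K; ++k) wn(k) = pois(k) * Uk[k](s, j);
      int k = (int)sampleIndex(wn, R::unif_rand());
      // baseline next: weight G[j, j'] * V_k(s, j')
      vec wj(nb);
      for (uword jp = 0; jp < nb; ++jp)
        wj(jp) = G(j, jp) * Vk[k](s, jp);
      uword jn = sampleIndex(wj, R::unif_rand());
      // calcium-like next: weight W_k[s, s'] * beta_t(s', jn)
      vec ws = Wd[k].row(s).t() % beta.slice(t).col(jn);
      uword sn = sampleIndex(ws, R::unif_rand());
      sCur(r) = sn; jCur(r) = jn;
      counts(t, r) = k;
      if (keepPaths) { cIdx(t, r) = (double)sn; bIdx(t, r) = (double)jn; }
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("counts") = counts,
    Rcpp::Named("cIndex") = keepPaths ? Rcpp::wrap(cIdx) : R_NilValue,
    Rcpp::Named("bIndex") = keepPaths ? Rcpp::wrap(bIdx) : R_NilValue);
}
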