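// Propagation of state fractions for sequential unfolding chains along a
// linear temperature ramp. The governing ODEs are linear in the fractions at
// every temperature, so each accepted step applies the exponential of the
// local coefficient matrix frozen at the step midpoint (exponential midpoint
// rule), with step-doubling error control and Richardson extrapolation. The
// matrix exponential is exact for frozen coefficients; accuracy is limited
// only by the temperature variation of the coefficients.
//
// The terminal state of the chain receives flux but has no dynamics of its
// own, so it is dropped from the ODE and recovered by mass conservation;
// the common chains then reduce to a scalar exponential (one-step and
// fast-equilibrium models) or an analytic 2x2 exponential (the general
// three-state model), with arma::expmat only for longer chains.
//
// For the explicit two-rate first step, the fast-equilibrium regime (first
// step relaxing much faster than the step traversal) is handled by switching
// to the algebraically reduced chain: the N+I pool is propagated with
// K = k1/k-1 and re-split with a first-order quasi-static correction.
// Without the switch the midpoint rule's order collapses on the fast
// components and the controller stalls.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double R_GAS = 8.3145;

struct Chain {
  int kind1;                 // 0 equilibrium, 1 irreversible, 2 two-rate
  double eq_tm, eq_dhk, eq_dcpk;
  double tr_e1, tr_tf1, tr_em1, tr_tfm1;
  arma::vec irr_e, irr_tf;   // Arrhenius params of the irreversible drains
  int nstates;               // full chain states incl. terminal
  int nact;                  // ODE (active) states
};

static inline double arr_k(double e, double tf, double T) {
  double x = -(e / R_GAS) * (1.0 / T - 1.0 / tf);
  // clamp far beyond any physical rate; keeps optimizer excursions finite
  if (x > 500.0) x = 500.0; else if (x < -500.0) x = -500.0;
  return std::exp(x);
}

static inline double eq_K(const Chain& c, double T, double* dhk_T_out) {
  double dH = c.eq_dhk + c.eq_dcpk * (T - c.eq_tm);
  double dS = c.eq_dhk / c.eq_tm + c.eq_dcpk * std::log(T / c.eq_tm);
  double dG = dH - T * dS;
  if (dhk_T_out) *dhk_T_out = dH;
  return std::exp(-dG / (R_GAS * T));
}

// quasi-static split of the N+I pool for a fast-relaxing two-rate step;
// u* restores the first-order lag of the fast components behind their
// moving equilibrium
struct PoolSplit { double f, u_over_pool, k1, km1, k2, lnKp; };

static PoolSplit pool_split(const Chain& c, double T, double v) {
  PoolSplit s;
  s.k1  = arr_k(c.tr_e1,  c.tr_tf1,  T);
  s.km1 = arr_k(c.tr_em1, c.tr_tfm1, T);
  s.k2  = arr_k(c.irr_e[0], c.irr_tf[0], T);
  s.f = s.k1 / (s.k1 + s.km1);
  s.lnKp = (c.tr_e1 - c.tr_em1) / (R_GAS * T * T);
  s.u_over_pool = -s.f * (1.0 - s.f) * (s.k2 + v * s.lnKp) / (s.k1 + s.km1);
  return s;
}

// active-state coefficient matrix A(T): dy/dT = A(T) y, terminal state
// dropped (flux into it simply leaves the active set)
static void coef_matrix(const Chain& c, double T, double v, arma::mat& A) {
  A.zeros();
  const int nirr = c.irr_e.n_elem;
  const int nact = c.nact;
  if (c.kind1 == 0) {
    double dhk_T;
    double K = eq_K(c, T, &dhk_T);
    double k2 = arr_k(c.irr_e[0], c.irr_tf[0], T);
    A(0, 0) = -(K / (1.0 + K)) * (k2 / v + dhk_T / (R_GAS * T * T));
    if (nact > 1) A(1, 0) = k2 * K / v;
    // active product j (row j, j>=1) is the product of drain step j
    for (int j = 1; j <= nirr - 1; ++j) {
      double kk = arr_k(c.irr_e[j], c.irr_tf[j], T);
      A(j, j) -= kk / v;
      if (j + 1 < nact) A(j + 1, j) += kk / v;
    }
  } else if (c.kind1 == 1) {
    for (int i = 0; i < nirr; ++i) {
      double kk = arr_k(c.irr_e[i], c.irr_tf[i], T);
      A(i, i) -= kk / v;
      if (i + 1 < nact) A(i + 1, i) += kk / v;
    }
  } else {
    double k1  = arr_k(c.tr_e1,  c.tr_tf1,  T);
    double km1 = arr_k(c.tr_em1, c.tr_tfm1, T);
    A(0, 0) = -k1 / v;  A(0, 1) =  km1 / v;
    A(1, 0) =  k1 / v;  A(1, 1) = -km1 / v;
    for (int i = 0; i < nirr; ++i) {
      double kk = arr_k(c.irr_e[i], c.irr_tf[i], T);
      A(i + 1, i + 1) -= kk / v;
      if (i + 2 < nact) A(i + 2, i + 1) += kk / v;
    }
  }
}

// reduced (pool) coefficient matrix for the fast-equilibrium limit of a
// two-rate first step: state [pool = x_n + x_i, products except terminal]
static void coef_matrix_reduced(const Chain& c, double T, double v,
                                arma::mat& A) {
  A.zeros();
  const int nirr = c.irr_e.n_elem;
  const int nred = c.nact - 1;
  PoolSplit s = pool_split(c, T, v);
  double cf = s.f + s.u_over_pool;
  A(0, 0) = -cf * s.k2 / v;
  if (nred > 1) A(1, 0) = cf * s.k2 / v;
  for (int j = 1; j <= nirr - 1; ++j) {
    double kk = arr_k(c.irr_e[j], c.irr_tf[j], T);
    A(j, j) -= kk / v;
    if (j + 1 < nred) A(j + 1, j) += kk / v;
  }
}

// y <- exp(A h) y with analytic forms for n = 1, 2
static void apply_expm(const arma::mat& A, double h, arma::vec& y) {
  const int n = y.n_elem;
  if (n == 1) {
    y[0] *= std::exp(std::min(A(0, 0) * h, 500.0));
    return;
  }
  if (n == 2) {
    // eigenvalues mu +/- w; rates are non-negative so the discriminant is
    // non-negative and the exponential splits into two real exponentials
    double a = A(0, 0), b = A(0, 1), cc = A(1, 0), d = A(1, 1);
    double mu = 0.5 * (a + d);
    double w2 = 0.25 * (a - d) * (a - d) + b * cc;
    double w = std::sqrt(std::max(w2, 0.0));
    double l1h = std::min((mu + w) * h, 500.0);
    double l2h = std::min((mu - w) * h, 500.0);
    double e1 = std::exp(l1h), e2 = std::exp(l2h);
    double ch = 0.5 * (e1 + e2);
    double sh;                    // e^{mu h} sinh(w h)/w
    if (std::abs(w * h) > 1e-6) {
      sh = 0.5 * (e1 - e2) / w;
    } else {
      double wh = w * h;
      sh = std::exp(std::min(mu * h, 500.0)) * h * (1.0 + wh * wh / 6.0);
    }
    double y0 = y[0], y1 = y[1];
    y[0] = (ch + sh * (a - mu)) * y0 + sh * b * y1;
    y[1] = sh * cc * y0 + (ch + sh * (d - mu)) * y1;
    return;
  }
  y = arma::expmat(A * h) * y;
}

static Chain parse_chain(const List& chain) {
  Chain c;
  c.kind1 = as<int>(chain["kind1"]);
  c.eq_tm = c.eq_dhk = c.eq_dcpk = 0.0;
  c.tr_e1 = c.tr_tf1 = c.tr_em1 = c.tr_tfm1 = 0.0;
  if (c.kind1 == 0) {
    c.eq_tm = as<double>(chain["eq_tm"]);
    c.eq_dhk = as<double>(chain["eq_dhk"]);
    c.eq_dcpk = as<double>(chain["eq_dcpk"]);
  } else if (c.kind1 == 2) {
    c.tr_e1 = as<double>(chain["tr_e1"]);
    c.tr_tf1 = as<double>(chain["tr_tf1"]);
    c.tr_em1 = as<double>(chain["tr_em1"]);
    c.tr_tfm1 = as<double>(chain["tr_tfm1"]);
  }
  c.irr_e = as<arma::vec>(chain["irr_e"]);
  c.irr_tf = as<arma::vec>(chain["irr_tf"]);
  const int nirr = c.irr_e.n_elem;
  c.nstates = (c.kind1 == 0) ? nirr + 2 : (c.kind1 == 2) ? nirr + 2 : nirr + 1;
  c.nact = (c.kind1 == 0) ? nirr : (c.kind1 == 2) ? nirr + 1 : nirr;
  return c;
}

// fast-relaxation regime of the two-rate step: the N/I split is slaved to
// its quasi-static value; with the first-order correction the residual bias
// is O((lnK' v / relax)^2)
static bool is_fast(const Chain& c, double T, double v) {
  if (c.kind1 != 2) return false;
  PoolSplit s = pool_split(c, T, v);
  double relax = s.k1 + s.km1;
  double drift = std::abs(v) * std::max(std::abs(s.lnKp), 0.05) + s.k2;
  return relax > 40.0 * drift && relax / std::abs(v) > 20.0;
}

// one midpoint-expm trial step from T over h (in place on y)
static void trial_step(const Chain& c, double T, double h, double v,
                       bool fast, arma::vec& y, arma::mat& A, arma::mat& Ar) {
  double Tm = T + 0.5 * h;
  if (!fast) {
    coef_matrix(c, Tm, v, A);
    apply_expm(A, h, y);
    return;
  }
  // collapse (x_n, x_i) -> pool, step the reduced chain, re-split at T + h
  const int nred = c.nact - 1;
  arma::vec yr(nred);
  yr[0] = y[0] + y[1];
  for (int i = 2; i < c.nact; ++i) yr[i - 1] = y[i];
  coef_matrix_reduced(c, Tm, v, Ar);
  apply_expm(Ar, h, yr);
  PoolSplit s = pool_split(c, T + h, v);
  double u = s.u_over_pool * yr[0];
  y[1] = s.f * yr[0] + u;
  y[0] = yr[0] - y[1];
  for (int i = 2; i < c.nact; ++i) y[i] = yr[i - 1];
}

// [[Rcpp::export]]
List chain_propagate_cpp(List chain, NumericVector Tgrid, double v,
                         NumericVector x0, double rtol, double atol,
                         int max_subdiv) {
  Chain c = parse_chain(chain);
  const int n = Tgrid.size();
  const int nact = c.nact;
  const int nirr = c.irr_e.n_elem;

  // map full initial fractions onto the active states
  arma::vec y(nact);
  if (c.kind1 == 0) {
    y[0] = x0[0];                               // x_n (x_i algebraic)
    for (int j = 1; j < nact; ++j) y[j] = x0[j + 1];
  } else {
    for (int j = 0; j < nact; ++j) y[j] = x0[j];
  }

  arma::mat X(n, c.nstates), dX(n, c.nstates);
  arma::mat A(nact, nact), Ar(std::max(nact - 1, 1), std::max(nact - 1, 1));
  arma::vec y_full(nact), y_half(nact);

  // record one grid node: full fractions (terminal state by conservation)
  // and analytic temperature derivatives
  auto record = [&](int idx, double T) {
    arma::vec xs(c.nstates), xd(c.nstates);
    if (c.kind1 == 2 && is_fast(c, T, v)) {
      // slaved regime: states and derivatives from the corrected pool
      // dynamics; the raw A*y expression would be a difference of huge
      // near-cancelling rates evaluated off the true manifold
      PoolSplit s = pool_split(c, T, v);
      double pool = y[0] + y[1];
      double xi = (s.f + s.u_over_pool) * pool;
      double pool_p = -s.k2 * xi / v;
      double fp = s.f * (1.0 - s.f) * s.lnKp;  // df/dT
      double xi_p = s.f * pool_p + fp * pool;  // u' dropped (second order)
      xs[0] = pool - xi; xd[0] = pool_p - xi_p;
      xs[1] = xi;        xd[1] = xi_p;
      for (int i = 2; i < nact; ++i) {
        double influx = (i == 2) ? s.k2 * xi
          : arr_k(c.irr_e[i - 2], c.irr_tf[i - 2], T) * y[i - 1];
        double out = (i - 1 < nirr)
          ? arr_k(c.irr_e[i - 1], c.irr_tf[i - 1], T) * y[i] : 0.0;
        xs[i] = y[i];
        xd[i] = (influx - out) / v;
      }
    } else {
      coef_matrix(c, T, v, A);
      arma::vec yd = A * y;  // includes every outflux (diagonals kept)
      if (c.kind1 == 0) {
        double dhk_T;
        double K = eq_K(c, T, &dhk_T);
        double Kp = K * dhk_T / (R_GAS * T * T);
        xs[0] = y[0];
        xs[1] = K * y[0];
        xd[0] = yd[0];
        xd[1] = Kp * y[0] + K * yd[0];
        for (int j = 1; j < nact; ++j) { xs[j + 1] = y[j]; xd[j + 1] = yd[j]; }
      } else {
        for (int j = 0; j < nact; ++j) { xs[j] = y[j]; xd[j] = yd[j]; }
      }
    }
    // terminal state by conservation
    double tot = 0.0, dtot = 0.0;
    for (int j = 0; j < c.nstates - 1; ++j) { tot += xs[j]; dtot += xd[j]; }
    xs[c.nstates - 1] = 1.0 - tot;
    xd[c.nstates - 1] = -dtot;
    for (int j = 0; j < c.nstates; ++j) { X(idx, j) = xs[j]; dX(idx, j) = xd[j]; }
  };

  record(0, Tgrid[0]);

  double h_try = (n > 1) ? (Tgrid[1] - Tgrid[0]) : 0.0;
  for (int g = 1; g < n; ++g) {
    double Ta = Tgrid[g - 1], Tb = Tgrid[g];
    double dir = (Tb >= Ta) ? 1.0 : -1.0;
    double T = Ta;
    if (dir * h_try <= 0.0) h_try = Tb - Ta;
    int guard = 0;
    while (dir * (Tb - T) > 1e-12 * std::max(1.0, std::abs(Tb))) {
      if (++guard > max_subdiv)
        stop("Propagation failed to converge between %.3f and %.3f K.", Ta, Tb);
      double h = h_try;
      if (dir * (T + h - Tb) > 0.0) h = Tb - T;
      bool fast = is_fast(c, T + 0.5 * h, v);
      y_full = y; trial_step(c, T, h, v, fast, y_full, A, Ar);
      y_half = y; trial_step(c, T, 0.5 * h, v, fast, y_half, A, Ar);
      trial_step(c, T + 0.5 * h, 0.5 * h, v, fast, y_half, A, Ar);
      // error relative to the largest fraction: components at roundoff
      // level must not block acceptance
      double ynorm = 0.0;
      for (int i = 0; i < nact; ++i)
        ynorm = std::max(ynorm, std::abs(y_half[i]));
      double sc = atol + rtol * std::max(ynorm, 1e-30);
      double err = 0.0;
      for (int i = 0; i < nact; ++i)
        err = std::max(err, std::abs(y_full[i] - y_half[i]) / sc);
      // floor on the step: sub-milli-Kelvin structure carries no physical
      // information, and the floor keeps the partially-relaxed band of a
      // two-rate step (between resolved and slaved dynamics) from stalling
      double h_min = 1e-3 * std::abs(Tb - Ta);
      if (err <= 1.0 || std::abs(h) <= h_min) {
        // second-order midpoint rule: Richardson-extrapolate to third order
        y = y_half + (y_half - y_full) / 3.0;
        T += h;
        double fac = (err > 0.0) ? 0.9 * std::pow(err, -1.0 / 3.0) : 4.0;
        h_try = h * std::min(4.0, std::max(0.2, fac));
      } else {
        h_try = h * std::max(0.2, 0.9 * std::pow(err, -1.0 / 3.0));
      }
      if (dir * h_try < h_min) h_try = dir * h_min;
    }
    record(g, Tb);
  }

  return List::create(_["x"] = X, _["dx"] = dX);
}
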