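// Core numerics for the connectionist gene-circuit model:
//  - regulation-expression sigmoid
//  - reaction-diffusion right-hand side on a 1-D row of nuclei
//  - Bulirsch-Stoer (modified midpoint + Richardson extrapolation)
//    adaptive-step integrator
//  - trajectory walker over a mitotic schedule (interphase / mitosis /
//    instantaneous division)
// Kept in C++ with preallocated flat buffers because a single
// optimisation run evaluates the objective (and hence the ODE solve)
// tens of thousands of times on very small state matrices, where
// allocation overhead would dominate.

#include <Rcpp.h>
#include <cmath>
#include <vector>

static const int PHASE_INTERPHASE = 0;
static const int PHASE_MITOSIS = 1;
static const int PHASE_DIVISION = 2;

static const int SIG_RATIO = 0;
static const int SIG_LOGISTIC = 1;

// g(u) = (u / sqrt(u^2 + 1) + 1) / 2, bounded in (0, 1)
static inline double sigmoid_ratio(double u) {
  return 0.5 * (u / std::sqrt(u * u + 1.0) + 1.0);
}
static inline double sigmoid_logistic(double u) {
  return 1.0 / (1.0 + std::exp(-u));
}

// State layout: column-major nuclei x genes (matches R matrices),
// y[a * N + i] = concentration of gene a in nucleus i.
struct Circuit {
  int G;
  std::vector<double> W; // row-major W[a * G + b]: effect of b on a
  std::vector<double> m, h, R, D_base, lambda;
  int sig_type;

  // current epoch
  int N;
  std::vector<double> D_eff; // 4^n_div * D_base
  const double* bcd;
  bool production_on;

  void set_epoch(int N_, int n_div, const double* bcd_) {
    N = N_;
    bcd = bcd_;
    double f = std::pow(4.0, n_div);
    D_eff.resize(G);
    for (int a = 0; a < G; ++a) D_eff[a] = f * D_base[a];
  }

  // dg_i^a/dt: production (if on), Fickian diffusion with zero-flux
  // ends, first-order decay
  void rhs(const double* y, double* dy) const {
    for (int a = 0; a < G; ++a) {
      const double la = lambda[a], Da = D_eff[a], Ra = R[a];
      const double ma = m[a], ha = h[a];
      const double* Wa = &W[a * G];
      const double* ya = y + a * N;
      double* dya = dy + a * N;
      for (int i = 0; i < N; ++i) dya[i] = -la * ya[i];
      if (production_on) {
        for (int i = 0; i < N; ++i) {
          double u = ha + ma * bcd[i];
          for (int b = 0; b < G; ++b) u += Wa[b] * y[b * N + i];
          dya[i] += Ra * (sig_type == SIG_LOGISTIC ? sigmoid_logistic(u)
                                                   : sigmoid_ratio(u));
        }
      }
      if (Da != 0.0) {
        for (int i = 0; i + 1 < N; ++i) {
          double f = Da * (ya[i + 1] - ya[i]);
          dya[i] += f;
          dya[i + 1] -= f;
        }
      }
    }
  }
};

static const int KMAXX = 8;

// Adaptive Bulirsch-Stoer integrator with reusable workspace.
struct Integrator {
  const Circuit& c;
  int nv; // N * G state size
  std::vector<double> z0, z1, z2, dydt;
  std::vector<std::vector<double> > tab_prev, tab_cur;
  std::vector<double> scale;

  Integrator(const Circuit& circuit) : c(circuit) {
    nv = c.N * c.G;
    z0.resize(nv);
    z1.resize(nv);
    z2.resize(nv);
    dydt.resize(nv);
    scale.resize(nv);
    tab_prev.assign(KMAXX, std::vector<double>(nv));
    tab_cur.assign(KMAXX, std::vector<double>(nv));
  }

  // modified midpoint over H with nstep substeps; result into out
  void midpoint(const double* y, double H, int nstep, double* out) {
    const double hh = H / nstep;
    c.rhs(y, &dydt[0]);
    for (int v = 0; v < nv; ++v) {
      z0[v] = y[v];
      z1[v] = y[v] + hh * dydt[v];
    }
    for (int s = 1; s < nstep; ++s) {
      c.rhs(&z1[0], &dydt[0]);
      for (int v = 0; v < nv; ++v) {
        z2[v] = z0[v] + 2.0 * hh * dydt[v];
        z0[v] = z1[v];
        z1[v] = z2[v];
      }
    }
    c.rhs(&z1[0], &dydt[0]);
    for (int v = 0; v < nv; ++v)
      out[v] = 0.5 * (z1[v] + z0[v] + hh * dydt[v]);
  }

  // one accepted macro step; returns the proposed next step size
  double step(std::vector<double>& y, double& t, double htry,
              double rtol) {
    double H = htry;
    for (int v = 0; v < nv; ++v)
      scale[v] = rtol * (std::fabs(y[v]) + 1.0);
    for (;;) {
      for (int k = 0; k < KMAXX; ++k) {
        int nk = 2 * (k + 1);
        midpoint(&y[0], H, nk, &tab_cur[0][0]);
        bool finite = true;
        for (int v = 0; v < nv; ++v)
          if (!std::isfinite(tab_cur[0][v])) { finite = false; break; }
        if (!finite) break; // blow-up: retry with a smaller step
        // Aitken-Neville extrapolation in (H/n)^2 towards zero step
        for (int j = 1; j <= k; ++j) {
          double denom =
              std::pow(double(nk) / double(2 * (k + 1 - j)), 2.0) - 1.0;
          for (int v = 0; v < nv; ++v)
            tab_cur[j][v] = tab_cur[j - 1][v] +
                            (tab_cur[j - 1][v] - tab_prev[j - 1][v]) / denom;
        }
        if (k >= 1) {
          double err = 0.0;
          for (int v = 0; v < nv; ++v) {
            double e =
                std::fabs(tab_cur[k][v] - tab_cur[k - 1][v]) / scale[v];
            if (e > err) err = e;
          }
          if (err < 1.0) {
            y = tab_cur[k];
            t += H;
            double grow = 0.9 * std::pow(std::max(err, 1e-10),
                                         -1.0 / (2.0 * k + 1.0));
            if (grow > 5.0) grow = 5.0;
            if (grow < 0.2) grow = 0.2;
            return H * grow;
          }
        }
        tab_prev.swap(tab_cur);
      }
      H *= 0.25;
      if (std::fabs(H) < 1e-12)
        Rcpp::stop("Bulirsch-Stoer step size underflow at t = %f", t);
    }
  }

  void span(std::vector<double>& y, double t0, double t1, double rtol) {
    if (t1 <= t0) return;
    double t = t0;
    double h = t1 - t0; // ambitious first macro step; adapted immediately
    long n_steps = 0;
    while (t < t1 - 1e-12) {
      if (t + h > t1) h = t1 - t;
      h = step(y, t, h, rtol);
      if (++n_steps > 100000)
        Rcpp::stop("step budget exceeded at t = %f (stiffness beyond the "
                   "solver's range)", t);
    }
    for (int v = 0; v < nv; ++v)
      if (!std::isfinite(y[v]))
        Rcpp::stop("non-finite concentrations during integration at t = %f",
                   t);
  }
};

static Circuit circuit_from_list(const Rcpp::List& params) {
  Circuit c;
  Rcpp::NumericMatrix W = params["W"];
  c.G = W.nrow();
  if (W.ncol() != c.G) Rcpp::stop("W must be square");
  c.W.resize(c.G * c.G);
  for (int a = 0; a < c.G; ++a)
    for (int b = 0; b < c.G; ++b) c.W[a * c.G + b] = W(a, b);
  c.m = Rcpp::as<std::vector<double> >(params["m"]);
  c.h = Rcpp::as<std::vector<double> >(params["h"]);
  c.R = Rcpp::as<std::vector<double> >(params["R"]);
  c.D_base = Rcpp::as<std::vector<double> >(params["D_base"]);
  c.lambda = Rcpp::as<std::vector<double> >(params["decay"]);
  if ((int)c.m.size() != c.G || (int)c.h.size() != c.G ||
      (int)c.R.size() != c.G || (int)c.D_base.size() != c.G ||
      (int)c.lambda.size() != c.G)
    Rcpp::stop("parameter vectors must have length %d", c.G);
  c.sig_type = SIG_RATIO;
  if (params.containsElementNamed("sigmoid")) {
    std::string sg = Rcpp::as<std::string>(params["sigmoid"]);
    if (sg == "logistic") c.sig_type = SIG_LOGISTIC;
    else if (sg != "ratio")
      Rcpp::stop("unknown sigmoid form '%s'", sg.c_str());
  }
  return c;
}

// [[Rcpp::export(name = ".cpp_circuit_rhs")]]
Rcpp::NumericMatrix cpp_circuit_rhs(const Rcpp::NumericMatrix& conc,
                                    const Rcpp::NumericVector& bcd,
                                    const Rcpp::List& params, int n_div,
                                    bool production_on) {
  Circuit c = circuit_from_list(params);
  if (conc.ncol() != c.G) Rcpp::stop("conc must have %d columns", c.G);
  if (bcd.size() != conc.nrow())
    Rcpp::stop("bcd must have one value per nucleus");
  c.set_epoch(conc.nrow(), n_div, bcd.begin());
  c.production_on = production_on;
  Rcpp::NumericMatrix out(conc.nrow(), conc.ncol());
  c.rhs(conc.begin(), out.begin());
  return out;
}

// [[Rcpp::export(name = ".cpp_integrate_interval")]]
Rcpp::NumericMatrix cpp_integrate_interval(const Rcpp::NumericMatrix& conc,
                                           const Rcpp::NumericVector& bcd,
                                           const Rcpp::List& params,
                                           int n_div, bool production_on,
                                           double t0, double t1,
                                           double rtol) {
  Circuit c = circuit_from_list(params);
  c.set_epoch(conc.nrow(), n_div, bcd.begin());
  c.production_on = production_on;
  Integrator integ(c);
  std::vector<double> y(conc.begin(), conc.end());
  integ.span(y, t0, t1, rtol);
  Rcpp::NumericMatrix out(conc.nrow(), conc.ncol());
  std::copy(y.begin(), y.end(), out.begin());
  return out;
}

// Simulate over a mitotic schedule.
// schedule: kind (0/1/2), start, end vectors; contiguous, time-increasing;
// division phases have start == end.
// bcd_list: per-epoch Bcd vectors, element e used while n_div == n_div0 + e.
// Output times falling exactly on a division instant yield the
// post-division state.
// [[Rcpp::export(name = ".cpp_simulate")]]
Rcpp::List cpp_simulate(const Rcpp::List& params,
                        const Rcpp::NumericMatrix& conc0, int n_div0,
                        const Rcpp::List& bcd_list,
                        const Rcpp::IntegerVector& kind,
                        const Rcpp::NumericVector& ph_start,
                        const Rcpp::NumericVector& ph_end,
                        const Rcpp::NumericVector& output_times,
                        double rtol) {
  Circuit c = circuit_from_list(params);
  const double eps = 1e-9;
  int n_div = n_div0;
  int epoch = 0;
  int N = conc0.nrow();
  if (conc0.ncol() != c.G) Rcpp::stop("conc0 must have %d columns", c.G);
  std::vector<double> y(conc0.begin(), conc0.end());
  std::vector<std::vector<double> > bcds(bcd_list.size());
  for (int e = 0; e < bcd_list.size(); ++e)
    bcds[e] = Rcpp::as<std::vector<double> >(bcd_list[e]);
  if ((int)bcds[0].size() != N)
    Rcpp::stop("initial Bcd profile has %d values; expected %d",
               (int)bcds[0].size(), N);

  const int n_out = output_times.size();
  Rcpp::List out_conc(n_out);
  Rcpp::IntegerVector out_ndiv(n_out);
  int iout = 0;
  const int n_ph = kind.size();
  double t = (n_ph > 0) ? ph_start[0] : 0.0;

  auto record_upto = [&](double tcur) {
    while (iout < n_out && output_times[iout] <= tcur + eps) {
      Rcpp::NumericMatrix mat(N, c.G);
      std::copy(y.begin(), y.end(), mat.begin());
      out_conc[iout] = mat;
      out_ndiv[iout] = n_div;
      ++iout;
    }
  };

  record_upto(t); // outputs at (or before) the schedule start

  for (int ip = 0; ip < n_ph; ++ip) {
    if (kind[ip] == PHASE_DIVISION) {
      // each nucleus splits; daughters copy the mother's concentrations
      std::vector<double> y2(2 * N * c.G);
      for (int a = 0; a < c.G; ++a)
        for (int i = 0; i < N; ++i) {
          y2[a * 2 * N + 2 * i] = y[a * N + i];
          y2[a * 2 * N + 2 * i + 1] = y[a * N + i];
        }
      y.swap(y2);
      N *= 2;
      ++n_div;
      ++epoch;
      if (epoch >= (int)bcds.size())
        Rcpp::stop("no Bcd profile supplied for division epoch %d", epoch);
      if ((int)bcds[epoch].size() != N)
        Rcpp::stop("Bcd profile for epoch %d has %d values; expected %d",
                   epoch, (int)bcds[epoch].size(), N);
      t = ph_end[ip];
      record_upto(t);
    } else {
      c.set_epoch(N, n_div, &bcds[epoch][0]);
      c.production_on = (kind[ip] == PHASE_INTERPHASE);
      Integrator integ(c);
      double t1 = ph_end[ip];
      // is the next phase an instantaneous division at t1?
      bool div_next = (ip + 1 < n_ph) && (kind[ip + 1] == PHASE_DIVISION) &&
                      (std::fabs(ph_start[ip + 1] - t1) < eps);
      while (iout < n_out && output_times[iout] < t1 - eps) {
        integ.span(y, t, output_times[iout], rtol);
        t = output_times[iout];
        record_upto(t);
      }
      integ.span(y, t, t1, rtol);
      t = t1;
      if (!div_next) record_upto(t);
    }
  }
  record_upto(t);
  if (iout < n_out)
    Rcpp::stop("output time %f lies beyond the schedule end %f",
               output_times[iout], t);

  return Rcpp::List::create(Rcpp::Named("conc") = out_conc,
                            Rcpp::Named("n_div") = out_ndiv);
}
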