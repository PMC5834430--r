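#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Projected steepest-descent fitting of multi-exponential diffusion decay
// models. All inputs arrive pre-scaled from R: b in ms/um^2, diffusivities
// in um^2/ms, so every free parameter is O(0.1-5) and a single step size is
// meaningful across the whole parameter vector.
//
// Model codes and free-parameter layout (implied fast fraction eliminated):
//   1 biexp      p = (f_slow, d_slow, d_fast)                 k = 3
//   2 triexp     p = (f_vs, f_slow, d_vs, d_slow, d_fast)     k = 5
//   3 modtriexp  p = (f0, f_slow, d_slow, d_fast)             k = 4

namespace {

struct Layout {
  int n_frac;   // leading fraction parameters
  int n_par;    // total free parameters
};

Layout layout_for(int model) {
  switch (model) {
    case 1: return {1, 3};
    case 2: return {2, 5};
    case 3: return {2, 4};
    default: stop("unknown model code");
  }
}

// model prediction at one b for parameter vector p
double predict_one(int model, const std::vector<double>& p, double b) {
  if (model == 1) {
    double fs = p[0];
    return fs * std::exp(-p[1] * b) + (1.0 - fs) * std::exp(-p[2] * b);
  } else if (model == 2) {
    double fvs = p[0], fs = p[1];
    return fvs * std::exp(-p[2] * b) + fs * std::exp(-p[3] * b) +
           (1.0 - fvs - fs) * std::exp(-p[4] * b);
  } else {
    double f0 = p[0], fs = p[1];
    return f0 + fs * std::exp(-p[2] * b) +
           (1.0 - f0 - fs) * std::exp(-p[3] * b);
  }
}

double rss_of(int model, const std::vector<double>& p,
              const NumericVector& b, const NumericVector& y) {
  double s = 0.0;
  for (int i = 0; i < b.size(); ++i) {
    double r = predict_one(model, p, b[i]) - y[i];
    s += r * r;
  }
  return s;
}

void gradient(int model, const std::vector<double>& p,
              const NumericVector& b, const NumericVector& y,
              std::vector<double>& g) {
  std::fill(g.begin(), g.end(), 0.0);
  for (int i = 0; i < b.size(); ++i) {
    double bi = b[i];
    if (model == 1) {
      double es = std::exp(-p[1] * bi), ef = std::exp(-p[2] * bi);
      double m = p[0] * es + (1.0 - p[0]) * ef;
      double r2 = 2.0 * (m - y[i]);
      g[0] += r2 * (es - ef);
      g[1] += r2 * (-p[0] * bi * es);
      g[2] += r2 * (-(1.0 - p[0]) * bi * ef);
    } else if (model == 2) {
      double evs = std::exp(-p[2] * bi), es = std::exp(-p[3] * bi),
             ef = std::exp(-p[4] * bi);
      double ff = 1.0 - p[0] - p[1];
      double m = p[0] * evs + p[1] * es + ff * ef;
      double r2 = 2.0 * (m - y[i]);
      g[0] += r2 * (evs - ef);
      g[1] += r2 * (es - ef);
      g[2] += r2 * (-p[0] * bi * evs);
      g[3] += r2 * (-p[1] * bi * es);
      g[4] += r2 * (-ff * bi * ef);
    } else {
      double es = std::exp(-p[2] * bi), ef = std::exp(-p[3] * bi);
      double ff = 1.0 - p[0] - p[1];
      double m = p[0] + p[1] * es + ff * ef;
      double r2 = 2.0 * (m - y[i]);
      g[0] += r2 * (1.0 - ef);
      g[1] += r2 * (es - ef);
      g[2] += r2 * (-p[1] * bi * es);
      g[3] += r2 * (-ff * bi * ef);
    }
  }
}

// Euclidean projection of the leading n_frac entries onto
// {f >= 0, sum f <= 1}; diffusivities clipped at zero.
void project(const Layout& lay, std::vector<double>& p) {
  int m = lay.n_frac;
  double s = 0.0;
  for (int i = 0; i < m; ++i) {
    if (p[i] < 0.0) p[i] = 0.0;
    s += p[i];
  }
  if (s > 1.0) {
    // exact projection onto the unit simplex (sum = 1): sort-and-threshold
    std::vector<double> u(p.begin(), p.begin() + m);
    std::sort(u.begin(), u.end(), std::greater<double>());
    double css = 0.0, theta = 0.0;
    int rho = 0;
    for (int i = 0; i < m; ++i) {
      css += u[i];
      double t = (css - 1.0) / (i + 1);
      if (u[i] - t > 0.0) { rho = i + 1; theta = t; }
    }
    for (int i = 0; i < m; ++i) p[i] = std::max(p[i] - theta, 0.0);
  }
  for (int i = m; i < lay.n_par; ++i)
    if (p[i] < 0.0) p[i] = 0.0;
}

}  // namespace

// [[Rcpp::export(name = ".fit_descent_cpp")]]
List fit_descent_cpp(NumericVector b, NumericVector y, int model,
                     NumericVector init, int max_iterations, double rel_tol,
                     double step_init, bool trace) {
  Layout lay = layout_for(model);
  if (init.size() != lay.n_par) stop("init has wrong length for model");
  if (b.size() != y.size()) stop("b and y lengths differ");

  std::vector<double> p(init.begin(), init.end());
  project(lay, p);
  std::vector<double> g(lay.n_par), cand(lay.n_par);
  std::vector<double> p_prev(lay.n_par), g_prev(lay.n_par);
  double f_cur = rss_of(model, p, b, y);
  double step = step_init;
  bool converged = false, have_prev = false;
  int iter = 0;
  std::vector<double> tr;
  if (trace) tr.push_back(f_cur);

  const double step_min = 1e-17, step_max = 1e4;
  for (iter = 0; iter < max_iterations; ++iter) {
    gradient(model, p, b, y, g);
    double gnorm = 0.0;
    for (double gi : g) gnorm += gi * gi;
    if (std::sqrt(gnorm) < 1e-15) { converged = true; break; }

    // spectral (Barzilai-Borwein) initial step from the previous accepted
    // move, safeguarded below by the backtracking line search
    if (have_prev) {
      double sy = 0.0, ss = 0.0;
      for (int j = 0; j < lay.n_par; ++j) {
        double sj = p[j] - p_prev[j], yj = g[j] - g_prev[j];
        sy += sj * yj;
        ss += sj * sj;
      }
      if (sy > 0.0 && ss > 0.0)
        step = std::min(std::max(ss / sy, 1e-12), step_max);
    }

    bool accepted = false;
    double f_new = f_cur;
    while (step >= step_min) {
      for (int j = 0; j < lay.n_par; ++j) cand[j] = p[j] - step * g[j];
      project(lay, cand);
      f_new = rss_of(model, cand, b, y);
      if (f_new < f_cur) { accepted = true; break; }
      step *= 0.5;
    }
    if (!accepted) { converged = true; break; }  // no descent direction left

    double drop = f_cur - f_new;
    p_prev = p;
    g_prev = g;
    have_prev = true;
    p = cand;
    f_cur = f_new;
    if (trace) tr.push_back(f_cur);
    step = std::min(step * 2.0, step_max);
    if (drop < rel_tol * std::max(f_cur, 1e-30)) { converged = true; ++iter; break; }
  }

  List out = List::create(
      _["params"] = NumericVector(p.begin(), p.end()),
      _["rss"] = f_cur,
      _["iterations"] = iter,
      _["converged"] = converged);
  if (trace) out["trace"] = NumericVector(tr.begin(), tr.end());
  return out;
}
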