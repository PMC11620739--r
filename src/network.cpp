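// Simulation core for the self-organizing grid-cell network.
//
// The per-step loop implements: Gaussian place-cell inputs -> total field
// (feedforward + normalized recurrent) -> adaptation -> threshold-linear
// transfer with exact active fraction -> Hebbian update with clipping and
// projection of each weight row into the unit ball -> running averages ->
// rate-map accumulator.  Two numerical devices keep a 1e6-step run fast
// without changing the model: input tuning curves are truncated at
// 4.5 sigma (relative contributions < 5e-5), and the per-row norm
// projection is tracked through a lazy scalar multiplier with an exactly
// maintained sum of squares (recomputed in full every 8192 steps to absorb
// floating-point drift).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_generate_trajectory(int n_steps, double step_len, double turn_sd,
                             double arena, int max_redraw = 10000) {
  if (n_steps <= 0) stop("n_steps must be positive");
  NumericMatrix pos(n_steps, 2);
  NumericVector head(n_steps);
  double x = arena / 2.0, y = arena / 2.0;
  double h = R::runif(0.0, 2.0 * M_PI);
  for (int t = 0; t < n_steps; ++t) {
    double nh = h + R::rnorm(0.0, turn_sd);
    double nx = x + step_len * std::cos(nh);
    double ny = y + step_len * std::sin(nh);
    int tries = 0;
    while (nx < 0 || nx > arena || ny < 0 || ny > arena) {
      // boundary rule: redraw the turn until the step stays inside
      nh = h + R::rnorm(0.0, turn_sd);
      if (++tries > max_redraw) {
        // pathological heading (possible when turn_sd == 0): aim inward
        nh = std::atan2(arena / 2.0 - y, arena / 2.0 - x);
      }
      nx = x + step_len * std::cos(nh);
      ny = y + step_len * std::sin(nh);
      if (tries > max_redraw + 2) stop("trajectory stuck at boundary");
    }
    x = nx;
    y = ny;
    h = nh;
    pos(t, 0) = x;
    pos(t, 1) = y;
    head[t] = h;
  }
  return List::create(_["positions"] = pos, _["headings"] = head);
}

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix W_in0, NumericMatrix W_rec, NumericMatrix traj,
                  List par, IntegerVector checkpoint_steps) {
  const int NG = W_in0.nrow();
  const int NI = W_in0.ncol();
  const int n_steps = traj.nrow();

  const double arena = as<double>(par["arena_side"]);
  const double sigma = as<double>(par["input_sigma"]);
  const double peak = as<double>(par["input_peak_rate"]);
  const double beta = as<double>(par["beta_adapt"]);
  const double gainG = as<double>(par["gain_G"]);
  const double afrac = as<double>(par["active_fraction"]);
  const double eps = as<double>(par["epsilon_learn"]);
  const double delta = as<double>(par["delta_avg"]);
  const double tau = as<double>(par["tau_map"]);
  const int n_px = as<int>(par["n_px"]);
  const double px_size = as<double>(par["pixel_size"]);
  const int rec_off_step = as<int>(par["rec_off_step"]);  // -1: never
  const bool adapt_new = par.containsElementNamed("adapt_use_new") ?
      as<bool>(par["adapt_use_new"]) : false;

  const int n_side = static_cast<int>(std::lround(std::sqrt(double(NI))));
  if (n_side * n_side != NI) stop("n_input must be a perfect square");
  const double cstep = arena / n_side;  // input lattice spacing
  std::vector<double> centers(n_side);
  for (int a = 0; a < n_side; ++a) centers[a] = (a + 0.5) * cstep;

  bool has_rec = false;
  for (int i = 0; i < NG * NG && !has_rec; ++i) has_rec = (W_rec[i] != 0.0);

  // weight storage with lazy per-row scale
  std::vector<double> w(static_cast<size_t>(NG) * NI), s(NG, 1.0), q(NG, 0.0);
  for (int i = 0; i < NG; ++i) {
    double qq = 0;
    for (int j = 0; j < NI; ++j) {
      double v = W_in0(i, j);
      w[static_cast<size_t>(i) * NI + j] = v;
      qq += v * v;
    }
    q[i] = qq;
    if (qq > 0) s[i] = 1.0 / std::sqrt(qq);
  }

  std::vector<double> h(NG, 0), hact(NG, 0), hinact(NG, 0), r(NG, 0),
      rbar_g(NG, 0), rbar_in(NI, 0), rin(NI, 0), val(NG);
  std::vector<int> ord(NG);
  const int m_active = static_cast<int>(std::ceil(afrac * NG));

  const double map_off = (arena - n_px * px_size) / 2.0;
  std::vector<double> maps(static_cast<size_t>(n_px) * n_px * NG, 0.0);
  std::vector<int> occupancy(static_cast<size_t>(n_px) * n_px, 0);

  std::vector<int> cps(checkpoint_steps.begin(), checkpoint_steps.end());
  std::sort(cps.begin(), cps.end());
  List checkpoints(cps.size());
  IntegerVector cp_steps(cps.size());
  size_t cp_next = 0;

  const double trunc_r = 4.5 * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double* Wrec = has_rec ? &W_rec[0] : nullptr;

  std::vector<int> jlist;  // input cells within the truncation window
  jlist.reserve(256);
  std::vector<int> supp;  // presynaptic support of the Hebbian update
  supp.reserve(NI);

  for (int t = 0; t < n_steps; ++t) {
    const double x = traj(t, 0), y = traj(t, 1);
    if (t == rec_off_step) Wrec = nullptr;  // attractor turned off

    // --- input rates (truncated Gaussian tuning curves) ---
    for (int j : jlist) rin[j] = 0.0;
    jlist.clear();
    int a0 = std::max(0, static_cast<int>(std::floor((x - trunc_r) / cstep - 0.5)));
    int a1 = std::min(n_side - 1,
                      static_cast<int>(std::ceil((x + trunc_r) / cstep - 0.5)));
    int b0 = std::max(0, static_cast<int>(std::floor((y - trunc_r) / cstep - 0.5)));
    int b1 = std::min(n_side - 1,
                      static_cast<int>(std::ceil((y + trunc_r) / cstep - 0.5)));
    for (int b = b0; b <= b1; ++b) {
      double dy = y - centers[b];
      for (int a = a0; a <= a1; ++a) {
        double dx = x - centers[a];
        double d2 = dx * dx + dy * dy;
        if (d2 <= trunc_r * trunc_r) {
          int j = a + n_side * b;
          rin[j] = peak * std::exp(-d2 * inv2s2);
          jlist.push_back(j);
        }
      }
    }

    // --- total field: feedforward + normalized recurrent (previous rates) ---
    double mean_r = 0;
    for (int i = 0; i < NG; ++i) mean_r += r[i];
    mean_r /= NG;
    for (int i = 0; i < NG; ++i) {
      const double* wi = &w[static_cast<size_t>(i) * NI];
      double acc = 0;
      for (int j : jlist) acc += wi[j] * rin[j];
      h[i] = s[i] * acc;
    }
    if (Wrec && mean_r > 1e-12) {
      const double inv_mr = 1.0 / mean_r;
      for (int i = 0; i < NG; ++i) {
        const double* wr = Wrec + static_cast<size_t>(i) * NG;
        double acc = 0;
        for (int k = 0; k < NG; ++k) acc += wr[k] * r[k];
        h[i] += acc * inv_mr;
      }
    }

    // --- adaptation ---
    for (int i = 0; i < NG; ++i) {
      double ha_old = hact[i];
      hact[i] = h[i] - hinact[i];
      hinact[i] += beta * (adapt_new ? hact[i] : ha_old);
    }

    // --- threshold-linear transfer with exact active fraction ---
    for (int i = 0; i < NG; ++i) ord[i] = i;
    std::nth_element(ord.begin(), ord.begin() + m_active, ord.end(),
                     [&](int a, int b) {
                       return hact[a] > hact[b] || (hact[a] == hact[b] && a < b);
                     });
    const double T = hact[ord[m_active]];  // (m_active+1)-th largest
    double denom = 0;
    for (int i = 0; i < NG; ++i) val[i] = 0;
    for (int ii = 0; ii < m_active; ++ii) {
      int i = ord[ii];
      double v = hact[i] - T;
      if (v < 0) v = 0;
      val[i] = v;
      denom += v;
    }
    denom /= NG;
    if (denom < 1e-12) {
      for (int i = 0; i < NG; ++i) r[i] = 0;
    } else {
      const double g = gainG / denom;
      for (int i = 0; i < NG; ++i) r[i] = g * val[i];
    }

    // --- Hebbian update with clipping and unit-sphere projection ---
    if (eps > 0) {
      // presynaptic support of this step: inputs firing now or recently
      supp.clear();
      for (int j = 0; j < NI; ++j)
        if (rin[j] != 0.0 || rbar_in[j] != 0.0) supp.push_back(j);
      for (int i = 0; i < NG; ++i) {
        const double rg = r[i] * eps, rb = rbar_g[i] * eps;
        if (rg == 0 && rb == 0) continue;
        double* wi = &w[static_cast<size_t>(i) * NI];
        const double inv_s = 1.0 / s[i];
        double dq = 0;
        for (int j : supp) {
          double dtrue = rin[j] * rg - rbar_in[j] * rb;
          double old = wi[j];
          double nw = old + dtrue * inv_s;
          if (nw < 0) nw = 0;
          dq += nw * nw - old * old;
          wi[j] = nw;
        }
        q[i] += dq;
        if (q[i] > 0) s[i] = 1.0 / std::sqrt(q[i]);  // row on the unit sphere
      }
    }

    // --- running averages (after the weight update) ---
    for (int i = 0; i < NG; ++i) rbar_g[i] = rbar_g[i] * (1 - delta) + r[i] * delta;
    for (int j = 0; j < NI; ++j) {
      double v = rbar_in[j] * (1 - delta) + rin[j] * delta;
      rbar_in[j] = (v < 1e-16) ? 0.0 : v;
    }

    // --- rate-map accumulator: only the traversed pixel is touched ---
    int px = std::min(n_px - 1, std::max(0, static_cast<int>((x - map_off) / px_size)));
    int py = std::min(n_px - 1, std::max(0, static_cast<int>((y - map_off) / px_size)));
    double* mp = &maps[(static_cast<size_t>(py) * n_px + px) * NG];
    for (int i = 0; i < NG; ++i) mp[i] = mp[i] * (1 - tau) + r[i] * tau;
    occupancy[static_cast<size_t>(py) * n_px + px] += 1;

    // --- housekeeping ---
    if ((t & 8191) == 8191) {
      Rcpp::checkUserInterrupt();
      bool bad = false;
      for (int i = 0; i < NG; ++i)
        if (!R_finite(hact[i]) || !R_finite(r[i])) bad = true;
      if (bad) stop("non-finite network state at step %d", t + 1);
      for (int i = 0; i < NG; ++i) {
        double* wi = &w[static_cast<size_t>(i) * NI];
        double qq = 0;
        for (int j = 0; j < NI; ++j) {
          wi[j] *= s[i];
          qq += wi[j] * wi[j];
        }
        s[i] = 1.0;
        q[i] = qq;
        if (qq > 1.0) s[i] = 1.0 / std::sqrt(qq);
      }
    }

    if (cp_next < cps.size() && t + 1 == cps[cp_next]) {
      NumericVector cpm(maps.size());
      // store as [cell, px, py] for natural R indexing map[cell][x][y]
      for (int py2 = 0; py2 < n_px; ++py2)
        for (int px2 = 0; px2 < n_px; ++px2)
          for (int i = 0; i < NG; ++i)
            cpm[i + NG * (px2 + static_cast<size_t>(n_px) * py2)] =
                maps[(static_cast<size_t>(py2) * n_px + px2) * NG + i];
      cpm.attr("dim") = IntegerVector::create(NG, n_px, n_px);
      checkpoints[cp_next] = cpm;
      cp_steps[cp_next] = cps[cp_next];
      ++cp_next;
    }
  }

  NumericMatrix W_out(NG, NI);
  for (int i = 0; i < NG; ++i)
    for (int j = 0; j < NI; ++j)
      W_out(i, j) = w[static_cast<size_t>(i) * NI + j] * s[i];
  NumericVector maps_out(maps.size());
  for (int py = 0; py < n_px; ++py)
    for (int px = 0; px < n_px; ++px)
      for (int i = 0; i < NG; ++i)
        maps_out[i + NG * (px + static_cast<size_t>(n_px) * py)] =
            maps[(static_cast<size_t>(py) * n_px + px) * NG + i];
  maps_out.attr("dim") = IntegerVector::create(NG, n_px, n_px);
  IntegerMatrix occ(n_px, n_px);
  for (int py = 0; py < n_px; ++py)
    for (int px = 0; px < n_px; ++px)
      occ(px, py) = occupancy[static_cast<size_t>(py) * n_px + px];

  return List::create(
      _["W_in"] = W_out, _["maps"] = maps_out, _["occupancy"] = occ,
      _["checkpoints"] = checkpoints, _["checkpoint_steps"] = cp_steps,
      _["h_act"] = NumericVector(hact.begin(), hact.end()),
      _["h_inact"] = NumericVector(hinact.begin(), hinact.end()),
      _["r_grid"] = NumericVector(r.begin(), r.end()),
      _["r_bar_grid"] = NumericVector(rbar_g.begin(), rbar_g.end()),
      _["r_bar_in"] = NumericVector(rbar_in.begin(), rbar_in.end()));
}
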