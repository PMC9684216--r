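// Euler integration of the two-hemisphere visuo-tactile rate network.
//
// State per hemisphere: tactile map u_t (n units), visual map u_v (n units),
// one multisensory unit u_m, one inhibitory interneuron u_i.  Activities are
// logistic functions of the state.  The interneuron of one hemisphere is
// driven by the OTHER hemisphere's multisensory activity read from a delay
// line (callosal transmission delay).
//
// Hemispheres are labelled "b" (bright-associated hand) and "d" (dim hand).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::vec logis(const arma::vec& u, double slope, double thresh) {
  return 1.0 / (1.0 + arma::exp(-slope * (u - thresh)));
}
static inline double logis1(double u, double slope, double thresh) {
  return 1.0 / (1.0 + std::exp(-slope * (u - thresh)));
}

// [[Rcpp::export]]
List vt_integrate_cpp(const arma::mat& K_t_b, const arma::mat& K_v_b,
                      const arma::mat& K_t_d, const arma::mat& K_v_d,
                      const arma::vec& ff_t_b, const arma::vec& ff_v_b,
                      const arma::vec& ff_t_d, const arma::vec& ff_v_d,
                      const arma::vec& fb_t_b, const arma::vec& fb_v_b,
                      const arma::vec& fb_t_d, const arma::vec& fb_v_d,
                      double w_inter_b, double w_inter_d,
                      const arma::vec& inh_t_b, const arma::vec& inh_v_b,
                      const arma::vec& inh_t_d, const arma::vec& inh_v_d,
                      const arma::vec& drive_t_b, const arma::vec& drive_v_b,
                      const arma::vec& drive_t_d, const arma::vec& drive_v_d,
                      double slope_u, double thresh_u,
                      double slope_m, double thresh_m,
                      double slope_i, double thresh_i,
                      double tau_u, double tau_m, double tau_i,
                      double dt, int delay_steps,
                      int max_steps, double tol,
                      bool record, int fixed_steps) {
  const arma::uword n = K_t_b.n_rows;

  arma::vec u_t_b(n, arma::fill::zeros), u_v_b(n, arma::fill::zeros);
  arma::vec u_t_d(n, arma::fill::zeros), u_v_d(n, arma::fill::zeros);
  double u_m_b = 0.0, u_m_d = 0.0, u_i_b = 0.0, u_i_d = 0.0;

  arma::vec y_t_b = logis(u_t_b, slope_u, thresh_u);
  arma::vec y_v_b = logis(u_v_b, slope_u, thresh_u);
  arma::vec y_t_d = logis(u_t_d, slope_u, thresh_u);
  arma::vec y_v_d = logis(u_v_d, slope_u, thresh_u);
  double y_m_b = logis1(u_m_b, slope_m, thresh_m);
  double y_m_d = logis1(u_m_d, slope_m, thresh_m);
  double y_i_b = logis1(u_i_b, slope_i, thresh_i);
  double y_i_d = logis1(u_i_d, slope_i, thresh_i);

  // multisensory activity history for the callosal delay line (index = step)
  const int nmax = (fixed_steps > 0) ? fixed_steps : max_steps;
  std::vector<double> hist_m_b(nmax + 1), hist_m_d(nmax + 1);
  hist_m_b[0] = y_m_b;
  hist_m_d[0] = y_m_d;

  const double au = dt / tau_u, am = dt / tau_m, ai = dt / tau_i;

  arma::mat trace;
  if (record) trace.set_size(nmax + 1, 11);
  auto record_row = [&](int step) {
    trace(step, 0) = step * dt;
    trace(step, 1) = y_m_b;  trace(step, 2) = y_m_d;
    trace(step, 3) = y_i_b;  trace(step, 4) = y_i_d;
    trace(step, 5) = u_i_b;  trace(step, 6) = u_i_d;
    trace(step, 7) = y_t_b.max(); trace(step, 8) = y_t_d.max();
    trace(step, 9) = y_v_b.max(); trace(step, 10) = y_v_d.max();
  };
  if (record) record_row(0);

  bool converged = false;
  int step = 0;
  for (step = 1; step <= nmax; ++step) {
    // contralateral multisensory activity seen through the callosal delay
    int lag = step - 1 - delay_steps;
    double del_m_b = (lag >= 0) ? hist_m_b[lag] : 0.0;  // b's M, seen by d's interneuron
    double del_m_d = (lag >= 0) ? hist_m_d[lag] : 0.0;

    // net inputs from activities at step-1 (synchronous update)
    arma::vec net_t_b = drive_t_b + K_t_b * y_t_b + fb_t_b * y_m_b - inh_t_b * y_i_b;
    arma::vec net_v_b = drive_v_b + K_v_b * y_v_b + fb_v_b * y_m_b - inh_v_b * y_i_b;
    arma::vec net_t_d = drive_t_d + K_t_d * y_t_d + fb_t_d * y_m_d - inh_t_d * y_i_d;
    arma::vec net_v_d = drive_v_d + K_v_d * y_v_d + fb_v_d * y_m_d - inh_v_d * y_i_d;
    double net_m_b = arma::dot(ff_t_b, y_t_b) + arma::dot(ff_v_b, y_v_b);
    double net_m_d = arma::dot(ff_t_d, y_t_d) + arma::dot(ff_v_d, y_v_d);
    double net_i_b = w_inter_d * del_m_d;  // b's interneuron driven by d's M
    double net_i_d = w_inter_b * del_m_b;

    u_t_b += au * (net_t_b - u_t_b);
    u_v_b += au * (net_v_b - u_v_b);
    u_t_d += au * (net_t_d - u_t_d);
    u_v_d += au * (net_v_d - u_v_d);
    u_m_b += am * (net_m_b - u_m_b);
    u_m_d += am * (net_m_d - u_m_d);
    u_i_b += ai * (net_i_b - u_i_b);
    u_i_d += ai * (net_i_d - u_i_d);

    arma::vec ny_t_b = logis(u_t_b, slope_u, thresh_u);
    arma::vec ny_v_b = logis(u_v_b, slope_u, thresh_u);
    arma::vec ny_t_d = logis(u_t_d, slope_u, thresh_u);
    arma::vec ny_v_d = logis(u_v_d, slope_u, thresh_u);
    double ny_m_b = logis1(u_m_b, slope_m, thresh_m);
    double ny_m_d = logis1(u_m_d, slope_m, thresh_m);
    double ny_i_b = logis1(u_i_b, slope_i, thresh_i);
    double ny_i_d = logis1(u_i_d, slope_i, thresh_i);

    if (!u_t_b.is_finite() || !u_v_b.is_finite() ||
        !u_t_d.is_finite() || !u_v_d.is_finite() ||
        !std::isfinite(u_m_b) || !std::isfinite(u_m_d) ||
        !std::isfinite(u_i_b) || !std::isfinite(u_i_d)) {
      std::string pop = "unisensory";
      if (!std::isfinite(u_m_b) || !std::isfinite(u_m_d)) pop = "multisensory";
      if (!std::isfinite(u_i_b) || !std::isfinite(u_i_d)) pop = "inhibitory";
      stop("numerical instability in population '" + pop + "' at t = " +
           std::to_string(step * dt) + " ms");
    }

    double diff = 0.0;
    diff = std::max(diff, arma::abs(ny_t_b - y_t_b).max());
    diff = std::max(diff, arma::abs(ny_v_b - y_v_b).max());
    diff = std::max(diff, arma::abs(ny_t_d - y_t_d).max());
    diff = std::max(diff, arma::abs(ny_v_d - y_v_d).max());
    diff = std::max(diff, std::fabs(ny_m_b - y_m_b));
    diff = std::max(diff, std::fabs(ny_m_d - y_m_d));
    diff = std::max(diff, std::fabs(ny_i_b - y_i_b));
    diff = std::max(diff, std::fabs(ny_i_d - y_i_d));

    y_t_b = ny_t_b; y_v_b = ny_v_b; y_t_d = ny_t_d; y_v_d = ny_v_d;
    y_m_b = ny_m_b; y_m_d = ny_m_d; y_i_b = ny_i_b; y_i_d = ny_i_d;
    hist_m_b[step] = y_m_b;
    hist_m_d[step] = y_m_d;
    if (record) record_row(step);

    // wait past the delay line before declaring a steady state
    if (fixed_steps <= 0 && step > delay_steps && diff < tol) {
      converged = true;
      break;
    }
  }
  if (step > nmax) step = nmax;
  if (fixed_steps > 0) converged = true;

  List out = List::create(
    _["y_t_b"] = y_t_b, _["y_v_b"] = y_v_b,
    _["y_t_d"] = y_t_d, _["y_v_d"] = y_v_d,
    _["y_m_b"] = y_m_b, _["y_m_d"] = y_m_d,
    _["y_i_b"] = y_i_b, _["y_i_d"] = y_i_d,
    _["u_t_b"] = u_t_b, _["u_v_b"] = u_v_b,
    _["u_t_d"] = u_t_d, _["u_v_d"] = u_v_d,
    _["u_m_b"] = u_m_b, _["u_m_d"] = u_m_d,
    _["u_i_b"] = u_i_b, _["u_i_d"] = u_i_d,
    _["converged"] = converged, _["n_steps"] = step);
  if (record) {
    out["trace"] = trace.rows(0, std::min(step, nmax));
  }
  return out;
}
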