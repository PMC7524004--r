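// Explicit Euler integration of the delay-coupled FitzHugh-Nagumo network.
//
// State per node i:
//   dx_i/dt = x_i (a - x_i)(x_i - 1) - y_i + sum_{j != i} C_{ij} h(x_j(t - tau)) + drive_i(t)
//   dy_i/dt = b x_i - gamma y_i
//   h(x) = (1 + tanh x) / 2
//
// The delay tau is a whole number of Euler steps, shared by all edges of one
// matrix, implemented with a ring buffer holding the last tau states. Before
// t = tau the buffer returns the constant extension of the initial state.
//
// Timed protocol events enter in two forms:
//  * coupling scaling: the effective matrix is C + g(s) * D for a sparse
//    delta matrix D and a piecewise-linear gain g over the event's step span;
//  * additive drives on dx/dt: a sinusoid (phase zero at event start) or a
//    rectangular pulse train with real-valued period in samples.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ScaleEvent {
  arma::sp_mat D;
  long start, end;   // half-open step interval [start, end)
  double g0, g1;
  bool linear;       // linear ramp of g; otherwise constant g1
  double gain(long s) const {
    if (!linear) return g1;
    double frac = double(s - start) / double(end - start);
    return g0 + (g1 - g0) * frac;
  }
};

struct DriveEvent {
  arma::uvec nodes;  // 0-based
  int kind;          // 0 = sinusoid, 1 = pulse train
  double amplitude;
  double omega;      // radians per step (sinusoid)
  double period;     // steps (pulse train)
  double width;      // steps (pulse train)
  long start, end;
  double value(long s) const {
    if (kind == 0) return amplitude * std::sin(omega * double(s - start));
    double t = double(s - start);
    double phase = t - period * std::floor(t / period);
    return (phase < width) ? amplitude : 0.0;
  }
};

inline arma::vec sigmoid_h(const arma::vec& x) {
  return 0.5 * (1.0 + arma::tanh(x));
}

} // namespace

// [[Rcpp::export]]
List simulate_fhn_cpp(const arma::sp_mat& C,
                      int tau_steps,
                      double a, double b, double gamma_,
                      double dt,
                      arma::vec x0, arma::vec y0,
                      long n_steps,
                      List scale_events,
                      List drive_events,
                      const arma::mat& channel_weights,
                      bool record_x, bool record_y,
                      long record_from) {
  const arma::uword n = C.n_rows;
  if (x0.n_elem != n || y0.n_elem != n)
    stop("initial state length does not match matrix dimension");
  if (tau_steps < 1) stop("tau_steps must be >= 1");

  std::vector<ScaleEvent> sev;
  for (R_xlen_t e = 0; e < scale_events.size(); ++e) {
    List ev = scale_events[e];
    ScaleEvent s;
    s.D = as<arma::sp_mat>(ev["D"]);
    s.start = as<long>(ev["start_step"]);
    s.end = as<long>(ev["end_step"]);
    s.g0 = as<double>(ev["g0"]);
    s.g1 = as<double>(ev["g1"]);
    s.linear = as<bool>(ev["linear"]);
    if (s.D.n_rows != n || s.D.n_cols != n)
      stop("scale-event delta matrix dimension mismatch");
    sev.push_back(s);
  }
  std::vector<DriveEvent> dev;
  for (R_xlen_t e = 0; e < drive_events.size(); ++e) {
    List ev = drive_events[e];
    DriveEvent d;
    d.nodes = as<arma::uvec>(ev["nodes"]);
    d.kind = as<int>(ev["kind"]);
    d.amplitude = as<double>(ev["amplitude"]);
    d.omega = as<double>(ev["omega"]);
    d.period = as<double>(ev["period"]);
    d.width = as<double>(ev["width"]);
    d.start = as<long>(ev["start_step"]);
    d.end = as<long>(ev["end_step"]);
    if (!d.nodes.is_empty() && d.nodes.max() >= n)
      stop("drive-event node index out of range");
    dev.push_back(d);
  }

  const arma::uword k = channel_weights.n_cols;
  if (channel_weights.n_rows != n)
    stop("channel weight matrix must have one row per node");

  const long n_rec = n_steps + 1 - record_from; // states record_from .. n_steps
  if (n_rec < 1) stop("record_from leaves nothing to record");
  arma::mat channels(n_rec, k, arma::fill::zeros);
  arma::mat X, Y;
  if (record_x) X.set_size(n_rec, n);
  if (record_y) Y.set_size(n_rec, n);

  arma::vec x = x0, y = y0;
  arma::mat hist(n, tau_steps);
  hist.each_col() = x0; // constant pre-history

  auto record = [&](long s) {
    if (s < record_from) return;
    long r = s - record_from;
    if (k > 0) channels.row(r) = (x.t() * channel_weights);
    if (record_x) X.row(r) = x.t();
    if (record_y) Y.row(r) = y.t();
  };
  record(0);

  arma::vec drive(n);
  for (long s = 0; s < n_steps; ++s) {
    const arma::uword slot = arma::uword(s % tau_steps);
    arma::vec hh = sigmoid_h(hist.col(slot)); // h(x(t - tau))
    hist.col(slot) = x;                       // becomes x(t) for step s + tau

    arma::vec input = C * hh;
    for (const ScaleEvent& ev : sev)
      if (s >= ev.start && s < ev.end) input += ev.gain(s) * (ev.D * hh);

    bool any_drive = false;
    for (const DriveEvent& ev : dev) {
      if (s < ev.start || s >= ev.end) continue;
      if (!any_drive) { drive.zeros(); any_drive = true; }
      double v = ev.value(s);
      for (arma::uword t = 0; t < ev.nodes.n_elem; ++t)
        drive(ev.nodes(t)) += v;
    }

    arma::vec dx = x % (a - x) % (x - 1.0) - y + input;
    if (any_drive) dx += drive;
    arma::vec dy = b * x - gamma_ * y;
    x += dt * dx;
    y += dt * dy;

    if (!x.is_finite() || arma::abs(x).max() > 1e6) {
      std::ostringstream msg;
      msg << "integration blow-up at step " << (s + 1)
          << " (state non-finite or |x| > 1e6)";
      stop(msg.str());
    }
    record(s + 1);
  }

  List out = List::create(_["channels"] = channels,
                          _["x_final"] = x, _["y_final"] = y);
  if (record_x) out["x"] = X;
  if (record_y) out["y"] = Y;
  return out;
}
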