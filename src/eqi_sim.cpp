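#include <Rcpp.h>
using namespace Rcpp;

// Forward simulation of one EQI contraction at the sampling rate.
//
// State: joint angle theta (deg, plantarflexion-positive) and cumulative
// fatigue f (fraction of capacity lost). Isometric capacity is
//   C_iso(theta, f) = mvic * (1 - f) * (1 - fl_gain * theta)
// i.e. capacity grows linearly towards dorsiflexion (force-length effect).
// Concentric capacity is C_iso * con_factor (< 1: shortening costs force).
//
// Phases: (0) concentric push from maximal dorsiflexion at push_v deg/s
// while concentric capacity exceeds the machine load; (1) hold/yield: the
// joint holds while C_iso >= load and drifts dorsally at
// yield_gain * (load - torque) deg/s otherwise, with torque =
// min(load, C_iso); fatigue integrates fatigue_rate * torque/mvic * dt.
// An optional give-up event (giveup_time < Inf) decays the voluntary drive
// exponentially after that many seconds of phase 1, collapsing torque below
// the half-load threshold before the RoM limit is reached. (2) tail: after
// the contraction ends the angle stays put, velocity is zero and torque
// decays to zero, giving the offset rules data to fire on.
//
// [[Rcpp::export]]
List sim_eqi_core(double dt, double rom_pf, double rom_df, double mvic,
                  double load, double fl_gain, double fatigue_rate,
                  double yield_gain, double con_factor, double push_v,
                  double f0, double giveup_time, double t_max,
                  double tail_s) {
  const double drive_tau = 0.15;  // s, voluntary-drive collapse constant
  const double f_cap = 0.98;

  double fl0 = 1.0 - fl_gain * rom_df;  // most dorsiflexed = strongest
  if (mvic * (1.0 - f0) * fl0 * con_factor <= load) {
    return List::create(_["infeasible"] = true);
  }

  int n_max = (int)std::ceil((t_max + tail_s) / dt) + 2;
  std::vector<double> th, ve, tq, cap, fa;
  th.reserve(n_max); ve.reserve(n_max); tq.reserve(n_max);
  cap.reserve(n_max); fa.reserve(n_max);

  double theta = rom_df, f = f0, t = 0.0;
  int phase = 0;
  int apex_i = -1, end_i = -1;
  double phase1_t = 0.0, tail_t0 = 0.0, torque_at_end = 0.0;
  std::string end_reason = "timeout";

  for (int i = 0; i < n_max; i++) {
    double flv = 1.0 - fl_gain * theta;
    double C_iso = mvic * (1.0 - f) * flv;
    double v = 0.0, torque = 0.0;

    if (phase == 0) {
      if (C_iso * con_factor <= load || theta >= rom_pf - 1e-12) {
        phase = 1;
        apex_i = i;
        phase1_t = t;
      } else {
        v = push_v;
        torque = load;
      }
    }
    if (phase == 1) {
      double drive = 1.0;
      bool collapsing = R_finite(giveup_time) &&
        (t - phase1_t) >= giveup_time;
      if (collapsing) {
        drive = std::exp(-((t - phase1_t) - giveup_time) / drive_tau);
      }
      torque = std::min(load, C_iso) * drive;
      double deficit = load - torque;
      v = (deficit > 0.0) ? -yield_gain * deficit : 0.0;
      if (theta <= rom_df + 1e-12) {
        phase = 2; end_i = i; end_reason = "end_of_rom";
        tail_t0 = t; torque_at_end = torque;
      } else if (collapsing && torque < 0.5 * load) {
        phase = 2; end_i = i; end_reason = "gave_up";
        tail_t0 = t; torque_at_end = torque;
      }
    }
    bool done = false;
    if (phase == 2) {
      v = 0.0;
      torque = torque_at_end * std::exp(-(t - tail_t0) / drive_tau);
      if (t - tail_t0 >= tail_s) done = true;
    }

    th.push_back(theta); ve.push_back(v); tq.push_back(torque);
    cap.push_back(C_iso); fa.push_back(f);

    if (done) break;
    if (phase <= 1 && t >= t_max) { end_i = i; break; }

    theta += v * dt;
    if (theta < rom_df) theta = rom_df;
    if (theta > rom_pf) theta = rom_pf;
    f += fatigue_rate * (torque / mvic) * dt;
    if (f > f_cap) f = f_cap;
    t += dt;
  }

  int n = (int)th.size();
  if (end_i < 0) end_i = n - 1;
  return List::create(
    _["infeasible"] = false,
    _["theta"] = NumericVector(th.begin(), th.end()),
    _["velocity"] = NumericVector(ve.begin(), ve.end()),
    _["torque"] = NumericVector(tq.begin(), tq.end()),
    _["capacity"] = NumericVector(cap.begin(), cap.end()),
    _["fatigue"] = NumericVector(fa.begin(), fa.end()),
    _["apex_index"] = apex_i + 1,     // 1-based for R
    _["end_index"] = end_i + 1,
    _["end_reason"] = end_reason,
    _["f_end"] = fa[end_i]
  );
}
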