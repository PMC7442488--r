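// Core integrator for the rate-based PC/PV/SOM/VIP microcircuit.
//
// Dynamics (all rates in 1/s, time in ms):
//   soma:      tau_e dr_E/dt = -r_E + [I - theta]_+
//              I     = lam_d * [I_D + ca]_+ + (1 - lam_e) * I_E   (bracket optional)
//              I_E   = x_E - W_EP r_P
//              I_D   = x_D - W_DS r_S + W_DE r_E
//              ca    = c_amp * H(I_D0 - theta_c),  I_D0 = lam_e I_E + (1-lam_d) I_D
//   interneurons: tau_i dr_X/dt = -r_X + (net input), rates clamped at 0 after
//              each step (rectified linear units).
//
// Plasticity (optional, applied every step as Euler on dw/dt, masked to the
// structural connectivity and clipped at 0 to respect Dale's principle):
//   variant 1 (backprop), 2 (local recurrent), 3 (PV-homeostatic); see R docs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline vec pos(const vec& x) {
  return arma::clamp(x, 0.0, arma::datum::inf);
}

struct Net {
  mat EP, DS, DE, PE, PP, PS, PV, SE, SV, VE, VS;
  double tau_e, tau_i, theta, lam_d, lam_e, c_amp, theta_c;
  bool dend_rect;   // rectify dendritic contribution to the soma
  bool ca_at_eq;    // Heaviside convention: true -> H(0) = 1
};

struct Currents {
  vec IE, ID, ID0, ca, dendr, I, exc, inh;
};

// Synaptic currents and derived dendritic quantities at a given state.
static void currents(const Net& n, const vec& rE, const vec& rP, const vec& rS,
                     const vec& xE, const vec& xD, Currents& c) {
  c.IE  = xE - n.EP * rP;
  c.ID  = xD - n.DS * rS + n.DE * rE;
  c.ID0 = n.lam_e * c.IE + (1.0 - n.lam_d) * c.ID;
  c.ca.set_size(rE.n_elem);
  for (arma::uword i = 0; i < rE.n_elem; ++i) {
    bool fire = n.ca_at_eq ? (c.ID0[i] >= n.theta_c) : (c.ID0[i] > n.theta_c);
    c.ca[i] = fire ? n.c_amp : 0.0;
  }
  vec dend = c.ID + c.ca;
  c.dendr = n.dend_rect ? pos(dend) : dend;
  c.I   = n.lam_d * c.dendr + (1.0 - n.lam_e) * c.IE;
  c.exc = (1.0 - n.lam_e) * xE + n.lam_d * c.dendr;
  c.inh = (1.0 - n.lam_e) * (n.EP * rP);
}

static void derivs(const Net& n, const vec& rE, const vec& rP, const vec& rS,
                   const vec& rV, const vec& xE, const vec& xD, const vec& xP,
                   const vec& xS, const vec& xV,
                   vec& dE, vec& dP, vec& dS, vec& dV, Currents& c) {
  currents(n, rE, rP, rS, xE, xD, c);
  dE = (-rE + pos(c.I - n.theta)) / n.tau_e;
  dP = (-rP + (xP + n.PE * rE - n.PP * rP - n.PS * rS - n.PV * rV)) / n.tau_i;
  dS = (-rS + (xS + n.SE * rE - n.SV * rV)) / n.tau_i;
  dV = (-rV + (xV + n.VE * rE - n.VS * rS)) / n.tau_i;
}

// [[Rcpp::export]]
List cpp_simulate_phase(List weights, List state, List drive, List par,
                        double dt, double duration, double record_every,
                        double avg_start, List plast) {
  Net n;
  n.EP = as<mat>(weights["ep"]); n.DS = as<mat>(weights["ds"]);
  n.DE = as<mat>(weights["de"]); n.PE = as<mat>(weights["pe"]);
  n.PP = as<mat>(weights["pp"]); n.PS = as<mat>(weights["ps"]);
  n.PV = as<mat>(weights["pv"]); n.SE = as<mat>(weights["se"]);
  n.SV = as<mat>(weights["sv"]); n.VE = as<mat>(weights["ve"]);
  n.VS = as<mat>(weights["vs"]);
  n.tau_e = as<double>(par["tau_e"]);   n.tau_i = as<double>(par["tau_i"]);
  n.theta = as<double>(par["theta"]);   n.lam_d = as<double>(par["lambda_d"]);
  n.lam_e = as<double>(par["lambda_e"]); n.c_amp = as<double>(par["c_amp"]);
  n.theta_c = as<double>(par["theta_c"]);
  n.dend_rect = as<bool>(par["dend_rect"]);
  n.ca_at_eq  = as<bool>(par["ca_at_eq"]);

  vec rE = as<vec>(state["r_e"]), rP = as<vec>(state["r_p"]);
  vec rS = as<vec>(state["r_s"]), rV = as<vec>(state["r_v"]);
  const vec xE = as<vec>(drive["x_e"]), xD = as<vec>(drive["x_d"]);
  const vec xP = as<vec>(drive["x_p"]), xS = as<vec>(drive["x_s"]);
  const vec xV = as<vec>(drive["x_v"]);

  const int variant = as<int>(plast["variant"]);
  double eta_ep = 0, eta_ds = 0, eta_px = 0, eta_pe = 0, eps = 0;
  bool do_ep = false, do_ds = false, do_ps = false, do_pv = false, do_pe = false;
  vec rho_e, rho_p, inv_npost;
  mat m_ep, m_ds, m_ps, m_pv, m_pe;
  if (variant > 0) {
    eta_ep = as<double>(plast["eta_ep"]); eta_ds = as<double>(plast["eta_ds"]);
    eta_px = as<double>(plast["eta_px"]); eta_pe = as<double>(plast["eta_pe"]);
    eps = as<double>(plast["epsilon"]);
    do_ep = as<bool>(plast["do_ep"]); do_ds = as<bool>(plast["do_ds"]);
    do_ps = as<bool>(plast["do_ps"]); do_pv = as<bool>(plast["do_pv"]);
    do_pe = as<bool>(plast["do_pe"]);
    rho_e = as<vec>(plast["rho_e"]);
    rho_p = as<vec>(plast["rho_p"]);
    m_ep = as<mat>(plast["m_ep"]); m_ds = as<mat>(plast["m_ds"]);
    m_ps = as<mat>(plast["m_ps"]); m_pv = as<mat>(plast["m_pv"]);
    m_pe = as<mat>(plast["m_pe"]);
    inv_npost = as<vec>(plast["inv_npost"]);
  }

  const int n_steps = (int) std::lround(duration / dt);
  const int rec_stride = record_every > 0 ? (int) std::lround(record_every / dt) : 0;
  int n_rec = rec_stride > 0 ? n_steps / rec_stride + 1 : 0;

  mat trE, trP, trS, trV, trcur;
  vec tr_time;
  if (n_rec > 0) {
    trE.set_size(n_rec, rE.n_elem); trP.set_size(n_rec, rP.n_elem);
    trS.set_size(n_rec, rS.n_elem); trV.set_size(n_rec, rV.n_elem);
    trcur.set_size(n_rec, 4);  // mean exc, inh, dendritic, calcium over PCs
    tr_time.set_size(n_rec);
  }

  vec sE(rE.n_elem, arma::fill::zeros), sP(rP.n_elem, arma::fill::zeros);
  vec sS(rS.n_elem, arma::fill::zeros), sV(rV.n_elem, arma::fill::zeros);
  vec sIE(rE.n_elem, arma::fill::zeros), sID(rE.n_elem, arma::fill::zeros);
  vec sID0(rE.n_elem, arma::fill::zeros), sCA(rE.n_elem, arma::fill::zeros);
  vec sEXC(rE.n_elem, arma::fill::zeros), sINH(rE.n_elem, arma::fill::zeros);
  vec sDEN(rE.n_elem, arma::fill::zeros);
  int n_avg = 0;

  Currents c0, c1;
  vec k1E, k1P, k1S, k1V, k2E, k2P, k2S, k2V;

  int irec = 0;
  if (n_rec > 0) {  // record the initial state
    currents(n, rE, rP, rS, xE, xD, c0);
    tr_time[0] = 0.0;
    trE.row(0) = rE.t(); trP.row(0) = rP.t();
    trS.row(0) = rS.t(); trV.row(0) = rV.t();
    trcur(0, 0) = arma::mean(c0.exc); trcur(0, 1) = arma::mean(c0.inh);
    trcur(0, 2) = arma::mean(n.lam_d * c0.dendr); trcur(0, 3) = arma::mean(c0.ca);
    irec = 1;
  }

  for (int s = 1; s <= n_steps; ++s) {
    // Heun's method; rates clamped at 0 after predictor and corrector.
    derivs(n, rE, rP, rS, rV, xE, xD, xP, xS, xV, k1E, k1P, k1S, k1V, c0);
    vec pE = pos(rE + dt * k1E), pP = pos(rP + dt * k1P);
    vec pS = pos(rS + dt * k1S), pV = pos(rV + dt * k1V);
    derivs(n, pE, pP, pS, pV, xE, xD, xP, xS, xV, k2E, k2P, k2S, k2V, c1);
    rE = pos(rE + 0.5 * dt * (k1E + k2E));
    rP = pos(rP + 0.5 * dt * (k1P + k2P));
    rS = pos(rS + 0.5 * dt * (k1S + k2S));
    rV = pos(rV + 0.5 * dt * (k1V + k2V));

    bool want_cur = (variant > 0 && (do_ds)) ||
      (s * dt > avg_start) || (rec_stride > 0 && s % rec_stride == 0);
    if (want_cur) currents(n, rE, rP, rS, xE, xD, c0);

    if (variant > 0) {
      if (do_ep && eta_ep > 0) {
        n.EP += (eta_ep * dt) * ((rE - rho_e) * rP.t()) % m_ep;
        n.EP = arma::clamp(n.EP, 0.0, arma::datum::inf);
      }
      if (do_ds && eta_ds > 0) {
        // rule acts only where the dendrite is active: epsilon trims
        // onset-driven growth without eroding inhibition of silent
        // dendrites
        vec A = pos(c0.ID + c0.ca);
        vec drive = A - eps;
        drive.elem(arma::find(A <= 0.0)).zeros();
        n.DS += (eta_ds * dt) * (drive * rS.t()) % m_ds;
        n.DS = arma::clamp(n.DS, 0.0, arma::datum::inf);
      }
      if ((do_ps || do_pv) && eta_px > 0) {
        vec err;  // per-PV drive of the SOM/VIP -> PV updates
        if (variant == 1) {
          err = (m_ep.t() * (rho_e - rE)) % inv_npost;
        } else if (variant == 2) {
          err = n.PE * (rho_e - rE);
        } else {  // homeostatic on the PV rate itself
          err = rP - rho_p;
        }
        if (do_ps) {
          n.PS += (eta_px * dt) * (err * rS.t()) % m_ps;
          n.PS = arma::clamp(n.PS, 0.0, arma::datum::inf);
        }
        if (do_pv) {
          n.PV += (eta_px * dt) * (err * rV.t()) % m_pv;
          n.PV = arma::clamp(n.PV, 0.0, arma::datum::inf);
        }
      }
      if (do_pe && eta_pe > 0 && variant == 3) {
        n.PE += (eta_pe * dt) * ((rho_p - rP) * rE.t()) % m_pe;
        n.PE = arma::clamp(n.PE, 0.0, arma::datum::inf);
      }
    }

    if (s * dt > avg_start) {
      sE += rE; sP += rP; sS += rS; sV += rV;
      sIE += c0.IE; sID += c0.ID; sID0 += c0.ID0; sCA += c0.ca;
      sEXC += c0.exc; sINH += c0.inh; sDEN += n.lam_d * c0.dendr;
      ++n_avg;
    }
    if (rec_stride > 0 && s % rec_stride == 0) {
      tr_time[irec] = s * dt;
      trE.row(irec) = rE.t(); trP.row(irec) = rP.t();
      trS.row(irec) = rS.t(); trV.row(irec) = rV.t();
      trcur(irec, 0) = arma::mean(c0.exc); trcur(irec, 1) = arma::mean(c0.inh);
      trcur(irec, 2) = arma::mean(n.lam_d * c0.dendr);
      trcur(irec, 3) = arma::mean(c0.ca);
      ++irec;
    }
  }

  double inv = n_avg > 0 ? 1.0 / n_avg : 0.0;
  List avg = List::create(
    _["r_e"] = sE * inv, _["r_p"] = sP * inv, _["r_s"] = sS * inv,
    _["r_v"] = sV * inv, _["i_e_syn"] = sIE * inv, _["i_d_syn"] = sID * inv,
    _["i_d0"] = sID0 * inv, _["ca"] = sCA * inv, _["exc"] = sEXC * inv,
    _["inh"] = sINH * inv, _["dend"] = sDEN * inv, _["n_avg"] = n_avg);

  List out = List::create(
    _["state"] = List::create(_["r_e"] = rE, _["r_p"] = rP,
                              _["r_s"] = rS, _["r_v"] = rV),
    _["avg"] = avg);
  if (variant > 0) {
    out["weights"] = List::create(
      _["ep"] = n.EP, _["ds"] = n.DS, _["de"] = n.DE, _["pe"] = n.PE,
      _["pp"] = n.PP, _["ps"] = n.PS, _["pv"] = n.PV, _["se"] = n.SE,
      _["sv"] = n.SV, _["ve"] = n.VE, _["vs"] = n.VS);
  }
  if (n_rec > 0) {
    out["traces"] = List::create(
      _["time"] = tr_time, _["r_e"] = trE, _["r_p"] = trP, _["r_s"] = trS,
      _["r_v"] = trV, _["currents"] = trcur);
  }
  return out;
}
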