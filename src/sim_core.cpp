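// Compartmental membrane-equation integrator.
//
// Crank-Nicolson on the linear cable part (axial coupling, leak, frozen
// channel/synapse conductances) with channel gating advanced by exact
// exponential updates per step: scalar exponential-Euler for HH gates and
// a matrix exponential for Markov state vectors, both with transition
// rates frozen at the step-start transmembrane potential. Calcium stores
// and ribbon-synapse pools are advanced by semi-implicit scalar updates.
//
// Units: volts, seconds, ohms, farads, siemens, amperes; calcium in uM.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Gate {
  int power;
  double v0, dv;          // table grid origin and spacing (V or uM)
  arma::vec alpha, beta;  // 1/s
  bool ca_input;          // gate driven by [Ca]0 instead of voltage
  double state;
};

struct HHChannel {
  int comp;
  double gmax, erev;
  bool is_ca;
  std::vector<Gate> gates;
};

struct MarkovChannel {
  int comp;
  double gmax, erev;
  bool is_ca;
  int nstate;
  double v0, dv;
  arma::cube Q;           // ngrid slices of nstate x nstate generator Q
  arma::uvec open;        // 0-based open state indices
  arma::vec p;
};

struct CaStore {
  int comp;
  double kappa;           // uM per (A s): influx scaling
  double vmax;            // uM/s max pump rate
  double capk;            // uM pump half saturation
  double ca_rest;         // uM
  double ca;
};

struct Ribbon {
  int store;              // index into stores
  double vmax_pool, gl, rmsr;
  double pool;
  double rate;            // ves/s, last computed
};

inline double table_at(const arma::vec& tab, double v0, double dv, double v) {
  double u = (v - v0) / dv;
  int n = tab.n_elem;
  if (u <= 0.0) return tab(0);
  if (u >= n - 1.0) return tab(n - 1);
  int i = (int)u;
  double f = u - i;
  return tab(i) * (1.0 - f) + tab(i + 1) * f;
}

// interpolate a generator matrix at v
inline arma::mat q_at(const MarkovChannel& ch, double v) {
  double u = (v - ch.v0) / ch.dv;
  int n = ch.Q.n_slices;
  if (u <= 0.0) return ch.Q.slice(0);
  if (u >= n - 1.0) return ch.Q.slice(n - 1);
  int i = (int)u;
  double f = u - i;
  return ch.Q.slice(i) * (1.0 - f) + ch.Q.slice(i + 1) * f;
}

} // namespace

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(List spec, List drive, double dt, int nsteps,
                  int record_every) {
  const arma::vec cm = as<arma::vec>(spec["cm"]);         // F
  const arma::vec gleak = as<arma::vec>(spec["g_leak"]);  // S (0 for rm=Inf)
  const arma::vec vr = as<arma::vec>(spec["vr"]);         // V
  const int n = cm.n_elem;

  arma::mat edges;  // col 0,1: 0-based endpoints, col 2: conductance S
  if (spec.containsElementNamed("edges") && !Rf_isNull(spec["edges"]))
    edges = as<arma::mat>(spec["edges"]);

  // --- channels -----------------------------------------------------------
  std::vector<HHChannel> hh;
  std::vector<MarkovChannel> mk;
  if (spec.containsElementNamed("channels")) {
    List chl = spec["channels"];
    for (int i = 0; i < chl.size(); ++i) {
      List c = chl[i];
      std::string type = as<std::string>(c["type"]);
      if (type == "hh") {
        HHChannel h;
        h.comp = as<int>(c["comp"]) - 1;
        h.gmax = as<double>(c["gmax"]);
        h.erev = as<double>(c["erev"]);
        h.is_ca = as<bool>(c["is_ca"]);
        List gl = c["gates"];
        for (int g = 0; g < gl.size(); ++g) {
          List gg = gl[g];
          Gate gt;
          gt.power = as<int>(gg["power"]);
          gt.v0 = as<double>(gg["v0"]);
          gt.dv = as<double>(gg["dv"]);
          gt.alpha = as<arma::vec>(gg["alpha"]);
          gt.beta = as<arma::vec>(gg["beta"]);
          gt.ca_input = as<bool>(gg["ca_input"]);
          gt.state = as<double>(gg["state"]);
          h.gates.push_back(gt);
        }
        hh.push_back(h);
      } else {
        MarkovChannel m;
        m.comp = as<int>(c["comp"]) - 1;
        m.gmax = as<double>(c["gmax"]);
        m.erev = as<double>(c["erev"]);
        m.is_ca = as<bool>(c["is_ca"]);
        m.v0 = as<double>(c["v0"]);
        m.dv = as<double>(c["dv"]);
        m.Q = as<arma::cube>(c["Q"]);
        m.nstate = m.Q.n_rows;
        m.open = as<arma::uvec>(c["open"]);  // 1-based from R
        m.open -= 1;
        m.p = as<arma::vec>(c["p"]);
        mk.push_back(m);
      }
    }
  }

  // --- calcium stores and ribbon synapses ---------------------------------
  std::vector<CaStore> stores;
  if (spec.containsElementNamed("stores")) {
    List sl = spec["stores"];
    for (int i = 0; i < sl.size(); ++i) {
      List s = sl[i];
      CaStore st;
      st.comp = as<int>(s["comp"]) - 1;
      st.kappa = as<double>(s["kappa"]);
      st.vmax = as<double>(s["vmax"]);
      st.capk = as<double>(s["capk"]);
      st.ca_rest = as<double>(s["ca_rest"]);
      st.ca = as<double>(s["ca"]);
      stores.push_back(st);
    }
  }
  // map compartment -> store index for channel ca coupling and ca gating
  std::vector<int> store_of(n, -1);
  for (size_t i = 0; i < stores.size(); ++i) store_of[stores[i].comp] = i;

  std::vector<Ribbon> ribbons;
  if (spec.containsElementNamed("ribbons")) {
    List rl = spec["ribbons"];
    for (int i = 0; i < rl.size(); ++i) {
      List r = rl[i];
      Ribbon rb;
      rb.store = as<int>(r["store"]) - 1;
      rb.vmax_pool = as<double>(r["vmax_pool"]);
      rb.gl = as<double>(r["gl"]);
      rb.rmsr = as<double>(r["rmsr"]);
      rb.pool = as<double>(r["pool"]);
      rb.rate = 0.0;
      ribbons.push_back(rb);
    }
  }

  // --- drives -------------------------------------------------------------
  // current injections: list of (comp, trace[nsteps+1]) in amperes
  std::vector<std::pair<int, arma::vec>> iinj;
  if (drive.containsElementNamed("i_inj") && !Rf_isNull(drive["i_inj"])) {
    List il = drive["i_inj"];
    for (int i = 0; i < il.size(); ++i) {
      List e = il[i];
      iinj.push_back({as<int>(e["comp"]) - 1, as<arma::vec>(e["trace"])});
    }
  }
  // synaptic conductances: list of (comp, erev, trace[nsteps+1]) in S
  struct Syn { int comp; double erev; arma::vec g; };
  std::vector<Syn> syn;
  if (drive.containsElementNamed("g_syn") && !Rf_isNull(drive["g_syn"])) {
    List sl = drive["g_syn"];
    for (int i = 0; i < sl.size(); ++i) {
      List e = sl[i];
      syn.push_back({as<int>(e["comp"]) - 1, as<double>(e["erev"]),
                     as<arma::vec>(e["trace"])});
    }
  }
  // extracellular voltage: n x (nsteps+1) matrix in volts, optional
  arma::mat vex;
  bool has_vex = drive.containsElementNamed("vex") && !Rf_isNull(drive["vex"]);
  if (has_vex) vex = as<arma::mat>(drive["vex"]);

  // somatic voltage clamp (for the depolarized-equilibrium screen)
  int clamp_comp = -1, clamp_steps = 0;
  double clamp_v = 0.0;
  if (drive.containsElementNamed("clamp") && !Rf_isNull(drive["clamp"])) {
    List cl = drive["clamp"];
    clamp_comp = as<int>(cl["comp"]) - 1;
    clamp_v = as<double>(cl["v"]);
    clamp_steps = as<int>(cl["steps"]);
  }

  arma::vec V = as<arma::vec>(spec["v0"]);  // volts

  // initialize HH gates flagged with negative state to steady state
  for (auto& h : hh) {
    for (auto& g : h.gates) {
      if (g.state < 0) {
        double x = g.ca_input
          ? (store_of[h.comp] >= 0 ? stores[store_of[h.comp]].ca : 0.0)
          : V(h.comp) - (has_vex ? vex(h.comp, 0) : 0.0);
        double a = table_at(g.alpha, g.v0, g.dv, x);
        double b = table_at(g.beta, g.v0, g.dv, x);
        g.state = (a + b > 0) ? a / (a + b) : 0.0;
      }
    }
  }

  // axial coupling matrix (constant)
  arma::mat A(n, n, arma::fill::zeros);
  for (size_t e = 0; e < edges.n_rows; ++e) {
    int a = (int)edges(e, 0), b = (int)edges(e, 1);
    double g = edges(e, 2);
    A(a, a) += g; A(b, b) += g;
    A(a, b) -= g; A(b, a) -= g;
  }

  const bool passive = hh.empty() && mk.empty() && syn.empty() &&
                       clamp_comp < 0;

  // recording
  const int nrec = nsteps / record_every + 1;
  arma::mat Vrec(n, nrec);
  arma::mat rate_rec(ribbons.size(), ribbons.empty() ? 0 : nrec);
  arma::mat ca_rec(stores.size(), stores.empty() ? 0 : nrec);
  arma::mat pool_rec(ribbons.size(), ribbons.empty() ? 0 : nrec);
  int rec_i = 0;

  // initial release rates from initial calcium/pool
  for (auto& rb : ribbons) {
    double ca = stores[rb.store].ca;
    rb.rate = ca * ca * (rb.pool / rb.vmax_pool) * rb.gl;
  }

  auto record = [&](int k) {
    Vrec.col(rec_i) = V;
    for (size_t i = 0; i < ribbons.size(); ++i) {
      rate_rec(i, rec_i) = ribbons[i].rate;
      pool_rec(i, rec_i) = ribbons[i].pool;
    }
    for (size_t i = 0; i < stores.size(); ++i) ca_rec(i, rec_i) = stores[i].ca;
    rec_i++;
  };
  record(0);

  std::string status = "ok";
  arma::mat LHS, RHS_M;
  arma::mat P_lu; bool factored = false;

  arma::vec gchan(n), schan(n);

  for (int k = 0; k < nsteps; ++k) {
    // transmembrane potential at step start (drives gating)
    arma::vec W = V;
    if (has_vex) W -= vex.col(k);

    // --- advance gating states (rates frozen at step start) ---
    gchan.zeros(); schan.zeros();
    for (auto& h : hh) {
      double prod = 1.0;
      for (auto& g : h.gates) {
        double x = g.ca_input
          ? (store_of[h.comp] >= 0 ? stores[store_of[h.comp]].ca : 0.0)
          : W(h.comp);
        double a = table_at(g.alpha, g.v0, g.dv, x);
        double b = table_at(g.beta, g.v0, g.dv, x);
        double tot = a + b;
        double cinf = tot > 0 ? a / tot : g.state;
        g.state = cinf + (g.state - cinf) * std::exp(-dt * tot);
        double cp = g.state;
        for (int p = 1; p < g.power; ++p) cp *= g.state;
        prod *= cp;
      }
      double ge = h.gmax * prod;
      gchan(h.comp) += ge;
      schan(h.comp) += ge * h.erev;
    }
    for (auto& m : mk) {
      arma::mat Q = q_at(m, W(m.comp));
      m.p = arma::expmat(Q.t() * dt) * m.p;
      double po = arma::accu(m.p.elem(m.open));
      double ge = m.gmax * po;
      gchan(m.comp) += ge;
      schan(m.comp) += ge * m.erev;
    }

    // --- assemble linear system:  C dV/dt = -(B) V + s ---
    arma::vec gmem = gleak + gchan;
    arma::vec s = gleak % vr + schan;
    for (auto& sy : syn) {
      double g = 0.5 * (sy.g(k) + sy.g(k + 1));
      gmem(sy.comp) += g;
      s(sy.comp) += g * sy.erev;
    }
    for (auto& ii : iinj) s(ii.first) += 0.5 * (ii.second(k) + ii.second(k + 1));
    if (has_vex) {
      arma::vec vx_mid = 0.5 * (vex.col(k) + vex.col(k + 1));
      s += gmem % vx_mid;
      s += cm % (vex.col(k + 1) - vex.col(k)) / dt;
    }

    bool clamped = (clamp_comp >= 0 && k < clamp_steps);
    if (passive) {
      if (!factored) {
        LHS = A; LHS.diag() += gmem;
        RHS_M = -0.5 * LHS;
        LHS = 0.5 * LHS;
        LHS.diag() += cm / dt;
        RHS_M.diag() += cm / dt;
        P_lu = arma::inv(LHS);
        factored = true;
      }
      V = P_lu * (RHS_M * V + s);
    } else {
      arma::mat B = A; B.diag() += gmem;
      arma::mat L = 0.5 * B; L.diag() += cm / dt;
      arma::vec rhs = (-0.5) * (B * V) + (cm / dt) % V + s;
      if (clamped) {
        L.row(clamp_comp).zeros();
        L(clamp_comp, clamp_comp) = 1.0;
        rhs(clamp_comp) = clamp_v;
      }
      bool okslv = arma::solve(V, L, rhs, arma::solve_opts::fast);
      if (!okslv) { status = "unstable"; break; }
    }

    if (!V.is_finite() || arma::abs(V).max() > 1.0) {  // > 1000 mV: blown up
      status = "unstable";
      break;
    }

    // --- calcium stores (semi-implicit scalar update) ---
    if (!stores.empty()) {
      arma::vec Wn = V;
      if (has_vex) Wn -= vex.col(k + 1);
      arma::vec ica(stores.size(), arma::fill::zeros);
      for (auto& h : hh) {
        if (h.is_ca && store_of[h.comp] >= 0) {
          double prod = 1.0;
          for (auto& g : h.gates) {
            double cp = g.state;
            for (int p = 1; p < g.power; ++p) cp *= g.state;
            prod *= cp;
          }
          ica(store_of[h.comp]) += h.gmax * prod * (h.erev - Wn(h.comp));
        }
      }
      for (auto& m : mk) {
        if (m.is_ca && store_of[m.comp] >= 0) {
          double po = arma::accu(m.p.elem(m.open));
          ica(store_of[m.comp]) += m.gmax * po * (m.erev - Wn(m.comp));
        }
      }
      for (size_t i = 0; i < stores.size(); ++i) {
        CaStore& st = stores[i];
        double influx = st.kappa * std::abs(ica(i));
        double pump = st.vmax * st.ca / (st.ca + st.capk);
        double source = st.vmax * st.ca_rest / (st.ca_rest + st.capk);
        st.ca += dt * (influx - pump + source);
        if (st.ca < 0) st.ca = 0;
      }
    }

    // --- ribbon synapses (release then pool replenishment) ---
    for (auto& rb : ribbons) {
      double ca = stores[rb.store].ca;
      double r = ca * ca * (rb.pool / rb.vmax_pool) * rb.gl;
      rb.pool += -r * dt + rb.rmsr * dt * (1.0 - rb.pool / rb.vmax_pool);
      if (rb.pool < 0) rb.pool = 0;
      if (rb.pool > rb.vmax_pool) rb.pool = rb.vmax_pool;
      rb.rate = r;
    }

    if ((k + 1) % record_every == 0) record(k + 1);
  }

  // pad truncated recordings with the last recorded state
  if (rec_i < nrec) {
    for (int j = rec_i; j < nrec; ++j) {
      Vrec.col(j) = Vrec.col(rec_i - 1);
      for (size_t i = 0; i < ribbons.size(); ++i) {
        rate_rec(i, j) = rate_rec(i, rec_i - 1);
        pool_rec(i, j) = pool_rec(i, rec_i - 1);
      }
      for (size_t i = 0; i < stores.size(); ++i)
        ca_rec(i, j) = ca_rec(i, rec_i - 1);
    }
  }

  // final state for chaining (settle -> stimulus)
  List gate_state;
  {
    List hs(hh.size());
    for (size_t i = 0; i < hh.size(); ++i) {
      NumericVector st(hh[i].gates.size());
      for (size_t g = 0; g < hh[i].gates.size(); ++g) st[g] = hh[i].gates[g].state;
      hs[i] = st;
    }
    List ms(mk.size());
    for (size_t i = 0; i < mk.size(); ++i) ms[i] = wrap(mk[i].p);
    gate_state = List::create(_["hh"] = hs, _["markov"] = ms);
  }
  NumericVector ca_fin(stores.size()), pool_fin(ribbons.size());
  for (size_t i = 0; i < stores.size(); ++i) ca_fin[i] = stores[i].ca;
  for (size_t i = 0; i < ribbons.size(); ++i) pool_fin[i] = ribbons[i].pool;

  return List::create(
    _["V"] = Vrec, _["rate"] = rate_rec, _["ca"] = ca_rec,
    _["pool"] = pool_rec, _["status"] = status,
    _["steps_done"] = rec_i * record_every,
    _["final"] = List::create(_["v"] = wrap(V), _["gates"] = gate_state,
                              _["ca"] = ca_fin, _["pool"] = pool_fin));
}
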