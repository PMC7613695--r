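// Fewest-switches surface-hopping propagator: compiled mirror of the R
// reference engine (run_trajectory(engine = "r")).  Same algorithm, same
// order of operations, same RNG consumption (one uniform draw per nuclear
// step), so both engines produce matching trajectories for a given seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double EV_AMU = 103.642697;   // eV per amu A^2 fs^-2
static const double HBAR   = 0.6582119569; // eV fs

struct TermTable {
  arma::ivec state, coord, type;
  arma::vec p1, p2, p3;
};

static inline double cexp_clip(double x) {
  if (x > 60.0) x = 60.0;
  if (x < -60.0) x = -60.0;
  return std::exp(x);
}

// diagonal of the diabatic matrix and its per-coordinate gradients
static void eval_terms(const TermTable& tt, const arma::vec& q,
                       arma::vec& diag, arma::mat& dV) {
  diag.zeros();
  dV.zeros();
  const int nt = tt.state.n_elem;
  for (int i = 0; i < nt; ++i) {
    const int s = tt.state[i], c = tt.coord[i];
    const double x = q[c], p1 = tt.p1[i], p2 = tt.p2[i], p3 = tt.p3[i];
    double v = 0, d = 0;
    switch (tt.type[i]) {
    case 1: { v = 0.5 * p1 * (x - p2) * (x - p2); d = p1 * (x - p2); break; }
    case 2: { double e = cexp_clip(-p2 * (x - p3));
              v = p1 * (1 - e) * (1 - e); d = 2 * p1 * (1 - e) * p2 * e; break; }
    case 3: { double e = cexp_clip(-p2 * (x - p3));
              v = p1 * e; d = -p2 * p1 * e; break; }
    case 4: { double r = (x / p2) * (x / p2) - 1;
              v = p1 * r * r; d = p1 * 2 * r * 2 * x / (p2 * p2); break; }
    case 5: { double r = x - p2; v = p1 * r * r * r * r;
              d = 4 * p1 * r * r * r; break; }
    case 6: { v = p1 * (x - p2); d = p1; break; }
    }
    diag[s] += v;
    dV(c, s) += d;
  }
}

struct Adiab {
  arma::vec E;
  arma::mat U;
  arma::mat W;          // squared coefficients (diabat x adiabat)
  arma::mat grads;      // nc x n
  arma::vec tripw;      // triplet weight per adiabat
};

static bool adiabatize_cpp(const TermTable& tt, const arma::vec& origins,
                           const arma::mat& Vconst, const arma::uvec& istrip,
                           const arma::vec& q, const arma::mat* prevU,
                           Adiab& out) {
  const int n = origins.n_elem, nc = q.n_elem;
  arma::vec diag(n);
  arma::mat dV(nc, n);
  eval_terms(tt, q, diag, dV);
  arma::mat V = Vconst;
  V.diag() = origins + diag;
  if (!V.is_finite()) return false;
  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, V)) return false;
  // ascending order is guaranteed by eig_sym
  if (prevU) {
    for (int k = 0; k < n; ++k)
      if (arma::dot(prevU->col(k), evec.col(k)) < 0) evec.col(k) *= -1.0;
  } else {
    for (int k = 0; k < n; ++k) {
      arma::uword imax = arma::abs(evec.col(k)).index_max();
      if (evec(imax, k) < 0) evec.col(k) *= -1.0;
    }
  }
  arma::mat W = arma::square(evec);
  out.E = eval;
  out.U = evec;
  out.W = W;
  out.grads = dV * W;
  out.tripw = W.t() * arma::conv_to<arma::vec>::from(istrip);
  return true;
}

static double kinetic(const arma::vec& p, const arma::vec& m) {
  return 0.5 * arma::accu(arma::square(p) / m) * EV_AMU;
}

// [[Rcpp::export(name = ".fssh_run_cpp")]]
List fssh_run_cpp(List model_data, arma::vec q, arma::vec p, int state1,
                  List config) {
  TermTable tt;
  tt.state = as<arma::ivec>(model_data["term_state"]);   // 0-based
  tt.coord = as<arma::ivec>(model_data["term_coord"]);
  tt.type  = as<arma::ivec>(model_data["term_type"]);
  tt.p1 = as<arma::vec>(model_data["term_p1"]);
  tt.p2 = as<arma::vec>(model_data["term_p2"]);
  tt.p3 = as<arma::vec>(model_data["term_p3"]);
  arma::vec origins = as<arma::vec>(model_data["origins"]);
  arma::mat Vconst  = as<arma::mat>(model_data["Vconst"]);
  arma::uvec istrip = as<arma::uvec>(model_data["is_triplet"]);
  arma::vec masses  = as<arma::vec>(model_data["masses"]);

  const double dt = as<double>(config["dt"]);
  const int nsub = as<int>(config["n_substeps"]);
  const double tmax = as<double>(config["t_max"]);
  const bool deco = as<bool>(config["decoherence"]);
  const double decoC = as<double>(config["decoherence_C_eV"]);
  const double termgap = as<double>(config["termination_gap"]);
  const bool forbid0 = as<bool>(config["forbid_ground_hops"]);
  const int recevery = as<int>(config["record_every"]);

  const int n = origins.n_elem, nc = q.n_elem;
  const int nsteps = (int)std::ceil(tmax / dt);
  int a = state1 - 1;                         // 0-based active state
  RNGScope rngScope;

  Adiab ad;
  if (!adiabatize_cpp(tt, origins, Vconst, istrip, q, nullptr, ad))
    stop("initial adiabatization failed");
  arma::cx_vec cc(n, arma::fill::zeros);
  cc[a] = arma::cx_double(1.0, 0.0);

  const int nrec_max = nsteps / recevery + 2;
  arma::vec times(nrec_max);
  arma::mat positions(nrec_max, nc), momenta(nrec_max, nc);
  arma::ivec active_rec(nrec_max);
  arma::mat energies(nrec_max, n), populations(nrec_max, n);
  arma::ivec manifold_rec(nrec_max), rank_rec(nrec_max);
  arma::vec etot(nrec_max);
  std::vector<double> hop_time;
  std::vector<int> hop_from, hop_to, hop_acc;

  int ri = 0;
  auto record = [&](double t) {
    times[ri] = t;
    positions.row(ri) = q.t();
    momenta.row(ri) = p.t();
    active_rec[ri] = a + 1;
    energies.row(ri) = ad.E.t();
    populations.row(ri) = arma::real(cc % arma::conj(cc)).t();
    bool trip = ad.tripw[a] > 0.5;
    manifold_rec[ri] = trip ? 1 : 0;
    int rank = 0;   // position of the active state within its manifold
    for (int k = 0; k <= a; ++k)
      if ((ad.tripw[k] > 0.5) == trip) ++rank;
    rank_rec[ri] = rank;
    etot[ri] = ad.E[a] + kinetic(p, masses);
    ++ri;
  };
  record(0.0);

  double t = 0.0;
  bool failed = false;
  int reason = 0;                // 1 IC, 2 T1-trapped, 3 timeout, 4 failed

  for (int istep = 1; istep <= nsteps; ++istep) {
    // velocity Verlet on the active surface
    arma::vec g = ad.grads.col(a);
    arma::vec phalf = p - 0.5 * dt * g / EV_AMU;
    arma::vec qn = q + dt * (phalf / masses);
    Adiab ad2;
    if (!adiabatize_cpp(tt, origins, Vconst, istrip, qn, &ad.U, ad2)) {
      failed = true; break;
    }
    arma::vec pn = phalf - 0.5 * dt * ad2.grads.col(a) / EV_AMU;
    if (!ad2.E.is_finite() || !pn.is_finite()) { failed = true; break; }

    // overlap couplings (Loewdin orthonormalization)
    arma::mat S = ad.U.t() * ad2.U;
    double detS = arma::det(S);
    if (std::abs(detS) < 0.5) {
      arma::vec qm = (q + qn) / 2;
      Adiab adm;
      bool okm = adiabatize_cpp(tt, origins, Vconst, istrip, qm, &ad.U, adm);
      if (okm) S = (ad.U.t() * adm.U) * (adm.U.t() * ad2.U);
      if (!okm || std::abs(arma::det(S)) < 0.5) { failed = true; break; }
    }
    arma::mat Us, Vs;
    arma::vec sv;
    arma::svd(Us, sv, Vs, S);
    arma::mat So = Us * Vs.t();
    arma::mat Tm = (So - So.t()) / (2 * dt);
    arma::cx_mat Tc = arma::conv_to<arma::cx_mat>::from(Tm);

    // trivial-crossing tracking: follow the diabatic character when the
    // active adiabat swaps with a neighbour within one step
    int jstar = (int)arma::abs(So.row(a)).index_max();

    // electronic propagation, interaction picture, RK4 substeps
    const double dte = dt / nsub;
    arma::vec E1 = ad.E, dE = (ad2.E - ad.E) / dt;
    auto phase = [&](double tt_) -> arma::vec {
      return (E1 * tt_ + 0.5 * dE * tt_ * tt_) / HBAR;
    };
    auto eip = [&](double tt_, double sgn) -> arma::cx_vec {
      arma::vec ph = sgn * phase(tt_);
      return arma::exp(arma::cx_vec(arma::zeros<arma::vec>(ph.n_elem), ph));
    };
    auto deriv = [&](double tt_, const arma::cx_vec& av) -> arma::cx_vec {
      arma::cx_vec e = eip(tt_, 1.0);
      return -(e % (Tc * (arma::conj(e) % av)));
    };
    arma::cx_vec av = cc;                    // phase(0) = 0
    arma::vec hop_g(n, arma::fill::zeros);
    for (int j = 1; j <= nsub; ++j) {
      double t0 = (j - 1) * dte;
      arma::cx_vec cnow = av % eip(t0, -1.0);
      double pa = std::norm(cnow[a]);
      if (pa > 1e-12) {
        arma::vec b = 2.0 * arma::real(std::conj(cnow[a]) * cnow) % Tm.row(a).t();
        b.elem(arma::find(b < 0)).zeros();
        hop_g += dte * b / pa;
      }
      arma::cx_vec k1 = deriv(t0, av);
      arma::cx_vec k2 = deriv(t0 + dte / 2, av + dte / 2 * k1);
      arma::cx_vec k3 = deriv(t0 + dte / 2, av + dte / 2 * k2);
      arma::cx_vec k4 = deriv(t0 + dte, av + dte * k3);
      av += dte / 6 * (k1 + 2 * k2 + 2 * k3 + k4);
    }
    cc = av % eip(dt, -1.0);

    // fewest-switches hop decision (one uniform draw per nuclear step);
    // an excited-excited trivial crossing instead follows the character
    int target = -1;
    if (jstar != a) {
      a = jstar;
    } else {
    if (forbid0) hop_g[(int)ad2.W.row(0).index_max()] = 0;
    hop_g[a] = 0;
    double tot = arma::accu(hop_g);
    if (tot > 1) hop_g /= tot;
    double u = R::unif_rand();
    double cum = 0;
    for (int k = 0; k < n; ++k) {
      cum += hop_g[k];
      if (u < cum) { target = k; break; }
    }
    }
    if (target >= 0) {
      double dEhop = ad2.E[target] - ad2.E[a];
      double ekin = kinetic(pn, masses);
      bool acc = dEhop <= ekin;
      hop_time.push_back(t + dt);
      hop_from.push_back(a + 1);
      hop_to.push_back(target + 1);
      hop_acc.push_back(acc ? 1 : 0);
      if (acc) {
        double fac = std::sqrt(std::max(0.0, ekin - dEhop) / ekin);
        pn *= fac;
        a = target;
      }
    }
    q = qn; p = pn; ad = ad2;

    if (deco) {
      double ek = kinetic(p, masses);
      double pa = std::norm(cc[a]);
      if (ek > 0 && pa > 0) {
        double rest = 0;
        for (int k = 0; k < n; ++k) {
          if (k == a) continue;
          double dd = std::abs(ad.E[k] - ad.E[a]);
          if (dd > 0) {
            double tau = (HBAR / dd) * (1 + decoC / ek);
            cc[k] *= std::exp(-dt / tau);
          }
          rest += std::norm(cc[k]);
        }
        cc[a] *= std::sqrt(std::max(0.0, 1 - rest) / pa);
      }
    }

    t += dt;
    if (istep % recevery == 0) record(t);

    // termination: gap to the closed-shell ground-state surface (the
    // adiabat with maximal closed-shell weight; the signed gap is
    // negative after a diabatic passage through the ground-state seam)
    int s0 = (int)ad.W.row(0).index_max();
    double gap = ad.E[a] - ad.E[s0];
    if (termgap > 0 && a != s0 && gap < termgap) {
      reason = ad.tripw[a] > 0.5 ? 2 : 1;
      break;
    }
    if (t >= tmax) { reason = 3; break; }
  }
  if (failed) reason = 4;
  else if (reason == 0) reason = 3;

  arma::ivec man_final(n);
  for (int k = 0; k < n; ++k) man_final[k] = ad.tripw[k] > 0.5 ? 1 : 0;

  return List::create(
    _["times"] = times.head(ri),
    _["positions"] = positions.head_rows(ri),
    _["momenta"] = momenta.head_rows(ri),
    _["active"] = active_rec.head(ri),
    _["energies"] = energies.head_rows(ri),
    _["populations"] = populations.head_rows(ri),
    _["manifold"] = manifold_rec.head(ri),
    _["rank"] = rank_rec.head(ri),
    _["total_energy"] = etot.head(ri),
    _["hop_time"] = hop_time, _["hop_from"] = hop_from,
    _["hop_to"] = hop_to, _["hop_accepted"] = hop_acc,
    _["reason"] = reason,
    _["final_state"] = a + 1,
    _["final_manifold"] = man_final,
    _["time"] = t);
}
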