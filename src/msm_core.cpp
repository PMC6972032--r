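// Core numerics: interval-censored panel log-likelihood for a
// continuous-time Markov multi-state model with piecewise-constant
// intensities, its exact gradient by reverse-mode differentiation of the
// uniformization recursion, and exact continuous-time simulation.
//
// Likelihood intervals carry at most two constant-intensity segments
// (covariates change only at visits; the only within-interval change is
// the age-65 crossing).  Only one row of each transition probability
// matrix is ever needed, so P is applied to a state row vector by
// uniformization,
//     v P = sum_k Pois(k; L*dt) v M^k,   M = I + Q/L,  L >= max_i |Q_ii|,
// truncated when the remaining Poisson tail is below 1e-14.  Long or
// stiff segments are split so that L*dt <= 40 per piece, keeping the
// Poisson weights well inside double range.  The identity holds for any
// admissible L, so P is (to truncation error) independent of L and the
// gradient may treat L as constant.  All work buffers are preallocated
// and reused across intervals: this loop is the fitting bottleneck.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Model {
  int ns, nt, K, absorb;
  std::vector<int> from, to;
  std::vector<int> lq_idx, g_idx, b_idx;
  std::vector<double> lq_fix, g_fix, b_fix;
};

Model unpack_model(const List& layout) {
  Model m;
  m.ns = as<int>(layout["ns"]);
  m.nt = as<int>(layout["nt"]);
  m.K = as<int>(layout["K"]);
  m.absorb = as<int>(layout["absorb"]);
  m.from = as<std::vector<int>>(layout["from"]);
  m.to = as<std::vector<int>>(layout["to"]);
  m.lq_idx = as<std::vector<int>>(layout["lq_idx"]);
  m.lq_fix = as<std::vector<double>>(layout["lq_fix"]);
  m.g_idx = as<std::vector<int>>(layout["g_idx"]);
  m.g_fix = as<std::vector<double>>(layout["g_fix"]);
  m.b_idx = as<std::vector<int>>(layout["b_idx"]);
  m.b_fix = as<std::vector<double>>(layout["b_fix"]);
  return m;
}

// per-transition intensities and the generator for covariate row z, age flag a
void build_Q(const Model& m, const double* th, const double* z, double a,
             double* qt, double* Q) {
  std::fill(Q, Q + m.ns * m.ns, 0.0);
  for (int t = 0; t < m.nt; ++t) {
    double eta = m.lq_idx[t] >= 0 ? th[m.lq_idx[t]] : m.lq_fix[t];
    for (int k = 0; k < m.K; ++k) {
      int bi = m.b_idx[t + m.nt * k];
      double b = bi >= 0 ? th[bi] : m.b_fix[t + m.nt * k];
      if (b != 0.0 && z[k] != 0.0) eta += b * z[k];
    }
    if (a != 0.0) {
      double g = m.g_idx[t] >= 0 ? th[m.g_idx[t]] : m.g_fix[t];
      eta += g * a;
    }
    double q = std::exp(eta);
    qt[t] = q;
    Q[m.from[t] * m.ns + m.to[t]] += q;
    Q[m.from[t] * m.ns + m.from[t]] -= q;
  }
}

const double TAIL_TOL = 1e-14;
const double SPLIT_A = 40.0;
const double MAX_A = 5000.0;   // beyond this the trial parameters are absurd

// Forward/backward record for one constant-Q segment (buffers reused).
struct SegWork {
  int ns = 0, nsplit = 0;
  double lam = 0.0;
  std::vector<double> M;       // ns*ns
  std::vector<int> kmax;       // per split
  std::vector<int> woff, soff; // offsets into wts / S, nsplit+1 entries
  std::vector<double> wts;     // Poisson weights, concatenated
  std::vector<double> S;       // stored rows s_0..s_{kmax-1}, concatenated
};

struct Scratch {
  std::vector<double> w, wn, acc, r, rn, v, g;
  std::vector<double> qt1, qt2, qtd, Q1, Q2, Qd, dQ, dM, zbuf;
  SegWork seg1, seg2;
  void init(int ns, int nt, int K) {
    w.resize(ns); wn.resize(ns); acc.resize(ns); r.resize(ns); rn.resize(ns);
    v.resize(ns); g.resize(ns);
    qt1.resize(nt); qt2.resize(nt); qtd.resize(nt);
    Q1.resize(ns * ns); Q2.resize(ns * ns); Qd.resize(ns * ns);
    dQ.resize(ns * ns); dM.resize(ns * ns);
    zbuf.resize(K > 0 ? K : 1);
  }
};

// Propagate row vector v across one segment; fills `work` for the
// backward pass when keep = true.
bool seg_forward(const double* Q, double dt, int ns, std::vector<double>& v,
                 SegWork& work, Scratch& sc, bool keep) {
  double lam = 0.0;
  for (int i = 0; i < ns; ++i) lam = std::max(lam, -Q[i * ns + i]);
  work.ns = ns;
  work.lam = lam;
  if (!(lam * dt <= MAX_A)) return false;  // overflow guard (also catches NaN)
  if (lam * dt < 1e-300) { work.nsplit = 0; return true; }  // P = I
  int nsplit = (int)std::ceil(lam * dt / SPLIT_A);
  if (nsplit < 1) nsplit = 1;
  double a = lam * (dt / nsplit);
  work.nsplit = nsplit;
  work.M.resize(ns * ns);
  for (int i = 0; i < ns; ++i) {
    for (int j = 0; j < ns; ++j) work.M[i * ns + j] = Q[i * ns + j] / lam;
    work.M[i * ns + i] += 1.0;
  }
  work.kmax.resize(nsplit);
  work.woff.resize(nsplit + 1); work.woff[0] = 0;
  work.soff.resize(nsplit + 1); work.soff[0] = 0;
  work.wts.clear();
  if (keep) work.S.clear();
  int hard = (int)(a + 12.0 * std::sqrt(a + 1.0) + 25.0);
  std::vector<double>& w = sc.w;
  std::vector<double>& wn = sc.wn;
  std::vector<double>& acc = sc.acc;
  for (int sp = 0; sp < nsplit; ++sp) {
    size_t w0 = work.wts.size();
    double c = std::exp(-a), cum = c;
    work.wts.push_back(c);
    int k = 0;
    while (cum < 1.0 - TAIL_TOL && k < hard) {
      ++k;
      c *= a / k;
      cum += c;
      work.wts.push_back(c);
    }
    int kmax = k;
    work.kmax[sp] = kmax;
    work.woff[sp + 1] = (int)work.wts.size();
    const double* cs = &work.wts[w0];
    for (int i = 0; i < ns; ++i) { w[i] = v[i]; acc[i] = cs[0] * v[i]; }
    if (keep && kmax > 0) work.S.insert(work.S.end(), w.begin(), w.end());
    for (int kk = 1; kk <= kmax; ++kk) {
      for (int j = 0; j < ns; ++j) {
        double s = 0.0;
        for (int i = 0; i < ns; ++i) s += w[i] * work.M[i * ns + j];
        wn[j] = s;
      }
      w.swap(wn);
      if (keep && kk < kmax) work.S.insert(work.S.end(), w.begin(), w.end());
      for (int i = 0; i < ns; ++i) acc[i] += cs[kk] * w[i];
    }
    v = acc;
    work.soff[sp + 1] = (int)(keep ? work.S.size() : 0);
  }
  return true;
}

// Backward pass: g = dL/dv_out on entry, dL/dv_in on exit; accumulates
// dL/dQ (lam treated as constant; see header comment).
void seg_backward(const SegWork& work, std::vector<double>& g,
                  std::vector<double>& dQ, Scratch& sc) {
  int ns = work.ns;
  if (work.nsplit == 0) return;  // identity segment
  std::vector<double>& dM = sc.dM;
  std::fill(dM.begin(), dM.end(), 0.0);
  std::vector<double>& r = sc.r;
  std::vector<double>& rn = sc.rn;
  for (int sp = work.nsplit - 1; sp >= 0; --sp) {
    int kmax = work.kmax[sp];
    const double* cs = &work.wts[work.woff[sp]];
    const double* S = kmax > 0 ? &work.S[work.soff[sp]] : nullptr;
    for (int i = 0; i < ns; ++i) r[i] = cs[kmax] * g[i];
    for (int k = kmax - 1; k >= 0; --k) {
      const double* sk = &S[k * ns];
      for (int i = 0; i < ns; ++i) {
        double si = sk[i];
        if (si != 0.0) {
          for (int j = 0; j < ns; ++j) dM[i * ns + j] += si * r[j];
        }
      }
      for (int i = 0; i < ns; ++i) {
        double s = cs[k] * g[i];
        const double* Mi = &work.M[i * ns];
        for (int j = 0; j < ns; ++j) s += Mi[j] * r[j];
        rn[i] = s;
      }
      r.swap(rn);
    }
    g = r;  // dL/dv at the start of this split
  }
  for (int i = 0; i < ns * ns; ++i) dQ[i] += dM[i] / work.lam;
}

// chain dL/dQ (for covariates z, age flag a) into the theta gradient
void chain_dQ(const Model& m, const double* qt, const double* dQ,
              const double* z, double a, double* grad) {
  for (int t = 0; t < m.nt; ++t) {
    double dldq = dQ[m.from[t] * m.ns + m.to[t]] -
                  dQ[m.from[t] * m.ns + m.from[t]];
    if (dldq == 0.0) continue;
    double base = qt[t] * dldq;
    if (m.lq_idx[t] >= 0) grad[m.lq_idx[t]] += base;
    for (int k = 0; k < m.K; ++k) {
      int bi = m.b_idx[t + m.nt * k];
      if (bi >= 0 && z[k] != 0.0) grad[bi] += base * z[k];
    }
    if (m.g_idx[t] >= 0 && a != 0.0) grad[m.g_idx[t]] += base * a;
  }
}

}  // namespace

// Panel log-likelihood (and optionally its exact gradient).
// iv columns: s0, s1 (1-based), dt1, a1, dt2, a2, z_1..z_K
// de columns: s0, dt1, a1, dt2, a2, adeath, z_1..z_K
// sv columns: s0, dt1, a1, dt2, a2, z_1..z_K   (known alive at segment end)
// [[Rcpp::export]]
List cpp_panel_loglik(NumericVector theta, List layout, NumericMatrix iv,
                      NumericMatrix de, NumericMatrix sv, bool want_grad) {
  Model m = unpack_model(layout);
  int ns = m.ns;
  const double* th = theta.begin();
  Scratch sc;
  sc.init(ns, m.nt, m.K);
  std::vector<double> grad(theta.size(), 0.0);
  double ll = 0.0;
  bool overflow = false;
  std::vector<int> bad_iv, bad_de;
  std::vector<double>& v = sc.v;
  std::vector<double>& g = sc.g;

  for (int r = 0; r < iv.nrow(); ++r) {
    int s0 = (int)iv(r, 0) - 1, s1 = (int)iv(r, 1) - 1;
    double dt1 = iv(r, 2), a1 = iv(r, 3), dt2 = iv(r, 4), a2 = iv(r, 5);
    for (int k = 0; k < m.K; ++k) sc.zbuf[k] = iv(r, 6 + k);
    const double* z = sc.zbuf.data();
    std::fill(v.begin(), v.end(), 0.0);
    v[s0] = 1.0;
    build_Q(m, th, z, a1, sc.qt1.data(), sc.Q1.data());
    bool ok = seg_forward(sc.Q1.data(), dt1, ns, v, sc.seg1, sc, want_grad);
    bool two = dt2 > 0.0;
    if (ok && two) {
      build_Q(m, th, z, a2, sc.qt2.data(), sc.Q2.data());
      ok = seg_forward(sc.Q2.data(), dt2, ns, v, sc.seg2, sc, want_grad);
    }
    if (!ok) { overflow = true; ll = R_NegInf; continue; }
    double p = v[s1];
    if (!(p > 0.0) || !std::isfinite(p)) {
      bad_iv.push_back(r + 1);
      ll = R_NegInf;
      continue;
    }
    ll += std::log(p);
    if (want_grad) {
      std::fill(g.begin(), g.end(), 0.0);
      g[s1] = 1.0 / p;
      if (two) {
        std::fill(sc.dQ.begin(), sc.dQ.end(), 0.0);
        seg_backward(sc.seg2, g, sc.dQ, sc);
        chain_dQ(m, sc.qt2.data(), sc.dQ.data(), z, a2, grad.data());
      }
      std::fill(sc.dQ.begin(), sc.dQ.end(), 0.0);
      seg_backward(sc.seg1, g, sc.dQ, sc);
      chain_dQ(m, sc.qt1.data(), sc.dQ.data(), z, a1, grad.data());
    }
  }

  for (int r = 0; r < de.nrow(); ++r) {
    int s0 = (int)de(r, 0) - 1;
    double dt1 = de(r, 1), a1 = de(r, 2), dt2 = de(r, 3), a2 = de(r, 4);
    double ad = de(r, 5);
    for (int k = 0; k < m.K; ++k) sc.zbuf[k] = de(r, 6 + k);
    const double* z = sc.zbuf.data();
    std::fill(v.begin(), v.end(), 0.0);
    v[s0] = 1.0;
    build_Q(m, th, z, a1, sc.qt1.data(), sc.Q1.data());
    bool ok = seg_forward(sc.Q1.data(), dt1, ns, v, sc.seg1, sc, want_grad);
    bool two = dt2 > 0.0;
    if (ok && two) {
      build_Q(m, th, z, a2, sc.qt2.data(), sc.Q2.data());
      ok = seg_forward(sc.Q2.data(), dt2, ns, v, sc.seg2, sc, want_grad);
    }
    if (!ok) { overflow = true; ll = R_NegInf; continue; }
    // death intensities at the death instant
    build_Q(m, th, z, ad, sc.qtd.data(), sc.Qd.data());
    double dens = 0.0;
    for (int t = 0; t < m.nt; ++t) {
      if (m.to[t] == m.absorb) dens += v[m.from[t]] * sc.qtd[t];
    }
    if (!(dens > 0.0) || !std::isfinite(dens)) {
      bad_de.push_back(r + 1);
      ll = R_NegInf;
      continue;
    }
    ll += std::log(dens);
    if (want_grad) {
      std::fill(g.begin(), g.end(), 0.0);
      // the density involves q_{k,E} directly (not via the Q row balance),
      // so only the death-transition parameters get the direct term
      for (int t = 0; t < m.nt; ++t) {
        if (m.to[t] != m.absorb) continue;
        g[m.from[t]] += sc.qtd[t] / dens;
        double base = sc.qtd[t] * (v[m.from[t]] / dens);
        if (m.lq_idx[t] >= 0) grad[m.lq_idx[t]] += base;
        for (int k = 0; k < m.K; ++k) {
          int bi = m.b_idx[t + m.nt * k];
          if (bi >= 0 && z[k] != 0.0) grad[bi] += base * z[k];
        }
        if (m.g_idx[t] >= 0 && ad != 0.0) grad[m.g_idx[t]] += base * ad;
      }
      if (two) {
        std::fill(sc.dQ.begin(), sc.dQ.end(), 0.0);
        seg_backward(sc.seg2, g, sc.dQ, sc);
        chain_dQ(m, sc.qt2.data(), sc.dQ.data(), z, a2, grad.data());
      }
      std::fill(sc.dQ.begin(), sc.dQ.end(), 0.0);
      seg_backward(sc.seg1, g, sc.dQ, sc);
      chain_dQ(m, sc.qt1.data(), sc.dQ.data(), z, a1, grad.data());
    }
  }

  // known-alive-at-cutoff rows: probability of remaining in any living
  // state from the last visit to the vital-status ascertainment time
  for (int r = 0; r < sv.nrow(); ++r) {
    int s0 = (int)sv(r, 0) - 1;
    double dt1 = sv(r, 1), a1 = sv(r, 2), dt2 = sv(r, 3), a2 = sv(r, 4);
    for (int k = 0; k < m.K; ++k) sc.zbuf[k] = sv(r, 5 + k);
    const double* z = sc.zbuf.data();
    std::fill(v.begin(), v.end(), 0.0);
    v[s0] = 1.0;
    build_Q(m, th, z, a1, sc.qt1.data(), sc.Q1.data());
    bool ok = seg_forward(sc.Q1.data(), dt1, ns, v, sc.seg1, sc, want_grad);
    bool two = dt2 > 0.0;
    if (ok && two) {
      build_Q(m, th, z, a2, sc.qt2.data(), sc.Q2.data());
      ok = seg_forward(sc.Q2.data(), dt2, ns, v, sc.seg2, sc, want_grad);
    }
    if (!ok) { overflow = true; ll = R_NegInf; continue; }
    double p = 0.0;
    for (int i = 0; i < ns; ++i) if (i != m.absorb) p += v[i];
    if (!(p > 0.0) || !std::isfinite(p)) { ll = R_NegInf; continue; }
    ll += std::log(p);
    if (want_grad) {
      std::fill(g.begin(), g.end(), 0.0);
      for (int i = 0; i < ns; ++i) if (i != m.absorb) g[i] = 1.0 / p;
      if (two) {
        std::fill(sc.dQ.begin(), sc.dQ.end(), 0.0);
        seg_backward(sc.seg2, g, sc.dQ, sc);
        chain_dQ(m, sc.qt2.data(), sc.dQ.data(), z, a2, grad.data());
      }
      std::fill(sc.dQ.begin(), sc.dQ.end(), 0.0);
      seg_backward(sc.seg1, g, sc.dQ, sc);
      chain_dQ(m, sc.qt1.data(), sc.dQ.data(), z, a1, grad.data());
    }
  }

  return List::create(_["loglik"] = ll,
                      _["grad"] = NumericVector(grad.begin(), grad.end()),
                      _["bad_iv"] = IntegerVector(bad_iv.begin(), bad_iv.end()),
                      _["bad_de"] = IntegerVector(bad_de.begin(), bad_de.end()),
                      _["overflow"] = overflow);
}

// Exact event-time simulation of one subject over consecutive
// constant-intensity segments (competing exponential sojourns).  Segments
// are laid out contiguously per subject (offsets seg_off, 0-based,
// length n+1); seg_Q rows hold the ns*ns generator row-major; seg_visit
// marks segment ends that are study visits.  States are recorded at
// marked boundaries; absorption records the exact event time and stops
// the subject.  Uses the R RNG.
// [[Rcpp::export]]
List cpp_sim_cohort(IntegerVector seg_off, NumericVector seg_dur,
                    NumericMatrix seg_Q, IntegerVector seg_visit,
                    IntegerVector s0, int ns, int absorb) {
  int n = s0.size();
  int max_visits = 0;
  for (int i = 0; i < n; ++i) {
    int nv = 0;
    for (int s = seg_off[i]; s < seg_off[i + 1]; ++s) nv += seg_visit[s];
    if (nv > max_visits) max_visits = nv;
  }
  IntegerMatrix states(n, max_visits);
  std::fill(states.begin(), states.end(), NA_INTEGER);
  NumericVector death(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    int cur = s0[i];
    double t = 0.0;
    bool dead = false;
    int vis = 0;
    for (int s = seg_off[i]; s < seg_off[i + 1]; ++s) {
      double dur = seg_dur[s];
      if (!dead) {
        double rem = dur;
        while (rem > 0.0) {
          double rate = -seg_Q(s, cur * ns + cur);
          if (rate <= 0.0) break;
          double soj = ::exp_rand() / rate;
          if (soj >= rem) break;
          rem -= soj;
          // destination ~ categorical over Q[cur, j]/rate
          double u = ::unif_rand() * rate, c = 0.0;
          int dest = cur;
          for (int j = 0; j < ns; ++j) {
            if (j == cur) continue;
            c += seg_Q(s, cur * ns + j);
            if (u <= c) { dest = j; break; }
          }
          cur = dest;
          if (cur == absorb) {
            dead = true;
            death[i] = t + (dur - rem);
            break;
          }
        }
      }
      t += dur;
      if (seg_visit[s]) {
        if (!dead) states(i, vis) = cur;
        ++vis;
      }
    }
  }
  return List::create(_["states"] = states, _["death_time"] = death);
}

// Monte-Carlo oracle: replicate one chain nrep times over the given
// segments; returns the state at the end of the last segment (the
// absorbing state if absorbed) and the exact absorption time (NA if not
// absorbed).
// [[Rcpp::export]]
List cpp_sim_chain_mc(NumericVector seg_dur, NumericMatrix seg_Q, int s0,
                      int nrep, int ns, int absorb) {
  IntegerVector fin(nrep);
  NumericVector death(nrep, NA_REAL);
  int nseg = seg_dur.size();
  for (int r = 0; r < nrep; ++r) {
    int cur = s0;
    double t = 0.0;
    bool dead = false;
    for (int s = 0; s < nseg && !dead; ++s) {
      double rem = seg_dur[s];
      while (rem > 0.0) {
        double rate = -seg_Q(s, cur * ns + cur);
        if (rate <= 0.0) break;
        double soj = ::exp_rand() / rate;
        if (soj >= rem) break;
        rem -= soj;
        double u = ::unif_rand() * rate, c = 0.0;
        for (int j = 0; j < ns; ++j) {
          if (j == cur) continue;
          c += seg_Q(s, cur * ns + j);
          if (u <= c) { cur = j; break; }
        }
        if (cur == absorb) {
          dead = true;
          death[r] = t + (seg_dur[s] - rem);
          break;
        }
      }
      t += seg_dur[s];
    }
    fin[r] = cur;
  }
  return List::create(_["final_state"] = fin, _["death_time"] = death);
}
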