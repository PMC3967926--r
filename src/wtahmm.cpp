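// Event-driven core of the stochastic WTA circuit and the discrete-time
// (fixed-ISI, rectangular-EPSP) samplers/trainers.  All randomness goes
// through R's RNG so set.seed() in R governs every draw.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline double lse2(const std::vector<double>& u, int from, int len) {
  double m = R_NegInf;
  for (int i = 0; i < len; ++i) if (u[from + i] > m) m = u[from + i];
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < len; ++i) s += std::exp(u[from + i] - m);
  return m + std::log(s);
}

// sample index in [0, len) from softmax of u[from..from+len)
inline int softmax_draw(const std::vector<double>& u, int from, int len,
                        double lse) {
  if (!R_finite(lse)) return (int)std::floor(unif_rand() * len);
  double r = unif_rand(), acc = 0.0;
  for (int i = 0; i < len; ++i) {
    acc += std::exp(u[from + i] - lse);
    if (r < acc) return i;
  }
  return len - 1;
}

// Trace-scaled potentiation / constant depression: dw = eta (x e^-w - 1).
// The potentiation term is steep for strongly depressed synapses (fast
// re-specialization); a per-update cap prevents the discrete jump from
// overshooting the instantaneous fixed point w = log x by orders of
// magnitude when w sits near the floor.
const double STDP_CAP = 3.0;
inline double stdp_one(double w, double x, double eta, double /*unused*/,
                       double floor_) {
  double d = (x > 0.0) ? eta * (x * std::exp(-w) - 1.0) : -eta;
  if (d > STDP_CAP) d = STDP_CAP;
  double nw = w + d;
  return (nw < floor_) ? floor_ : nw;
}

} // namespace

// Continuous-time event-driven simulation of (possibly several) WTA groups.
// Traces are kept as difference-of-exponentials components (xp, xq): the
// trace value is amp * (xp - xq); for single-exponential kernels xq stays 0.
// [[Rcpp::export]]
List sim_run_cpp(NumericMatrix W_, NumericMatrix V_, NumericVector b_,
                 IntegerVector group, double R,
                 List kern, List state, NumericVector in_t,
                 IntegerVector in_ch, double t_end, List learn) {
  const int K = W_.nrow(), N = W_.ncol();
  const int G = Rcpp::max(group);
  const double isi_mean = 1000.0 / R; // ms

  // kernels
  const double ff_tau_d = as<double>(kern["ff_tau_d"]);
  const double ff_tau_r = as<double>(kern["ff_tau_r"]); // <= 0: single exp
  const double ff_amp   = as<double>(kern["ff_amp"]);
  const double lat_tau_d = as<double>(kern["lat_tau_d"]);
  const double lat_tau_r = as<double>(kern["lat_tau_r"]);
  const double lat_amp   = as<double>(kern["lat_amp"]);
  const double lat_delay = as<double>(kern["lat_delay"]);
  const double refr_amp  = as<double>(kern["refr_amp"]);
  const double refr_tau  = as<double>(kern["refr_tau"]);

  // learning config
  const int mode = as<int>(learn["mode"]); // 0 none, 1 online, 2 accumulate
  const double eta = as<double>(learn["eta"]);
  const double wfloor = as<double>(learn["floor"]);
  const bool excl_self = as<bool>(learn["exclude_self"]);
  const bool homeo = as<bool>(learn["homeostasis"]);
  const double eta_b = homeo ? as<double>(learn["eta_b"]) : 0.0;
  const double r_star = homeo ? as<double>(learn["target_rate"]) : 0.0;
  const double tau_w = homeo ? as<double>(learn["rate_window"]) : 1.0;
  const double log1m = std::log(1.0 - eta);

  // row-major working copies (contiguous over presynaptic index for both
  // the membrane inner products and the per-row learning updates)
  std::vector<double> W(K * N), V(K * K);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < N; ++i) W[k * N + i] = W_(k, i);
    for (int l = 0; l < K; ++l) V[k * K + l] = V_(k, l);
  }
  NumericVector b = clone(b_);
  std::vector<double> Wt = W, Vt = V; // mode-2 shadow tags

  // state
  double t = as<double>(state["time"]);
  std::vector<double> xp = as<std::vector<double> >(state["xp"]);
  std::vector<double> xq = as<std::vector<double> >(state["xq"]);
  std::vector<double> yp = as<std::vector<double> >(state["yp"]);
  std::vector<double> yq = as<std::vector<double> >(state["yq"]);
  std::vector<double> last_sp = as<std::vector<double> >(state["last_spike"]);
  std::vector<double> next_t = as<std::vector<double> >(state["next_t"]);
  std::vector<double> pend_t = as<std::vector<double> >(state["pend_t"]);
  std::vector<int> pend_n = as<std::vector<int> >(state["pend_n"]);
  std::vector<double> rhat = as<std::vector<double> >(state["rhat"]);
  std::vector<int> last_win = as<std::vector<int> >(state["last_winner"]);

  // group layout: member lists
  std::vector<std::vector<int> > members(G);
  for (int k = 0; k < K; ++k) members[group[k] - 1].push_back(k);

  for (int g = 0; g < G; ++g)
    if (!R_finite(next_t[g])) next_t[g] = t + exp_rand() * isi_mean;

  size_t in_i = 0, pend_head = 0;
  const int n_in = in_t.size();

  std::vector<double> sp_t, sp_surp;
  std::vector<int> sp_n, sp_g;

  std::vector<double> xval(N), yval(K), u(K), uff(K);

  // advance all traces from t to `to`, integrating afferent events and
  // matured delayed lateral spikes at their exact times (closed form)
  auto advance = [&](double to) {
    double dt = to - t;
    if (dt > 0) {
      double dfd = std::exp(-dt / ff_tau_d);
      double dfr = (ff_tau_r > 0) ? std::exp(-dt / ff_tau_r) : 0.0;
      for (int i = 0; i < N; ++i) { xp[i] *= dfd; if (ff_tau_r > 0) xq[i] *= dfr; }
      double dld = std::exp(-dt / lat_tau_d);
      double dlr = (lat_tau_r > 0) ? std::exp(-dt / lat_tau_r) : 0.0;
      for (int k = 0; k < K; ++k) { yp[k] *= dld; if (lat_tau_r > 0) yq[k] *= dlr; }
    }
    while (in_i < (size_t)n_in && in_t[in_i] <= to) {
      double a = to - in_t[in_i];
      int ch = in_ch[in_i] - 1;
      xp[ch] += std::exp(-a / ff_tau_d);
      if (ff_tau_r > 0) xq[ch] += std::exp(-a / ff_tau_r);
      ++in_i;
    }
    while (pend_head < pend_t.size() && pend_t[pend_head] <= to) {
      double a = to - pend_t[pend_head];
      int k = pend_n[pend_head] - 1;
      yp[k] += std::exp(-a / lat_tau_d);
      if (lat_tau_r > 0) yq[k] += std::exp(-a / lat_tau_r);
      ++pend_head;
    }
    t = to;
  };

  while (true) {
    int gmin = 0;
    for (int g = 1; g < G; ++g) if (next_t[g] < next_t[gmin]) gmin = g;
    double tn = next_t[gmin];
    if (tn > t_end) { advance(t_end); break; }
    double dt_ev = tn - t;
    advance(tn);

    for (int i = 0; i < N; ++i) xval[i] = ff_amp * (xp[i] - xq[i]);
    for (int k = 0; k < K; ++k) yval[k] = lat_amp * (yp[k] - yq[k]);

    // homeostatic intrinsic plasticity (stochastic approximation with an
    // exponentially averaged rate estimate)
    if (homeo && dt_ev > 0) {
      double drw = std::exp(-dt_ev / tau_w);
      for (int k = 0; k < K; ++k) {
        rhat[k] *= drw;
        b[k] += eta_b * (r_star - rhat[k]) * (dt_ev / 1000.0);
      }
    }

    const std::vector<int>& mem = members[gmin];
    const int m = (int)mem.size();
    std::vector<double> ulat(m), ub(m);
    for (int j = 0; j < m; ++j) {
      int k = mem[j];
      const double* wr = &W[k * N];
      const double* vr = &V[(size_t)k * K];
      double uf = b[k];
      for (int i = 0; i < N; ++i) uf += wr[i] * xval[i];
      double ul = 0.0;
      for (int l = 0; l < K; ++l) ul += vr[l] * yval[l];
      double refr = 0.0;
      if (R_finite(last_sp[k]) && refr_amp > 0)
        refr = refr_amp * std::exp(-(t - last_sp[k]) / refr_tau);
      uff[j] = uf;
      ulat[j] = ul + b[k] - refr;
      ub[j] = b[k];
      u[j] = uf + ul - refr;
    }
    double lu = lse2(u, 0, m), lf = lse2(uff, 0, m);
    int widx = softmax_draw(u, 0, m, lu);
    int k = mem[widx];

    sp_t.push_back(t); sp_n.push_back(k + 1); sp_g.push_back(gmin + 1);
    // baseline-corrected input log-likelihood: both the feedforward-only
    // and the prediction-only marginals are subtracted, so fluctuations
    // injected by either synapse class alone cancel
    sp_surp.push_back(lu - lf - lse2(ulat, 0, m) + lse2(ub, 0, m));

    if (mode > 0) {
      double* Wu = (mode == 2) ? &Wt[k * N] : &W[k * N];
      double* Vu = (mode == 2) ? &Vt[(size_t)k * K] : &V[(size_t)k * K];
      for (int i = 0; i < N; ++i)
        Wu[i] = stdp_one(Wu[i], xval[i], eta, log1m, wfloor);
      for (int l = 0; l < K; ++l) {
        if (excl_self && l == k) continue;
        Vu[l] = stdp_one(Vu[l], yval[l], eta, log1m, wfloor);
      }
    }

    last_sp[k] = t;
    last_win[gmin] = k + 1;
    if (homeo) rhat[k] += 1000.0 / tau_w;
    pend_t.push_back(t + lat_delay); pend_n.push_back(k + 1);
    next_t[gmin] = t + exp_rand() * isi_mean;
  }

  // compact pending queue
  std::vector<double> pt2(pend_t.begin() + pend_head, pend_t.end());
  std::vector<int> pn2(pend_n.begin() + pend_head, pend_n.end());

  List st_out = List::create(
    _["time"] = t, _["xp"] = xp, _["xq"] = xq, _["yp"] = yp, _["yq"] = yq,
    _["last_spike"] = last_sp, _["next_t"] = next_t,
    _["pend_t"] = pt2, _["pend_n"] = pn2, _["rhat"] = rhat,
    _["last_winner"] = last_win);

  NumericMatrix W_out(K, N), V_out(K, K), Wt_out(K, N), Vt_out(K, K);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < N; ++i) {
      W_out(k, i) = W[k * N + i];
      Wt_out(k, i) = Wt[k * N + i];
    }
    for (int l = 0; l < K; ++l) {
      V_out(k, l) = V[(size_t)k * K + l];
      Vt_out(k, l) = Vt[(size_t)k * K + l];
    }
  }
  return List::create(
    _["spike_t"] = sp_t, _["spike_n"] = sp_n, _["spike_g"] = sp_g,
    _["surprise"] = sp_surp, _["W"] = W_out, _["V"] = V_out, _["b"] = b,
    _["W_tag"] = Wt_out, _["V_tag"] = Vt_out, _["state"] = st_out);
}

namespace {

// one forward-sampled path through a discrete-mode network; returns the
// accumulated log importance weight; optionally applies/accumulates STDP on
// (Wu, Vu) while the dynamics run on (W, V)
double path_discrete(const NumericMatrix& W, const NumericMatrix& V,
                     const NumericVector& b, const IntegerVector& x,
                     bool baseline, double eta, double log1m, double wfloor,
                     bool learn, bool excl_self, bool learn_b,
                     NumericMatrix* Wu, NumericMatrix* Vu,
                     NumericVector* bu, int* path_out) {
  const int K = W.nrow(), L = W.ncol(), T = x.size();
  std::vector<double> u(K), uf(K);
  // row/column log-normalizers of the equivalent HMM tables, so the
  // importance weight is exactly log p_model(x, y) - log q(y | x) even
  // before the emergent weight normalization has converged:
  // ls_k = lse_l W(k,l), lr_j = lse_k (V(k,j) + b_k), lz0 = lse_k (b_k + ls_k)
  std::vector<double> ls(K), lr(K), tmp(K);
  for (int k = 0; k < K; ++k) {
    double m = R_NegInf;
    for (int l = 0; l < L; ++l) if (W(k, l) > m) m = W(k, l);
    double s = 0.0;
    for (int l = 0; l < L; ++l) s += std::exp(W(k, l) - m);
    ls[k] = m + std::log(s);
  }
  for (int j2 = 0; j2 < K; ++j2) {
    for (int k = 0; k < K; ++k) tmp[k] = V(k, j2) + b[k];
    lr[j2] = lse2(tmp, 0, K);
  }
  for (int k = 0; k < K; ++k) tmp[k] = b[k] + ls[k];
  const double lz0 = lse2(tmp, 0, K);

  int j = 0; // previous winner, 1-based; 0 = sequence start (zero trace)
  double logw = 0.0;
  for (int n = 0; n < T; ++n) {
    int l = x[n] - 1;
    for (int k = 0; k < K; ++k) {
      uf[k] = W(k, l) + b[k];
      u[k] = uf[k] + (j > 0 ? V(k, j - 1) : 0.0);
    }
    double lu = lse2(u, 0, K);
    logw += R_finite(lu) ? lu : -745.0;
    logw -= (j > 0) ? lr[j - 1] : lz0;
    if (baseline) logw -= lse2(uf, 0, K);
    int k = softmax_draw(u, 0, K, lu);
    if (j > 0) logw -= ls[k];
    if (learn) {
      for (int ll = 0; ll < L; ++ll)
        (*Wu)(k, ll) = stdp_one((*Wu)(k, ll), ll == l ? 1.0 : 0.0,
                                eta, log1m, wfloor);
      for (int kk = 0; kk < K; ++kk) {
        if (excl_self && kk == k) continue;
        (*Vu)(k, kk) = stdp_one((*Vu)(k, kk),
                                (j > 0 && kk == j - 1) ? 1.0 : 0.0,
                                eta, log1m, wfloor);
      }
      // excitability (prior) learning: exp(b_k) tracks the win frequency
      if (learn_b)
        for (int kk = 0; kk < K; ++kk)
          (*bu)[kk] = stdp_one((*bu)[kk], kk == k ? 1.0 : 0.0,
                               eta, log1m, wfloor);
    }
    if (path_out) path_out[n] = k + 1;
    j = k + 1;
  }
  return logw;
}

} // namespace

// Forward-sample S paths (no learning) with their log importance weights.
// [[Rcpp::export]]
List sample_paths_cpp(NumericMatrix W, NumericMatrix V, NumericVector b,
                      IntegerVector x, int S, bool baseline) {
  const int T = x.size();
  IntegerMatrix paths(S, T);
  NumericVector logw(S);
  std::vector<int> buf(T);
  for (int s = 0; s < S; ++s) {
    logw[s] = path_discrete(W, V, b, x, baseline, 0.0, 0.0, -10.0,
                            false, false, false, nullptr, nullptr, nullptr,
                            buf.data());
    for (int n = 0; n < T; ++n) paths(s, n) = buf[n];
  }
  return List::create(_["paths"] = paths, _["logw"] = logw);
}

// Train a discrete-mode network on symbol sequences.
// mode: 0 forward (online STDP), 1 rejection with linear c tracking,
//       2 rejection with the batch normalizing constant, 3 importance
// [[Rcpp::export]]
List train_discrete_cpp(NumericMatrix W_, NumericMatrix V_, NumericVector b_,
                        List seqs, int mode, double eta, int S,
                        double step_down, double step_up, double log_c0,
                        int epochs, bool shuffle, double wfloor,
                        bool excl_self, bool learn_b, int max_replays,
                        bool baseline) {
  NumericMatrix W = clone(W_), V = clone(V_);
  NumericVector b = clone(b_);
  const double log1m = std::log(1.0 - eta);
  const int nseq = seqs.size();
  double log_c = log_c0;

  std::vector<int> replay_log, iter_log;
  std::vector<double> logw_log, c_log;
  std::vector<int> order(nseq);
  for (int i = 0; i < nseq; ++i) order[i] = i;

  int iter = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle)
      for (int i = nseq - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        std::swap(order[i], order[j]);
      }
    for (int si = 0; si < nseq; ++si) {
      IntegerVector x = seqs[order[si]];
      ++iter;
      if (mode == 0) {
        double lw = path_discrete(W, V, b, x, baseline, eta, log1m, wfloor,
                                  true, excl_self, learn_b, &W, &V, &b,
                                  nullptr);
        iter_log.push_back(iter); replay_log.push_back(1);
        logw_log.push_back(lw); c_log.push_back(NA_REAL);
      } else if (mode == 1) {
        int reps = 0; bool accepted = false; double lw = NA_REAL;
        NumericMatrix Wt, Vt; NumericVector bt;
        while (!accepted && reps < max_replays) {
          ++reps;
          Wt = clone(W); Vt = clone(V); bt = clone(b);
          lw = path_discrete(W, V, b, x, baseline, eta, log1m, wfloor,
                             true, excl_self, learn_b, &Wt, &Vt, &bt,
                             nullptr);
          double pa = std::exp(std::min(0.0, lw - log_c));
          accepted = unif_rand() < pa;
          // negative feedback keeps the acceptance rate at
          // step_down / (step_up + step_down) = 1/S
          log_c += accepted ? step_up : -step_down;
        }
        // a replay budget overrun consolidates the last proposal (flagged
        // by replays == max_replays in the log)
        W = Wt; V = Vt; b = bt;
        iter_log.push_back(iter); replay_log.push_back(reps);
        logw_log.push_back(lw); c_log.push_back(log_c);
      } else { // batch rejection / importance
        std::vector<double> lws(S);
        std::vector<NumericMatrix> Wts(S), Vts(S);
        std::vector<NumericVector> bts(S);
        for (int s = 0; s < S; ++s) {
          Wts[s] = clone(W); Vts[s] = clone(V); bts[s] = clone(b);
          lws[s] = path_discrete(W, V, b, x, baseline, eta, log1m, wfloor,
                                 true, excl_self, learn_b, &Wts[s],
                                 &Vts[s], &bts[s], nullptr);
        }
        double lZ = lse2(lws, 0, S);
        if (mode == 2) {
          int sel = softmax_draw(lws, 0, S, lZ);
          W = Wts[sel]; V = Vts[sel]; b = bts[sel];
          logw_log.push_back(lws[sel]);
        } else {
          // omega-weighted mixture of the per-path synaptic tags
          NumericMatrix Wn = clone(W), Vn = clone(V);
          NumericVector bn = clone(b);
          const int K = W.nrow(), L = W.ncol();
          for (int s = 0; s < S; ++s) {
            double om = std::exp(lws[s] - lZ);
            for (int k = 0; k < K; ++k) {
              bn[k] += om * (bts[s][k] - b[k]);
              for (int l = 0; l < L; ++l)
                Wn(k, l) += om * (Wts[s](k, l) - W(k, l));
              for (int kk = 0; kk < K; ++kk)
                Vn(k, kk) += om * (Vts[s](k, kk) - V(k, kk));
            }
          }
          W = Wn; V = Vn; b = bn;
          logw_log.push_back(lZ - std::log((double)S));
        }
        iter_log.push_back(iter); replay_log.push_back(S);
        c_log.push_back(lZ - std::log((double)S));
      }
    }
  }
  return List::create(
    _["W"] = W, _["V"] = V, _["b"] = b,
    _["iter"] = iter_log, _["replays"] = replay_log,
    _["logw"] = logw_log, _["log_c"] = c_log,
    _["log_c_final"] = log_c);
}
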