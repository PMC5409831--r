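// Direct-method stochastic simulation of a PRC2 target-gene chromatin domain.
//
// State: per-histone K27 methylation level (0-3), deposition origin
// (replication vs transcription-coupled exchange), age label (old/new, for
// SILAC-style bookkeeping), an open/closed promoter flag (bursty variant), and
// optionally the mRNA/protein copy numbers of a coupled trans-regulator.
//
// All 2N+1 chromatin propensities (plus promoter and regulator reactions where
// enabled) are recomputed after every system update.  DNA replication is a
// deterministic interrupt: if the projected next-reaction time crosses a
// replication boundary, time advances to the boundary, each nucleosome pair is
// replaced by an unmethylated pair with probability 1 - survival, and the
// algorithm restarts from the rebuilt propensities.  Only one daughter locus
// is followed.  Random numbers come from R's RNG stream, so set.seed() at the
// R level makes trajectories exactly reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

enum Variant { MAIN = 0, TWO_STATE = 1, PROC_ME = 2, PROC_DEM = 3, BURST = 4 };

enum Event {
  EV_INIT = 0, EV_ME = 1, EV_DEM = 2, EV_TX = 3, EV_REPL = 4,
  EV_OPEN = 5, EV_CLOSE = 6,
  EV_MRNA_BIRTH = 7, EV_MRNA_DEATH = 8, EV_PROT_BIRTH = 9, EV_PROT_DEATH = 10,
  EV_ALPHA_STEP = 11, EV_END = 12
};

enum Origin { ORIG_REPL = 0, ORIG_EX = 1 };

// Neighbor histones contributing allosteric PRC2 feedback: the partner histone
// on the same nucleosome plus the four histones of the two flanking
// nucleosomes.  1-based index convention of the model, truncated at the
// domain boundaries.
std::vector<std::vector<int> > neighbor_table(int N) {
  std::vector<std::vector<int> > nb(N);
  for (int i = 1; i <= N; ++i) {
    static const int even_off[5] = {-3, -2, -1, 1, 2};
    static const int odd_off[5]  = {-2, -1, 1, 2, 3};
    const int* off = (i % 2 == 0) ? even_off : odd_off;
    for (int k = 0; k < 5; ++k) {
      int j = i + off[k];
      if (j >= 1 && j <= N) nb[i - 1].push_back(j - 1);
    }
  }
  return nb;
}

struct Rec {
  std::vector<double> t, ev, n0, n1, n2, n3, tx, prom, alpha, nex, code;
  void push(double t_, int ev_, const int* cnt, long tx_, int prom_,
            double alpha_, int nex_, double code_) {
    t.push_back(t_); ev.push_back(ev_);
    n0.push_back(cnt[0]); n1.push_back(cnt[1]);
    n2.push_back(cnt[2]); n3.push_back(cnt[3]);
    tx.push_back((double)tx_); prom.push_back(prom_);
    alpha.push_back(alpha_); nex.push_back(nex_);
    code.push_back(code_);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(List cfg) {
  // --- unpack configuration -------------------------------------------------
  const int N = as<int>(cfg["N"]);
  const double T_cc = as<double>(cfg["T_cc"]);
  const bool repl_on = as<bool>(cfg["replicate_dna"]);
  const double surv = as<double>(cfg["replication_survival"]);
  const double beta = as<double>(cfg["beta"]);
  const double k01 = as<double>(cfg["k_me0_1"]), k12 = as<double>(cfg["k_me1_2"]),
               k23 = as<double>(cfg["k_me"]);
  const double g01 = as<double>(cfg["gamma_me0_1"]), g12 = as<double>(cfg["gamma_me1_2"]),
               g23 = as<double>(cfg["gamma_me2_3"]);
  const double rho = as<double>(cfg["rho_me2"]);
  const double f_min = as<double>(cfg["f_min"]), f_max = as<double>(cfg["f_max"]);
  const double P_T = as<double>(cfg["P_T"]);
  const double p_dem = as<double>(cfg["p_dem"]), p_ex = as<double>(cfg["p_ex"]);
  const double g_dem = as<double>(cfg["gamma_dem"]);
  const double f_cap = as<double>(cfg["f_cap"]);
  const int variant = as<int>(cfg["variant"]);
  const double k_on_max = as<double>(cfg["k_on_max"]), k_off = as<double>(cfg["k_off"]),
               k_on_min = as<double>(cfg["k_on_min"]), f_0 = as<double>(cfg["f_0"]),
               k_on_cap = as<double>(cfg["k_on_cap"]);
  const double t_end = as<double>(cfg["t_end"]);
  // trans input: 0 constant, 1 step at t_switch, 2 coupled regulator
  const int alpha_mode = as<int>(cfg["alpha_mode"]);
  const double alpha0 = as<double>(cfg["alpha0"]), alpha1 = as<double>(cfg["alpha1"]);
  const double t_switch = as<double>(cfg["t_switch"]);
  const double sR = as<double>(cfg["s_R"]), dR = as<double>(cfg["d_R"]),
               sP = as<double>(cfg["s_P"]), dP = as<double>(cfg["d_P"]);
  const double meanP = as<double>(cfg["mean_protein"]);
  int m_cnt = as<int>(cfg["m0"]), p_cnt = as<int>(cfg["p0"]);
  const bool record_events = as<bool>(cfg["record_events"]);
  const NumericVector sample_times = as<NumericVector>(cfg["sample_times"]);
  // first-passage stop rule on the repressive-mark count (me3 alone for the
  // two-state variant): dir +1 stops when count > thr, -1 when count < thr
  const int stop_dir = as<int>(cfg["stop_dir"]);
  const double stop_thr = as<double>(cfg["stop_threshold"]);
  const double label_time = as<double>(cfg["label_time"]);  // < 0: no labeling
  IntegerVector S_init = as<IntegerVector>(cfg["initial_levels"]);

  if (N % 2 != 0) stop("N must be even (nucleosomes are histone pairs)");
  if (S_init.size() != N) stop("initial_levels must have length N");

  const std::vector<std::vector<int> > nb = neighbor_table(N);

  std::vector<int> S(N), origin(N, ORIG_REPL), age(N, 0);  // age 0 = old
  for (int i = 0; i < N; ++i) {
    S[i] = S_init[i];
    if (S[i] < 0 || S[i] > 3) stop("methylation levels must be in 0..3");
  }
  int promoter = as<int>(cfg["promoter0"]);  // 0 closed, 1 open (burst only)

  double t = 0.0;
  long tx_cum = 0;
  int cnt[4] = {0, 0, 0, 0};
  for (int i = 0; i < N; ++i) cnt[S[i]]++;
  int n_ex = 0;
  // base-4 encoding of the full methylation configuration (small N only),
  // letting exact per-state occupancy checks run against the event record
  const bool encode_state = N <= 26;

  const int n_cycles = (int)std::ceil(t_end / T_cc - 1e-9);
  std::vector<double> tx_per_cycle(std::max(n_cycles, 1), 0.0);

  // propensities: methylation (N), noisy demethylation (N), transcription,
  // promoter open/close (burst), regulator (4)
  std::vector<double> a_me(N), a_dem(N);
  double a_tx = 0, a_open = 0, a_close = 0, a_reg[4] = {0, 0, 0, 0};
  double alpha = (alpha_mode == 2) ? p_cnt / meanP : alpha0;

  Rec rec;
  auto state_code = [&]() -> double {
    if (!encode_state) return NA_REAL;
    double c = 0.0, b = 1.0;
    for (int i = 0; i < N; ++i) { c += S[i] * b; b *= 4.0; }
    return c;
  };
  if (record_events) {
    rec.t.reserve(4096);
    rec.push(t, EV_INIT, cnt, tx_cum, promoter, alpha, n_ex, state_code());
  }
  const int n_samp = sample_times.size();
  int si = 0;
  std::vector<double> smp;  // snapshot rows, 13 cols each
  smp.reserve(13 * (size_t)n_samp);

  bool crossed = false;
  double t_cross = NA_REAL;

  RNGScope rngscope;

  // --- helpers --------------------------------------------------------------
  auto repressive_count = [&]() -> int {
    return (variant == TWO_STATE) ? cnt[3] : (cnt[2] + cnt[3]);
  };
  auto check_stop = [&]() {
    if (crossed || stop_dir == 0) return;
    int n = repressive_count();
    if ((stop_dir > 0 && n > stop_thr) || (stop_dir < 0 && n < stop_thr)) {
      crossed = true;
      t_cross = t;
    }
  };
  check_stop();  // initial state may already satisfy the rule

  auto snapshot = [&](double ts) {
    int n_old = 0, n_new = 0, me3_old = 0, me3_new = 0;
    for (int i = 0; i < N; ++i) {
      if (age[i] == 0) { n_old++; if (S[i] == 3) me3_old++; }
      else             { n_new++; if (S[i] == 3) me3_new++; }
    }
    double row[13] = {ts, (double)cnt[0], (double)cnt[1], (double)cnt[2],
                      (double)cnt[3], (double)n_old, (double)me3_old,
                      (double)n_new, (double)me3_new, (double)n_ex,
                      (double)tx_cum, (double)promoter, alpha};
    for (int k = 0; k < 13; ++k) smp.push_back(row[k]);
  };
  // record snapshots for sample times strictly before `upto`, using the
  // current (piecewise-constant, right-continuous) state
  auto flush_samples = [&](double upto) {
    while (si < n_samp && sample_times[si] < upto) { snapshot(sample_times[si]); si++; }
  };

  auto set_level = [&](int i, int lvl) {
    cnt[S[i]]--; S[i] = lvl; cnt[lvl]++;
  };
  auto deposit_age = [&]() -> int {
    return (label_time >= 0 && t >= label_time) ? 1 : 0;
  };

  auto compute_propensities = [&]() -> double {
    if (alpha_mode == 1) alpha = (t >= t_switch) ? alpha1 : alpha0;
    else if (alpha_mode == 2) alpha = p_cnt / meanP;
    double tot = 0.0;
    if (variant == TWO_STATE) {
      double fb = k23 * (double)cnt[3] / N;
      for (int i = 0; i < N; ++i) {
        a_me[i] = (S[i] == 0) ? (g23 + fb) : 0.0;
        a_dem[i] = 0.0;
        tot += a_me[i];
      }
      a_tx = f_max - ((double)cnt[3] / N) * (f_max - f_min);
      tot += a_tx;
    } else {
      for (int i = 0; i < N; ++i) {
        double E = 0.0;
        const std::vector<int>& nbi = nb[i];
        for (size_t k = 0; k < nbi.size(); ++k) {
          int sj = S[nbi[k]];
          if (sj == 3) E += 1.0;
          else if (sj == 2) E += rho;
        }
        double a;
        switch (S[i]) {
          case 0: a = beta * (g01 + k01 * E); break;
          case 1: a = beta * (g12 + k12 * E); break;
          case 2: a = beta * (g23 + k23 * E); break;
          default: a = 0.0;
        }
        a_me[i] = a;
        a_dem[i] = (S[i] >= 1) ? g_dem : 0.0;
        tot += a_me[i] + a_dem[i];
      }
      double Pfrac = (double)(cnt[2] + cnt[3]) / N;
      if (variant == BURST) {
        double kon = k_on_max - (Pfrac / P_T) * (k_on_max - k_on_min);
        kon = alpha * std::max(kon, k_on_min);
        kon = std::min(kon, k_on_cap);
        a_open = (promoter == 0) ? kon : 0.0;
        a_close = (promoter == 1) ? k_off : 0.0;
        a_tx = (promoter == 1) ? f_0 : 0.0;
        tot += a_open + a_close + a_tx;
      } else {
        double f = f_max - (Pfrac / P_T) * (f_max - f_min);
        f = alpha * std::max(f, f_min);
        a_tx = std::min(f, f_cap);
        tot += a_tx;
      }
    }
    if (alpha_mode == 2) {
      a_reg[0] = sR;
      a_reg[1] = dR * m_cnt;
      a_reg[2] = sP * m_cnt;
      a_reg[3] = dP * p_cnt;
      tot += a_reg[0] + a_reg[1] + a_reg[2] + a_reg[3];
    }
    return tot;
  };

  // transcription event: exchange draws first (a hit on either histone resets
  // the whole nucleosome to me0/me0), then one-methyl demethylation draws on
  // the surviving histones
  auto apply_transcription = [&]() {
    tx_cum++;
    int cyc = (int)(t / T_cc);
    if (cyc >= (int)tx_per_cycle.size()) cyc = (int)tx_per_cycle.size() - 1;
    tx_per_cycle[cyc] += 1.0;
    if (variant == TWO_STATE) {
      for (int i = 0; i < N; ++i)
        if (S[i] == 3 && unif_rand() < p_dem) set_level(i, 0);
      return;
    }
    std::vector<char> exch(N, 0);
    if (p_ex > 0) {
      for (int i = 0; i < N; ++i)
        if (unif_rand() < p_ex) { exch[i] = 1; exch[i ^ 1] = 1; }  // pair (2k, 2k+1)
      int ag = deposit_age();
      for (int i = 0; i < N; ++i)
        if (exch[i]) {
          if (origin[i] != ORIG_EX) n_ex++;
          set_level(i, 0); origin[i] = ORIG_EX; age[i] = ag;
        }
    }
    if (p_dem > 0) {
      for (int i = 0; i < N; ++i)
        if (!exch[i] && S[i] >= 1 && unif_rand() < p_dem)
          set_level(i, variant == PROC_DEM ? 0 : S[i] - 1);
    }
  };

  auto apply_replication = [&]() {
    int ag = deposit_age();
    for (int k = 0; k < N; k += 2) {
      if (unif_rand() < 1.0 - surv) {
        for (int i = k; i <= k + 1; ++i) {
          if (origin[i] == ORIG_EX) n_ex--;
          set_level(i, 0); origin[i] = ORIG_REPL; age[i] = ag;
        }
      }
    }
  };

  // --- main loop ------------------------------------------------------------
  double next_repl = repl_on ? T_cc : R_PosInf;
  bool step_pending = (alpha_mode == 1) && (t_switch > 0) && (t_switch < t_end);

  while (t < t_end && !crossed) {
    double rtot = compute_propensities();
    double boundary = std::min(next_repl, t_end);
    if (step_pending && t_switch < boundary) boundary = t_switch;

    double t_next;
    bool is_reaction;
    if (rtot <= 0.0) {            // absorbed: advance straight to the boundary
      t_next = boundary;
      is_reaction = false;
    } else {
      t_next = t + exp_rand() / rtot;
      is_reaction = (t_next < boundary);
      if (!is_reaction) t_next = boundary;
    }

    flush_samples(t_next);

    if (!is_reaction) {
      t = t_next;
      if (t >= t_end) break;
      if (step_pending && t == t_switch) {
        step_pending = false;
        alpha = alpha1;
        if (record_events) rec.push(t, EV_ALPHA_STEP, cnt, tx_cum, promoter, alpha, n_ex, state_code());
        if (t == next_repl) {  // coincident boundary: also replicate
          apply_replication();
          next_repl += T_cc;
          if (record_events) rec.push(t, EV_REPL, cnt, tx_cum, promoter, alpha, n_ex, state_code());
          check_stop();
        }
        continue;
      }
      apply_replication();
      next_repl += T_cc;
      if (record_events) rec.push(t, EV_REPL, cnt, tx_cum, promoter, alpha, n_ex, state_code());
      check_stop();
      continue;
    }

    t = t_next;
    // categorical reaction choice
    double u = unif_rand() * rtot;
    int ev = -1;
    double acc = 0.0;
    int idx = -1;
    for (int i = 0; i < N && ev < 0; ++i) {
      acc += a_me[i];
      if (u < acc) { ev = EV_ME; idx = i; }
    }
    for (int i = 0; i < N && ev < 0; ++i) {
      acc += a_dem[i];
      if (u < acc) { ev = EV_DEM; idx = i; }
    }
    if (ev < 0) { acc += a_tx; if (u < acc) ev = EV_TX; }
    if (ev < 0 && variant == BURST) {
      acc += a_open; if (u < acc) ev = EV_OPEN;
      if (ev < 0) { acc += a_close; if (u < acc) ev = EV_CLOSE; }
    }
    if (ev < 0 && alpha_mode == 2) {
      acc += a_reg[0]; if (u < acc) ev = EV_MRNA_BIRTH;
      if (ev < 0) { acc += a_reg[1]; if (u < acc) ev = EV_MRNA_DEATH; }
      if (ev < 0) { acc += a_reg[2]; if (u < acc) ev = EV_PROT_BIRTH; }
      if (ev < 0) { acc += a_reg[3]; if (u < acc) ev = EV_PROT_DEATH; }
    }
    if (ev < 0) ev = (alpha_mode == 2) ? EV_PROT_DEATH : EV_TX;  // fp round-off

    switch (ev) {
      case EV_ME:
        if (variant == PROC_ME || variant == TWO_STATE) set_level(idx, 3);
        else set_level(idx, S[idx] + 1);
        break;
      case EV_DEM:
        set_level(idx, variant == PROC_DEM ? 0 : S[idx] - 1);
        break;
      case EV_TX:
        apply_transcription();
        break;
      case EV_OPEN: promoter = 1; break;
      case EV_CLOSE: promoter = 0; break;
      case EV_MRNA_BIRTH: m_cnt++; break;
      case EV_MRNA_DEATH: m_cnt--; break;
      case EV_PROT_BIRTH: p_cnt++; break;
      case EV_PROT_DEATH: p_cnt--; break;
    }
    if (alpha_mode == 2) alpha = p_cnt / meanP;
    if (record_events) rec.push(t, ev, cnt, tx_cum, promoter, alpha, n_ex, state_code());
    check_stop();
  }

  if (!crossed) t = t_end;
  flush_samples(t + 1e-9);
  if (record_events) rec.push(t, EV_END, cnt, tx_cum, promoter, alpha, n_ex, state_code());

  // --- assemble results -----------------------------------------------------
  List out;
  if (record_events) {
    size_t n = rec.t.size();
    NumericMatrix ev_mat(n, 11);
    for (size_t r = 0; r < n; ++r) {
      ev_mat(r, 0) = rec.t[r];  ev_mat(r, 1) = rec.ev[r];
      ev_mat(r, 2) = rec.n0[r]; ev_mat(r, 3) = rec.n1[r];
      ev_mat(r, 4) = rec.n2[r]; ev_mat(r, 5) = rec.n3[r];
      ev_mat(r, 6) = rec.tx[r]; ev_mat(r, 7) = rec.prom[r];
      ev_mat(r, 8) = rec.alpha[r]; ev_mat(r, 9) = rec.nex[r];
      ev_mat(r, 10) = rec.code[r];
    }
    colnames(ev_mat) = CharacterVector::create(
      "time_s", "event", "n_me0", "n_me1", "n_me2", "n_me3",
      "tx_cum", "promoter", "alpha", "n_exchange", "state_code");
    out["events"] = ev_mat;
  } else {
    out["events"] = R_NilValue;
  }
  {
    size_t nr = smp.size() / 13;
    NumericMatrix sm(nr, 13);
    for (size_t r = 0; r < nr; ++r)
      for (int c = 0; c < 13; ++c) sm(r, c) = smp[13 * r + c];
    colnames(sm) = CharacterVector::create(
      "time_s", "n_me0", "n_me1", "n_me2", "n_me3",
      "n_old", "n_me3_old", "n_new", "n_me3_new",
      "n_exchange", "tx_cum", "promoter", "alpha");
    out["samples"] = sm;
  }
  out["final_levels"] = IntegerVector(S.begin(), S.end());
  out["final_origin"] = IntegerVector(origin.begin(), origin.end());
  out["final_age"] = IntegerVector(age.begin(), age.end());
  out["promoter"] = promoter;
  out["mRNA"] = m_cnt;
  out["protein"] = p_cnt;
  out["t_final"] = t;
  out["crossed"] = crossed;
  out["t_cross"] = t_cross;
  out["tx_total"] = (double)tx_cum;
  out["tx_per_cycle"] = NumericVector(tx_per_cycle.begin(), tx_per_cycle.end());
  return out;
}

// Two-stage birth-death regulator simulated on its own (mRNA -> protein).
// Returns the per-event trace; rates in s^-1.
// [[Rcpp::export]]
List cpp_regulator(double s_R, double d_R, double s_P, double d_P,
                   int m0, int p0, double t_end) {
  double t = 0.0;
  int m = m0, p = p0;
  std::vector<double> tt, mm, pp;
  tt.reserve(1 << 16);
  tt.push_back(t); mm.push_back(m); pp.push_back(p);
  RNGScope rngscope;
  while (t < t_end) {
    double a0 = s_R, a1 = d_R * m, a2 = s_P * m, a3 = d_P * p;
    double rtot = a0 + a1 + a2 + a3;
    if (rtot <= 0) break;
    t += exp_rand() / rtot;
    if (t >= t_end) break;
    double u = unif_rand() * rtot;
    if (u < a0) m++;
    else if (u < a0 + a1) m--;
    else if (u < a0 + a1 + a2) p++;
    else p--;
    tt.push_back(t); mm.push_back(m); pp.push_back(p);
  }
  tt.push_back(t_end); mm.push_back(m); pp.push_back(p);
  return List::create(_["time_s"] = NumericVector(tt.begin(), tt.end()),
                      _["mRNA"] = NumericVector(mm.begin(), mm.end()),
                      _["protein"] = NumericVector(pp.begin(), pp.end()));
}
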