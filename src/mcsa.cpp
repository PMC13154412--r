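#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Monte Carlo simulated annealing core for coupling-matrix design.
//
// The design set is an M x L integer matrix of 0-based residue codes.
// Single-site counts n1[i][a] and pair counts n2[(i<j)][a][b] are updated
// incrementally as cells mutate, and the coupling matrix C is refreshed
// only at the positions a proposal touched; a debug mode recomputes
// everything from scratch and asserts agreement to 1e-9.
//
// Two acceptance granularities:
//   per-sequence (default): each mutated sequence is retained or reverted
//     by its own Metropolis decision; one inner iteration is one pass over
//     all M sequences.
//   whole-sweep: all mutations of one pass form a single proposal accepted
//     or rejected as a unit.
//
// All randomness flows through R's RNG, so set.seed() in R makes entire
// trajectories bit-reproducible.

namespace {

struct State {
  int M, L, A;
  double pc, dw;
  std::vector<int> design;     // M x L, column-major like R
  std::vector<int> n1;         // L*A
  std::vector<int> n2;         // L*L*A*A, only i<j slots used
  std::vector<double> f, k;    // L*A
  std::vector<double> C;       // L*L
  std::vector<double> q;       // A
  std::vector<double> Cnat;    // L*L
  double E;

  inline int &cell(int mu, int i) { return design[(size_t)i * M + mu]; }
  inline int &c1(int i, int a) { return n1[i * A + a]; }
  inline int &c2(int i, int a, int j, int b) {
    return n2[((size_t)(i * L + j) * A + a) * A + b];
  }
  inline double &Cij(int i, int j) { return C[i * L + j]; }
  inline double cnat(int i, int j) const { return Cnat[i * L + j]; }

  void refresh_fk_row(int i) {
    for (int a = 0; a < A; ++a) {
      double fa = (1.0 - pc) * c1(i, a) / M + pc / A;
      f[i * A + a] = fa;
      k[i * A + a] = std::log(fa * (1.0 - q[a])) - std::log(q[a] * (1.0 - fa));
    }
  }

  double coupling(int i, int j) {
    double out = 0.0;
    if (i == j) {
      for (int a = 0; a < A; ++a) {
        double fia = f[i * A + a], kia = k[i * A + a];
        for (int b = 0; b < A; ++b) {
          double D = ((a == b) ? fia : 0.0) - fia * f[i * A + b];
          double w = kia * k[i * A + b];
          out += w * w * D * D;
        }
      }
    } else {
      int lo = i < j ? i : j, hi = i < j ? j : i;
      const double invM = 1.0 / M, pcAA = pc / ((double)A * A);
      for (int a = 0; a < A; ++a) {
        double fia = f[i * A + a], kia = k[i * A + a];
        for (int b = 0; b < A; ++b) {
          int cnt = (i < j) ? c2(lo, a, hi, b) : c2(lo, b, hi, a);
          double fjab = (1.0 - pc) * cnt * invM + pcAA;
          double D = fjab - fia * f[j * A + b];
          double w = kia * k[j * A + b];
          out += w * w * D * D;
        }
      }
    }
    return out;
  }

  double E_from_C() const {
    double out = 0.0;
    for (int i = 0; i < L; ++i)
      for (int j = 0; j < L; ++j) {
        double d = C[i * L + j] - Cnat[i * L + j];
        out += (i == j) ? dw * d * d : d * d;
      }
    return out;
  }

  void recount() {
    std::fill(n1.begin(), n1.end(), 0);
    std::fill(n2.begin(), n2.end(), 0);
    for (int mu = 0; mu < M; ++mu)
      for (int i = 0; i < L; ++i) {
        int a = cell(mu, i);
        c1(i, a)++;
        for (int j = i + 1; j < L; ++j) c2(i, a, j, cell(mu, j))++;
      }
  }

  void rebuild() {
    recount();
    for (int i = 0; i < L; ++i) refresh_fk_row(i);
    for (int i = 0; i < L; ++i)
      for (int j = i; j < L; ++j) Cij(i, j) = Cij(j, i) = coupling(i, j);
    E = E_from_C();
  }

  // apply one cell change to design + count tallies
  void apply_change(int mu, int i, int from, int to) {
    cell(mu, i) = to;
    c1(i, from)--;
    c1(i, to)++;
    for (int j = 0; j < L; ++j) {
      if (j == i) continue;
      int b = cell(mu, j);
      if (i < j) {
        c2(i, from, j, b)--;
        c2(i, to, j, b)++;
      } else {
        c2(j, b, i, from)--;
        c2(j, b, i, to)++;
      }
    }
  }
};

struct Saved {
  std::vector<int> pos;          // touched positions
  std::vector<double> fk;        // saved f,k rows (2*A per position)
  std::vector<double> Crows;     // saved C rows (L per position)
  double E;
};

// refresh f,k and C at the touched positions; State::E updated via deltas
void update_stats(State &s, const std::vector<int> &S, Saved &sv) {
  sv.pos = S;
  sv.fk.clear();
  sv.Crows.clear();
  sv.E = s.E;
  for (int i : S) {
    for (int a = 0; a < s.A; ++a) {
      sv.fk.push_back(s.f[i * s.A + a]);
      sv.fk.push_back(s.k[i * s.A + a]);
    }
    for (int j = 0; j < s.L; ++j) sv.Crows.push_back(s.Cij(i, j));
  }
  for (int i : S) s.refresh_fk_row(i);
  for (size_t si = 0; si < S.size(); ++si) {
    int i = S[si];
    for (int j = 0; j < s.L; ++j) {
      bool j_touched = false;
      size_t sj = 0;
      for (; sj < S.size(); ++sj)
        if (S[sj] == j) {
          j_touched = true;
          break;
        }
      if (j_touched && sj < si) continue;  // pair already refreshed
      double oldC = s.Cij(i, j);
      double newC = s.coupling(i, j);
      s.Cij(i, j) = newC;
      s.Cij(j, i) = newC;
      double dn = newC - s.cnat(i, j), dd = oldC - s.cnat(i, j);
      s.E += (i == j) ? s.dw * (dn * dn - dd * dd) : 2.0 * (dn * dn - dd * dd);
    }
  }
}

void revert_stats(State &s, const Saved &sv) {
  size_t pf = 0, pc_ = 0;
  for (int i : sv.pos) {
    for (int a = 0; a < s.A; ++a) {
      s.f[i * s.A + a] = sv.fk[pf++];
      s.k[i * s.A + a] = sv.fk[pf++];
    }
    for (int j = 0; j < s.L; ++j) {
      s.Cij(i, j) = sv.Crows[pc_];
      s.Cij(j, i) = sv.Crows[pc_];
      ++pc_;
    }
  }
  s.E = sv.E;
}

void debug_verify(State &s) {
  State chk = s;
  chk.rebuild();
  if (chk.n1 != s.n1 || chk.n2 != s.n2)
    stop("incremental tallies diverged from full recount");
  for (int i = 0; i < s.L * s.L; ++i)
    if (std::abs(chk.C[i] - s.C[i]) > 1e-9)
      stop("incremental coupling matrix diverged from full recomputation");
  if (std::abs(chk.E - s.E) > 1e-9)
    stop("incremental objective diverged from full recomputation");
}

}  // namespace

// [[Rcpp::export]]
List mcsa_run(IntegerMatrix init, NumericMatrix f_native, NumericVector q,
              double pc, NumericMatrix Cnat, double T0, double decay,
              int n_outer, int n_inner, double mut_prob, double diag_weight,
              bool guided, bool per_sequence, int early_stop, int trace_every,
              int debug_every) {
  const int M = init.nrow(), L = init.ncol(), A = f_native.ncol();
  State s;
  s.M = M;
  s.L = L;
  s.A = A;
  s.pc = pc;
  s.dw = diag_weight;
  s.design.assign(init.begin(), init.end());
  s.n1.assign(L * A, 0);
  s.n2.assign((size_t)L * L * A * A, 0);
  s.f.assign(L * A, 0.0);
  s.k.assign(L * A, 0.0);
  s.C.assign(L * L, 0.0);
  s.q.assign(q.begin(), q.end());
  s.Cnat.assign(Cnat.begin(), Cnat.end());
  s.rebuild();

  // cumulative native frequencies per position, for guided proposals
  std::vector<double> cum(L * A);
  for (int i = 0; i < L; ++i) {
    double acc = 0.0;
    for (int a = 0; a < A; ++a) {
      acc += f_native(i, a);
      cum[i * A + a] = acc;
    }
    cum[i * A + A - 1] = 1.0;
  }
  auto draw_residue = [&](int i, int cur) -> int {
    if (guided) {
      double u = unif_rand();
      const double *c0 = &cum[i * A];
      int nx = (int)(std::lower_bound(c0, c0 + A, u) - c0);
      return nx >= A ? A - 1 : nx;  // may equal cur (guided redraw)
    }
    int r = (int)(unif_rand() * (A - 1));
    if (r >= A - 1) r = A - 2;
    return (r >= cur) ? r + 1 : r;
  };

  const double initial_E = s.E;
  double best_E = s.E;
  std::vector<int> best = s.design;

  std::vector<int> ch_mu, ch_i, ch_old, ch_new;
  std::vector<int> touched;
  Saved sv;

  std::vector<int> tr_outer, tr_inner;
  std::vector<double> tr_T, tr_E, tr_best, tr_acc;
  long decisions = 0, accepted_total = 0, unit = 0;
  int consecutive_rej = 0;
  bool stop_early = false;

  for (int outer = 0; outer < n_outer && !stop_early; ++outer) {
    double T = T0 * std::pow(decay, outer);
    for (int inner = 0; inner < n_inner; ++inner) {
      ++unit;
      long acc_this_unit = 0, dec_this_unit = 0;
      ch_mu.clear();
      ch_i.clear();
      ch_old.clear();
      ch_new.clear();
      for (int mu = 0; mu < M; ++mu) {
        int first = (int)ch_mu.size();
        for (int i = 0; i < L; ++i) {
          if (unif_rand() >= mut_prob) continue;
          int cur = s.cell(mu, i);
          int nx = draw_residue(i, cur);
          if (nx == cur) continue;
          ch_mu.push_back(mu);
          ch_i.push_back(i);
          ch_old.push_back(cur);
          ch_new.push_back(nx);
          s.apply_change(mu, i, cur, nx);
        }
        if (!per_sequence) continue;
        int nch = (int)ch_mu.size() - first;
        if (nch == 0) continue;
        touched.clear();
        for (int c = first; c < (int)ch_mu.size(); ++c)
          touched.push_back(ch_i[c]);
        std::sort(touched.begin(), touched.end());
        touched.erase(std::unique(touched.begin(), touched.end()),
                      touched.end());
        update_stats(s, touched, sv);
        double dE = s.E - sv.E;
        ++decisions;
        ++dec_this_unit;
        bool accept = (dE <= 0.0) || (unif_rand() < std::exp(-dE / T));
        if (accept) {
          ++accepted_total;
          ++acc_this_unit;
        } else {
          for (int c = (int)ch_mu.size() - 1; c >= first; --c)
            s.apply_change(ch_mu[c], ch_i[c], ch_new[c], ch_old[c]);
          revert_stats(s, sv);
        }
        ch_mu.resize(first);
        ch_i.resize(first);
        ch_old.resize(first);
        ch_new.resize(first);
      }

      if (!per_sequence) {
        // one Metropolis decision for the whole sweep
        touched.clear();
        for (int c = 0; c < (int)ch_mu.size(); ++c) touched.push_back(ch_i[c]);
        std::sort(touched.begin(), touched.end());
        touched.erase(std::unique(touched.begin(), touched.end()),
                      touched.end());
        if (!touched.empty()) {
          update_stats(s, touched, sv);
          double dE = s.E - sv.E;
          ++decisions;
          ++dec_this_unit;
          bool accept = (dE <= 0.0) || (unif_rand() < std::exp(-dE / T));
          if (accept) {
            ++accepted_total;
            ++acc_this_unit;
          } else {
            for (int c = (int)ch_mu.size() - 1; c >= 0; --c)
              s.apply_change(ch_mu[c], ch_i[c], ch_new[c], ch_old[c]);
            revert_stats(s, sv);
          }
        }
      }

      // re-anchor E to the maintained coupling matrix once per inner unit
      // (bounds floating-point drift of the incremental updates)
      s.E = s.E_from_C();
      if (s.E < best_E) {
        best_E = s.E;
        best = s.design;
      }
      if (debug_every > 0 && unit % debug_every == 0) debug_verify(s);
      if (unit % trace_every == 0) {
        tr_outer.push_back(outer);
        tr_inner.push_back(inner);
        tr_T.push_back(T);
        tr_E.push_back(s.E);
        tr_best.push_back(best_E);
        tr_acc.push_back(dec_this_unit > 0
                             ? (double)acc_this_unit / dec_this_unit
                             : 1.0);
      }
      if (dec_this_unit > 0 && acc_this_unit == 0)
        ++consecutive_rej;
      else
        consecutive_rej = 0;
      if (early_stop > 0 && consecutive_rej >= early_stop) {
        stop_early = true;
        break;
      }
    }
    if (outer % 20 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix best_mat(M, L);
  std::copy(best.begin(), best.end(), best_mat.begin());
  return List::create(
      _["design"] = best_mat, _["initial_E"] = initial_E,
      _["final_E"] = best_E,
      _["accept_rate"] = decisions > 0 ? (double)accepted_total / decisions
                                       : 1.0,
      _["outer"] = wrap(tr_outer), _["inner"] = wrap(tr_inner),
      _["temperature"] = wrap(tr_T), _["E"] = wrap(tr_E),
      _["best_E"] = wrap(tr_best), _["accepted"] = wrap(tr_acc));
}
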