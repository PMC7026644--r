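// Metropolis simulated annealing over base-pair sets with a minimal
// nearest-neighbour energy (Turner 2004 stacks, terminal AU/GU, lone and
// noncanonical penalties) and an optional pairing-score restraint.
// Crossing pairs are allowed; the only hard constraints are one partner
// per base and the minimum enclosed loop span.
#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// base codes A=0 C=1 G=2 U=3; pair types CG=0 GC=1 GU=2 UG=3 AU=4 UA=5,
// -1 = noncanonical. flip(p) = p ^ 1 swaps the strand orientation.
static inline int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  return -1;
}

struct EnergyCtx {
  const int *s;            // sequence codes
  int L;
  const double *stacks;    // 6x6, column-major
  double lone, noncan, auend;
  const double *ps;        // L x L, column-major (0 if no restraint)
  double wm;               // weight / mean positive Ps (0 disables)
};

// stack free energy between outer pair (i,j) and inner pair (i+1,j-1),
// both assumed present; 0 if either is noncanonical
static inline double stack_term(const EnergyCtx &c, int i, int j) {
  int p1 = pair_type(c.s[i], c.s[j]);
  int p2 = pair_type(c.s[i + 1], c.s[j - 1]);
  if (p1 < 0 || p2 < 0) return 0.0;
  int p2f = p2 ^ 1;
  return c.stacks[p1 + 6 * p2f];
}

// terms carried by pair (i,j) itself: lone penalty, noncanonical
// penalty, terminal AU/GU penalty (once per missing neighbour, but a
// lone pair pays it once, not twice), and the restraint
static inline double local_term(const EnergyCtx &c, const int *partner,
                                int i, int j) {
  bool outer = (i - 1 >= 0 && j + 1 < c.L && partner[i - 1] == j + 1);
  bool inner = (i + 1 < j - 1 && partner[i + 1] == j - 1);
  double e = 0.0;
  if (!outer && !inner) e += c.lone;
  int pt = pair_type(c.s[i], c.s[j]);
  if (pt < 0) {
    e += c.noncan;
  } else if (pt >= 2) {  // GU, UG, AU, UA closing a helix end
    int nend = (outer ? 0 : 1) + (inner ? 0 : 1);
    if (nend == 2) nend = 1;
    e += nend * c.auend;
  }
  if (c.wm != 0.0) e -= c.wm * c.ps[i + c.L * j];
  return e;
}

static double full_energy(const EnergyCtx &c, const int *partner) {
  double e = 0.0;
  for (int i = 0; i < c.L; ++i) {
    int j = partner[i];
    if (j > i) {
      e += local_term(c, partner, i, j);
      if (i + 1 < j - 1 && partner[i + 1] == j - 1) e += stack_term(c, i, j);
    }
  }
  return e;
}

// energy of the neighbourhood affected by toggling pair (i,j): local
// terms of (i-1,j+1), (i,j), (i+1,j-1) plus the two stacks incident to
// (i,j)
static double region_energy(const EnergyCtx &c, const int *partner,
                            int i, int j) {
  double e = 0.0;
  for (int d = -1; d <= 1; ++d) {
    int ii = i + d, jj = j - d;
    if (ii >= 0 && jj < c.L && ii < jj && partner[ii] == jj)
      e += local_term(c, partner, ii, jj);
  }
  for (int d = -1; d <= 0; ++d) {
    int ii = i + d, jj = j - d;
    if (ii >= 0 && jj < c.L && ii < jj && partner[ii] == jj &&
        ii + 1 < jj - 1 && partner[ii + 1] == jj - 1)
      e += stack_term(c, ii, jj);
  }
  return e;
}

static EnergyCtx make_ctx(const IntegerVector &seq,
                          const NumericMatrix &stacks, double lone,
                          double noncan, double auend,
                          const NumericMatrix &ps, double wm) {
  EnergyCtx c;
  c.s = &seq[0];
  c.L = seq.size();
  c.stacks = &stacks[0];
  c.lone = lone;
  c.noncan = noncan;
  c.auend = auend;
  c.ps = &ps[0];
  c.wm = wm;
  return c;
}

// [[Rcpp::export]]
double cpp_energy(IntegerVector partner1, IntegerVector seq,
                  NumericMatrix stacks, double lone, double noncan,
                  double auend, NumericMatrix ps, double wm) {
  int L = seq.size();
  std::vector<int> partner(L);
  for (int i = 0; i < L; ++i) partner[i] = partner1[i] - 1;  // 0-based, -1 free
  EnergyCtx c = make_ctx(seq, stacks, lone, noncan, auend, ps, wm);
  return full_energy(c, partner.data());
}

// Move kernel: with probability 1/2 remove a uniformly random existing
// pair (no-op when the structure is empty), otherwise toggle a
// candidate pair drawn uniformly from all loop-feasible pairs (remove
// it if present, add it if both ends are free, no-op otherwise). The
// two sub-kernels overlap, so acceptance carries the exact
// Metropolis-Hastings proposal ratio — both directions' total proposal
// probabilities are O(1): removing one of n pairs is proposed with
// probability 1/2 (1/N_cand + 1/n) and the reverse addition with
// 1/(2 N_cand). The chain therefore satisfies detailed balance with
// respect to exp(-E/T) while keeping removals frequent enough to
// escape local minima during annealing.
struct MCState {
  EnergyCtx c;
  double e_cur = 0.0;  // running energy, updated incrementally
  std::vector<int> partner;
  std::vector<int> cand_i, cand_j;   // loop-feasible candidate pairs
  std::vector<int> pairs_i;          // i of each current pair
  std::vector<int> list_pos;         // index of i in pairs_i, or -1
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  MCState(const EnergyCtx &ctx, int min_loop, uint64_t seed) : c(ctx) {
    min_loop_ = min_loop;
    partner.assign(c.L, -1);
    list_pos.assign(c.L, -1);
    for (int i = 0; i < c.L; ++i)
      for (int j = i + min_loop + 1; j < c.L; ++j) {
        cand_i.push_back(i);
        cand_j.push_back(j);
      }
    rng.seed(seed);
  }

  void add_pair(int i, int j) {
    partner[i] = j; partner[j] = i;
    list_pos[i] = (int)pairs_i.size();
    pairs_i.push_back(i);
  }
  void remove_pair(int i, int j) {
    partner[i] = -1; partner[j] = -1;
    int k = list_pos[i];
    int last = pairs_i.back();
    pairs_i[k] = last;
    list_pos[last] = k;
    pairs_i.pop_back();
    list_pos[i] = -1;
  }

  // `hastings` switches the exact proposal-ratio correction on; every
  // caller uses it, so the chain's stationary distribution at fixed
  // temperature is exactly Boltzmann.
  void try_remove(int i, int j, double temp, bool hastings) {
    double ratio = 1.0;
    if (hastings) {
      double n = (double)pairs_i.size();
      double q_fwd = P_REMOVE / n + P_TOGGLE / cand_i.size();
      double q_rev = P_TOGGLE / cand_i.size();
      ratio = q_rev / q_fwd;
    }
    double before = region_energy(c, partner.data(), i, j);
    remove_pair(i, j);
    double dE = region_energy(c, partner.data(), i, j) - before;
    double acc = std::exp(-dE / temp) * ratio;
    if (acc < 1.0 && unif(rng) >= acc) add_pair(i, j);  // reject
    else e_cur += dE;
  }

  void try_add(int i, int j, double temp, bool hastings) {
    double ratio = 1.0;
    if (hastings) {
      double n1 = (double)pairs_i.size() + 1.0;
      double q_fwd = P_TOGGLE / cand_i.size();
      double q_rev = P_REMOVE / n1 + P_TOGGLE / cand_i.size();
      ratio = q_rev / q_fwd;
    }
    double before = region_energy(c, partner.data(), i, j);
    add_pair(i, j);
    double dE = region_energy(c, partner.data(), i, j) - before;
    double acc = std::exp(-dE / temp) * ratio;
    if (acc < 1.0 && unif(rng) >= acc) remove_pair(i, j);  // reject
    else e_cur += dE;
  }

  // Shift move (the third move type of standard RNA folding-kinetics
  // samplers, alongside insertion and deletion): keep one endpoint of a
  // uniformly chosen pair and move the other to a uniformly chosen
  // free, loop-valid partner. The free-partner set of the kept
  // endpoint has the same size before and after (the old partner
  // becomes free exactly as the new one becomes occupied), so the
  // proposal is symmetric and needs no correction.
  int min_loop_ = 0;

  bool valid_span(int a, int b) {
    int lo = a < b ? a : b, hi = a < b ? b : a;
    return hi - lo - 1 >= min_loop_;
  }

  void try_shift(double temp) {
    if (pairs_i.empty()) return;
    size_t k = (size_t)(unif(rng) * pairs_i.size());
    if (k >= pairs_i.size()) k = pairs_i.size() - 1;
    int i = pairs_i[k], j = partner[i];
    int keep = (unif(rng) < 0.5) ? i : j;
    int old_p = (keep == i) ? j : i;
    // uniform free, loop-valid new partner of `keep`
    int n_free = 0, pick = -1;
    for (int p = 0; p < c.L; ++p) {
      if (partner[p] < 0 && p != keep && valid_span(keep, p)) ++n_free;
    }
    if (n_free == 0) return;
    int target = (int)(unif(rng) * n_free);
    if (target >= n_free) target = n_free - 1;
    for (int p = 0, seen = 0; p < c.L; ++p) {
      if (partner[p] < 0 && p != keep && valid_span(keep, p)) {
        if (seen == target) { pick = p; break; }
        ++seen;
      }
    }
    int oi = i < j ? i : j, oj = i < j ? j : i;
    int ni = keep < pick ? keep : pick, nj = keep < pick ? pick : keep;
    double before1 = region_energy(c, partner.data(), oi, oj);
    remove_pair(oi, oj);
    double dE = region_energy(c, partner.data(), oi, oj) - before1;
    double before2 = region_energy(c, partner.data(), ni, nj);
    add_pair(ni, nj);
    dE += region_energy(c, partner.data(), ni, nj) - before2;
    if (dE > 0.0 && unif(rng) >= std::exp(-dE / temp)) {
      remove_pair(ni, nj);
      add_pair(oi, oj);
    } else {
      e_cur += dE;
    }
  }

  void step(double temp, bool hastings) {
    double u = unif(rng);
    if (u < P_REMOVE) {
      if (pairs_i.empty()) return;
      size_t k = (size_t)(unif(rng) * pairs_i.size());
      if (k >= pairs_i.size()) k = pairs_i.size() - 1;
      int i = pairs_i[k];
      try_remove(i, partner[i], temp, hastings);
    } else if (u < P_REMOVE + P_TOGGLE) {
      size_t k = (size_t)(unif(rng) * cand_i.size());
      if (k >= cand_i.size()) k = cand_i.size() - 1;
      int i = cand_i[k], j = cand_j[k];
      if (partner[i] == j) {
        try_remove(i, j, temp, hastings);
      } else if (partner[i] < 0 && partner[j] < 0) {
        try_add(i, j, temp, hastings);
      }
    } else {
      try_shift(temp);
    }
  }

  static constexpr double P_REMOVE = 1.0 / 3.0;
  static constexpr double P_TOGGLE = 1.0 / 3.0;
};

// [[Rcpp::export]]
List cpp_anneal(IntegerVector seq, NumericMatrix stacks, double lone,
                double noncan, double auend, int min_loop,
                NumericMatrix ps, double wm, double t0, double cool,
                double tend, int steps_per_temp, double seed) {
  EnergyCtx c = make_ctx(seq, stacks, lone, noncan, auend, ps, wm);
  MCState st(c, min_loop, (uint64_t)seed);
  // best-of-run: an annealing schedule is an optimizer, so the lowest-
  // energy structure visited anywhere along the schedule is returned,
  // not the structure the chain happens to end in
  std::vector<int> best(st.partner);
  double e_best = 0.0;
  for (double temp = t0; temp >= tend * (1.0 - 1e-12); temp *= cool) {
    for (int k = 0; k < steps_per_temp; ++k) {
      st.step(temp, true);
      if (st.e_cur < e_best - 1e-12) {
        e_best = st.e_cur;
        best = st.partner;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  IntegerVector partner1(c.L);
  for (int i = 0; i < c.L; ++i) partner1[i] = best[i] + 1;
  return List::create(_["partner"] = partner1,
                      _["energy"] = full_energy(c, best.data()));
}

// Fixed-temperature sampler recording pair occupancy, for equilibrium
// checks against exhaustive Boltzmann enumeration.
// [[Rcpp::export]]
List cpp_mc_sample(IntegerVector seq, NumericMatrix stacks, double lone,
                   double noncan, double auend, int min_loop,
                   NumericMatrix ps, double wm, double temp,
                   int n_steps, int burn_in, int thin, double seed) {
  EnergyCtx c = make_ctx(seq, stacks, lone, noncan, auend, ps, wm);
  MCState st(c, min_loop, (uint64_t)seed);
  NumericMatrix counts(c.L, c.L);
  long n_samples = 0;
  for (int k = 0; k < burn_in; ++k) st.step(temp, true);
  for (int k = 0; k < n_steps; ++k) {
    st.step(temp, true);
    if ((k + 1) % thin == 0) {
      for (int i = 0; i < c.L; ++i) {
        int j = st.partner[i];
        if (j > i) counts(i, j) += 1.0;
      }
      ++n_samples;
    }
    if ((k & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["counts"] = counts,
                      _["n_samples"] = (double)n_samples);
}
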