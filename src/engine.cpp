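// Compiled core: ADI diffusion solver and the per-hour lattice update.
//
// Cell codes on the integer lattice: 0 = empty, 1 = doubly sensitive,
// 2 = resistant to drug 1, 3 = resistant to drug 2, 4 = doubly resistant.
//
// All randomness is drawn from R's RNG (unif_rand), so runs are fully
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int s1_of(int t) { return (t == 2 || t == 4) ? 0 : 1; }
static inline int s2_of(int t) { return (t == 3 || t == 4) ? 0 : 1; }

// --------------------------------------------------------------------------
// ADI diffusion, zero-flux (reflecting) boundaries.
//
// One step of c_t = D lap(c) with dt = 1, dx = 1, split Peaceman-Rachford
// style: implicit in x / explicit in y, then implicit in y / explicit in x,
// each half-step with a = D*dt/2. Both half-step operators have zero column
// sums under the Neumann discretization, so total mass is conserved to
// floating-point rounding.

// Solve (I - a L) x = rhs where L is the 1-D Neumann Laplacian of size n.
static void thomas_neumann(const double* rhs, double* x, int n, double a,
                           std::vector<double>& cp, std::vector<double>& dp) {
  // diagonal: 1 + a at the two ends, 1 + 2a inside; off-diagonals: -a
  double b0 = 1.0 + a;
  cp[0] = -a / b0;
  dp[0] = rhs[0] / b0;
  for (int i = 1; i < n; ++i) {
    double bi = (i == n - 1) ? 1.0 + a : 1.0 + 2.0 * a;
    double m = bi + a * cp[i - 1];
    cp[i] = -a / m;
    dp[i] = (rhs[i] + a * dp[i - 1]) / m;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
}

static void adi_step_inplace(NumericMatrix conc, double D) {
  int nr = conc.nrow(), nc = conc.ncol();
  if (D <= 0.0 || (nr < 2 && nc < 2)) return;
  double a = D / 2.0;
  int nmax = nr > nc ? nr : nc;
  std::vector<double> cp(nmax), dp(nmax), rhs(nmax), sol(nmax);
  NumericMatrix u(nr, nc);

  // half-step 1: implicit along rows (within a column), explicit across columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double left  = (j > 0)      ? conc(i, j - 1) : conc(i, j);
      double right = (j < nc - 1) ? conc(i, j + 1) : conc(i, j);
      rhs[i] = conc(i, j) + a * (left - 2.0 * conc(i, j) + right);
    }
    thomas_neumann(rhs.data(), sol.data(), nr, a, cp, dp);
    for (int i = 0; i < nr; ++i) u(i, j) = sol[i];
  }

  // half-step 2: implicit across columns (within a row), explicit along rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double up   = (i > 0)      ? u(i - 1, j) : u(i, j);
      double down = (i < nr - 1) ? u(i + 1, j) : u(i, j);
      rhs[j] = u(i, j) + a * (up - 2.0 * u(i, j) + down);
    }
    thomas_neumann(rhs.data(), sol.data(), nc, a, cp, dp);
    for (int j = 0; j < nc; ++j) conc(i, j) = sol[j];
  }
}

static bool is_uniform(const NumericMatrix& m) {
  int n = m.nrow() * m.ncol();
  if (n == 0) return true;
  double v = m[0];
  for (int k = 1; k < n; ++k) if (m[k] != v) return false;
  return true;
}

// One unit-time application of the diffusion operator per step. The
// Peaceman-Rachford split is unconditionally stable at any D but loses
// accuracy (and positivity) on sharp sources when D*dt/2 is large, so the
// unit step is taken as ceil(2D) sub-steps, keeping each half-step
// coefficient at or below 1/4.
// [[Rcpp::export]]
void adi_diffuse_cpp(NumericMatrix conc, double D, int nsteps) {
  // spatially uniform fields are exact fixed points of the diffusion
  // operator; skip the solve so they stay bitwise uniform
  if (is_uniform(conc) || D <= 0.0) return;
  int nsub = (int)std::ceil(2.0 * D);
  if (nsub < 1) nsub = 1;
  for (int s = 0; s < nsteps * nsub; ++s) adi_step_inplace(conc, D / nsub);
}

// --------------------------------------------------------------------------
// Cell-level stochastic update

// Daughter phenotype at division: each permitted target type with
// probability mu, parent type otherwise. With allow_reverse = false only
// transitions that strictly add resistance are permitted.
static int mutate_type(int parent, double mu, bool allow_reverse) {
  int targets[3];
  int k = 0;
  int p1 = 1 - s1_of(parent), p2 = 1 - s2_of(parent);  // resistance bits
  for (int t = 1; t <= 4; ++t) {
    if (t == parent) continue;
    if (!allow_reverse) {
      int t1 = 1 - s1_of(t), t2 = 1 - s2_of(t);
      if (t1 < p1 || t2 < p2) continue;  // would lose a resistance
    }
    targets[k++] = t;
  }
  if (k == 0 || mu <= 0.0) return parent;
  double u = unif_rand();
  if (u < k * mu) {
    int idx = (int)(u / mu);
    if (idx >= k) idx = k - 1;
    return targets[idx];
  }
  return parent;
}

// One hour of world time, in place:
//   1. drug phase: uniform dose (if dosing_now), ADI diffusion, decay
//   2. cell phase: visit every cell present at the start of the step in a
//      fresh uniform random order; Bernoulli death from the local drug
//      concentrations; survivors may divide into an empty Moore neighbor or,
//      if fully crowded, replace a random neighbor with probability
//      replacement_prob. Daughters (which may mutate) are not revisited.
// Returns the per-type counts after the step.
// [[Rcpp::export]]
IntegerVector step_world_cpp(IntegerMatrix cells,
                             NumericMatrix conc1, NumericMatrix conc2,
                             double dose1, double dose2, bool dosing_now,
                             NumericVector division_rates, double death_rate,
                             double replacement_prob, double mutation_rate,
                             bool allow_reverse, double psi1, double psi2,
                             double decay_fraction, double diffusion_rate) {
  int nr = cells.nrow(), nc = cells.ncol(), n = nr * nc;

  // drug phase: dose -> diffuse -> decay
  if (dosing_now) {
    if (dose1 > 0) for (int k = 0; k < n; ++k) conc1[k] += dose1;
    if (dose2 > 0) for (int k = 0; k < n; ++k) conc2[k] += dose2;
  }
  if (diffusion_rate > 0) {
    if (!is_uniform(conc1)) adi_step_inplace(conc1, diffusion_rate);
    if (!is_uniform(conc2)) adi_step_inplace(conc2, diffusion_rate);
  }
  double keep = 1.0 - decay_fraction;
  for (int k = 0; k < n; ++k) { conc1[k] *= keep; conc2[k] *= keep; }

  // snapshot of occupied sites, visited in a fresh random order
  static std::vector<int> order;
  order.clear();
  for (int k = 0; k < n; ++k) if (cells[k] != 0) order.push_back(k);
  int m = (int)order.size();
  for (int i = m - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    int tmp = order[i]; order[i] = order[j]; order[j] = tmp;
  }

  std::vector<char> born(n, 0);
  int nbr[8];

  for (int v = 0; v < m; ++v) {
    int k = order[v];
    int type = cells[k];
    if (type == 0 || born[k]) continue;  // died/replaced earlier this step

    double d = death_rate + s1_of(type) * conc1[k] * psi1 +
               s2_of(type) * conc2[k] * psi2;
    if (d > 1.0) d = 1.0;
    if (unif_rand() < d) { cells[k] = 0; continue; }

    if (unif_rand() >= division_rates[type - 1]) continue;

    // Moore neighborhood (no wrap-around)
    int i = k % nr, j = k / nr;
    int nn = 0, nemp = 0;
    int emp[8];
    for (int dj = -1; dj <= 1; ++dj) {
      int jj = j + dj;
      if (jj < 0 || jj >= nc) continue;
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di;
        if (ii < 0 || ii >= nr) continue;
        int kk = jj * nr + ii;
        nbr[nn++] = kk;
        if (cells[kk] == 0) emp[nemp++] = kk;
      }
    }
    int target = -1;
    if (nemp > 0) {
      int pick = (int)(unif_rand() * nemp);
      if (pick >= nemp) pick = nemp - 1;
      target = emp[pick];
    } else if (nn > 0 && replacement_prob > 0 &&
               unif_rand() < replacement_prob) {
      int pick = (int)(unif_rand() * nn);
      if (pick >= nn) pick = nn - 1;
      target = nbr[pick];
    }
    if (target >= 0) {
      cells[target] = mutate_type(type, mutation_rate, allow_reverse);
      born[target] = 1;
    }
  }

  IntegerVector counts(4);
  for (int k = 0; k < n; ++k) if (cells[k] != 0) counts[cells[k] - 1]++;
  return counts;
}
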