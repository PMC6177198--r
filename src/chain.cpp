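#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Aspiration-dynamics Markov chain, Fermi decision function.
//
// One elementary step: pick a focal individual uniformly, compute its payoff
// under the configured scheme, flip its strategy with probability
// 1/(1+exp(-beta*(e_i - pi_i))). Uses R's RNG (unif_rand) so that set.seed()
// in R governs reproducibility.
//
// adj/offs: CSR adjacency, 0-based (ignored in well-mixed mode).
// state0:   0/1 vector, 1 = strategy A.
// Payoff schemes: 0 = single game organised by the focal;
//                 1 = average over the d games organised by the focal and
//                     each of its d-1 neighbours (regular structures only,
//                     degree == d-1 enforced by the caller).

static inline double fermi(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// sample one uniform integer in [0, n)
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;  // guard against unif_rand() == 1.0
}

// [[Rcpp::export]]
List cpp_run_chain(IntegerVector adj, IntegerVector offs, bool well_mixed,
                   int d, NumericVector a, NumericVector b, NumericVector e,
                   double beta, IntegerVector state0, double n_steps_,
                   double burn_in_, int scheme, int n_batches, int thin) {
  const long long n_steps = (long long)n_steps_;
  const long long burn_in = (long long)burn_in_;
  const int N = state0.size();
  const int need = d - 1;

  std::vector<int> s(state0.begin(), state0.end());
  long long countA = 0;
  for (int i = 0; i < N; ++i) countA += s[i];

  const long long T = n_steps - burn_in;          // post-burn-in samples
  const long long batch_len = (n_batches > 0) ? T / n_batches : 0;
  std::vector<double> batch_sum(n_batches > 0 ? n_batches : 1, 0.0);
  long double abund_sum = 0.0L;

  std::vector<double> traj;
  if (thin > 0) traj.reserve((size_t)(T / thin) + 1);

  std::vector<int> scratch(64);  // coplayer sampling buffer (resized on demand)

  for (long long t = 0; t < n_steps; ++t) {
    const int i = runif_int(N);
    double pay = 0.0;

    if (scheme == 0) {
      // single game: d-1 coplayers without replacement
      int k = 0;
      if (well_mixed) {
        // rejection sampling of distinct non-focal ids (d << N)
        int picked[8];
        for (int c = 0; c < need; ++c) {
          int cand;
          bool dup;
          do {
            cand = runif_int(N);
            dup = (cand == i);
            for (int q = 0; q < c && !dup; ++q) dup = (cand == picked[q]);
          } while (dup);
          picked[c] = cand;
          k += s[cand];
        }
      } else {
        const int deg = offs[i + 1] - offs[i];
        if (deg == need) {
          for (int q = offs[i]; q < offs[i + 1]; ++q) k += s[adj[q]];
        } else {
          // partial Fisher-Yates over the neighbour slice
          if ((int)scratch.size() < deg) scratch.resize(deg);
          for (int q = 0; q < deg; ++q) scratch[q] = adj[offs[i] + q];
          for (int c = 0; c < need; ++c) {
            int j = c + runif_int(deg - c);
            std::swap(scratch[c], scratch[j]);
            k += s[scratch[c]];
          }
        }
      }
      pay = s[i] ? a[k] : b[k];
    } else {
      // averaged scheme: the focal's payoff in the games organised by itself
      // and by each neighbour; organiser's game = organiser + its full
      // neighbourhood (degree d-1), focal's coplayers = the other d-1 members
      double tot = 0.0;
      int k_own = 0;
      for (int q = offs[i]; q < offs[i + 1]; ++q) k_own += s[adj[q]];
      tot += s[i] ? a[k_own] : b[k_own];
      for (int q = offs[i]; q < offs[i + 1]; ++q) {
        const int o = adj[q];
        int kA = s[o];
        for (int r = offs[o]; r < offs[o + 1]; ++r) kA += s[adj[r]];
        kA -= s[i];  // exclude the focal itself
        tot += s[i] ? a[kA] : b[kA];
      }
      pay = tot / d;
    }

    const double pflip = fermi(beta * (e[i] - pay));
    if (unif_rand() < pflip) {
      countA += s[i] ? -1 : 1;
      s[i] = 1 - s[i];
    }

    if (t >= burn_in) {
      const long long u = t - burn_in;
      const double x = (double)countA / N;
      abund_sum += x;
      if (batch_len > 0) {
        const long long bidx = u / batch_len;
        if (bidx < n_batches) batch_sum[(size_t)bidx] += x;
      }
      if (thin > 0 && u % thin == 0) traj.push_back(x);
    }
  }

  const double mean_x = (double)(abund_sum / (long double)T);
  double se = NA_REAL;
  if (batch_len > 1 && n_batches > 1) {
    double mb = 0.0;
    for (int bdx = 0; bdx < n_batches; ++bdx) {
      batch_sum[bdx] /= batch_len;
      mb += batch_sum[bdx];
    }
    mb /= n_batches;
    double ss = 0.0;
    for (int bdx = 0; bdx < n_batches; ++bdx) {
      const double dev = batch_sum[bdx] - mb;
      ss += dev * dev;
    }
    se = std::sqrt(ss / (n_batches - 1.0) / n_batches);
  }

  return List::create(
    _["mean_abundance_A"] = mean_x,
    _["std_error"] = se,
    _["n_samples"] = (double)T,
    _["final_state"] = IntegerVector(s.begin(), s.end()),
    _["trajectory"] = NumericVector(traj.begin(), traj.end()));
}
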