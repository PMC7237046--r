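#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bases are coded 1=A, 2=C, 3=G, 4=U. Canonical pairs: GC, AU, GU.
// The DP runs in long double: a 401-nt GC-rich window can reach Z ~ 1e500,
// beyond double range, but far inside long double range; no rescaling needed.

static void pair_weights(long double q[5][5], double e_gc, double e_au,
                         double e_gu, double kT) {
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b) q[a][b] = 0.0L;
  q[2][3] = q[3][2] = expl((long double)(-e_gc / kT));
  q[1][4] = q[4][1] = expl((long double)(-e_au / kT));
  q[3][4] = q[4][3] = expl((long double)(-e_gu / kT));
}

// McCaskill-style O(N^3) recursion with hard unpaired constraints.
// Z[i*n+j]  : partition function of subsequence [i..j] (empty structure = 1)
// Zb[i*n+j] : ditto, conditional on pair (i,j); sigma rewards helix stacking.
static long double dp_logz(const int* s, const char* forced, int n,
                           const long double q[5][5], long double sigma,
                           int minhp, std::vector<long double>& Z,
                           std::vector<long double>& Zb) {
  for (int j = 0; j < n; ++j) {
    for (int i = j; i >= 0; --i) {
      long double zb = 0.0L;
      if (j - i - 1 >= minhp && !forced[i] && !forced[j]) {
        long double w = q[s[i]][s[j]];
        if (w > 0.0L) {
          long double zin = (i + 1 <= j - 1) ? Z[(i + 1) * n + (j - 1)] : 1.0L;
          if (sigma != 1.0L && i + 1 < j - 1)
            zin += (sigma - 1.0L) * Zb[(i + 1) * n + (j - 1)];
          zb = w * zin;
        }
      }
      Zb[i * n + j] = zb;
      long double z = (i <= j - 1) ? Z[i * n + (j - 1)] : 1.0L;
      for (int k = i; k <= j - minhp - 1; ++k) {
        long double zbk = Zb[k * n + j];
        if (zbk > 0.0L) z += ((k > i) ? Z[i * n + (k - 1)] : 1.0L) * zbk;
      }
      Z[i * n + j] = z;
    }
  }
  return logl(Z[n - 1]);
}

// [[Rcpp::export]]
double c_log_partition(IntegerVector s, LogicalVector forced, double e_gc,
                       double e_au, double e_gu, double stack_bonus,
                       double kT, int minhp) {
  int n = s.size();
  long double q[5][5];
  pair_weights(q, e_gc, e_au, e_gu, kT);
  long double sigma = expl((long double)(-stack_bonus / kT));
  std::vector<int> si(n);
  std::vector<char> f(n);
  for (int i = 0; i < n; ++i) {
    si[i] = s[i];
    f[i] = forced[i] ? 1 : 0;
  }
  std::vector<long double> Z((size_t)n * n), Zb((size_t)n * n);
  return (double)dp_logz(si.data(), f.data(), n, q, sigma, minhp, Z, Zb);
}

// Opening probability of every width-k footprint [start, start+k), 0-based
// starts 0..n-k; returns p_open per start plus the unconstrained log Z.
// [[Rcpp::export]]
NumericVector c_open_profile(IntegerVector s, int width, double e_gc,
                             double e_au, double e_gu, double stack_bonus,
                             double kT, int minhp) {
  int n = s.size();
  long double q[5][5];
  pair_weights(q, e_gc, e_au, e_gu, kT);
  long double sigma = expl((long double)(-stack_bonus / kT));
  std::vector<int> si(n);
  for (int i = 0; i < n; ++i) si[i] = s[i];
  std::vector<char> f(n, 0);
  std::vector<long double> Z((size_t)n * n), Zb((size_t)n * n);
  long double lz0 = dp_logz(si.data(), f.data(), n, q, sigma, minhp, Z, Zb);
  int m = n - width + 1;
  NumericVector out(m);
  for (int st = 0; st < m; ++st) {
    std::fill(f.begin(), f.end(), 0);
    for (int i = st; i < st + width; ++i) f[i] = 1;
    long double lzc = dp_logz(si.data(), f.data(), n, q, sigma, minhp, Z, Zb);
    out[st] = (double)expl(lzc - lz0);
  }
  out.attr("log_z") = (double)lz0;
  return out;
}
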