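#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Meiosis over one genome: crossover count per chromosome is Poisson with
// mean equal to the chromosome's genetic length in Morgans, crossover
// positions uniform, and the starting parental strand chosen at random.
// Loci must be ordered by (chromosome, position). Uses R's RNG so results
// are governed by set.seed().
static void gamete_into(const int* h1, const int* h2, int* out,
                        const IntegerVector& chr, const NumericVector& pos,
                        double chr_len, int n_loci) {
  int l = 0;
  while (l < n_loci) {
    int c = chr[l];
    int start = l;
    while (l < n_loci && chr[l] == c) ++l; // [start, l) is this chromosome
    int k = (int) R::rpois(chr_len);
    std::vector<double> xo(k);
    for (int j = 0; j < k; ++j) xo[j] = R::unif_rand() * chr_len;
    std::sort(xo.begin(), xo.end());
    int phase = (R::unif_rand() < 0.5) ? 0 : 1;
    int xi = 0;
    for (int m = start; m < l; ++m) {
      while (xi < k && xo[xi] < pos[m]) { phase ^= 1; ++xi; }
      out[m] = phase == 0 ? h1[m] : h2[m];
    }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_gamete(IntegerVector h1, IntegerVector h2,
                         IntegerVector chr, NumericVector pos,
                         double chr_len) {
  int n_loci = h1.size();
  IntegerVector out(n_loci);
  gamete_into(h1.begin(), h2.begin(), out.begin(), chr, pos, chr_len, n_loci);
  return out;
}

// Produce offspring haplotypes: offspring i receives one gamete from
// sire[i] and one from dam[i] (1-based individual indices into H, which has
// two rows per individual: individual j occupies rows 2j-1 and 2j).
// [[Rcpp::export]]
IntegerMatrix cpp_breed(IntegerMatrix H, IntegerVector sire, IntegerVector dam,
                        IntegerVector chr, NumericVector pos, double chr_len) {
  int n_off = sire.size();
  int n_loci = H.ncol();
  IntegerMatrix out(2 * n_off, n_loci);
  // work on transposed copies so each haplotype is contiguous
  std::vector<int> buf1(n_loci), buf2(n_loci), gam(n_loci);
  for (int i = 0; i < n_off; ++i) {
    for (int par = 0; par < 2; ++par) {
      int p = (par == 0 ? sire[i] : dam[i]) - 1;
      for (int m = 0; m < n_loci; ++m) {
        buf1[m] = H(2 * p, m);
        buf2[m] = H(2 * p + 1, m);
      }
      gamete_into(buf1.data(), buf2.data(), gam.data(), chr, pos, chr_len,
                  n_loci);
      for (int m = 0; m < n_loci; ++m) out(2 * i + par, m) = gam[m];
    }
  }
  return out;
}

// Tabular (recursive) additive relationship matrix. sire/dam are 0 for
// unknown, otherwise 1-based indices of earlier individuals.
// [[Rcpp::export]]
NumericMatrix cpp_tabular_A(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(j, s);
      if (d >= 0) a += 0.5 * A(j, d);
      A(i, j) = A(j, i) = a;
    }
    A(i, i) = 1.0 + (s >= 0 && d >= 0 ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}

// ROH-segment coancestry f_R over all pairs of individuals (including the
// diagonal's four ordered self gamete pairs). For each of the four ordered
// gamete pairs, maximal runs of contiguous identical markers are found
// (runs never span chromosome boundaries); runs of at least min_run markers
// contribute their marker-count length; f_R = contributed length / (4M).
static double run_share(const int* a, const int* b, const IntegerVector& chr,
                        int n_loci, int min_run) {
  double total = 0.0;
  int run = 0;
  int prev_chr = -1;
  for (int m = 0; m < n_loci; ++m) {
    if (chr[m] != prev_chr) {
      if (run >= min_run) total += run;
      run = 0;
      prev_chr = chr[m];
    }
    if (a[m] == b[m]) {
      ++run;
    } else {
      if (run >= min_run) total += run;
      run = 0;
    }
  }
  if (run >= min_run) total += run;
  return total;
}

// [[Rcpp::export]]
NumericMatrix cpp_roh_f(IntegerMatrix H, IntegerVector chr, int min_run) {
  int n = H.nrow() / 2;
  int M = H.ncol();
  NumericMatrix F(n, n);
  // contiguous per-gamete storage
  std::vector<std::vector<int>> G(2 * n, std::vector<int>(M));
  for (int r = 0; r < 2 * n; ++r)
    for (int m = 0; m < M; ++m) G[r][m] = H(r, m);
  for (int i = 0; i < n; ++i) {
    for (int k = i; k < n; ++k) {
      double s = 0.0;
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b)
          s += run_share(G[2 * i + a].data(), G[2 * k + b].data(), chr, M,
                         min_run);
      double f = s / (4.0 * M);
      F(i, k) = F(k, i) = f;
    }
  }
  return F;
}
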