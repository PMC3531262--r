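#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Diploid haplotype-copying HMM, forward-backward.
//
// Hidden state at each locus: an ordered pair (j,k) of reference haplotypes
// the two chromosomes of the test animal are copying from. Per interval the
// two copying processes switch independently: stay with probability 1-rho,
// otherwise jump to a uniformly chosen haplotype (including the current
// one), i.e. a Li-Stephens transition kernel. Emission at a typed locus is
// the probability of the observed unphased genotype given the state's two
// template alleles, each read through an allele-error channel with flip
// probability eps. Untyped or missing loci emit uniformly.
//
// The pair kernel factorises: with P the K x K state distribution, row sums
// r and total S, one transition step is
//   P'[j,k] = a^2 P[j,k] + a b (r[j] + c[k]) + b^2 S,  a = 1-rho, b = rho/K,
// so a locus costs O(K^2). P is symmetric throughout (symmetric start,
// kernel and emissions), hence c = r. Instead of rescaling the matrix per
// locus, the 1/S normalisation is folded into the kernel constants, which
// keeps every locus to a single fused read/write sweep. Forward matrices
// for the whole chromosome stay in memory (L*K*K doubles) so posteriors at
// every locus come out of one backward sweep.

// [[Rcpp::export]]
List diploid_fb_cpp(IntegerMatrix H, IntegerVector obs, NumericVector rho,
                    double eps) {
  const int K = H.nrow();
  const int L = H.ncol();
  if (K < 2) stop("need at least 2 reference haplotypes");
  if (obs.size() != L) stop("obs length must match marker count");
  if (rho.size() != L - 1 && L > 1) stop("rho must have L-1 entries");

  // em[a1][a2][g]: P(observed genotype g | template alleles a1, a2);
  // the same table serves as the predictive error channel.
  const double p1[2] = {eps, 1.0 - eps};
  double em[2][2][3];
  for (int a1 = 0; a1 < 2; ++a1)
    for (int a2 = 0; a2 < 2; ++a2) {
      const double q1 = p1[a1], q2 = p1[a2];
      em[a1][a2][0] = (1 - q1) * (1 - q2);
      em[a1][a2][1] = q1 * (1 - q2) + (1 - q1) * q2;
      em[a1][a2][2] = q1 * q2;
    }

  const size_t KK = (size_t)K * K;
  const int* hbase = INTEGER(H);
  std::vector< std::vector<double> > fwd(L, std::vector<double>(KK));
  std::vector<double> r(K), rnew(K), e0(K), e1(K);
  double S;

  // per-locus emission factors by template-allele of the second haplotype
  auto build_emission = [&](int m) {
    const int g = obs[m];
    const int* hcol = hbase + (size_t)m * K;
    if (g < 0) {
      std::fill(e0.begin(), e0.end(), 1.0);
      std::fill(e1.begin(), e1.end(), 1.0);
    } else {
      for (int k = 0; k < K; ++k) {
        e0[k] = em[0][hcol[k]][g];
        e1[k] = em[1][hcol[k]][g];
      }
    }
  };

  // forward, locus 0
  {
    build_emission(0);
    const int* hcol = hbase;
    double* F = fwd[0].data();
    S = 0.0;
    for (int j = 0; j < K; ++j) {
      const double* erow = hcol[j] ? e1.data() : e0.data();
      double acc = 0.0;
      double* Frow = F + (size_t)j * K;
      for (int k = 0; k < K; ++k) {
        Frow[k] = erow[k];
        acc += erow[k];
      }
      r[j] = acc;
      S += acc;
    }
    if (S <= 0) stop("forward underflow at locus 1");
  }
  // forward, loci 2..L
  for (int m = 1; m < L; ++m) {
    build_emission(m);
    const int* hcol = hbase + (size_t)m * K;
    const double a = 1.0 - rho[m - 1], b = rho[m - 1] / K;
    const double A2 = a * a / S, AB = a * b / S, B2 = b * b;
    const double* P = fwd[m - 1].data();
    double* F = fwd[m].data();
    double Snew = 0.0;
    for (int j = 0; j < K; ++j) {
      const double* erow = hcol[j] ? e1.data() : e0.data();
      const double* Prow = P + (size_t)j * K;
      double* Frow = F + (size_t)j * K;
      const double rj = r[j];
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        const double v = (A2 * Prow[k] + AB * (rj + r[k]) + B2) * erow[k];
        Frow[k] = v;
        acc += v;
      }
      rnew[j] = acc;
      Snew += acc;
    }
    if (Snew <= 0) stop("forward underflow at locus %d", m + 1);
    r.swap(rnew);
    S = Snew;
  }

  // backward sweep with in-place messages; posteriors on the way down
  NumericMatrix post(3, L);
  IntegerMatrix phased(2, L);
  std::vector<double> bwd(KK, 1.0), rb(K);
  for (int m = L - 1; m >= 0; --m) {
    build_emission(m);
    const int* hcol = hbase + (size_t)m * K;
    const double* F = fwd[m].data();

    // one read pass: posterior accumulators + emission-folded row sums
    double s00 = 0.0, s01 = 0.0, s11 = 0.0, tot = 0.0, Sb = 0.0;
    double best = -1.0;
    int bj = 0, bk = 0;
    for (int j = 0; j < K; ++j) {
      const int aj = hcol[j];
      const double* erow = aj ? e1.data() : e0.data();
      const double* Frow = F + (size_t)j * K;
      const double* Brow = bwd.data() + (size_t)j * K;
      double s0 = 0.0, s1 = 0.0, sm = 0.0, racc = 0.0;
      for (int k = 0; k < K; ++k) {
        const double g = Frow[k] * Brow[k];
        const int t = aj + hcol[k];
        if (t == 0) s0 += g;
        else if (t == 1) sm += g;
        else s1 += g;
        if (g > best) { best = g; bj = j; bk = k; }
        racc += Brow[k] * erow[k];
      }
      s00 += s0; s01 += sm; s11 += s1;
      rb[j] = racc;
      Sb += racc;
    }
    tot = s00 + s01 + s11;
    if (tot <= 0) stop("posterior underflow at locus %d", m + 1);
    s00 /= tot; s01 /= tot; s11 /= tot;
    for (int g = 0; g < 3; ++g) {
      post(g, m) = s00 * em[0][0][g] + s01 * em[0][1][g] + s11 * em[1][1][g];
    }
    phased(0, m) = hcol[bj];
    phased(1, m) = hcol[bk];

    if (m > 0) {
      if (Sb <= 0) stop("backward underflow at locus %d", m + 1);
      const double a = 1.0 - rho[m - 1], b = rho[m - 1] / K;
      const double A2 = a * a / Sb, AB = a * b / Sb, B2 = b * b;
      for (int j = 0; j < K; ++j) {
        const double* erow = hcol[j] ? e1.data() : e0.data();
        double* Brow = bwd.data() + (size_t)j * K;
        const double rj = rb[j];
        for (int k = 0; k < K; ++k) {
          Brow[k] = A2 * Brow[k] * erow[k] + AB * (rj + rb[k]) + B2;
        }
      }
    }
  }

  return List::create(_["posterior"] = post, _["phased"] = phased);
}
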