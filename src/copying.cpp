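#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Li-Stephens-style haplotype-copying HMM.
// States: the H reference haplotypes.  Transition across a gap of d bp:
//   P(h -> h') = exp(-lambda d) * 1{h == h'} + (1 - exp(-lambda d)) / H
// Emission: 1 - eps on allele match, eps on mismatch.
// Posterior state weights are read at one context-SNP index (the one
// nearest the query position; ties resolved to the left).

static void normalize(std::vector<double>& v) {
  double tot = 0.0;
  for (double x : v) tot += x;
  if (tot <= 0.0) {
    double u = 1.0 / v.size();
    for (double& x : v) x = u;
  } else {
    for (double& x : v) x /= tot;
  }
}

// Posterior over reference haplotypes at context index t (0-based).
static std::vector<double> fb_gamma(const IntegerMatrix& haps,
                                    const std::vector<int>& refs,
                                    const std::vector<int>& target,
                                    const NumericVector& pos,
                                    int t, double lambda, double eps) {
  const int H = refs.size();
  const int S = target.size();
  std::vector<double> alpha(H), nxt(H), beta(H, 1.0), eb(H);

  for (int h = 0; h < H; ++h) {
    alpha[h] = (haps(refs[h], 0) == target[0] ? 1.0 - eps : eps) / H;
  }
  normalize(alpha);
  for (int s = 1; s <= t; ++s) {
    double rho = std::exp(-lambda * (pos[s] - pos[s - 1]));
    for (int h = 0; h < H; ++h) {
      double e = (haps(refs[h], s) == target[s]) ? 1.0 - eps : eps;
      nxt[h] = e * (rho * alpha[h] + (1.0 - rho) / H);
    }
    alpha.swap(nxt);
    normalize(alpha);
  }
  for (int s = S - 2; s >= t; --s) {
    double rho = std::exp(-lambda * (pos[s + 1] - pos[s]));
    double acc = 0.0;
    for (int h = 0; h < H; ++h) {
      eb[h] = ((haps(refs[h], s + 1) == target[s + 1]) ? 1.0 - eps : eps) * beta[h];
      acc += eb[h];
    }
    for (int h = 0; h < H; ++h) {
      nxt[h] = rho * eb[h] + (1.0 - rho) * acc / H;
    }
    beta.swap(nxt);
    normalize(beta);
  }
  std::vector<double> gamma(H);
  for (int h = 0; h < H; ++h) gamma[h] = alpha[h] * beta[h];
  normalize(gamma);
  return gamma;
}

static int query_index(const NumericVector& pos, double qpos) {
  int t = 0;
  double best = std::abs(pos[0] - qpos);
  for (int s = 1; s < pos.size(); ++s) {
    double d = std::abs(pos[s] - qpos);
    if (d < best) { best = d; t = s; }   // strict: ties keep the left index
  }
  return t;
}

// [[Rcpp::export]]
NumericVector copying_weights_cpp(IntegerMatrix ref_haps, IntegerVector target,
                                  NumericVector positions, double query_pos,
                                  double lambda, double eps) {
  const int H = ref_haps.nrow();
  const int S = ref_haps.ncol();
  std::vector<int> refs(H), tgt(S);
  for (int h = 0; h < H; ++h) refs[h] = h;
  for (int s = 0; s < S; ++s) tgt[s] = target[s];
  int t = query_index(positions, query_pos);
  std::vector<double> g = fb_gamma(ref_haps, refs, tgt, positions, t, lambda, eps);
  return NumericVector(g.begin(), g.end());
}

// Leave-one-individual-out genotype posteriors for one focal variant.
// haps: (2N x S) context-SNP alleles for all haplotypes; indel: (2N) focal
// alleles.  For sample i, rows 2i and 2i+1 are the target pair and are
// removed from the reference set.  Returns N x 4: p_refref, p_refalt,
// p_altalt, skip (1 when the focal variant is monomorphic among the
// remaining reference haplotypes).
// [[Rcpp::export]]
NumericMatrix loo_posteriors_cpp(IntegerMatrix haps, IntegerVector indel,
                                 NumericVector positions, double query_pos,
                                 double lambda, double eps) {
  const int nh = haps.nrow();
  const int S = haps.ncol();
  const int N = nh / 2;
  const int t = query_index(positions, query_pos);
  NumericMatrix out(N, 4);
  std::vector<int> refs(nh - 2), tgt(S);

  for (int i = 0; i < N; ++i) {
    int r1 = 2 * i, r2 = 2 * i + 1;
    int k = 0;
    int first = -1;
    bool poly = false;
    for (int r = 0; r < nh; ++r) {
      if (r == r1 || r == r2) continue;
      refs[k++] = r;
      if (first < 0) first = indel[r];
      else if (indel[r] != first) poly = true;
    }
    if (!poly) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
      out(i, 3) = 1.0;
      continue;
    }
    double pa[2];
    int targets[2] = {r1, r2};
    for (int w = 0; w < 2; ++w) {
      for (int s = 0; s < S; ++s) tgt[s] = haps(targets[w], s);
      std::vector<double> g = fb_gamma(haps, refs, tgt, positions, t, lambda, eps);
      double p = 0.0;
      for (size_t h = 0; h < refs.size(); ++h) p += g[h] * indel[refs[h]];
      pa[w] = p;
    }
    out(i, 0) = (1.0 - pa[0]) * (1.0 - pa[1]);
    out(i, 1) = pa[0] * (1.0 - pa[1]) + (1.0 - pa[0]) * pa[1];
    out(i, 2) = pa[0] * pa[1];
    out(i, 3) = 0.0;
  }
  return out;
}
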