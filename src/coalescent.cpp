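// Coalescent machinery for unlinked biallelic SNP loci.
//
// Each locus is an independent Kingman coalescent with a single mutation
// placed on the tree with probability proportional to branch length,
// redrawn until the pooled-sample minor allele frequency passes the
// ascertainment threshold.  Only subtree leaf counts are tracked, never
// the full topology: every coalescence event finalizes the two child
// branches (length and per-deme leaf counts), which is all that mutation
// placement needs.  Gene copies are paired at random into diploids within
// demes.  Buffers are reused across loci; R's RNG is used throughout so
// set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Block {
  int d1;        // sampled leaves below this lineage, deme 1
  int d2;        // sampled leaves below this lineage, deme 2
  double birth;  // time (generations back) the lineage came into being
};

struct Branch {
  double len;
  int d1, d2;
};

// Coalesce blocks[0..k) within a single pool of constant diploid size N
// from time t until t_end (possibly infinite); finalized branches are
// appended.  Returns the time reached; k is updated in place.
double coalesce_pool(std::vector<Block>& blocks, int& k, double N, double t,
                     double t_end, std::vector<Branch>& branches) {
  while (k > 1) {
    double rate = (double)k * (k - 1) / (4.0 * N);
    double dt = R::exp_rand() / rate;
    if (t + dt >= t_end) return t_end;
    t += dt;
    int i = (int)(unif_rand() * k);
    int j = (int)(unif_rand() * (k - 1));
    if (j >= i) j++;
    branches.push_back({t - blocks[i].birth, blocks[i].d1, blocks[i].d2});
    branches.push_back({t - blocks[j].birth, blocks[j].d1, blocks[j].d2});
    blocks[i].d1 += blocks[j].d1;
    blocks[i].d2 += blocks[j].d2;
    blocks[i].birth = t;
    blocks[j] = blocks[k - 1];
    k--;
  }
  return t;
}

// Random gamete pairing: writes n diploid dosages built from 2n gene
// copies of which d carry the derived allele; `alleles` is scratch.
void pair_dosages(int n, int d, int* out, std::vector<int>& alleles) {
  int g = 2 * n;
  alleles.assign(g, 0);
  for (int i = 0; i < d; i++) alleles[i] = 1;
  for (int i = g - 1; i > 0; i--) {  // Fisher-Yates
    int j = (int)(unif_rand() * (i + 1));
    int tmp = alleles[i]; alleles[i] = alleles[j]; alleles[j] = tmp;
  }
  for (int i = 0; i < n; i++) out[i] = alleles[2 * i] + alleles[2 * i + 1];
}

}  // namespace

//' @name sim_two_deme_genotypes
//' @title Simulate SNP genotypes under a two-deme piecewise-constant scenario
//' @description Internal workhorse. Two isolated demes of diploid sizes
//'   \code{N1}, \code{N2} from the present back to \code{epoch_t[1]}, where
//'   lineages merge into an ancestral deme following the piecewise-constant
//'   sizes \code{epoch_N} on the epochs starting at \code{epoch_t} (the
//'   last epoch extends to infinity).
//' @return integer dosage matrix, (n1 + n2) individuals x n_loci loci
//'   (deme-1 individuals first); attribute \code{redraws} counts rejected
//'   trees under MAF ascertainment.
//' @keywords internal
// [[Rcpp::export(name = ".sim_two_deme_genotypes")]]
IntegerMatrix sim_two_deme_genotypes(int n1, int n2, double N1, double N2,
                                     NumericVector epoch_t,
                                     NumericVector epoch_N,
                                     int n_loci, double min_maf,
                                     int max_redraw) {
  IntegerMatrix out(n1 + n2, n_loci);
  int* outp = INTEGER(out);
  int n_ind = n1 + n2;
  int total_genes = 2 * n_ind;
  long redraws = 0;
  double t_div = epoch_t[0];
  int n_epochs = epoch_t.size();

  std::vector<Branch> branches;
  branches.reserve(2 * total_genes);
  std::vector<Block> b1(2 * n1), b2(2 * n2), pool(total_genes);
  std::vector<int> buf1(std::max(n1, 1)), buf2(std::max(n2, 1)), alleles;
  alleles.reserve(total_genes);

  for (int l = 0; l < n_loci; l++) {
    int tries = 0;
    for (;;) {
      if (++tries > max_redraw + 1)
        stop("MAF ascertainment failed after %d redraws at locus %d",
             max_redraw, l + 1);
      branches.clear();
      int k1 = 2 * n1, k2 = 2 * n2;
      for (int i = 0; i < k1; i++) b1[i] = {1, 0, 0.0};
      for (int i = 0; i < k2; i++) b2[i] = {0, 1, 0.0};
      if (k1 > 0) coalesce_pool(b1, k1, N1, 0.0, t_div, branches);
      if (k2 > 0) coalesce_pool(b2, k2, N2, 0.0, t_div, branches);
      int k = k1 + k2;
      for (int i = 0; i < k1; i++) pool[i] = b1[i];
      for (int i = 0; i < k2; i++) pool[k1 + i] = b2[i];
      double t = t_div;
      for (int e = 0; e < n_epochs && k > 1; e++) {
        double t_end = (e + 1 < n_epochs) ? epoch_t[e + 1] : R_PosInf;
        t = coalesce_pool(pool, k, epoch_N[e], t, t_end, branches);
      }
      // single mutation, uniform on total branch length
      double L = 0.0;
      size_t nb = branches.size();
      for (size_t b = 0; b < nb; b++) L += branches[b].len;
      double u = unif_rand() * L, acc = 0.0;
      size_t chosen = nb - 1;
      for (size_t b = 0; b < nb; b++) {
        acc += branches[b].len;
        if (u <= acc) { chosen = b; break; }
      }
      int d1 = branches[chosen].d1, d2 = branches[chosen].d2;
      int d = d1 + d2;
      double maf = std::min(d, total_genes - d) / (double)total_genes;
      if (maf >= min_maf - 1e-12) {
        if (n1 > 0) pair_dosages(n1, d1, buf1.data(), alleles);
        if (n2 > 0) pair_dosages(n2, d2, buf2.data(), alleles);
        int* col = outp + (size_t)l * n_ind;
        for (int i = 0; i < n1; i++) col[i] = buf1[i];
        for (int i = 0; i < n2; i++) col[n1 + i] = buf2[i];
        redraws += tries - 1;
        break;
      }
    }
  }
  out.attr("redraws") = (double)redraws;
  return out;
}

//' @name sim_island_genotypes
//' @title Simulate SNP genotypes under a finite-island coalescent
//' @description Internal. \code{n_demes} demes of diploid size \code{N};
//'   per-lineage migration rate \code{m} per generation to a uniformly
//'   chosen other deme. The first \code{length(samp)} demes are sampled
//'   with \code{samp} diploids each. Single-mutation SNPs with pooled-MAF
//'   ascertainment as in the two-deme simulator.
//' @return integer dosage matrix, sum(samp) individuals x n_loci loci
//'   (individuals blocked by sampled deme).
//' @keywords internal
// [[Rcpp::export(name = ".sim_island_genotypes")]]
IntegerMatrix sim_island_genotypes(int n_demes, IntegerVector samp, double N,
                                   double m, int n_loci, double min_maf,
                                   int max_redraw) {
  int s = samp.size();
  if (s > n_demes) stop("more sampled demes than demes");
  int n_ind = 0;
  for (int i = 0; i < s; i++) n_ind += samp[i];
  int total_genes = 2 * n_ind;
  IntegerMatrix out(n_ind, n_loci);
  int* outp = INTEGER(out);

  // flat buffers: per-block deme-count vectors with stride s
  std::vector<int> bd(total_genes * s);        // block leaf counts
  std::vector<double> bbirth(total_genes);
  std::vector<int> bdeme(total_genes);
  std::vector<double> brlen; brlen.reserve(4 * total_genes);
  std::vector<int> brd; brd.reserve(4 * total_genes * s);
  std::vector<int> k(n_demes);
  std::vector<int> buf(total_genes), alleles;
  alleles.reserve(total_genes);

  for (int l = 0; l < n_loci; l++) {
    int tries = 0;
    for (;;) {
      if (++tries > max_redraw + 1)
        stop("MAF ascertainment failed after %d redraws at locus %d",
             max_redraw, l + 1);
      int K = 0;
      for (int i = 0; i < s; i++)
        for (int g = 0; g < 2 * samp[i]; g++) {
          for (int q = 0; q < s; q++) bd[K * s + q] = 0;
          bd[K * s + i] = 1;
          bbirth[K] = 0.0;
          bdeme[K] = i;
          K++;
        }
      std::fill(k.begin(), k.end(), 0);
      for (int i = 0; i < s; i++) k[i] = 2 * samp[i];
      brlen.clear();
      brd.clear();
      double t = 0.0;
      while (K > 1) {
        double coal = 0.0;
        for (int d0 = 0; d0 < n_demes; d0++)
          coal += (double)k[d0] * (k[d0] - 1);
        coal /= 4.0 * N;
        double rate = coal + K * m;
        t += R::exp_rand() / rate;
        if (unif_rand() * rate < coal) {
          double u = unif_rand() * coal * 4.0 * N, acc = 0.0;
          int deme = 0;
          for (int d0 = 0; d0 < n_demes; d0++) {
            acc += (double)k[d0] * (k[d0] - 1);
            if (u <= acc) { deme = d0; break; }
          }
          int a = (int)(unif_rand() * k[deme]);
          int b = (int)(unif_rand() * (k[deme] - 1));
          if (b >= a) b++;
          int ii = -1, jj = -1, seen = 0;
          for (int q = 0; q < K; q++) {
            if (bdeme[q] == deme) {
              if (seen == a) ii = q;
              if (seen == b) jj = q;
              seen++;
              if (ii >= 0 && jj >= 0 && seen > std::max(a, b)) break;
            }
          }
          brlen.push_back(t - bbirth[ii]);
          for (int q = 0; q < s; q++) brd.push_back(bd[ii * s + q]);
          brlen.push_back(t - bbirth[jj]);
          for (int q = 0; q < s; q++) brd.push_back(bd[jj * s + q]);
          for (int q = 0; q < s; q++) bd[ii * s + q] += bd[jj * s + q];
          bbirth[ii] = t;
          // move last block into slot jj
          for (int q = 0; q < s; q++) bd[jj * s + q] = bd[(K - 1) * s + q];
          bbirth[jj] = bbirth[K - 1];
          bdeme[jj] = bdeme[K - 1];
          K--;
          k[deme]--;
        } else {
          int q = (int)(unif_rand() * K);
          int from = bdeme[q];
          int to = (int)(unif_rand() * (n_demes - 1));
          if (to >= from) to++;
          bdeme[q] = to;
          k[from]--; k[to]++;
        }
      }
      size_t nb = brlen.size();
      double L = 0.0;
      for (size_t b = 0; b < nb; b++) L += brlen[b];
      double u = unif_rand() * L, acc = 0.0;
      size_t chosen = nb - 1;
      for (size_t b = 0; b < nb; b++) {
        acc += brlen[b];
        if (u <= acc) { chosen = b; break; }
      }
      int d = 0;
      for (int q = 0; q < s; q++) d += brd[chosen * s + q];
      double maf = std::min(d, total_genes - d) / (double)total_genes;
      if (maf >= min_maf - 1e-12) {
        int* col = outp + (size_t)l * n_ind;
        int row = 0;
        for (int q = 0; q < s; q++) {
          pair_dosages(samp[q], (int)brd[chosen * s + q], buf.data(),
                       alleles);
          for (int i = 0; i < samp[q]; i++) col[row++] = buf[i];
        }
        break;
      }
    }
  }
  return out;
}

//' @name sim_pair_tmrca
//' @title Pairwise coalescence times in a constant-size deme
//' @description Internal. Simulates a sample of \code{n} gene copies in one
//'   deme of constant diploid size \code{N} and records the coalescence
//'   time of the first two sampled copies (their TMRCA), per replicate.
//' @keywords internal
// [[Rcpp::export(name = ".sim_pair_tmrca")]]
NumericVector sim_pair_tmrca(int n, double N, int reps) {
  NumericVector out(reps);
  for (int r = 0; r < reps; r++) {
    int blk0 = 0, blk1 = 1;
    int k = n;
    double t = 0.0;
    while (blk0 != blk1) {
      double rate = (double)k * (k - 1) / (4.0 * N);
      t += R::exp_rand() / rate;
      int i = (int)(unif_rand() * k);
      int j = (int)(unif_rand() * (k - 1));
      if (j >= i) j++;
      if (i > j) { int tmp = i; i = j; j = tmp; }
      // block j is absorbed into block i; the last block moves to slot j
      if (blk0 == j) blk0 = i; else if (blk0 == k - 1) blk0 = j;
      if (blk1 == j) blk1 = i; else if (blk1 == k - 1) blk1 = j;
      k--;
    }
    out[r] = t;
  }
  return out;
}

//' @name null_loglik_samples
//' @title Monte-Carlo null distribution of genotype log-likelihood sums
//' @description Internal. Given per-locus HWE genotype probabilities
//'   (columns: P(0), P(1), P(2) copies of the alternate allele), simulates
//'   \code{B} multilocus genotypes and returns their summed log10
//'   likelihoods.
//' @keywords internal
// [[Rcpp::export(name = ".null_loglik_samples")]]
NumericVector null_loglik_samples(NumericMatrix gp, int B) {
  int L = gp.nrow();
  std::vector<double> c0(L), c1(L), l0(L), l1(L), l2(L);
  for (int i = 0; i < L; i++) {
    double s = gp(i, 0) + gp(i, 1) + gp(i, 2);
    c0[i] = gp(i, 0) / s;
    c1[i] = (gp(i, 0) + gp(i, 1)) / s;
    l0[i] = log10(gp(i, 0) / s);
    l1[i] = log10(gp(i, 1) / s);
    l2[i] = log10(gp(i, 2) / s);
  }
  NumericVector out(B);
  for (int b = 0; b < B; b++) {
    double acc = 0.0;
    for (int i = 0; i < L; i++) {
      double u = unif_rand();
      acc += (u < c0[i]) ? l0[i] : (u < c1[i] ? l1[i] : l2[i]);
    }
    out[b] = acc;
  }
  return out;
}
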