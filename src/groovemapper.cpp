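// Compiled kernels: best-fit (Kabsch/Theobald-style) pairwise RMSD over a
// frame cube and epsilon-terminated average-linkage agglomeration.  Both
// are the hot loops of the conformer-population analysis; everything else
// stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Eigenvalues of a symmetric 3x3 matrix, descending, by the trigonometric
// closed form (no LAPACK call; this runs ~n_frames^2 / 2 times).
static inline void sym3_eigvals(const double K[3][3], double eig[3]) {
  const double q = (K[0][0] + K[1][1] + K[2][2]) / 3.0;
  const double p1 = K[0][1] * K[0][1] + K[0][2] * K[0][2] +
                    K[1][2] * K[1][2];
  const double a = K[0][0] - q, b = K[1][1] - q, c = K[2][2] - q;
  const double p2 = a * a + b * b + c * c + 2.0 * p1;
  if (p2 <= 0.0) {
    eig[0] = eig[1] = eig[2] = q;
    return;
  }
  const double p = std::sqrt(p2 / 6.0);
  // r = det((K - qI) / p) / 2
  const double b00 = a / p, b11 = b / p, b22 = c / p;
  const double b01 = K[0][1] / p, b02 = K[0][2] / p, b12 = K[1][2] / p;
  double r = (b00 * (b11 * b22 - b12 * b12) -
              b01 * (b01 * b22 - b12 * b02) +
              b02 * (b01 * b12 - b11 * b02)) / 2.0;
  r = std::max(-1.0, std::min(1.0, r));
  const double phi = std::acos(r) / 3.0;
  eig[0] = q + 2.0 * p * std::cos(phi);
  eig[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  eig[1] = 3.0 * q - eig[0] - eig[2];
}

// Best-fit RMSD of two centered n x 3 coordinate sets, reflections
// excluded: singular values of H = A'B are the square roots of the
// eigenvalues of H'H, and det(H) < 0 flips the sign of the smallest.
static double pair_rmsd(const arma::mat& A, const arma::mat& B,
                        double e0a, double e0b) {
  double H[3][3];
  const int n = A.n_rows;
  const double* a = A.memptr();
  const double* b = B.memptr();
  for (int p = 0; p < 3; ++p)
    for (int q = 0; q < 3; ++q) {
      double s = 0.0;
      const double* ap = a + p * n;
      const double* bq = b + q * n;
      for (int i = 0; i < n; ++i) s += ap[i] * bq[i];
      H[p][q] = s;
    }
  const double detH =
      H[0][0] * (H[1][1] * H[2][2] - H[1][2] * H[2][1]) -
      H[0][1] * (H[1][0] * H[2][2] - H[1][2] * H[2][0]) +
      H[0][2] * (H[1][0] * H[2][1] - H[1][1] * H[2][0]);
  double K[3][3];
  for (int p = 0; p < 3; ++p)
    for (int q = p; q < 3; ++q) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += H[k][p] * H[k][q];
      K[p][q] = K[q][p] = s;
    }
  double eig[3];
  sym3_eigvals(K, eig);
  double sv[3];
  for (int k = 0; k < 3; ++k) sv[k] = eig[k] > 0 ? std::sqrt(eig[k]) : 0.0;
  double D = sv[0] + sv[1] + (detH < 0 ? -sv[2] : sv[2]);
  double msd = (e0a + e0b - 2.0 * D) / static_cast<double>(n);
  return msd > 0 ? std::sqrt(msd) : 0.0;
}

// [[Rcpp::export]]
NumericMatrix pairwise_rmsd_cpp(const arma::cube& frames) {
  const int nf = frames.n_slices;
  std::vector<arma::mat> cent(nf);
  std::vector<double> e0(nf);
  for (int i = 0; i < nf; ++i) {
    arma::mat X = frames.slice(i);
    X.each_row() -= arma::mean(X, 0);
    cent[i] = X;
    e0[i] = arma::accu(X % X);
  }
  NumericMatrix D(nf, nf);
  for (int i = 0; i < nf; ++i) {
    for (int j = i + 1; j < nf; ++j) {
      double r = pair_rmsd(cent[i], cent[j], e0[i], e0[j]);
      D(i, j) = r;
      D(j, i) = r;
    }
  }
  return D;
}

// Average-linkage agglomeration on a precomputed distance matrix, merging
// the closest active pair while the minimum inter-cluster average distance
// is <= epsilon.  Clusters live at the slot of their smallest member index,
// so the documented tie-break (lowest (i, j) index pair) falls out of the
// ascending scan with strict improvement.  Cluster-pair sums of original
// entries are carried exactly; the scanned averages are refreshed only at
// merges, keeping the result comparable with a naive reference
// implementation.
// [[Rcpp::export]]
IntegerVector avg_linkage_cpp(const NumericMatrix& dist, double epsilon) {
  const int n = dist.nrow();
  std::vector<double> S(static_cast<size_t>(n) * n);   // pair sums
  std::vector<double> A(static_cast<size_t>(n) * n);   // pair averages
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      S[static_cast<size_t>(j) * n + i] =
          A[static_cast<size_t>(j) * n + i] = dist(i, j);
  std::vector<int> size(n, 1);
  std::vector<int> slot(n);  // cluster slot per frame
  std::vector<int> act(n);   // active slots, kept ascending
  for (int i = 0; i < n; ++i) slot[i] = act[i] = i;

  while (act.size() > 1) {
    double best = R_PosInf;
    int bi = -1, bj = -1;
    for (size_t a = 0; a < act.size(); ++a) {
      const int i = act[a];
      const double* Ai = &A[static_cast<size_t>(i) * n];
      for (size_t b = a + 1; b < act.size(); ++b) {
        const int j = act[b];
        if (Ai[j] < best) {
          best = Ai[j];
          bi = i;
          bj = j;
        }
      }
    }
    if (bi < 0 || best > epsilon) break;
    // merge bj into bi (bi < bj, so the merged cluster keeps the smallest
    // member index as its slot)
    const int nsz = size[bi] + size[bj];
    for (size_t a = 0; a < act.size(); ++a) {
      const int k = act[a];
      if (k == bi || k == bj) continue;
      const size_t kbi = static_cast<size_t>(k) * n + bi;
      const size_t bik = static_cast<size_t>(bi) * n + k;
      const double s = S[kbi] + S[static_cast<size_t>(k) * n + bj];
      S[kbi] = S[bik] = s;
      const double avg = s / (static_cast<double>(nsz) * size[k]);
      A[kbi] = A[bik] = avg;
    }
    size[bi] = nsz;
    act.erase(std::lower_bound(act.begin(), act.end(), bj));
    for (int f = 0; f < n; ++f)
      if (slot[f] == bj) slot[f] = bi;
  }
  IntegerVector out(n);
  for (int f = 0; f < n; ++f) out[f] = slot[f] + 1;  // 1-based slot labels
  return out;
}
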