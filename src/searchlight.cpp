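// Compiled kernels for the volumetric searchlight: per-sphere noise
// normalisation + crossnobis distances, and 26-connectivity cluster
// labelling. The R reference implementation of crossnobis is kept in
// R/crossnobis.R and the two are asserted equal in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <unordered_map>
#include <functional>

using namespace Rcpp;

// Schafer-Strimmer analytic shrinkage toward the diagonal target.
// X must be column-centred (per run). Mirrors shrinkage_lambda() in R.
static double shrink_lambda(const arma::mat &X) {
  const double n = (double)X.n_rows;
  if (X.n_rows < 3) return 1.0;
  arma::mat M = (X.t() * X) / n;
  arma::mat A = (arma::pow(X, 2).t() * arma::pow(X, 2));
  arma::mat var_s = n / std::pow(n - 1.0, 3) * (A - n * arma::pow(M, 2));
  arma::mat s = (n / (n - 1.0)) * M;
  double num = arma::accu(var_s) - arma::accu(var_s.diag());
  double den = arma::accu(arma::pow(s, 2)) - arma::accu(arma::pow(s.diag(), 2));
  if (den <= 0.0) return 1.0;
  double lam = num / den;
  if (lam < 0.0) lam = 0.0;
  if (lam > 1.0) lam = 1.0;
  return lam;
}

// betas: (M*C) x V with run-major rows (row (m-1)*C + c), already in signal
// units (not whitened); resid: stacked residual samples x V; resid_run:
// 1-based run id per residual row; spheres: list of 1-based voxel index
// vectors; pi, pj: 1-based condition indices of the pair list.
// Returns centers x npairs crossnobis distances (per-voxel normalised).
// [[Rcpp::export]]
arma::mat cpp_searchlight_rdms(const arma::mat &betas, int M, int C,
                               const arma::mat &resid,
                               const arma::ivec &resid_run,
                               const List &spheres,
                               const arma::uvec &pi_idx,
                               const arma::uvec &pj_idx,
                               double lambda) {
  const int n_centers = spheres.size();
  const int n_pairs = pi_idx.n_elem;
  arma::mat out(n_centers, n_pairs, arma::fill::zeros);

  // per-run residual row indices
  std::vector<arma::uvec> run_rows(M);
  for (int m = 0; m < M; ++m) {
    run_rows[m] = arma::find(resid_run == (m + 1));
  }

  for (int ci = 0; ci < n_centers; ++ci) {
    arma::uvec vox = as<arma::uvec>(spheres[ci]);
    vox -= 1;  // to 0-based
    const int P = vox.n_elem;

    // pooled run-wise covariance of centred residuals
    arma::mat S(P, P, arma::fill::zeros);
    arma::mat stacked(resid.n_rows, P);
    arma::uword row0 = 0;
    for (int m = 0; m < M; ++m) {
      arma::mat R = resid.submat(run_rows[m], vox);
      R.each_row() -= arma::mean(R, 0);
      S += (R.t() * R) / (double)(R.n_rows - 1);
      stacked.rows(row0, row0 + R.n_rows - 1) = R;
      row0 += R.n_rows;
    }
    S /= (double)M;
    for (int p = 0; p < P; ++p) {
      if (S(p, p) <= 0.0) {
        stop("zero-variance voxel in searchlight sphere (voxel %d)",
             (int)vox(p) + 1);
      }
    }
    double lam = lambda < 0 ? shrink_lambda(stacked.rows(0, row0 - 1)) : lambda;
    arma::mat Sigma = (1.0 - lam) * S + lam * arma::diagmat(S.diag());

    arma::vec eval;
    arma::mat evec;
    arma::eig_sym(eval, evec, Sigma);
    if (eval.min() <= 1e-10 * eval.max()) {
      stop("searchlight covariance is not positive definite");
    }
    arma::mat Sinv = evec * arma::diagmat(1.0 / eval) * evec.t();

    // cross-run Gram identity: sum_{m != n} Bm Sinv Bn' =
    //   T Sinv T' - sum_m Bm Sinv Bm', with T = sum_m Bm
    arma::mat T(C, P, arma::fill::zeros);
    arma::mat H(C, C, arma::fill::zeros);
    for (int m = 0; m < M; ++m) {
      arma::mat Bm = betas.rows(m * C, (m + 1) * C - 1).eval().cols(vox);
      T += Bm;
      H -= (Bm * Sinv) * Bm.t();
    }
    H += (T * Sinv) * T.t();
    const double norm = (double)M * (M - 1) * (double)P;
    for (int p = 0; p < n_pairs; ++p) {
      const int i = pi_idx(p) - 1, j = pj_idx(p) - 1;
      out(ci, p) = (H(i, i) + H(j, j) - H(i, j) - H(j, i)) / norm;
    }
  }
  return out;
}

// Label the supplied voxels (1-based linear indices into a dims[0] x dims[1]
// x dims[2] grid) into 26-connectivity clusters. Returns 1-based component
// labels aligned with `idx`.
// [[Rcpp::export]]
IntegerVector cpp_label_clusters(const IntegerVector &idx,
                                 const IntegerVector &dims) {
  const int n = idx.size();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::unordered_map<int, int> pos;  // linear index -> position in idx
  pos.reserve(n * 2);
  for (int k = 0; k < n; ++k) pos[idx[k]] = k;

  std::vector<int> parent(n);
  for (int k = 0; k < n; ++k) parent[k] = k;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  };

  for (int k = 0; k < n; ++k) {
    const int lin = idx[k] - 1;
    const int x = lin % nx;
    const int y = (lin / nx) % ny;
    const int z = lin / (nx * ny);
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          const int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          const int nlin = xx + nx * (yy + ny * zz) + 1;
          auto it = pos.find(nlin);
          if (it == pos.end()) continue;
          int ra = find(k), rb = find(it->second);
          if (ra != rb) parent[rb] = ra;
        }
      }
    }
  }
  // compact labels in first-appearance order
  IntegerVector labels(n);
  std::unordered_map<int, int> relabel;
  int next = 0;
  for (int k = 0; k < n; ++k) {
    int r = find(k);
    auto it = relabel.find(r);
    if (it == relabel.end()) {
      relabel[r] = ++next;
      labels[k] = next;
    } else {
      labels[k] = it->second;
    }
  }
  return labels;
}
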