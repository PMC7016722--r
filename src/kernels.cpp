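// Hot loops behind the R-level API: pairwise Kabsch RMSD, Shrake-Rupley
// point burial, and residue-blocked minimum cross distances.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Pairwise RMSD after optimal superposition, via the Gram/SVD identity:
// rmsd^2(i,j) = (|Xi|^2 + |Xj|^2 - 2 * (s1 + s2 + d*s3)) / n
// with s the singular values of Xi^T Xj (frames pre-centred) and
// d = sign(det) enforcing a proper rotation.
// coords: n_atoms x 3 x n_frames cube (a selection's coordinates, nm).
// [[Rcpp::export]]
arma::mat cpp_pairwise_rmsd(const arma::cube& coords) {
  const arma::uword nf = coords.n_slices;
  const arma::uword na = coords.n_rows;
  arma::cube C = coords;
  arma::vec g(nf);
  for (arma::uword i = 0; i < nf; ++i) {
    arma::rowvec m = arma::mean(C.slice(i), 0);
    C.slice(i).each_row() -= m;
    g(i) = arma::accu(arma::square(C.slice(i)));
  }
  arma::mat out(nf, nf, arma::fill::zeros);
  arma::mat33 M, U, V;
  arma::vec3 s;
  for (arma::uword i = 0; i < nf; ++i) {
    for (arma::uword j = i + 1; j < nf; ++j) {
      M = C.slice(i).t() * C.slice(j);
      if (!arma::svd(U, s, V, M)) Rcpp::stop("SVD failed in pairwise RMSD");
      double d = (arma::det(U) * arma::det(V) < 0.0) ? -1.0 : 1.0;
      double tr = s(0) + s(1) + d * s(2);
      double msd = (g(i) + g(j) - 2.0 * tr) / double(na);
      if (msd < 0) msd = 0;  // numerical guard
      out(i, j) = out(j, i) = std::sqrt(msd);
    }
  }
  return out;
}

// Shrake-Rupley exposed area per atom. xyz: n x 3 (nm) for the atoms whose
// area is evaluated and which mutually occlude; rext: per-atom radius + probe
// (nm); pts: npts x 3 unit-sphere test points (deterministic lattice).
// [[Rcpp::export]]
NumericVector cpp_sasa_atoms(const arma::mat& xyz, const arma::vec& rext,
                             const arma::mat& pts) {
  const arma::uword n = xyz.n_rows;
  const arma::uword np = pts.n_rows;
  NumericVector area(n);
  std::vector<arma::uword> nbr;
  for (arma::uword i = 0; i < n; ++i) {
    const double ri = rext(i);
    nbr.clear();
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i) continue;
      double cut = ri + rext(j);
      if (arma::norm(xyz.row(i) - xyz.row(j)) < cut) nbr.push_back(j);
    }
    arma::uword exposed = 0;
    for (arma::uword p = 0; p < np; ++p) {
      arma::rowvec pos = xyz.row(i) + ri * pts.row(p);
      bool buried = false;
      for (arma::uword k = 0; k < nbr.size(); ++k) {
        const arma::uword j = nbr[k];
        if (arma::norm(pos - xyz.row(j)) < rext(j)) { buried = true; break; }
      }
      if (!buried) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * double(exposed) / double(np);
  }
  return area;
}

// Minimum cross distance per residue pair for one frame.
// A: na x 3, B: nb x 3; ga/gb: 1-based residue group index per atom.
// Returns an nga x ngb matrix of minimum distances (Inf where a group pair
// has no atoms, which cannot happen for groups built from present residues).
// [[Rcpp::export]]
arma::mat cpp_group_min_cross(const arma::mat& A, const arma::mat& B,
                              const arma::ivec& ga, const arma::ivec& gb,
                              int nga, int ngb) {
  arma::mat out(nga, ngb);
  out.fill(arma::datum::inf);
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    const int gi = ga(i) - 1;
    for (arma::uword j = 0; j < B.n_rows; ++j) {
      const int gj = gb(j) - 1;
      double dx = A(i, 0) - B(j, 0);
      double dy = A(i, 1) - B(j, 1);
      double dz = A(i, 2) - B(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < out(gi, gj)) out(gi, gj) = d;
    }
  }
  return out;
}
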