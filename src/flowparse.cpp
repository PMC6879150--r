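#include <Rcpp.h>
using namespace Rcpp;

// Ring-resolved template inner products.
//
// A template family (radial or ground) is stored in compressed form: for
// singularity block ij, entries k in [ptr[ij], ptr[ij+1]) hold a Z-row index
// idx[k] (0-based, addressing the (cell, direction) axis), a weight w[k]
// (distance weight x direction-template weight / normalization) and an
// eccentricity-ring index q[k] in 0..nq-1. Z is passed transposed
// (columns of the original (speed[, disparity]) axis become rows) so that
// the inner accumulation runs over contiguous memory.
//
// Returns an array of dim (ncol_z, nq, nij): the inner product of the MT+
// signal with the template, resolved by eccentricity ring. Summing over
// rings gives the plain radial match; mixing rings with speed-template
// weights gives gradient/ground-unit drives.
// [[Rcpp::export]]
NumericVector cpp_template_drive(IntegerVector ptr, IntegerVector idx,
                                 NumericVector w, IntegerVector q,
                                 int nq, NumericMatrix Zt) {
  const int nij = ptr.size() - 1;
  const int nc = Zt.nrow();
  NumericVector out(static_cast<R_xlen_t>(nc) * nq * nij);
  std::vector<double> acc(static_cast<size_t>(nc) * nq);
  const double *zbase = REAL(Zt);
  double *o = REAL(out);
  for (int ij = 0; ij < nij; ++ij) {
    std::fill(acc.begin(), acc.end(), 0.0);
    const int k0 = ptr[ij], k1 = ptr[ij + 1];
    for (int k = k0; k < k1; ++k) {
      const double wk = w[k];
      const double *z = zbase + static_cast<R_xlen_t>(idx[k]) * nc;
      double *a = acc.data() + static_cast<size_t>(q[k]) * nc;
      for (int c = 0; c < nc; ++c) a[c] += wk * z[c];
    }
    std::copy(acc.begin(), acc.end(), o + static_cast<R_xlen_t>(ij) * nc * nq);
  }
  return out;
}

// Fused Euler integration of the MT+ leaky integrator and the depressing
// MT+ -> MSTd synapses over the substeps of one input frame. The MT+ drive
// (spatially integrated MT Layer 4/6 activity) is constant within a frame.
//   dm/dt = alpha * (drive - m)
//   du/dt = (1 - u)/tau_rec - kappa * u * m
// Returns new state vectors and the transmitted signal z = u * m at the end
// of the frame.
// [[Rcpp::export]]
List cpp_mtplus_frame(NumericVector m, NumericVector u, NumericVector drive,
                      double dt, int nsteps, double alpha, double tau_rec,
                      double kappa) {
  const R_xlen_t n = m.size();
  if (u.size() != n || drive.size() != n)
    stop("state and drive lengths differ");
  NumericVector m2 = clone(m), u2 = clone(u);
  double *mp = REAL(m2), *up = REAL(u2);
  const double *dp = REAL(drive);
  const double rinv = 1.0 / tau_rec;
  for (int s = 0; s < nsteps; ++s) {
    for (R_xlen_t i = 0; i < n; ++i) {
      const double mi = mp[i];
      const double ui = up[i];
      mp[i] = mi + dt * alpha * (dp[i] - mi);
      double un = ui + dt * ((1.0 - ui) * rinv - kappa * ui * mi);
      up[i] = un < 0.0 ? 0.0 : (un > 1.0 ? 1.0 : un);
    }
  }
  NumericVector z(n);
  double *zp = REAL(z);
  for (R_xlen_t i = 0; i < n; ++i) zp[i] = up[i] * mp[i];
  return List::create(_["m"] = m2, _["u"] = u2, _["z"] = z);
}
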