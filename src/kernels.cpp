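#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap(double d, double L) {
  return d - L * std::floor(d / L + 0.5);
}

// Per-molecule minimum bead-to-protein distance (minimum image), with early
// exit once a molecule is known to be inside the cutoff. Returns, per
// molecule, the squared minimum distance capped at cutoff^2 when reached.
// [[Rcpp::export(name = ".cpp_mol_min_dist2")]]
NumericVector mol_min_dist2(NumericMatrix lipid, IntegerVector molIndex,
                            int nMol, NumericMatrix prot,
                            NumericVector box, double cutoff) {
  const int nl = lipid.nrow(), np = prot.nrow();
  const double c2 = cutoff * cutoff;
  NumericVector out(nMol, R_PosInf);
  for (int i = 0; i < nl; ++i) {
    const int m = molIndex[i] - 1;
    if (out[m] <= c2) continue;
    const double x = lipid(i, 0), y = lipid(i, 1), z = lipid(i, 2);
    double best = out[m];
    for (int j = 0; j < np; ++j) {
      const double dx = wrap(x - prot(j, 0), box[0]);
      const double dy = wrap(y - prot(j, 1), box[1]);
      const double dz = wrap(z - prot(j, 2), box[2]);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        if (best <= c2) break;
      }
    }
    out[m] = best;
  }
  return out;
}

// Per-(residue x subunit) contact indicator for one frame: 1 when any
// species bead lies within `cutoff` (minimum image) of any bead of the
// residue. resGroup maps each protein bead to a group index 1..nGroup.
// [[Rcpp::export(name = ".cpp_residue_contacts")]]
IntegerVector residue_contacts(NumericMatrix fa, NumericMatrix prot,
                               IntegerVector resGroup, int nGroup,
                               NumericVector box, double cutoff) {
  const int nf = fa.nrow(), np = prot.nrow();
  const double c2 = cutoff * cutoff;
  IntegerVector out(nGroup, 0);
  for (int j = 0; j < np; ++j) {
    const int g = resGroup[j] - 1;
    if (out[g]) continue;
    const double x = prot(j, 0), y = prot(j, 1), z = prot(j, 2);
    for (int i = 0; i < nf; ++i) {
      const double dx = wrap(fa(i, 0) - x, box[0]);
      const double dy = wrap(fa(i, 1) - y, box[1]);
      const double dz = wrap(fa(i, 2) - z, box[2]);
      if (dx * dx + dy * dy + dz * dz <= c2) { out[g] = 1; break; }
    }
  }
  return out;
}

// Fixed-step RK4 integration of dP/dt = P Q with constant generator Q.
// Records the state vector every `recordEvery` steps (plus the final step).
// [[Rcpp::export(name = ".cpp_rk4")]]
NumericMatrix rk4_integrate(NumericVector p0, NumericMatrix Q, int nSteps,
                            double dt, int recordEvery) {
  const int n = p0.size();
  const int nRec = nSteps / recordEvery + ((nSteps % recordEvery) ? 2 : 1);
  NumericMatrix out(nRec, n);
  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> q(Q.begin(), Q.end());  // column-major copy
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  auto deriv = [&](const std::vector<double>& v, std::vector<double>& k) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      const double* col = &q[(size_t)j * n];
      for (int i = 0; i < n; ++i) s += v[i] * col[i];
      k[j] = s;
    }
  };
  int rec = 0;
  for (int j = 0; j < n; ++j) out(rec, j) = p[j];
  ++rec;
  for (int s = 1; s <= nSteps; ++s) {
    deriv(p, k1);
    for (int j = 0; j < n; ++j) tmp[j] = p[j] + 0.5 * dt * k1[j];
    deriv(tmp, k2);
    for (int j = 0; j < n; ++j) tmp[j] = p[j] + 0.5 * dt * k2[j];
    deriv(tmp, k3);
    for (int j = 0; j < n; ++j) tmp[j] = p[j] + dt * k3[j];
    deriv(tmp, k4);
    for (int j = 0; j < n; ++j)
      p[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (s % recordEvery == 0 || s == nSteps) {
      if (rec < nRec) {
        for (int j = 0; j < n; ++j) out(rec, j) = p[j];
        ++rec;
      }
    }
  }
  return out(Range(0, rec - 1), _);
}
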