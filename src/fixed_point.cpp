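#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Synchronous (Jacobi) fixed-point iteration over all metabolite pools.
//
// Each pool's isotopomer distribution is updated as a convex mixture of
// "terms". A term is either a fixed source vector (tracer inflow, unlabeled
// inflow), a linear image of one source pool's distribution (single-substrate
// carbon map, stored as a column-stochastic matrix), or a linear image of the
// Kronecker product of two source pools (condensation of two substrates into
// one product, e.g. oxaloacetate + acetyl-CoA -> 2-oxoglutarate).
//
// All matrices are built in R from the carbon-atom transition maps; only the
// mixing weights change with the flux vector, so a fit re-uses the matrices.
//
// term_type: 0 = fixed vector, 1 = single source, 2 = pair (kron) source.
// term_s1/term_s2: 0-based pool indices of the sources.
// Pair-term column ordering matches R's kronecker(d1, d2):
//   column index = i1 * size2 + i2 (0-based).

// [[Rcpp::export]]
List fixed_point_cpp(IntegerVector term_target, IntegerVector term_type,
                     IntegerVector term_s1, IntegerVector term_s2,
                     List term_mat, List term_fixed, NumericVector term_w,
                     IntegerVector sizes, double tol, int max_iter) {
  const int n_pools = sizes.size();
  const int n_terms = term_target.size();

  std::vector< std::vector<double> > d(n_pools), nd(n_pools);
  for (int p = 0; p < n_pools; ++p) {
    d[p].assign(sizes[p], 0.0);
    d[p][0] = 1.0;  // start unlabeled (pattern 00..0)
    nd[p].assign(sizes[p], 0.0);
  }

  // The carbon-map matrices are column-stochastic with at most two nonzero
  // entries per column (one per fumarase-scramble variant), so they are
  // converted once to a compressed per-column sparse form.
  std::vector<NumericVector> fvs(n_terms);
  std::vector< std::vector<int> > colptr(n_terms), rowidx(n_terms);
  std::vector< std::vector<double> > vals(n_terms);
  std::vector<int> ncols(n_terms, 0);
  for (int t = 0; t < n_terms; ++t) {
    if (term_type[t] == 0) { fvs[t] = as<NumericVector>(term_fixed[t]); continue; }
    NumericMatrix M = as<NumericMatrix>(term_mat[t]);
    const int nr = M.nrow(), nc = M.ncol();
    ncols[t] = nc;
    colptr[t].assign(nc + 1, 0);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (M(i, j) != 0.0) {
          rowidx[t].push_back(i);
          vals[t].push_back(M(i, j));
        }
      }
      colptr[t][j + 1] = (int) rowidx[t].size();
    }
  }

  double resid = R_PosInf;
  bool conv = false;
  int it = 0;
  std::vector<double> kron;

  for (it = 1; it <= max_iter; ++it) {
    for (int p = 0; p < n_pools; ++p)
      std::fill(nd[p].begin(), nd[p].end(), 0.0);

    for (int t = 0; t < n_terms; ++t) {
      const double w = term_w[t];
      if (w == 0.0) continue;
      std::vector<double> &out = nd[term_target[t]];

      if (term_type[t] == 0) {
        const NumericVector &v = fvs[t];
        for (int i = 0; i < (int) out.size(); ++i) out[i] += w * v[i];
      } else if (term_type[t] == 1) {
        const std::vector<double> &src = d[term_s1[t]];
        const std::vector<int> &cp = colptr[t];
        for (int j = 0; j < ncols[t]; ++j) {
          const double ws = w * src[j];
          if (ws == 0.0) continue;
          for (int k = cp[j]; k < cp[j + 1]; ++k)
            out[rowidx[t][k]] += ws * vals[t][k];
        }
      } else {
        const std::vector<double> &a = d[term_s1[t]];
        const std::vector<double> &b = d[term_s2[t]];
        const int la = (int) a.size(), lb = (int) b.size();
        kron.assign((size_t) la * lb, 0.0);
        for (int i = 0; i < la; ++i) {
          const double ai = a[i];
          if (ai == 0.0) continue;
          for (int j = 0; j < lb; ++j) kron[(size_t) i * lb + j] = ai * b[j];
        }
        const std::vector<int> &cp = colptr[t];
        for (int j = 0; j < ncols[t]; ++j) {
          const double ws = w * kron[j];
          if (ws == 0.0) continue;
          for (int k = cp[j]; k < cp[j + 1]; ++k)
            out[rowidx[t][k]] += ws * vals[t][k];
        }
      }
    }

    resid = 0.0;
    for (int p = 0; p < n_pools; ++p)
      for (int i = 0; i < (int) d[p].size(); ++i)
        resid += std::fabs(nd[p][i] - d[p][i]);
    d.swap(nd);
    if (resid <= tol) { conv = true; break; }
  }

  List dists(n_pools);
  for (int p = 0; p < n_pools; ++p)
    dists[p] = NumericVector(d[p].begin(), d[p].end());

  return List::create(_["dists"] = dists,
                      _["iterations"] = conv ? it : max_iter,
                      _["converged"] = conv,
                      _["residual"] = resid);
}
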