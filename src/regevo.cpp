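#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// PWM window scores along the forward strand of an integer-coded sequence.
// code: 1..4 (A,C,G,T), NA for ambiguous bases; mat: L x 4 log-odds.
// Windows containing an NA base score NA.
// [[Rcpp::export]]
NumericVector scan_scores_cpp(IntegerVector code, NumericMatrix mat) {
  int n = code.size(), L = mat.nrow();
  int nw = n - L + 1;
  if (nw < 1) return NumericVector(0);
  NumericVector out(nw);
  for (int w = 0; w < nw; ++w) {
    double s = 0.0;
    bool ok = true;
    for (int j = 0; j < L; ++j) {
      int b = code[w + j];
      if (b == NA_INTEGER) { ok = false; break; }
      s += mat(j, b - 1);
    }
    out[w] = ok ? s : NA_REAL;
  }
  return out;
}

// Hits on both strands at score >= thr. rcmat is the reverse-complement
// matrix; a forward-scan hit under rcmat is a minus-strand site occupying
// the same forward window. Returns a matrix with columns
// (start0, strand (1 = '+', 2 = '-'), score).
// [[Rcpp::export]]
NumericMatrix scan_hits_cpp(IntegerVector code, NumericMatrix mat,
                            NumericMatrix rcmat, double thr) {
  int n = code.size(), L = mat.nrow();
  int nw = n - L + 1;
  std::vector<double> st, sd, sc;
  for (int w = 0; w < std::max(nw, 0); ++w) {
    double sf = 0.0, sr = 0.0;
    bool ok = true;
    for (int j = 0; j < L; ++j) {
      int b = code[w + j];
      if (b == NA_INTEGER) { ok = false; break; }
      sf += mat(j, b - 1);
      sr += rcmat(j, b - 1);
    }
    if (!ok) continue;
    if (sf >= thr) { st.push_back(w); sd.push_back(1); sc.push_back(sf); }
    if (sr >= thr) { st.push_back(w); sd.push_back(2); sc.push_back(sr); }
  }
  int m = st.size();
  NumericMatrix out(m, 3);
  for (int k = 0; k < m; ++k) {
    out(k, 0) = st[k]; out(k, 1) = sd[k]; out(k, 2) = sc[k];
  }
  return out;
}

// Explicit-Euler integration of the gap-gene reaction-diffusion system.
//
//   dm_a(i)/dt = R_a * P_on,a(i) - lam_a * m + Dm_a * lap(m)
//   dp_a(i)/dt = tr_a * m - rho_a * p + Dp_a * lap(p)
//
// with zero-flux boundaries (mirrored neighbours). P_on is a logistic
// function of the signed sum of thermodynamic site occupancies plus a
// basal bias. Site occupancy phi = q/(1+q) with q = qcoef * c(tf, i);
// same-TF sites within the cooperativity range get a single-pass boost
// q' = q * (1 + omega * sum of unboosted neighbour phi).
//
// ext: 8 x n concentration matrix (external TF rows fixed; gap-protein
// rows, given by gene_rows (0-based), are overwritten from the protein
// state at every step). sites: per gene a list(qcoef, tf0, Tv, pi, pj)
// with tf0 the 0-based row of ext for each site's TF and (pi, pj)
// 0-based directed cooperative pairs (site pi receives phi of site pj).
// obs_steps: sorted 0-based step indices at which the state is recorded
// (step 0 = initial condition).
// [[Rcpp::export]]
List simulate_cpp(int n, double dt, int n_steps, IntegerVector obs_steps,
                  NumericMatrix ext, IntegerVector gene_rows,
                  NumericVector R, NumericVector lam, NumericVector Dm,
                  NumericVector tr, NumericVector rho, NumericVector Dp,
                  NumericVector theta, double omega, List sites,
                  NumericMatrix m0, NumericMatrix p0) {
  const int nG = 4;
  NumericMatrix C = clone(ext);
  std::vector<double> m(nG * n), p(nG * n), newm(nG * n), newp(nG * n);
  for (int g = 0; g < nG; ++g)
    for (int i = 0; i < n; ++i) {
      m[g * n + i] = m0(g, i);
      p[g * n + i] = p0(g, i);
    }

  std::vector< std::vector<double> > qc(nG), Tv(nG);
  std::vector< std::vector<int> > tfi(nG), ppi(nG), ppj(nG);
  int maxS = 1;
  for (int g = 0; g < nG; ++g) {
    List sg = sites[g];
    qc[g] = as< std::vector<double> >(sg["qcoef"]);
    Tv[g] = as< std::vector<double> >(sg["Tv"]);
    tfi[g] = as< std::vector<int> >(sg["tf0"]);
    ppi[g] = as< std::vector<int> >(sg["pi"]);
    ppj[g] = as< std::vector<int> >(sg["pj"]);
    if ((int)qc[g].size() > maxS) maxS = qc[g].size();
  }
  std::vector<double> phi(maxS * n), boost(maxS * n);
  std::vector<double> act(nG * n);
  std::vector<char> has(maxS);

  int nobs = obs_steps.size();
  NumericVector u(2 * nG * n * nobs);
  int obi = 0;
  bool blow = false;
  int blow_step = -1;

  // record helper as lambda
  auto record = [&](int ob) {
    for (int g = 0; g < nG; ++g)
      for (int i = 0; i < n; ++i) {
        u[0 + 2 * (g + nG * (i + (long)n * ob))] = m[g * n + i];
        u[1 + 2 * (g + nG * (i + (long)n * ob))] = p[g * n + i];
      }
  };
  while (obi < nobs && obs_steps[obi] == 0) { record(obi); ++obi; }

  for (int step = 1; step <= n_steps && !blow; ++step) {
    for (int g = 0; g < nG; ++g) {
      int rr = gene_rows[g];
      for (int i = 0; i < n; ++i) C(rr, i) = p[g * n + i];
    }
    for (int g = 0; g < nG; ++g) {
      int S = qc[g].size();
      for (int i = 0; i < n; ++i) act[g * n + i] = theta[g];
      if (S > 0) {
        for (int s = 0; s < S; ++s) {
          double q0 = qc[g][s];
          int r = tfi[g][s];
          for (int i = 0; i < n; ++i) {
            double q = q0 * C(r, i);
            phi[s * n + i] = q / (1.0 + q);
          }
        }
        int np = ppi[g].size();
        if (omega > 0 && np > 0) {
          std::fill(boost.begin(), boost.begin() + S * n, 0.0);
          std::fill(has.begin(), has.begin() + S, 0);
          for (int k = 0; k < np; ++k) {
            int a = ppi[g][k], b = ppj[g][k];
            has[a] = 1;
            for (int i = 0; i < n; ++i) boost[a * n + i] += phi[b * n + i];
          }
          for (int s = 0; s < S; ++s) {
            if (!has[s]) continue;
            double q0 = qc[g][s];
            int r = tfi[g][s];
            for (int i = 0; i < n; ++i) {
              double q = q0 * C(r, i) * (1.0 + omega * boost[s * n + i]);
              phi[s * n + i] = q / (1.0 + q);
            }
          }
        }
        for (int s = 0; s < S; ++s) {
          double T = Tv[g][s];
          for (int i = 0; i < n; ++i) act[g * n + i] += T * phi[s * n + i];
        }
      }
      for (int i = 0; i < n; ++i)
        act[g * n + i] = 1.0 / (1.0 + std::exp(-act[g * n + i]));
    }
    for (int g = 0; g < nG; ++g) {
      for (int i = 0; i < n; ++i) {
        double mm = m[g * n + i];
        double ml = m[g * n + (i > 0 ? i - 1 : i)];
        double mr = m[g * n + (i < n - 1 ? i + 1 : i)];
        double pp = p[g * n + i];
        double pl = p[g * n + (i > 0 ? i - 1 : i)];
        double pr = p[g * n + (i < n - 1 ? i + 1 : i)];
        newm[g * n + i] = mm + dt * (R[g] * act[g * n + i] - lam[g] * mm +
                                     Dm[g] * (ml + mr - 2.0 * mm));
        newp[g * n + i] = pp + dt * (tr[g] * mm - rho[g] * pp +
                                     Dp[g] * (pl + pr - 2.0 * pp));
      }
    }
    m.swap(newm);
    p.swap(newp);
    for (int k = 0; k < nG * n && !blow; ++k)
      if (!std::isfinite(m[k]) || !std::isfinite(p[k]) ||
          std::fabs(m[k]) > 1e8 || std::fabs(p[k]) > 1e8) {
        blow = true;
        blow_step = step;
      }
    if (blow) break;
    while (obi < nobs && obs_steps[obi] == step) { record(obi); ++obi; }
  }

  return List::create(_["u"] = u, _["blowup"] = blow,
                      _["blow_step"] = blow_step);
}

// Pairwise interval-overlap event counts within one locus.
// starts/ends: half-open site intervals sorted by start; group: integer
// group label (same-TF grouping or all-ones). Counts unordered pairs of
// sites in the same group with intersecting intervals.
// [[Rcpp::export]]
IntegerVector overlap_pairs_cpp(IntegerVector starts, IntegerVector ends,
                                IntegerVector group, int ngroup) {
  int S = starts.size();
  IntegerVector out(ngroup);
  for (int i = 0; i < S; ++i) {
    for (int j = i + 1; j < S; ++j) {
      if (starts[j] >= ends[i]) break;  // sorted by start: no later overlap with i
      if (group[j] == group[i]) out[group[i] - 1] += 1;
    }
  }
  return out;
}
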