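#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Rescale threshold for the linear-domain DP: when a partition sum exceeds
// this, the running value is folded into a per-position log factor.
static const double RESCALE = 1e100;

// ---------------------------------------------------------------- WM scan --

// seq: integer-encoded genome (0=A,1=C,2=G,3=T,4=N); logw: l x 4 matrix of
// log WM probabilities. Returns mismatch energies (consensus = 0) for every
// start on the forward strand and for the reverse-complement window, NA where
// the window contains N.
// [[Rcpp::export]]
List scan_wm_cpp(IntegerVector seq, NumericMatrix logw) {
  const int L = seq.size(), l = logw.nrow();
  const int n = L - l + 1;
  if (n <= 0) return List::create(_["e_fwd"] = NumericVector(0),
                                  _["e_rev"] = NumericVector(0));
  std::vector<double> logmax(l);
  for (int i = 0; i < l; ++i) {
    double m = logw(i, 0);
    for (int a = 1; a < 4; ++a) m = std::max(m, logw(i, a));
    logmax[i] = m;
  }
  NumericVector ef(n), er(n);
  for (int j = 0; j < n; ++j) {
    double sf = 0.0, sr = 0.0;
    bool ok = true;
    for (int i = 0; i < l; ++i) {
      int b = seq[j + i];
      if (b > 3) { ok = false; break; }
      sf += logmax[i] - logw(i, b);
      // reverse strand: the site read 3'->5' on the forward sequence; the
      // base at window offset i pairs with WM position l-1-i, complemented
      sr += logmax[l - 1 - i] - logw(l - 1 - i, 3 - b);
    }
    if (ok) { ef[j] = sf; er[j] = sr; }
    else    { ef[j] = NA_REAL; er[j] = NA_REAL; }
  }
  return List::create(_["e_fwd"] = ef, _["e_rev"] = er);
}

// ------------------------------------------------------- dinucleotide scan --

// lp: 16 log-propensities indexed 4*first+second; posw: weight per
// dinucleotide step (length l-1). Energies are -sum(posw * lp) over the
// window; e_rc is the same quantity for the reverse complement of the window.
// [[Rcpp::export]]
List scan_dinuc_cpp(IntegerVector seq, NumericVector lp, NumericVector posw,
                    int l) {
  const int L = seq.size();
  const int n = L - l + 1;
  if (n <= 0) return List::create(_["e_fwd"] = NumericVector(0),
                                  _["e_rc"] = NumericVector(0));
  NumericVector ef(n), er(n);
  for (int j = 0; j < n; ++j) {
    double sf = 0.0, sr = 0.0;
    bool ok = true;
    for (int k = 0; k < l - 1; ++k) {
      int b1 = seq[j + k], b2 = seq[j + k + 1];
      if (b1 > 3 || b2 > 3) { ok = false; break; }
      sf -= posw[k] * lp[4 * b1 + b2];
      // rc window dinucleotide at step k (from its 5' end) is
      // comp(seq[j+l-1-k]), comp(seq[j+l-2-k])
      int c1 = 3 - seq[j + l - 1 - k], c2 = 3 - seq[j + l - 2 - k];
      sr -= posw[k] * lp[4 * c1 + c2];
    }
    if (ok) { ef[j] = sf; er[j] = sr; }
    else    { ef[j] = NA_REAL; er[j] = NA_REAL; }
  }
  return List::create(_["e_fwd"] = ef, _["e_rc"] = er);
}

// ------------------------------------------------------ forward / backward --

struct DPResult {
  std::vector<double> logF, logR; // length L+1 each; logF[i] = log F(i)
  double logZ;
};

static DPResult dp_run(const std::vector<const double*> &q,
                       const std::vector<int> &ql,
                       const std::vector<int> &fl, int L) {
  const int nf = fl.size();
  std::vector<double> F(L + 1), ls(L + 1);
  F[0] = 1.0; ls[0] = 0.0;
  for (int i = 1; i <= L; ++i) {
    double s = ls[i - 1];
    double v = F[i - 1]; // free step, same scale
    for (int f = 0; f < nf; ++f) {
      int l = fl[f];
      if (i >= l) {
        int j = i - l;
        if (j < ql[f]) {
          double qq = q[f][j];
          if (qq > 0.0) v += qq * F[j] * std::exp(ls[j] - s);
        }
      }
    }
    if (v > RESCALE) { ls[i] = s + std::log(v); F[i] = 1.0; }
    else             { ls[i] = s; F[i] = v; }
  }
  DPResult res;
  res.logF.resize(L + 1);
  for (int i = 0; i <= L; ++i) res.logF[i] = std::log(F[i]) + ls[i];
  // backward: R(i) over bases i..L-1, R(L) = 1
  std::vector<double> Rv(L + 1), lsr(L + 1);
  Rv[L] = 1.0; lsr[L] = 0.0;
  for (int i = L - 1; i >= 0; --i) {
    double s = lsr[i + 1];
    double v = Rv[i + 1];
    for (int f = 0; f < nf; ++f) {
      int l = fl[f];
      if (i + l <= L && i < ql[f]) {
        double qq = q[f][i];
        if (qq > 0.0) v += qq * Rv[i + l] * std::exp(lsr[i + l] - s);
      }
    }
    if (v > RESCALE) { lsr[i] = s + std::log(v); Rv[i] = 1.0; }
    else             { lsr[i] = s; Rv[i] = v; }
  }
  res.logR.resize(L + 1);
  for (int i = 0; i <= L; ++i) res.logR[i] = std::log(Rv[i]) + lsr[i];
  res.logZ = res.logF[L];
  return res;
}

static void unpack_q(List qlist, std::vector<const double*> &q,
                     std::vector<int> &ql) {
  int nf = qlist.size();
  q.resize(nf); ql.resize(nf);
  for (int f = 0; f < nf; ++f) {
    NumericVector v = qlist[f];
    q[f] = REAL(v);
    ql[f] = v.size();
  }
}

// qlist: per factor, Boltzmann weight per 0-based start (length L-l_f+1,
// zeros at unbindable starts); footprints: per-factor site length.
// [[Rcpp::export]]
List forward_backward_cpp(List qlist, IntegerVector footprints, int L) {
  std::vector<const double*> q; std::vector<int> ql;
  unpack_q(qlist, q, ql);
  std::vector<int> fl(footprints.begin(), footprints.end());
  for (int f = 0; f < (int)fl.size(); ++f) {
    NumericVector v = qlist[f];
    for (int j = 0; j < v.size(); ++j)
      if (v[j] < 0 || !R_finite(v[j]))
        stop("negative or non-finite site weight (factor %d, start %d)",
             f + 1, j + 1);
  }
  DPResult r = dp_run(q, ql, fl, L);
  return List::create(_["logF"] = NumericVector(r.logF.begin(), r.logF.end()),
                      _["logR"] = NumericVector(r.logR.begin(), r.logR.end()),
                      _["logZ"] = r.logZ);
}

// Site posteriors and per-base occupancy from precomputed partition sums.
// [[Rcpp::export]]
List posteriors_cpp(NumericVector logF, NumericVector logR, double logZ,
                    List qlist, IntegerVector footprints, int L) {
  int nf = qlist.size();
  List post(nf), occ(nf);
  NumericVector total(L);
  for (int f = 0; f < nf; ++f) {
    NumericVector q = qlist[f];
    int l = footprints[f], n = q.size();
    NumericVector p(n), d(L + 1);
    for (int j = 0; j < n; ++j) {
      if (q[j] > 0.0) {
        p[j] = std::exp(logF[j] + std::log(q[j]) + logR[j + l] - logZ);
        d[j] += p[j];
        d[j + l] -= p[j];
      }
    }
    NumericVector o(L);
    double run = 0.0;
    for (int i = 0; i < L; ++i) {
      run += d[i];
      o[i] = run;
      total[i] += run;
    }
    post[f] = p;
    occ[f] = o;
  }
  NumericVector fr(L);
  for (int i = 0; i < L; ++i) fr[i] = 1.0 - total[i];
  return List::create(_["posteriors"] = post, _["occupancy"] = occ,
                      _["free"] = fr);
}

// Stochastic traceback: one configuration drawn exactly from the equilibrium
// distribution, using R's RNG. Returns matrix (factor index, 0-based start).
// [[Rcpp::export]]
IntegerMatrix sample_config_cpp(NumericVector logF, List qlist,
                                IntegerVector footprints, int L) {
  std::vector<const double*> q; std::vector<int> ql;
  unpack_q(qlist, q, ql);
  int nf = qlist.size();
  std::vector<int> fs, st;
  int i = L;
  while (i > 0) {
    double u = unif_rand();
    double acc = std::exp(logF[i - 1] - logF[i]);
    if (u < acc) { --i; continue; }
    bool placed = false;
    for (int f = 0; f < nf; ++f) {
      int l = footprints[f];
      if (i >= l && (i - l) < ql[f]) {
        double qq = q[f][i - l];
        if (qq > 0.0) {
          acc += qq * std::exp(logF[i - l] - logF[i]);
          if (u < acc) { fs.push_back(f + 1); st.push_back(i - l); i -= l;
                         placed = true; break; }
        }
      }
    }
    if (!placed) --i; // numerical slack: treat as free step
  }
  IntegerMatrix out(fs.size(), 2);
  for (int k = 0; k < (int)fs.size(); ++k) {
    out(k, 0) = fs[k];
    out(k, 1) = st[k];
  }
  return out;
}

// Draw n_cells configurations and emit noisy read midpoints for one factor
// (the nucleosome): each placed site emits Poisson(reads_mean) midpoints at
// dyad + N(0, noise_sd), clipped to the chromosome. Returns 0-based midpoints.
// [[Rcpp::export]]
IntegerVector sample_midpoints_cpp(NumericVector logF, List qlist,
                                   IntegerVector footprints, int L,
                                   int factor_index, int n_cells,
                                   double reads_mean, double noise_sd) {
  std::vector<const double*> q; std::vector<int> ql;
  unpack_q(qlist, q, ql);
  int nf = qlist.size();
  std::vector<int> mids;
  for (int cell = 0; cell < n_cells; ++cell) {
    int i = L;
    while (i > 0) {
      double u = unif_rand();
      double acc = std::exp(logF[i - 1] - logF[i]);
      if (u < acc) { --i; continue; }
      bool placed = false;
      for (int f = 0; f < nf; ++f) {
        int l = footprints[f];
        if (i >= l && (i - l) < ql[f]) {
          double qq = q[f][i - l];
          if (qq > 0.0) {
            acc += qq * std::exp(logF[i - l] - logF[i]);
            if (u < acc) {
              if (f + 1 == factor_index) {
                int dyad = (i - l) + l / 2;
                int nr = (int)R::rpois(reads_mean);
                for (int r = 0; r < nr; ++r) {
                  double m = dyad + (noise_sd > 0 ? R::rnorm(0.0, noise_sd)
                                                  : 0.0);
                  int mi = (int)std::lround(m);
                  if (mi < 0) mi = 0;
                  if (mi >= L) mi = L - 1;
                  mids.push_back(mi);
                }
              }
              i -= l; placed = true; break;
            }
          }
        }
      }
      if (!placed) --i;
    }
  }
  return IntegerVector(mids.begin(), mids.end());
}

// Draw n configurations and accumulate per-start site counts per factor,
// entirely in compiled code (used for large sampler-consistency checks).
// [[Rcpp::export]]
List sample_site_counts_cpp(NumericVector logF, List qlist,
                            IntegerVector footprints, int L, int n) {
  std::vector<const double*> q; std::vector<int> ql;
  unpack_q(qlist, q, ql);
  int nf = qlist.size();
  List counts(nf);
  std::vector<double*> cp(nf);
  for (int f = 0; f < nf; ++f) {
    NumericVector c(ql[f]);
    counts[f] = c;
    cp[f] = REAL(c);
  }
  for (int rep = 0; rep < n; ++rep) {
    int i = L;
    while (i > 0) {
      double u = unif_rand();
      double acc = std::exp(logF[i - 1] - logF[i]);
      if (u < acc) { --i; continue; }
      bool placed = false;
      for (int f = 0; f < nf; ++f) {
        int l = footprints[f];
        if (i >= l && (i - l) < ql[f]) {
          double qq = q[f][i - l];
          if (qq > 0.0) {
            acc += qq * std::exp(logF[i - l] - logF[i]);
            if (u < acc) { cp[f][i - l] += 1.0; i -= l; placed = true;
                           break; }
          }
        }
      }
      if (!placed) --i;
    }
  }
  return counts;
}

// ----------------------------------------------------------- region median --

// Exact median of values[start..end) per region (0-based half-open).
// [[Rcpp::export]]
NumericVector region_medians_cpp(NumericVector values, IntegerVector start,
                                 IntegerVector end) {
  int nr = start.size();
  NumericVector out(nr);
  std::vector<double> buf;
  for (int r = 0; r < nr; ++r) {
    int a = start[r], b = end[r];
    if (a < 0 || b > values.size() || a >= b)
      stop("region %d out of bounds or empty", r + 1);
    buf.assign(values.begin() + a, values.begin() + b);
    int n = b - a;
    int h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (n % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + h - 1, buf.begin() + h);
      m = 0.5 * (m + buf[h - 1]);
    }
    out[r] = m;
  }
  return out;
}

// ------------------------------------------------------------ MI threshold --

static inline double xlogx_term(double fxy, double fx, double fy) {
  if (fxy <= 0.0) return 0.0;
  return fxy * std::log(fxy / (fx * fy));
}

// Exhaustive threshold scan: regions with median > c are predicted
// "nucleosome". labels: 1 = annotated nucleosome, 0 = linker. Ties in MI are
// resolved toward the smallest threshold.
// [[Rcpp::export]]
List mi_scan_cpp(NumericVector medians, IntegerVector labels) {
  int n = medians.size();
  if (n < 2) stop("need at least two regions");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    return medians[a] < medians[b];
  });
  int totN = 0;
  for (int i = 0; i < n; ++i) totN += labels[i];
  if (totN == 0 || totN == n)
    stop("both labels must be present (entropy is zero)");
  double best = -1.0, bestc = 0.0;
  int cumN = 0; // annotated nucleosomes among the t smallest medians
  for (int t = 0; t <= n; ++t) {
    // first t regions predicted linker (median <= c), rest nucleosome
    bool valid = (t == 0 || t == n ||
                  medians[idx[t - 1]] < medians[idx[t]]);
    if (valid) {
      double f_ln = (double)cumN / n;              // pred linker, annot nuc
      double f_ll = (double)(t - cumN) / n;        // pred linker, annot link
      double f_nn = (double)(totN - cumN) / n;     // pred nuc, annot nuc
      double f_nl = (double)((n - t) - (totN - cumN)) / n;
      double pn = f_nn + f_nl, pl = f_ln + f_ll;   // prediction marginals
      double an = (double)totN / n, al = 1.0 - an; // annotation marginals
      double mi = xlogx_term(f_nn, pn, an) + xlogx_term(f_nl, pn, al) +
                  xlogx_term(f_ln, pl, an) + xlogx_term(f_ll, pl, al);
      double c;
      if (t == 0)      c = medians[idx[0]] - 1.0;
      else if (t == n) c = medians[idx[n - 1]];
      else             c = 0.5 * (medians[idx[t - 1]] + medians[idx[t]]);
      if (mi > best + 1e-15) { best = mi; bestc = c; }
    }
    if (t < n) cumN += labels[idx[t]];
  }
  double an = (double)totN / n;
  double H = -an * std::log(an) - (1.0 - an) * std::log(1.0 - an);
  return List::create(_["mi_star"] = best, _["c_star"] = bestc,
                      _["entropy"] = H, _["rho"] = best / H);
}

// -------------------------------------------------------- fitting objective --

static double logmeanexp2(const double *a, const double *b, int n,
                          double gamma) {
  // log mean over finite entries of both vectors of exp(-gamma * e)
  double m = -INFINITY;
  long cnt = 0;
  for (int j = 0; j < n; ++j) {
    if (R_finite(a[j])) { m = std::max(m, -gamma * a[j]); ++cnt; }
    if (b && R_finite(b[j])) { m = std::max(m, -gamma * b[j]); ++cnt; }
  }
  if (cnt == 0) return NA_REAL;
  double s = 0.0;
  for (int j = 0; j < n; ++j) {
    if (R_finite(a[j])) s += std::exp(-gamma * a[j] - m);
    if (b && R_finite(b[j])) s += std::exp(-gamma * b[j] - m);
  }
  return m + std::log(s / cnt);
}

// Calibration offset for one TF at a given specificity scale.
// [[Rcpp::export]]
double tf_e0_cpp(NumericVector e_fwd, NumericVector e_rev, double gamma) {
  return logmeanexp2(REAL(e_fwd), REAL(e_rev), e_fwd.size(), gamma);
}

// Single-shot quality evaluation used inside the optimizer loop.
// energies: per factor a list; TF: e_fwd/e_rev raw mismatch energies;
// nucleosome: e_cen, centred symmetrized energies (mean 0 over valid starts).
// e0: per-factor calibration offsets (NaN = compute here; ignored for
// nucleosome-kind factors). Scoring uses the summed occupancy of
// nucleosome-kind factors.
// [[Rcpp::export]]
List rho_objective_cpp(List energies, IntegerVector footprints,
                       LogicalVector is_nuc, NumericVector lnc,
                       NumericVector gamma, NumericVector e0in, int L,
                       IntegerVector reg_start, IntegerVector reg_end,
                       IntegerVector reg_label) {
  int nf = energies.size();
  List qlist(nf);
  for (int f = 0; f < nf; ++f) {
    List tr = energies[f];
    if (is_nuc[f]) {
      NumericVector e = tr["e_cen"];
      int n = e.size();
      NumericVector q(n);
      for (int j = 0; j < n; ++j)
        q[j] = R_finite(e[j]) ? std::exp(lnc[f] - gamma[f] * e[j]) : 0.0;
      qlist[f] = q;
    } else {
      NumericVector ef = tr["e_fwd"], er = tr["e_rev"];
      int n = ef.size();
      double e0 = (f < e0in.size() && R_finite(e0in[f])) ? e0in[f] :
        logmeanexp2(REAL(ef), REAL(er), n, gamma[f]);
      NumericVector q(n);
      for (int j = 0; j < n; ++j) {
        double v = 0.0;
        if (R_finite(ef[j])) v += std::exp(lnc[f] - gamma[f] * ef[j] - e0);
        if (R_finite(er[j])) v += std::exp(lnc[f] - gamma[f] * er[j] - e0);
        q[j] = v;
      }
      qlist[f] = q;
    }
  }
  std::vector<const double*> q; std::vector<int> ql;
  unpack_q(qlist, q, ql);
  std::vector<int> fl(footprints.begin(), footprints.end());
  DPResult r = dp_run(q, ql, fl, L);
  // nucleosome occupancy track
  NumericVector occ(L);
  std::vector<double> d(L + 1, 0.0);
  for (int f = 0; f < nf; ++f) {
    if (!is_nuc[f]) continue;
    NumericVector qv = qlist[f];
    int l = fl[f];
    for (int j = 0; j < qv.size(); ++j) {
      if (qv[j] > 0.0) {
        double p = std::exp(r.logF[j] + std::log(qv[j]) + r.logR[j + l] -
                            r.logZ);
        d[j] += p;
        d[j + l] -= p;
      }
    }
  }
  double run = 0.0;
  for (int i = 0; i < L; ++i) { run += d[i]; occ[i] = run; }
  NumericVector med = region_medians_cpp(occ, reg_start, reg_end);
  List sc = mi_scan_cpp(med, reg_label);
  sc["logZ"] = r.logZ;
  return sc;
}
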