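#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear tent: 0 below a, rises to 1 at b, falls to 0 at c.
static inline double ramp(double d, double a, double b, double c) {
  if (d <= a || d >= c) return 0.0;
  if (d <= b) return (d - a) / (b - a);
  return (c - d) / (c - b);
}

// Atom interaction classes: 1 hydrophobic, 2 donor, 3 acceptor,
// 4 donor_acceptor, 5 neutral. Probe types: 1 steric, 2 donor, 3 acceptor.
// Atoms passed here are heavy atoms only (hydrogens excluded upstream).
static void accumulate_terms(const NumericMatrix &A, const IntegerVector &aclass,
                             const NumericVector &avdw, const NumericMatrix &P,
                             const IntegerVector &ptype, const NumericMatrix &pdir,
                             const NumericVector &prad, double wh, double wp,
                             double wc, double plo, double pid, double phi,
                             double *contrib, double &hterm, double &pterm,
                             double &penterm) {
  int m = A.nrow(), n = P.nrow();
  for (int j = 0; j < n; j++) {
    double px = P(j, 0), py = P(j, 1), pz = P(j, 2);
    double s = 0.0;
    int pt = ptype[j];
    for (int i = 0; i < m; i++) {
      double dx = A(i, 0) - px, dy = A(i, 1) - py, dz = A(i, 2) - pz;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double d0 = avdw[i] + prad[j];
      double depth = (d0 - 0.5) - d;
      if (depth > 0) {
        double pen = wc * depth * depth;
        s -= pen;
        penterm -= pen;
      }
      int ac = aclass[i];
      if (pt == 1) {
        if (ac == 1) {
          double v = wh * ramp(d, d0 - 0.3, d0, d0 + 1.5);
          s += v;
          hterm += v;
        }
      } else {
        bool match = (pt == 2 && (ac == 3 || ac == 4)) ||
                     (pt == 3 && (ac == 2 || ac == 4));
        if (match && d > 1e-9) {
          double r = ramp(d, plo, pid, phi);
          if (r > 0) {
            double cosang =
                (dx * pdir(j, 0) + dy * pdir(j, 1) + dz * pdir(j, 2)) / d;
            if (cosang > 0) {
              double v = wp * r * cosang * cosang;
              s += v;
              pterm += v;
            }
          }
        }
      }
    }
    contrib[j] += s;
  }
}

// [[Rcpp::export]]
List cpp_score_terms(NumericMatrix A, IntegerVector aclass, NumericVector avdw,
                     NumericMatrix P, IntegerVector ptype, NumericMatrix pdir,
                     NumericVector prad, double wh, double wp, double wc,
                     double plo, double pid, double phi) {
  NumericVector contrib(P.nrow());
  double h = 0, p = 0, pen = 0;
  accumulate_terms(A, aclass, avdw, P, ptype, pdir, prad, wh, wp, wc, plo, pid,
                   phi, contrib.begin(), h, p, pen);
  return List::create(_["hydrophobic_term"] = h, _["polar_term"] = p,
                      _["penalty_term"] = pen, _["contrib"] = contrib);
}

// Per-probe contribution totals for many poses of one molecule.
// Returns an n_poses x n_probes matrix.
// [[Rcpp::export]]
NumericMatrix cpp_contrib_matrix(List poses, IntegerVector aclass,
                                 NumericVector avdw, NumericMatrix P,
                                 IntegerVector ptype, NumericMatrix pdir,
                                 NumericVector prad, double wh, double wp,
                                 double wc, double plo, double pid,
                                 double phi) {
  int np = poses.size(), nq = P.nrow();
  NumericMatrix out(np, nq);
  std::vector<double> contrib(nq);
  for (int k = 0; k < np; k++) {
    NumericMatrix A = poses[k];
    std::fill(contrib.begin(), contrib.end(), 0.0);
    double h = 0, p = 0, pen = 0;
    accumulate_terms(A, aclass, avdw, P, ptype, pdir, prad, wh, wp, wc, plo,
                     pid, phi, contrib.data(), h, p, pen);
    for (int j = 0; j < nq; j++) out(k, j) = contrib[j];
  }
  return out;
}

// Summed pairwise overlap integral of isotropic Gaussians (unit amplitude,
// per-atom standard deviations sa, sb).
// [[Rcpp::export]]
double cpp_overlap(NumericMatrix A, NumericVector sa, NumericMatrix B,
                   NumericVector sb) {
  int m = A.nrow(), n = B.nrow();
  double tot = 0.0;
  const double TWO_PI = 6.283185307179586;
  for (int i = 0; i < m; i++) {
    double s1 = sa[i] * sa[i];
    for (int j = 0; j < n; j++) {
      double s2 = s1 + sb[j] * sb[j];
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
             dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double pref = std::pow(TWO_PI * s1 * (s2 - s1) / s2, 1.5);
      tot += pref * std::exp(-d2 / (2.0 * s2));
    }
  }
  return tot;
}

// Single-probe contribution against many poses with per-pose atom typing
// (poses may belong to different molecules). Returns one value per pose.
// [[Rcpp::export]]
NumericVector cpp_single_probe_scores(List poses, List aclasses, List avdws,
                                      NumericMatrix P, IntegerVector ptype,
                                      NumericMatrix pdir, NumericVector prad,
                                      double wh, double wp, double wc,
                                      double plo, double pid, double phi) {
  int np = poses.size();
  NumericVector out(np);
  for (int k = 0; k < np; k++) {
    NumericMatrix A = poses[k];
    IntegerVector ac = aclasses[k];
    NumericVector av = avdws[k];
    double contrib = 0, h = 0, p = 0, pen = 0;
    accumulate_terms(A, ac, av, P, ptype, pdir, prad, wh, wp, wc, plo, pid,
                     phi, &contrib, h, p, pen);
    out[k] = contrib;
  }
  return out;
}

// Rigid-transform scoring in one call: rotate A0 (heavy atoms) about
// `center` by Euler angles par[0..2], translate by par[3..5], and return
// the total interaction score against the probes.
// [[Rcpp::export]]
double cpp_rigid_score(NumericVector par, NumericMatrix A0,
                       NumericVector center, IntegerVector aclass,
                       NumericVector avdw, NumericMatrix P,
                       IntegerVector ptype, NumericMatrix pdir,
                       NumericVector prad, double wh, double wp, double wc,
                       double plo, double pid, double phi) {
  double cx = std::cos(par[0]), sx = std::sin(par[0]);
  double cy = std::cos(par[1]), sy = std::sin(par[1]);
  double cz = std::cos(par[2]), sz = std::sin(par[2]);
  // Rz * Ry * Rx
  double r11 = cz * cy, r12 = cz * sy * sx - sz * cx,
         r13 = cz * sy * cx + sz * sx;
  double r21 = sz * cy, r22 = sz * sy * sx + cz * cx,
         r23 = sz * sy * cx - cz * sx;
  double r31 = -sy, r32 = cy * sx, r33 = cy * cx;
  int m = A0.nrow();
  NumericMatrix A(m, 3);
  for (int i = 0; i < m; i++) {
    double x = A0(i, 0) - center[0], y = A0(i, 1) - center[1],
           z = A0(i, 2) - center[2];
    A(i, 0) = r11 * x + r12 * y + r13 * z + center[0] + par[3];
    A(i, 1) = r21 * x + r22 * y + r23 * z + center[1] + par[4];
    A(i, 2) = r31 * x + r32 * y + r33 * z + center[2] + par[5];
  }
  std::vector<double> contrib(P.nrow(), 0.0);
  double h = 0, p = 0, pen = 0;
  accumulate_terms(A, aclass, avdw, P, ptype, pdir, prad, wh, wp, wc, plo,
                   pid, phi, contrib.data(), h, p, pen);
  return h + p + pen;
}
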