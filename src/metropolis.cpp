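#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of a potential tabulated on a uniform grid
// r = 0, dr, 2*dr, ..., rmax. Non-finite table values propagate as +Inf so
// the corresponding moves are rejected.
static inline double U_at(const double *U, int m, double dr, double r) {
  double j = r / dr;
  int j0 = (int)std::floor(j);
  if (j0 >= m - 1) return U[m - 1];
  if (j0 < 0) j0 = 0;
  double w = j - j0;
  double a = U[j0], b = U[j0 + 1];
  if (!R_finite(a) || !R_finite(b)) return R_PosInf;
  return a * (1 - w) + b * w;
}

// Metropolis chain over two-particle configurations in the arena disc,
// targeting exp(-U(|r1 - r2|)/kBT) with both particles otherwise uniform.
// Proposal: displace one randomly chosen particle by a vector uniform in a
// disc of radius `step`; moves leaving the arena are rejected. Four RNG
// draws per iteration regardless of branch, so the stream is reproducible.
// [[Rcpp::export]]
List cpp_pair_chain(NumericVector start, double R,
                    NumericVector Utab, double rtab_max, double kBT,
                    double step, int n_iter, int thin) {
  RNGScope scope;
  double x1 = start[0], y1 = start[1], x2 = start[2], y2 = start[3];
  const int m = Utab.size();
  const double dr = rtab_max / (m - 1);
  const double *U = Utab.begin();
  const double R2 = R * R;

  double dx = x1 - x2, dy = y1 - y2;
  double Ucur = U_at(U, m, dr, std::sqrt(dx * dx + dy * dy));

  int n_rec = (thin > 0) ? n_iter / thin : 0;
  NumericMatrix rec(n_rec, 4);
  int irec = 0;
  long accepted = 0;

  for (int t = 1; t <= n_iter; ++t) {
    double usel = unif_rand();
    double ur = unif_rand();
    double ua = unif_rand();
    double uacc = unif_rand();
    double rad = step * std::sqrt(ur);
    double ang = 2.0 * M_PI * ua;
    double ox = rad * std::cos(ang), oy = rad * std::sin(ang);
    bool first = usel < 0.5;
    double tx = (first ? x1 : x2) + ox;
    double ty = (first ? y1 : y2) + oy;
    if (tx * tx + ty * ty <= R2) {
      double ndx = first ? (tx - x2) : (x1 - tx);
      double ndy = first ? (ty - y2) : (y1 - ty);
      double Unew = U_at(U, m, dr, std::sqrt(ndx * ndx + ndy * ndy));
      if (R_finite(Unew) &&
          (Unew <= Ucur || uacc < std::exp(-(Unew - Ucur) / kBT))) {
        if (first) {
          x1 = tx;
          y1 = ty;
        } else {
          x2 = tx;
          y2 = ty;
        }
        Ucur = Unew;
        ++accepted;
      }
    }
    if (thin > 0 && t % thin == 0 && irec < n_rec) {
      rec(irec, 0) = x1;
      rec(irec, 1) = y1;
      rec(irec, 2) = x2;
      rec(irec, 3) = y2;
      ++irec;
    }
  }
  return List::create(_["samples"] = rec, _["accepted"] = (double)accepted,
                      _["state"] = NumericVector::create(x1, y1, x2, y2));
}
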