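#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Annual stepping core for the stratified population.
//
// State layout: counts[a, r, e, m] with
//   a: age 0..A-1 (A-1 is the open-ended terminal age, absorbing),
//   r: 0 urban, 1 rural,
//   e: education E0..E3,
//   m: migration state: 0 never; 1..13 rural_to_urban with years-since-move
//      0..12 (12 = 12+); 14..26 urban_to_rural likewise.
//
// Per-year inputs are event PROBABILITIES (competing risks already applied):
//   pdie[a, r, e, y], pmove[a, r, e, y], plus the fertility rate
//   fert[a, r, e, y] (births per woman-year) and the newborn education
//   distribution nb_edu[e, r, y].
//
// Within a year: death and migration are resolved jointly, survivors age one
// year (migration counters advance), and births are computed from
// start-of-year exposures, entering at age 0 in the mother's residence.

static inline int advance_mig(int m) {
  if (m == 0) return 0;              // never moved
  if (m == 13 || m == 26) return m;  // 12+ cap
  return m + 1;
}

// [[Rcpp::export]]
List cpp_run_sim(NumericVector counts, NumericVector pdie, NumericVector pmove,
                 NumericVector fert, NumericVector nb_edu,
                 double fraction_female, bool stochastic,
                 IntegerVector store) {
  IntegerVector cdim = counts.attr("dim");
  const int A = cdim[0], R = cdim[1], E = cdim[2], M = cdim[3];
  IntegerVector hdim = pdie.attr("dim");
  const int Y = hdim[3];
  if (hdim[0] != A || hdim[1] != R || hdim[2] != E)
    stop("hazard arrays do not match the state grid");
  const int ARE = A * R * E;

  std::vector<double> C(counts.begin(), counts.end());
  std::vector<double> Cnew(C.size());
  NumericVector popARE(ARE * (Y + 1));
  popARE.attr("dim") = IntegerVector::create(A, R, E, Y + 1);
  double *pop = REAL(popARE);
  NumericVector deaths(Y), births(Y), moves(Y);

  std::set<int> store_set(store.begin(), store.end());
  List stored;
  List stored_sums;   // per stored state: [A,R,E] x {all, ysm<=5, ysm<=11, ever}
  std::vector<int> stored_at;

  auto record_pop = [&](int t) {
    double *dst = pop + (size_t)ARE * t;
    for (int m = 0; m < M; ++m) {
      const double *src = C.data() + (size_t)ARE * m;
      for (int i = 0; i < ARE; ++i) dst[i] += src[i];
    }
  };
  auto maybe_store = [&](int t) {
    if (store_set.count(t + 1)) {  // 1-based year index
      NumericVector s(C.begin(), C.end());
      s.attr("dim") = cdim;
      stored.push_back(s);
      // migration-window summaries: columns all / moved<=5y / <=11y / ever
      NumericVector s4(ARE * 4);
      double *p4 = REAL(s4);
      for (int m = 0; m < M; ++m) {
        const double *src = C.data() + (size_t)ARE * m;
        int ysm = (m == 0) ? -1 : (m <= 13 ? m - 1 : m - 14);
        bool w6 = (ysm >= 0 && ysm <= 5), w12 = (ysm >= 0 && ysm <= 11);
        for (int i = 0; i < ARE; ++i) {
          double n = src[i];
          p4[i] += n;
          if (w6) p4[i + ARE] += n;
          if (w12) p4[i + 2 * ARE] += n;
          if (ysm >= 0) p4[i + 3 * ARE] += n;
        }
      }
      stored_sums.push_back(s4);
      stored_at.push_back(t + 1);
    }
  };

  record_pop(0);
  maybe_store(0);

  for (int y = 0; y < Y; ++y) {
    std::fill(Cnew.begin(), Cnew.end(), 0.0);
    double bsum[2] = {0.0, 0.0};
    double dsum = 0.0, msum = 0.0;
    const double *pd_y = REAL(pdie) + (size_t)ARE * y;
    const double *pm_y = REAL(pmove) + (size_t)ARE * y;
    const double *ft_y = REAL(fert) + (size_t)ARE * y;

    for (int e = 0; e < E; ++e) {
      for (int r = 0; r < R; ++r) {
        const int off_re = A * (r + R * e);
        const double *pd = pd_y + off_re;
        const double *pm = pm_y + off_re;
        const double *ft = ft_y + off_re;
        for (int m = 0; m < M; ++m) {
          const double *src = C.data() + off_re + (size_t)ARE * m;
          const int m2 = advance_mig(m);
          double *stay_dst = Cnew.data() + off_re + (size_t)ARE * m2;
          // movers switch residence and reset the migration clock
          const int m_new = (r == 1) ? 1 : 14;
          double *move_dst = Cnew.data() + A * ((1 - r) + R * e) +
                             (size_t)ARE * m_new;
          for (int a = 0; a < A; ++a) {
            double n = src[a];
            if (n <= 0.0) continue;
            double d, mv;
            if (stochastic) {
              d = R::rbinom(n, pd[a]);
              double rest = n - d;
              double cond = (pd[a] < 1.0) ? pm[a] / (1.0 - pd[a]) : 0.0;
              if (cond > 1.0) cond = 1.0;
              mv = (rest > 0.0) ? R::rbinom(rest, cond) : 0.0;
            } else {
              d = n * pd[a];
              mv = n * pm[a];
            }
            double stay = n - d - mv;
            if (stay < 0.0) stay = 0.0;
            dsum += d;
            msum += mv;
            bsum[r] += n * ft[a] * fraction_female;
            int a2 = (a + 1 < A) ? a + 1 : A - 1;
            stay_dst[a2] += stay;
            if (mv > 0.0) move_dst[a2] += mv;
          }
        }
      }
    }

    double btot = 0.0;
    for (int r = 0; r < R; ++r) {
      for (int e = 0; e < E; ++e) {
        double lam = bsum[r] * nb_edu[e + E * (r + R * y)];
        double nb = stochastic ? R::rpois(lam) : lam;
        btot += nb;
        Cnew[A * (r + R * e)] += nb;  // age 0, never moved
      }
    }
    deaths[y] = dsum;
    births[y] = btot;
    moves[y] = msum;

    C.swap(Cnew);
    record_pop(y + 1);
    maybe_store(y + 1);
  }

  NumericVector final_counts(C.begin(), C.end());
  final_counts.attr("dim") = cdim;
  return List::create(_["counts"] = final_counts,
                      _["pop_are"] = popARE,
                      _["deaths"] = deaths,
                      _["births"] = births,
                      _["moves"] = moves,
                      _["stored"] = stored,
                      _["stored_sums"] = stored_sums,
                      _["stored_at"] = wrap(stored_at));
}
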