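// Exact event-driven (non-Markovian) Monte Carlo of clonal dynamics in a
// stratified epithelium. Each live cell is represented by exactly one
// pending event in a binary heap: a division (proliferating cell), a
// stratification (differentiating basal cell) or a shedding (suprabasal
// cell, only when a shedding rate is configured). Division and
// stratification waiting times are drawn at cell birth, so arbitrary
// cell-cycle laws are exact without time discretization.
//
// Up to two proliferating cell types are supported; daughter-pair fates
// are drawn from a per-type probability vector over the six unordered
// pairs {AA, AB, AD, BB, BD, DD} where D is a differentiating basal cell.
// The single-progenitor model is the one-type special case (AA, AD, DD) =
// (r, 1 - 2r, r).
//
// All draws go through R's RNG so set.seed() in R controls everything.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Event {
  double t;
  int kind;           // 0..K-1 division of type k; K strat; K+1 shed
  double intensity;   // H2B-GFP label content carried by the cell
};
struct Later {
  bool operator()(const Event& a, const Event& b) const { return a.t > b.t; }
};

struct CycleLaw {
  int family;         // 0 exponential, 1 shifted gamma, 2 deterministic
  double mean, shape, tmin, scale;  // scale = (mean - tmin) / shape
};

inline double draw_cycle(const CycleLaw& c) {
  switch (c.family) {
  case 0: return R::rexp(c.mean);
  case 1: return c.tmin + R::rgamma(c.shape, c.scale);
  default: return c.mean;
  }
}

// Stationary-renewal residual life: U * X_star with X_star length-biased.
inline double draw_phase(const CycleLaw& c) {
  double x_star;
  switch (c.family) {
  case 0: x_star = R::rgamma(2.0, c.mean); break;
  case 1: {
    double b = (unif_rand() < (c.mean - c.tmin) / c.mean) ? 1.0 : 0.0;
    x_star = c.tmin + R::rgamma(c.shape + b, c.scale);
    break;
  }
  default: x_star = c.mean;
  }
  return unif_rand() * x_star;
}

struct Engine {
  int K;                       // number of proliferating types
  std::vector<CycleLaw> law;   // per type
  std::vector<std::vector<double>> fate_cum;  // per type, cumulative over 6 pairs
  double gamma_day;            // stratification rate (/day), may be +Inf
  double mu_day;               // shedding rate (/day), <= 0 disables tracking decay
  double part_alpha;           // > 0: beta-distributed label partition

  std::vector<Event> heap;
  long np[2];                  // proliferating count per type
  long nd, ns;                 // differentiating basal, suprabasal

  void reset() { heap.clear(); np[0] = np[1] = 0; nd = 0; ns = 0; }

  void push(double t, int kind, double inten) {
    heap.push_back(Event{t, kind, inten});
    std::push_heap(heap.begin(), heap.end(), Later());
  }

  void add_prolif(double t, int type, double inten, bool stationary) {
    double w = stationary ? draw_phase(law[type]) : draw_cycle(law[type]);
    push(t + w, type, inten);
    ++np[type];
  }

  void add_diff(double t, double inten) {
    if (!R_finite(gamma_day)) {     // instant stratification
      ++ns;
      if (mu_day > 0) push(t + R::rexp(1.0 / mu_day), K + 1, 0.0);
      return;
    }
    push(t + R::rexp(1.0 / gamma_day), K, inten);
    ++nd;
  }

  // Split the parent's label between the two daughters.
  void split(double inten, double& a, double& b) {
    if (part_alpha > 0) {
      double q = R::rbeta(part_alpha, part_alpha);
      a = inten * q; b = inten * (1.0 - q);
    } else {
      a = b = inten * 0.5;
    }
  }

  void divide(double t, int type, double inten) {
    --np[type];
    double u = unif_rand();
    const std::vector<double>& cum = fate_cum[type];
    int pair = 0;
    while (pair < 5 && u > cum[pair]) ++pair;
    double ia, ib;
    split(inten, ia, ib);
    switch (pair) {            // {AA, AB, AD, BB, BD, DD}
    case 0: add_prolif(t, 0, ia, false); add_prolif(t, 0, ib, false); break;
    case 1: add_prolif(t, 0, ia, false); add_prolif(t, 1, ib, false); break;
    case 2: add_prolif(t, 0, ia, false); add_diff(t, ib); break;
    case 3: add_prolif(t, 1, ia, false); add_prolif(t, 1, ib, false); break;
    case 4: add_prolif(t, 1, ia, false); add_diff(t, ib); break;
    default: add_diff(t, ia); add_diff(t, ib);
    }
  }

  void step(const Event& e) {
    if (e.kind < K) {
      divide(e.t, e.kind, e.intensity);
    } else if (e.kind == K) {  // stratification
      --nd; ++ns;
      if (mu_day > 0) push(e.t + R::rexp(1.0 / mu_day), K + 1, 0.0);
    } else {                   // shedding
      --ns;
    }
  }

  void run_until(double t_stop) {
    while (!heap.empty() && heap.front().t <= t_stop) {
      Event e = heap.front();
      std::pop_heap(heap.begin(), heap.end(), Later());
      heap.pop_back();
      step(e);
    }
  }
};

Engine make_engine(const NumericMatrix& fate, const IntegerVector& fam,
                   const NumericVector& mean_cc, const NumericVector& shape,
                   const NumericVector& tmin, double gamma_day, double mu_day,
                   double part_alpha) {
  Engine eng;
  eng.K = fate.nrow();
  if (eng.K < 1 || eng.K > 2) stop("one or two proliferating types supported");
  if (fate.ncol() != 6) stop("fate matrix must have 6 columns");
  eng.law.resize(eng.K);
  eng.fate_cum.resize(eng.K);
  for (int k = 0; k < eng.K; ++k) {
    CycleLaw c;
    c.family = fam[k]; c.mean = mean_cc[k]; c.shape = shape[k]; c.tmin = tmin[k];
    c.scale = (c.family == 1) ? (c.mean - c.tmin) / c.shape : 0.0;
    eng.law[k] = c;
    eng.fate_cum[k].resize(6);
    double s = 0.0;
    for (int j = 0; j < 6; ++j) { s += fate(k, j); eng.fate_cum[k][j] = s; }
    if (std::abs(s - 1.0) > 1e-8) stop("fate probabilities must sum to 1");
  }
  eng.gamma_day = gamma_day;
  eng.mu_day = mu_day;
  eng.part_alpha = part_alpha;
  return eng;
}

int draw_type(const NumericVector& frac) {
  if (frac.size() == 1) return 0;
  return (unif_rand() < frac[0]) ? 0 : 1;
}

} // namespace

// Simulate an ensemble of independent clones and record basal/suprabasal
// composition at each requested time (days). init_mode: 0 = proliferating
// cell (type drawn from frac), 1 = representative basal cell (proliferating
// with probability rho, else differentiating).
// [[Rcpp::export]]
List cpp_simulate_sizes(int n_clones, NumericVector record_times,
                        NumericMatrix fate, IntegerVector fam,
                        NumericVector mean_cc, NumericVector shape,
                        NumericVector tmin, double gamma_day, double mu_day,
                        double rho, NumericVector frac, int init_mode,
                        double part_alpha = 0.0) {
  Engine eng = make_engine(fate, fam, mean_cc, shape, tmin, gamma_day, mu_day,
                           part_alpha);
  const int T = record_times.size();
  IntegerMatrix m_prolif(n_clones, T), m_diff(n_clones, T), m_supra(n_clones, T);
  for (int i = 0; i < n_clones; ++i) {
    eng.reset();
    if (init_mode == 0 || unif_rand() < rho) {
      eng.add_prolif(0.0, draw_type(frac), 1.0, true);
    } else {
      eng.add_diff(0.0, 1.0);
    }
    for (int j = 0; j < T; ++j) {
      eng.run_until(record_times[j]);
      m_prolif(i, j) = eng.np[0] + eng.np[1];
      m_diff(i, j) = eng.nd;
      m_supra(i, j) = eng.ns;
    }
  }
  return List::create(_["n_progenitor"] = m_prolif, _["n_diff_basal"] = m_diff,
                      _["n_suprabasal"] = m_supra);
}

// Simulate label dilution in a pooled homeostatic basal population started
// from n_initial independent lineages with the given initial intensities.
// At each chase time the intensities of all basal cells then alive are
// returned (every live basal cell holds exactly one pending event in the
// heap, which is scanned directly).
// [[Rcpp::export]]
List cpp_simulate_dilution(NumericVector init_intensity,
                           NumericVector chase_times, NumericMatrix fate,
                           IntegerVector fam, NumericVector mean_cc,
                           NumericVector shape, NumericVector tmin,
                           double gamma_day, double rho, NumericVector frac,
                           double part_alpha = 0.0) {
  Engine eng = make_engine(fate, fam, mean_cc, shape, tmin, gamma_day,
                           /*mu_day=*/-1.0, part_alpha);
  eng.reset();
  const int n0 = init_intensity.size();
  for (int i = 0; i < n0; ++i) {
    if (unif_rand() < rho) eng.add_prolif(0.0, draw_type(frac),
                                          init_intensity[i], true);
    else eng.add_diff(0.0, init_intensity[i]);
  }
  const int T = chase_times.size();
  List out(T);
  for (int j = 0; j < T; ++j) {
    eng.run_until(chase_times[j]);
    std::vector<double> basal;
    basal.reserve(eng.heap.size());
    for (const Event& e : eng.heap)
      if (e.kind <= eng.K) basal.push_back(e.intensity);
    out[j] = NumericVector(basal.begin(), basal.end());
  }
  return out;
}
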