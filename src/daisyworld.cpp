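#include <Rcpp.h>
using namespace Rcpp;

// Daisyworld grid stepper. Species coding: 0 = empty, 1 = black, 2 = white.
// Toroidal grid with Moore (8-)neighbourhoods. One tick is:
//   1. heating: absorbed = (1 - albedo) * luminosity * solar_constant;
//      local_heating = 72*ln(absorbed) + 80 (80 when absorbed <= 0);
//      temperature <- (temperature + local_heating) / 2
//   2. diffusion: each patch keeps 50% of its temperature and splits the
//      other 50% equally among its 8 neighbours
//   3. ageing: every living daisy ages one tick; daisies reaching max_age
//      die (optionally also those outside [5,40] C when hard_kill is set)
//   4. sprouting: daisies are visited in a freshly shuffled order; each
//      attempts with probability p(T) = 0.1457*T - 0.0032*T^2 - 0.6443
//      (clipped to [0,1], evaluated at the parent's local temperature) to
//      seed one uniformly chosen Moore neighbour, succeeding only if that
//      patch is currently empty, so growth slows as neighbourhoods fill.
//      Claims are first-come within a tick.
// Uses R's RNG so results are governed by set.seed().

static inline int wrap(int v, int n) { return (v % n + n) % n; }

// [[Rcpp::export]]
List cpp_dw_simulate(IntegerVector species, IntegerVector age,
                     NumericVector temperature, int width, int height,
                     double luminosity, int steps,
                     double albedo_black, double albedo_white,
                     double albedo_surface, double solar_constant,
                     int max_age, bool hard_kill, bool record_counts) {
  const int n = width * height;
  if (species.size() != n || age.size() != n || temperature.size() != n)
    stop("state vectors must have width*height elements");

  IntegerVector sp = clone(species);
  IntegerVector ag = clone(age);
  NumericVector te = clone(temperature);
  NumericVector te_new(n);
  std::vector<int> daisies; daisies.reserve(n);

  // precompute Moore neighbour indices (toroidal)
  std::vector<int> nbr(n * 8);
  for (int y = 0; y < height; ++y) {
    for (int x = 0; x < width; ++x) {
      int p = y * width + x, q = 0;
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0) continue;
          nbr[p * 8 + q++] = wrap(y + dy, height) * width + wrap(x + dx, width);
        }
    }
  }

  IntegerMatrix counts(record_counts ? steps : 0, 3);

  for (int t = 0; t < steps; ++t) {
    // 1. heating
    for (int p = 0; p < n; ++p) {
      double albedo = sp[p] == 1 ? albedo_black
                    : sp[p] == 2 ? albedo_white : albedo_surface;
      double absorbed = (1.0 - albedo) * luminosity * solar_constant;
      double h = absorbed > 0 ? 72.0 * std::log(absorbed) + 80.0 : 80.0;
      te[p] = (te[p] + h) / 2.0;
    }
    // 2. diffusion (50% shared equally with 8 neighbours)
    for (int p = 0; p < n; ++p) {
      double recv = 0.0;
      for (int q = 0; q < 8; ++q) recv += te[nbr[p * 8 + q]];
      te_new[p] = 0.5 * te[p] + recv * (0.5 / 8.0);
    }
    std::copy(te_new.begin(), te_new.end(), te.begin());
    // 3. ageing and death
    for (int p = 0; p < n; ++p) {
      if (sp[p] != 0) {
        if (++ag[p] >= max_age ||
            (hard_kill && (te[p] < 5.0 || te[p] > 40.0))) {
          sp[p] = 0; ag[p] = 0;
        }
      }
    }
    // 4. sprouting, shuffled daisy order
    daisies.clear();
    for (int p = 0; p < n; ++p) if (sp[p] != 0) daisies.push_back(p);
    const int nd = (int) daisies.size();
    for (int i = nd - 1; i > 0; --i) {  // Fisher-Yates with R's RNG
      int j = (int) (unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(daisies[i], daisies[j]);
    }
    for (int i = 0; i < nd; ++i) {
      int p = daisies[i];
      double T = te[p];
      double prob = 0.1457 * T - 0.0032 * T * T - 0.6443;
      if (prob <= 0.0) continue;
      if (prob > 1.0) prob = 1.0;
      if (unif_rand() >= prob) continue;
      int q = (int) (unif_rand() * 8);
      if (q > 7) q = 7;
      int tgt = nbr[p * 8 + q];
      if (sp[tgt] == 0) { sp[tgt] = sp[p]; ag[tgt] = 0; }
    }
    if (record_counts) {
      int nb = 0, nw = 0;
      for (int p = 0; p < n; ++p) {
        if (sp[p] == 1) ++nb; else if (sp[p] == 2) ++nw;
      }
      counts(t, 0) = nb; counts(t, 1) = nw; counts(t, 2) = n - nb - nw;
    }
  }

  List out = List::create(_["species"] = sp, _["age"] = ag,
                          _["temperature"] = te);
  if (record_counts) out["counts_ts"] = counts;
  return out;
}
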