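// 2D Brownian-dynamics engine with lambda-rho bimolecular reactions on a
// periodic square. Per time step: Euler-Maruyama diffusion of all molecules,
// then first-order reactions (independent Bernoulli per molecule), then
// bimolecular reactions over all reactant pairs within the reactive radius
// (candidates from a cell list or an all-pairs scan, processed in random
// order, one reaction per molecule per step).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

namespace {

struct PSys {
  std::vector<double> x, y;
  std::vector<int> type;     // -1 = dead
  int nalive = 0;

  void compact() {
    size_t j = 0;
    for (size_t i = 0; i < type.size(); ++i)
      if (type[i] >= 0) {
        if (i != j) { x[j] = x[i]; y[j] = y[i]; type[j] = type[i]; }
        ++j;
      }
    x.resize(j); y.resize(j); type.resize(j);
  }
};

inline double wrap(double v, double L) {
  v -= L * std::floor(v / L);
  return (v >= L) ? 0.0 : v;  // guard against floor rounding at the boundary
}

inline double dist2_mi(double dx, double dy, double L) {
  dx = std::fabs(dx); if (dx > 0.5 * L) dx = L - dx;
  dy = std::fabs(dy); if (dy > 0.5 * L) dy = L - dy;
  return dx * dx + dy * dy;
}

} // namespace

// [[Rcpp::export(name = ".pb_run")]]
List pb_run(double L, double dt, double t_end, double record_interval,
            NumericVector sp_D,
            IntegerVector type0, NumericVector x0, NumericVector y0,
            LogicalVector init_random, IntegerVector init_total,
            IntegerVector uni_reactant, NumericVector uni_rate,
            IntegerMatrix uni_products, NumericVector uni_sep,
            IntegerVector bi_ra, IntegerVector bi_rb,
            NumericVector bi_lambda, NumericVector bi_rho,
            IntegerMatrix bi_products, IntegerMatrix bi_prodsrc,
            bool record_positions, int stop_species, int nreps,
            double seed, double stream0, bool force_cell_list) {
  const int nspec = sp_D.size();
  const int nuni = uni_reactant.size(), nbi = bi_ra.size();
  std::vector<double> step_sd(nspec);
  for (int s = 0; s < nspec; ++s) step_sd[s] = std::sqrt(2.0 * sp_D[s] * dt);
  std::vector<double> uni_p(nuni);
  for (int u = 0; u < nuni; ++u) uni_p[u] = 1.0 - std::exp(-uni_rate[u] * dt);
  std::vector<double> bi_p(nbi);
  double rho_max = 0.0;
  for (int b = 0; b < nbi; ++b) {
    bi_p[b] = 1.0 - std::exp(-bi_lambda[b] * dt);
    if (bi_rho[b] > rho_max) rho_max = bi_rho[b];
  }
  // species-pair -> reaction lookup; orientation flag (was the first molecule
  // of the pair reactant a?)
  std::vector<int> pair_rx((size_t)nspec * nspec, -1);
  std::vector<char> pair_ori((size_t)nspec * nspec, 1);
  for (int b = 0; b < nbi; ++b) {
    pair_rx[(size_t)bi_ra[b] * nspec + bi_rb[b]] = b;
    pair_ori[(size_t)bi_ra[b] * nspec + bi_rb[b]] = 1;
    pair_rx[(size_t)bi_rb[b] * nspec + bi_ra[b]] = b;
    pair_ori[(size_t)bi_rb[b] * nspec + bi_ra[b]] = 0;
  }
  // uni reactions grouped by reactant species
  std::vector<std::vector<int> > uni_by_sp(nspec);
  for (int u = 0; u < nuni; ++u) uni_by_sp[uni_reactant[u]].push_back(u);

  long nsteps = (long)std::llround(t_end / dt);
  int rec_every = 1;
  if (R_finite(record_interval) && record_interval > 0)
    rec_every = std::max(1, (int)std::llround(record_interval / dt));
  int ntimes = R_finite(record_interval) && record_interval > 0
    ? (int)(nsteps / rec_every) + 1 : 1;

  NumericVector rec_times(ntimes);
  for (int i = 0; i < ntimes; ++i) rec_times[i] = (double)i * rec_every * dt;
  NumericVector totals(Dimension(ntimes, nspec, nreps));
  NumericVector stop_times(nreps, NA_REAL);
  List pos_rec(record_positions ? ntimes : 0);
  if (record_positions && nreps != 1)
    stop("position recording requires nreps = 1");

  std::vector<int> cand_i, cand_j, cand_b;
  std::vector<int> cell_head, cell_next;

  for (int rep = 0; rep < nreps; ++rep) {
    Xoshiro rng((uint64_t)seed, (uint64_t)stream0 + (uint64_t)rep);
    PSys P;
    if (init_random[0]) {
      for (int s = 0; s < nspec; ++s)
        for (int m = 0; m < init_total[s]; ++m) {
          P.x.push_back(rng.unif() * L);
          P.y.push_back(rng.unif() * L);
          P.type.push_back(s);
        }
    } else {
      P.x.assign(x0.begin(), x0.end());
      P.y.assign(y0.begin(), y0.end());
      P.type.assign(type0.begin(), type0.end());
    }
    P.nalive = (int)P.type.size();
    std::vector<int> tot(nspec, 0);
    for (size_t i = 0; i < P.type.size(); ++i) tot[P.type[i]]++;

    int next_rec = 0;
    auto record_state = [&](int slot) {
      for (int s = 0; s < nspec; ++s)
        totals[slot + ntimes * (s + nspec * rep)] = tot[s];
      if (record_positions) {
        NumericMatrix m(P.nalive, 3);
        int r = 0;
        for (size_t i = 0; i < P.type.size(); ++i)
          if (P.type[i] >= 0) {
            m(r, 0) = P.type[i]; m(r, 1) = P.x[i]; m(r, 2) = P.y[i]; ++r;
          }
        pos_rec[slot] = m;
      }
    };
    record_state(next_rec++);

    bool stopped = false;
    std::vector<char> used;
    for (long step = 0; step < nsteps && !stopped; ++step) {
      if ((step & 0xFFF) == 0) Rcpp::checkUserInterrupt();
      size_t n = P.type.size();

      // diffusion
      for (size_t i = 0; i < n; ++i) {
        int s = P.type[i];
        if (s < 0) continue;
        double sd = step_sd[s];
        if (sd > 0) {
          P.x[i] = wrap(P.x[i] + rng.norm() * sd, L);
          P.y[i] = wrap(P.y[i] + rng.norm() * sd, L);
        }
      }

      // first-order reactions: independent Bernoulli per molecule per
      // reaction, processed in declaration order; one conversion per molecule
      for (size_t i = 0; i < n; ++i) {
        int s = P.type[i];
        if (s < 0 || uni_by_sp[s].empty()) continue;
        for (int u : uni_by_sp[s]) {
          if (uni_p[u] <= 0 || rng.unif() >= uni_p[u]) continue;
          int p1 = uni_products(u, 0), p2 = uni_products(u, 1);
          if (p2 < 0) {
            if (p1 >= 0) {
              P.type[i] = p1; tot[p1]++;
            } else { P.type[i] = -1; P.nalive--; }
            tot[s]--;
          } else {
            // dissociation: first product in place, second at distance sep
            P.type[i] = p1; tot[p1]++; tot[s]--;
            double a = rng.unif() * 6.283185307179586;
            P.x.push_back(wrap(P.x[i] + uni_sep[u] * std::cos(a), L));
            P.y.push_back(wrap(P.y[i] + uni_sep[u] * std::sin(a), L));
            P.type.push_back(p2);
            tot[p2]++; P.nalive++;
          }
          break;
        }
      }

      // bimolecular reactions
      if (nbi > 0 && rho_max > 0) {
        size_t m = P.type.size();
        cand_i.clear(); cand_j.clear(); cand_b.clear();
        double rho2;
        int nc = (int)std::floor(L / rho_max);
        if (nc > 4096) nc = 4096;
        // half-neighbor cell enumeration needs >= 3 cells per axis to avoid
        // periodic aliasing; otherwise fall back to the all-pairs scan
        if ((P.nalive <= 64 && !force_cell_list) || nc < 3) {
          for (size_t i = 0; i < m; ++i) {
            if (P.type[i] < 0) continue;
            for (size_t j = i + 1; j < m; ++j) {
              if (P.type[j] < 0) continue;
              int b = pair_rx[(size_t)P.type[i] * nspec + P.type[j]];
              if (b < 0) continue;
              rho2 = bi_rho[b] * bi_rho[b];
              if (dist2_mi(P.x[i] - P.x[j], P.y[i] - P.y[j], L) <= rho2) {
                cand_i.push_back((int)i); cand_j.push_back((int)j);
                cand_b.push_back(b);
              }
            }
          }
        } else {
          double cw = L / nc;
          cell_head.assign((size_t)nc * nc, -1);
          cell_next.assign(m, -1);
          for (size_t i = 0; i < m; ++i) {
            if (P.type[i] < 0) continue;
            int cx = (int)(P.x[i] / cw); if (cx >= nc) cx = nc - 1;
            int cy = (int)(P.y[i] / cw); if (cy >= nc) cy = nc - 1;
            int c = cx + nc * cy;
            cell_next[i] = cell_head[c];
            cell_head[c] = (int)i;
          }
          for (int cy = 0; cy < nc; ++cy)
            for (int cx = 0; cx < nc; ++cx) {
              int c = cx + nc * cy;
              for (int i = cell_head[c]; i >= 0; i = cell_next[i]) {
                // same cell: j after i in list
                for (int j = cell_next[i]; j >= 0; j = cell_next[j]) {
                  int b = pair_rx[(size_t)P.type[i] * nspec + P.type[j]];
                  if (b < 0) continue;
                  rho2 = bi_rho[b] * bi_rho[b];
                  if (dist2_mi(P.x[i] - P.x[j], P.y[i] - P.y[j], L) <= rho2) {
                    cand_i.push_back(i); cand_j.push_back(j);
                    cand_b.push_back(b);
                  }
                }
                // half of the neighbor cells (unique cell pairs)
                static const int NX[4] = {1, 1, 0, -1};
                static const int NY[4] = {0, 1, 1, 1};
                for (int d = 0; d < 4; ++d) {
                  int ax = (cx + NX[d] + nc) % nc, ay = (cy + NY[d] + nc) % nc;
                  int c2 = ax + nc * ay;
                  if (c2 == c) continue;
                  for (int i2 = cell_head[c2]; i2 >= 0; i2 = cell_next[i2]) {
                    int b = pair_rx[(size_t)P.type[i] * nspec + P.type[i2]];
                    if (b < 0) continue;
                    rho2 = bi_rho[b] * bi_rho[b];
                    if (dist2_mi(P.x[i] - P.x[i2], P.y[i] - P.y[i2], L) <= rho2) {
                      cand_i.push_back(i); cand_j.push_back(i2);
                      cand_b.push_back(b);
                    }
                  }
                }
              }
            }
        }

        size_t npair = cand_b.size();
        if (npair) {
          // random processing order; a molecule reacts at most once per step
          for (size_t i = npair - 1; i > 0; --i) {
            size_t j = (size_t)(rng.unif() * (i + 1));
            std::swap(cand_i[i], cand_i[j]);
            std::swap(cand_j[i], cand_j[j]);
            std::swap(cand_b[i], cand_b[j]);
          }
          used.assign(P.type.size(), 0);
          for (size_t p = 0; p < npair; ++p) {
            int i = cand_i[p], j = cand_j[p], b = cand_b[p];
            if (used[i] || used[j]) continue;
            if (rng.unif() >= bi_p[b]) continue;
            used[i] = used[j] = 1;
            // orient (a, b) reactants
            int ia = (P.type[i] == bi_ra[b]) ? i : j;
            int ib = (ia == i) ? j : i;
            int ta = P.type[ia], tb = P.type[ib];
            tot[ta]--; tot[tb]--;
            P.type[ia] = P.type[ib] = -1;
            P.nalive -= 2;
            for (int q = 0; q < 2; ++q) {
              int pr = bi_products(b, q);
              if (pr < 0) continue;
              int src = bi_prodsrc(b, q);  // 1 = reactant a, 2 = reactant b
              int at = (src == 1) ? ia : ib;
              P.x.push_back(P.x[at]); P.y.push_back(P.y[at]);
              P.type.push_back(pr);
              tot[pr]++; P.nalive++;
            }
          }
        }
      }

      if ((int)P.type.size() > 2 * P.nalive + 64) P.compact();

      double tnow = (step + 1) * dt;
      if ((step + 1) % rec_every == 0 && next_rec < ntimes)
        record_state(next_rec++);
      if (stop_species >= 0 && tot[stop_species] == 0) {
        stop_times[rep] = tnow;
        stopped = true;
      }
    }
    // pad remaining record slots (early stop) with final totals
    while (next_rec < ntimes) record_state(next_rec++);
  }

  List out = List::create(
    _["times"] = rec_times,
    _["totals"] = totals,
    _["stop_times"] = stop_times);
  if (record_positions) out["positions"] = pos_rec;
  return out;
}

// Pairwise candidate search used by the cell-list equivalence test: returns
// unordered index pairs (1-based) within cutoff under the minimum-image metric.
// [[Rcpp::export(name = ".pairs_within")]]
IntegerMatrix pairs_within(NumericVector x, NumericVector y, double L,
                           double cutoff) {
  int n = x.size();
  std::vector<int> ii, jj;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist2_mi(x[i] - x[j], y[i] - y[j], L) <= c2) {
        ii.push_back(i + 1); jj.push_back(j + 1);
      }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// Histogram of pairwise minimum-image distances (unordered pairs counted once)
// on bins defined by breaks (left-open, right-closed except the first bin).
// [[Rcpp::export(name = ".pair_dist_hist")]]
NumericVector pair_dist_hist(NumericVector x, NumericVector y, double L,
                             NumericVector breaks) {
  int n = x.size(), nb = breaks.size() - 1;
  NumericVector counts(nb);
  double rmax = breaks[nb], rmin = breaks[0];
  double w = (breaks[1] - breaks[0]);
  // detect uniform bin width for O(1) binning
  bool uni = true;
  for (int b = 1; b < nb; ++b)
    if (std::fabs((breaks[b + 1] - breaks[b]) - w) > 1e-12 * w) { uni = false; break; }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = std::sqrt(dist2_mi(x[i] - x[j], y[i] - y[j], L));
      if (d < rmin || d > rmax) continue;
      int b;
      if (uni) {
        b = (int)((d - rmin) / w);
        if (b >= nb) b = nb - 1;
      } else {
        b = (int)(std::upper_bound(breaks.begin(), breaks.end(), d) -
                  breaks.begin()) - 1;
        if (b >= nb) b = nb - 1;
        if (b < 0) b = 0;
      }
      counts[b] += 1.0;
    }
  return counts;
}
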