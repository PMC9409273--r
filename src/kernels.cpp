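// Compiled kernels: fused particle-based pulse simulator, aggregated
// Markov-ensemble gating sampler, 8-connected component labeling and
// brute-force nearest-neighbour search. All randomness flows through R's
// RNG (RNGScope), so set.seed() at the R level gives full reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Fast inline RNG (xoshiro256++) for the particle hot loops; seeded from
// R's RNG so that set.seed() still controls every run. Low-rate draws
// (Poisson injection, binomial counts, gating) stay on R's RNG.
struct XoRng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit XoRng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 1.1102230246251565e-16; }
};

// ---------------------------------------------------------------------------
// Aggregated ensemble sampler for a continuous-time Markov gating scheme.
// counts0: initial per-state channel counts; Q: generator (rates, s^-1);
// n_steps recording steps, each of n_sub substeps of length dt_s.
// Transitions per substep are sampled state-by-state with sequential
// binomials (exact multinomial decomposition).
// [[Rcpp::export]]
IntegerMatrix ensemble_kernel_cpp(IntegerVector counts0, NumericMatrix Q,
                                  int n_steps, int n_sub, double dt_s) {
  const int ns = counts0.size();
  std::vector<long> counts(ns);
  for (int i = 0; i < ns; ++i) counts[i] = counts0[i];

  // per-state outgoing edges and substep probabilities
  std::vector<std::vector<int> > tgt(ns);
  std::vector<std::vector<double> > pr(ns);
  for (int i = 0; i < ns; ++i) {
    double ptot = 0.0;
    for (int j = 0; j < ns; ++j) {
      if (j == i) continue;
      double p = Q(i, j) * dt_s;
      if (p > 0) { tgt[i].push_back(j); pr[i].push_back(p); ptot += p; }
    }
    if (ptot > 0.5)
      stop("substep too coarse: total exit probability %f > 0.5", ptot);
  }

  IntegerMatrix out(n_steps + 1, ns);
  for (int i = 0; i < ns; ++i) out(0, i) = counts[i];
  std::vector<long> delta(ns);

  for (int step = 0; step < n_steps; ++step) {
    for (int sub = 0; sub < n_sub; ++sub) {
      std::fill(delta.begin(), delta.end(), 0L);
      for (int i = 0; i < ns; ++i) {
        long n = counts[i];
        if (n == 0 || tgt[i].empty()) continue;
        double rem = 1.0;
        for (size_t e = 0; e < tgt[i].size(); ++e) {
          if (n == 0) break;
          double pc = pr[i][e] / rem;   // conditional on not having left yet
          if (pc > 1.0) pc = 1.0;
          long k = (long) R::rbinom((double) n, pc);
          if (k > 0) { delta[i] -= k; delta[tgt[i][e]] += k; n -= k; }
          rem -= pr[i][e];
          if (rem <= 0) break;
        }
      }
      for (int i = 0; i < ns; ++i) counts[i] += delta[i];
    }
    for (int i = 0; i < ns; ++i) out(step + 1, i) = counts[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fused pulse kernel. Geometry is passed as id_of_cell (0 = outside the
// domain, else 1-based voxel id over a nx*ny*nz grid); ions live on voxel
// ids. Buffer totals are uniform per voxel. Gating runs per channel with
// substepped jump sampling; reactions are substepped so per-event
// probabilities stay small; diffusion uses the lattice walk at the master
// step. Returns recorded traces plus the final ledger.
// [[Rcpp::export]]
List pulse_kernel_cpp(IntegerVector dims, IntegerVector id_of_cell,
                      IntegerVector slice, int n_voxels,
                      IntegerVector channels, IntegerVector ves_vox,
                      NumericMatrix Q, int open_state, int init_state,
                      double p_move,
                      int n_steps, int pre_steps, int record_every,
                      double dt, int n_sub_react, int n_sub_gate,
                      double inj_mean_per_open_step,
                      int b_total, double k1_buf, double koff_buf,
                      double k1_ves, double koff_ves, double gamma_fuse,
                      int sites_total, double basal_lambda) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny;
  const int ns = Q.nrow();
  const double dt_r = dt / n_sub_react;
  const double dt_g = dt / n_sub_gate;

  // voxel id -> linear cell index
  std::vector<int> cell_of(n_voxels + 1, -1);
  for (int c = 0; c < id_of_cell.size(); ++c)
    if (id_of_cell[c] > 0) cell_of[id_of_cell[c]] = c;

  // gating edge tables
  std::vector<std::vector<int> > gt(ns);
  std::vector<std::vector<double> > gp(ns);
  for (int i = 0; i < ns; ++i) {
    double ptot = 0;
    for (int j = 0; j < ns; ++j) {
      if (j == i) continue;
      double p = Q(i, j) * dt_g;
      if (p > 0) { gt[i].push_back(j); gp[i].push_back(p); ptot += p; }
    }
    if (ptot > 0.5) stop("gating substep too coarse");
  }

  // Buffer kinetics run once per master step with substep-compounded
  // probabilities: an ion in a voxel with bf free sites binds with
  // p_eff[bf] = 1 - (1 - p1)^n_sub (first-success over the substeps); a
  // bound ion unbinds with q_eff = 1 - (1 - q1)^n_sub, but an unbinding
  // ion may rebind within its remaining substeps (j ~ uniform) with
  // probability 1 - (1 - p1)^j, which reproduces the substep-resolved
  // bind/unbind equilibrium without per-substep passes over every ion.
  std::vector<double> p1(b_total + 1), p_eff(b_total + 1);
  std::vector<double> rebind((b_total + 1) * n_sub_react);
  for (int b = 0; b <= b_total; ++b) {
    p1[b] = 1.0 - std::exp(-k1_buf * b * dt_r);
    p_eff[b] = 1.0 - std::pow(1.0 - p1[b], n_sub_react);
    for (int j = 0; j < n_sub_react; ++j)
      rebind[b * n_sub_react + j] = 1.0 - std::pow(1.0 - p1[b], j);
  }
  const double q1 = 1.0 - std::exp(-koff_buf * dt_r);
  const double q_eff = 1.0 - std::pow(1.0 - q1, n_sub_react);
  const double q_off_ves = 1.0 - std::exp(-koff_ves * dt_r);
  const double p_fuse = 1.0 - std::exp(-gamma_fuse * dt);

  // state
  std::vector<int> free_ions;          // voxel id per free ion
  std::vector<int> free_ct(n_voxels + 1, 0);
  std::vector<int> buf_bound(n_voxels + 1, 0);
  std::vector<int> bound_list;         // voxel id per buffer-bound ion
  const int n_ch = channels.size();
  std::vector<int> ch_state(n_ch, init_state - 1);
  const int n_ves = ves_vox.size();
  std::vector<int> v_sites(n_ves, 0);
  std::vector<bool> v_fused(n_ves, false);
  std::vector<double> v_time(n_ves, NA_REAL);

  long injected = 0, consumed = 0, basal_placed = 0;

  // hot-loop RNG, seeded from R's RNG stream
  uint64_t kseed = (uint64_t) (R::unif_rand() * 4294967296.0);
  kseed = (kseed << 32) ^ (uint64_t) (R::unif_rand() * 4294967296.0);
  XoRng rng(kseed);

  // basal free calcium, Poisson per voxel
  for (int v = 1; v <= n_voxels; ++v) {
    int k = (int) R::rpois(basal_lambda);
    for (int m = 0; m < k; ++m) free_ions.push_back(v);
    free_ct[v] += k;
    basal_placed += k;
  }

  const int n_rec = n_steps / record_every + 2;
  NumericVector r_time(n_rec);
  IntegerVector r_open(n_rec), r_free(n_rec), r_free_s0(n_rec),
      r_buf(n_rec), r_vesb(n_rec), r_fused(n_rec);
  NumericVector r_inj(n_rec), r_consumed(n_rec);
  int rec = 0;

  for (int step = -pre_steps; step < n_steps; ++step) {
    const bool pulsing = step >= 0;

    // --- gating + injection + fusion (pulse phase only) ---
    int n_open = 0;
    if (pulsing) {
      for (int c = 0; c < n_ch; ++c) {
        for (int sub = 0; sub < n_sub_gate; ++sub) {
          int s = ch_state[c];
          if (gt[s].empty()) continue;
          double u = R::unif_rand(), acc = 0;
          for (size_t e = 0; e < gt[s].size(); ++e) {
            acc += gp[s][e];
            if (u < acc) { ch_state[c] = gt[s][e]; break; }
          }
        }
        if (ch_state[c] == open_state - 1) {
          ++n_open;
          int k = (int) R::rpois(inj_mean_per_open_step);
          if (k > 0) {
            int v = channels[c];
            for (int m = 0; m < k; ++m) free_ions.push_back(v);
            free_ct[v] += k;
            injected += k;
          }
        }
      }
      // fusion on the entry state, master dt
      for (int i = 0; i < n_ves; ++i) {
        if (!v_fused[i] && v_sites[i] == sites_total &&
            R::unif_rand() < p_fuse) {
          v_fused[i] = true;
          v_time[i] = step * dt;
          consumed += v_sites[i];
          v_sites[i] = 0;
        }
      }
    }

    // --- diffusion (lattice walk, bounce at walls) ---
    for (size_t i = 0; i < free_ions.size(); ++i) {
      double u = rng.unif();
      if (u >= p_move) continue;
      int dir = (int) (u / p_move * 6.0);
      if (dir > 5) dir = 5;
      int c = cell_of[free_ions[i]];
      int ii = c % nx, jj = (c / nx) % ny, kk = c / nxy;
      switch (dir) {
        case 0: ++ii; break; case 1: --ii; break;
        case 2: ++jj; break; case 3: --jj; break;
        case 4: ++kk; break; default: --kk; break;
      }
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;                       // bounce
      int tid = id_of_cell[ii + nx * jj + nxy * kk];
      if (tid <= 0) continue;           // bounce at the cone wall
      --free_ct[free_ions[i]];
      free_ions[i] = tid;
      ++free_ct[tid];
    }

    // --- buffer reactions, one compounded pass per master step ---
    {
      // binding over the start-of-step free pool (iterate from the end so
      // swap-removal is safe)
      for (int i = (int) free_ions.size() - 1; i >= 0; --i) {
        int v = free_ions[i];
        int bf = b_total - buf_bound[v];
        if (bf <= 0) continue;
        if (rng.unif() < p_eff[bf]) {
          ++buf_bound[v];
          bound_list.push_back(v);
          --free_ct[v];
          free_ions[i] = free_ions.back();
          free_ions.pop_back();
        }
      }
      // unbinding, with the within-step rebind correction; ions released
      // here stay free until the next step's binding pass
      long nb = (long) bound_list.size();
      if (nb > 0 && q_eff > 0) {
        long k = (long) R::rbinom((double) nb, q_eff);
        for (long m = 0; m < k; ++m) {
          long idx = (long) (rng.unif() * bound_list.size());
          if (idx >= (long) bound_list.size()) idx = bound_list.size() - 1;
          int v = bound_list[idx];
          int bf_after = b_total - buf_bound[v] + 1;
          int j = (int) (rng.unif() * n_sub_react);
          if (j >= n_sub_react) j = n_sub_react - 1;
          if (rng.unif() < rebind[bf_after * n_sub_react + j])
            continue;                       // rebound within the step
          bound_list[idx] = bound_list.back();
          bound_list.pop_back();
          --buf_bound[v];
          free_ions.push_back(v);
          ++free_ct[v];
        }
      }
    }
    // --- vesicle site kinetics, substepped ---
    for (int sub = 0; sub < n_sub_react; ++sub) {
      for (int i = 0; i < n_ves; ++i) {
        if (v_fused[i]) continue;
        int v = ves_vox[i];
        // unbinding
        for (int s = 0; s < v_sites[i]; ++s) {
          if (rng.unif() < q_off_ves) {
            --v_sites[i];
            free_ions.push_back(v);
            ++free_ct[v];
            --s;
          }
        }
        // binding, consuming local free ions
        int nfree_sites = sites_total - v_sites[i];
        int n_loc = free_ct[v];
        if (nfree_sites > 0 && n_loc > 0) {
          double pb = 1.0 - std::exp(-k1_ves * n_loc * dt_r);
          int nbind = 0;
          for (int s = 0; s < nfree_sites; ++s)
            if (rng.unif() < pb) ++nbind;
          if (nbind > n_loc) nbind = n_loc;
          for (int m = 0; m < nbind; ++m) {
            for (int j = (int) free_ions.size() - 1; j >= 0; --j) {
              if (free_ions[j] == v) {
                free_ions[j] = free_ions.back();
                free_ions.pop_back();
                break;
              }
            }
            --free_ct[v];
            ++v_sites[i];
          }
        }
      }
    }

    // --- recording (every record_every steps, plus the final step) ---
    if (pulsing && (((step + 1) % record_every == 0) || step == n_steps - 1)) {
      int s0 = 0;
      for (size_t i = 0; i < free_ions.size(); ++i)
        if (slice[free_ions[i] - 1] == 0) ++s0;
      int vb = 0, nf = 0;
      for (int i = 0; i < n_ves; ++i) { vb += v_sites[i]; if (v_fused[i]) ++nf; }
      r_time[rec] = (step + 1) * dt;   // state recorded after this step
      r_open[rec] = n_open;
      r_free[rec] = (int) free_ions.size();
      r_free_s0[rec] = s0;
      r_buf[rec] = (int) bound_list.size();
      r_vesb[rec] = vb;
      r_fused[rec] = nf;
      r_inj[rec] = (double) injected;
      r_consumed[rec] = (double) consumed;
      ++rec;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["time_s"] = r_time, _["open_count"] = r_open,
      _["free_ions"] = r_free, _["free_slice0"] = r_free_s0,
      _["buffer_bound"] = r_buf, _["vesicle_bound"] = r_vesb,
      _["fused"] = r_fused, _["injected"] = r_inj,
      _["consumed"] = r_consumed,
      _["basal_placed"] = (double) basal_placed,
      _["fusion_time"] = NumericVector(v_time.begin(), v_time.end()),
      _["n_recorded"] = rec);
}

// ---------------------------------------------------------------------------
// 8-connected component labeling of a logical matrix (column-major), BFS.
// Returns an integer matrix of labels (0 = background).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.clear();
      stack.push_back(r0 + nr * c0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int r = p % nr, c = p / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + nr * cc);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// For each reference point, distance to the nearest query point (2D).
// [[Rcpp::export]]
List nn_dist_cpp(NumericMatrix ref, NumericMatrix query) {
  const int nr = ref.nrow(), nq = query.nrow();
  NumericVector d(nr);
  IntegerVector idx(nr);
  for (int i = 0; i < nr; ++i) {
    double best = R_PosInf; int bj = NA_INTEGER;
    double x = ref(i, 0), y = ref(i, 1);
    for (int j = 0; j < nq; ++j) {
      double dx = query(j, 0) - x, dy = query(j, 1) - y;
      double dd = dx * dx + dy * dy;
      if (dd < best) { best = dd; bj = j + 1; }
    }
    d[i] = std::sqrt(best);
    idx[i] = bj;
  }
  return List::create(_["distance"] = d, _["index"] = idx);
}
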