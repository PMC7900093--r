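#include <Rcpp.h>
using namespace Rcpp;

// Lattice codes (signed sprout ids): 0 = vacant, -s = tip cell of sprout s,
// +s = stalk cell of sprout s (s >= 1). The grid is stored column-major as
// ny x nx (rows = y, cols = x); the TAF field varies along x only, so the
// movement bias and branching probability are per-column vectors.
//
// Anastomosis: a tip moving onto a tip-occupied site is removed iff
// `an_flag` (tip-to-tip); a tip moving onto a stalk-occupied site fuses
// with that vessel and is removed iff the stalk belongs to a *different*
// sprout (tip-to-sprout; re-entering the sprout's own trail is a blocked
// move, not a fusion event). Vacated sites always become stalk of the
// moving tip's sprout.

static inline int draw_dir(double b) {
  // Directions: 0 = +x (prob 1/4 + b), 1 = -x (1/4 - b), 2 = +y, 3 = -y.
  double r = unif_rand();
  if (r < 0.25 + b) return 0;
  if (r < 0.5) return 1;
  if (r < 0.75) return 2;
  return 3;
}

// Run update sweeps of the lattice model, recording column counts at the
// step indices in `record_steps` (1-based cumulative step numbers, strictly
// increasing). Tips are processed in a freshly shuffled order each sweep
// (random sequential update); tips created by branching enter the pool at
// the next sweep, inheriting the parent's sprout id unless
// `branch_new_sprout` is set.
// [[Rcpp::export]]
List cpp_abm_run(IntegerMatrix grid_in, NumericVector bias,
                 NumericVector pbranch, double Pm, int an_flag, int self_fuse,
                 int branch_new_sprout, IntegerVector record_steps) {
  const int ny = grid_in.nrow(), nx = grid_in.ncol();
  std::vector<int> grid(grid_in.begin(), grid_in.end()); // column-major
  std::vector<int> tips;
  tips.reserve(1024);
  int next_id = 1;
  for (int idx = 0; idx < nx * ny; ++idx) {
    if (grid[idx] < 0) tips.push_back(idx);
    if (std::abs(grid[idx]) >= next_id) next_id = std::abs(grid[idx]) + 1;
  }

  const int n_out = record_steps.size();
  const int n_steps = n_out > 0 ? record_steps[n_out - 1] : 0;
  List profiles(n_out);
  int out_i = 0;

  std::vector<int> order, newtips;
  std::vector<char> alive;

  for (int step = 1; step <= n_steps; ++step) {
    const int ntip = (int)tips.size();
    order.resize(ntip);
    for (int i = 0; i < ntip; ++i) order[i] = i;
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = ntip - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    alive.assign(ntip, 1);
    newtips.clear();

    for (int oi = 0; oi < ntip; ++oi) {
      const int idx = order[oi];
      if (!alive[idx]) continue;
      int pos = tips[idx];
      const int id = -grid[pos];
      int col = pos / ny, row = pos % ny;

      if (unif_rand() < Pm) {
        const int dir = draw_dir(bias[col]);
        int tc = col, tr = row;
        if (dir == 0) tc = col + 1;
        else if (dir == 1) tc = col - 1;
        else if (dir == 2) tr = row + 1;
        else tr = row - 1;
        if (tc >= 0 && tc < nx && tr >= 0 && tr < ny) { // reflecting edges: out-of-range moves abort
          const int tgt = tc * ny + tr;
          const int occ = grid[tgt];
          if (occ == 0) {                 // move; vacated site becomes stalk
            grid[pos] = id;
            grid[tgt] = -id;
            tips[idx] = tgt;
            pos = tgt; col = tc; row = tr;
          } else if (occ < 0) {           // tip-to-tip anastomosis (gated)
            if (an_flag) { grid[pos] = id; alive[idx] = 0; }
          } else if (occ != id || self_fuse) { // tip-to-sprout anastomosis
            grid[pos] = id;
            alive[idx] = 0;
          }                               // own trail: blocked move
        }
      }

      if (alive[idx] && pbranch[col] > 0.0 && unif_rand() < pbranch[col]) {
        int cand[4]; int ncand = 0;
        if (col + 1 < nx && grid[(col + 1) * ny + row] == 0) cand[ncand++] = (col + 1) * ny + row;
        if (col - 1 >= 0 && grid[(col - 1) * ny + row] == 0) cand[ncand++] = (col - 1) * ny + row;
        if (row + 1 < ny && grid[col * ny + row + 1] == 0) cand[ncand++] = col * ny + row + 1;
        if (row - 1 >= 0 && grid[col * ny + row - 1] == 0) cand[ncand++] = col * ny + row - 1;
        if (ncand > 0) {                  // branch silently fails with no vacant neighbour
          int pick = (int)(unif_rand() * ncand);
          if (pick >= ncand) pick = ncand - 1;
          grid[cand[pick]] = branch_new_sprout ? -(next_id++) : -id;
          newtips.push_back(cand[pick]);
        }
      }
    }

    // compact the tip pool
    std::vector<int> survivors;
    survivors.reserve(tips.size() + newtips.size());
    for (int i = 0; i < ntip; ++i)
      if (alive[i]) survivors.push_back(tips[i]);
    for (size_t i = 0; i < newtips.size(); ++i) survivors.push_back(newtips[i]);
    tips.swap(survivors);

    if (out_i < n_out && step == record_steps[out_i]) {
      NumericMatrix prof(nx, 2);
      for (int c = 0; c < nx; ++c) {
        int ntipc = 0, nstalkc = 0;
        const int base = c * ny;
        for (int r = 0; r < ny; ++r) {
          if (grid[base + r] < 0) ++ntipc;
          else if (grid[base + r] > 0) ++nstalkc;
        }
        prof(c, 0) = (double)ntipc / ny;
        prof(c, 1) = (double)nstalkc / ny;
      }
      profiles[out_i] = prof;
      ++out_i;
    }
  }

  IntegerMatrix grid_out(ny, nx);
  std::copy(grid.begin(), grid.end(), grid_out.begin());
  return List::create(_["profiles"] = profiles, _["grid"] = grid_out,
                      _["n_tips"] = (int)tips.size());
}
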