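#include <Rcpp.h>
#include <vector>
#include <cmath>

// Random sequential update engine for the 3D exclusion-process IBM.
//
// Species codes: 1 = melanoma, 2 = skin.
//
// RNG draw order is a documented contract, mirrored exactly by the pure-R
// reference engine (R/reference.R):
//   motility selection:   u_select, u_gate, [u_adhesion if melanoma passed
//                         the gate], u_direction (only if all gates passed)
//   proliferation:        u_select, u_gate, u_placement (only if a vacant
//                         von Neumann site exists)
// Direction order: +x, -x, +y, -y, +z, -z. Lateral boundaries wrap; a move
// selecting k < 0 or k >= nz is aborted (no re-draw). Daughters enter the
// registry immediately but the per-phase selection pool is frozen at phase
// start.

namespace {

const int DX[6] = {1, -1, 0, 0, 0, 0};
const int DY[6] = {0, 0, 1, -1, 0, 0};
const int DZ[6] = {0, 0, 0, 0, 1, -1};

struct Engine {
  int nx, ny, nz;
  std::vector<int> grid;           // 0 = vacant, else agent index + 1
  std::vector<int> ai, aj, ak;     // agent positions, 0-based
  std::vector<unsigned char> asp;  // species codes

  int idx(int i, int j, int k) const {
    return i + nx * (j + ny * k);
  }

  int wrapx(int i) const { return (i + nx) % nx; }
  int wrapy(int j) const { return (j + ny) % ny; }

  // adhesion count: melanoma occupants of the 26-site Moore neighbourhood,
  // laterally wrapped, vertically clipped
  int moore_melanoma(int i, int j, int k) const {
    int a = 0;
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = wrapy(j + dj);
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int id = grid[idx(wrapx(i + di), jj, kk)];
          if (id != 0 && asp[id - 1] == 1) ++a;
        }
      }
    }
    return a;
  }
};

inline int draw_index(int n) {
  int r = (int)(unif_rand() * n);
  return r >= n ? n - 1 : r;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_run(int nx, int ny, int nz,
                   Rcpp::IntegerVector i0, Rcpp::IntegerVector j0,
                   Rcpp::IntegerVector k0, Rcpp::IntegerVector species0,
                   double Pm_m, double Pm_s, double Pp_m, double Pp_s,
                   double q, int n_steps,
                   Rcpp::IntegerVector snapshot_steps) {
  if (nx < 3 || ny < 3)
    Rcpp::stop("engine requires nx >= 3 and ny >= 3 (lateral wrap)");
  Engine e;
  e.nx = nx; e.ny = ny; e.nz = nz;
  e.grid.assign((size_t)nx * ny * nz, 0);
  int n0 = i0.size();
  e.ai.reserve(n0 * 4); e.aj.reserve(n0 * 4); e.ak.reserve(n0 * 4);
  e.asp.reserve(n0 * 4);
  for (int n = 0; n < n0; ++n) {
    int i = i0[n], j = j0[n], k = k0[n];
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
      Rcpp::stop("initial agent outside the domain");
    int g = e.idx(i, j, k);
    if (e.grid[g] != 0) Rcpp::stop("initial condition violates exclusion");
    e.ai.push_back(i); e.aj.push_back(j); e.ak.push_back(k);
    e.asp.push_back((unsigned char)species0[n]);
    e.grid[g] = n + 1;
  }

  // tallies: attempted / gate aborts / adhesion aborts / boundary aborts /
  // crowding aborts / successes, for each phase
  long mv_att = 0, mv_gate = 0, mv_adh = 0, mv_bnd = 0, mv_crowd = 0,
       mv_ok = 0;
  long pr_att = 0, pr_gate = 0, pr_crowd = 0, pr_ok = 0;

  std::vector<int> snap_at(snapshot_steps.begin(), snapshot_steps.end());
  Rcpp::List snapshots;
  GetRNGstate();

  for (int step = 1; step <= n_steps; ++step) {
    // phase 1: motility; selection pool frozen at phase start
    int N = (int)e.ai.size();
    for (int s = 0; s < N; ++s) {
      ++mv_att;
      int agent = draw_index(N);
      bool mel = e.asp[agent] == 1;
      double pm = mel ? Pm_m : Pm_s;
      if (unif_rand() >= pm) { ++mv_gate; continue; }
      if (mel) {
        int a = e.moore_melanoma(e.ai[agent], e.aj[agent], e.ak[agent]);
        double mod = std::pow(1.0 - q, (double)a);
        if (unif_rand() >= mod) { ++mv_adh; continue; }
      }
      int dir = draw_index(6);
      int ti = e.wrapx(e.ai[agent] + DX[dir]);
      int tj = e.wrapy(e.aj[agent] + DY[dir]);
      int tk = e.ak[agent] + DZ[dir];
      if (tk < 0 || tk >= nz) { ++mv_bnd; continue; }
      int g = e.idx(ti, tj, tk);
      if (e.grid[g] != 0) { ++mv_crowd; continue; }
      e.grid[e.idx(e.ai[agent], e.aj[agent], e.ak[agent])] = 0;
      e.grid[g] = agent + 1;
      e.ai[agent] = ti; e.aj[agent] = tj; e.ak[agent] = tk;
      ++mv_ok;
    }

    // phase 2: proliferation; daughters not selectable until next step
    N = (int)e.ai.size();
    for (int s = 0; s < N; ++s) {
      ++pr_att;
      int agent = draw_index(N);
      double pp = e.asp[agent] == 1 ? Pp_m : Pp_s;
      if (unif_rand() >= pp) { ++pr_gate; continue; }
      int vac[6], nv = 0;
      for (int dir = 0; dir < 6; ++dir) {
        int tk = e.ak[agent] + DZ[dir];
        if (tk < 0 || tk >= nz) continue;
        int g = e.idx(e.wrapx(e.ai[agent] + DX[dir]),
                      e.wrapy(e.aj[agent] + DY[dir]), tk);
        if (e.grid[g] == 0) vac[nv++] = g;
      }
      if (nv == 0) { ++pr_crowd; continue; }
      int g = vac[draw_index(nv)];
      e.ai.push_back(g % nx);
      e.aj.push_back((g / nx) % ny);
      e.ak.push_back(g / (nx * ny));
      e.asp.push_back(e.asp[agent]);
      e.grid[g] = (int)e.ai.size();
      ++pr_ok;
    }

    if (!snap_at.empty() &&
        std::find(snap_at.begin(), snap_at.end(), step) != snap_at.end()) {
      snapshots.push_back(Rcpp::List::create(
          Rcpp::Named("step") = step,
          Rcpp::Named("i") = Rcpp::IntegerVector(e.ai.begin(), e.ai.end()),
          Rcpp::Named("j") = Rcpp::IntegerVector(e.aj.begin(), e.aj.end()),
          Rcpp::Named("k") = Rcpp::IntegerVector(e.ak.begin(), e.ak.end()),
          Rcpp::Named("species") =
              Rcpp::IntegerVector(e.asp.begin(), e.asp.end())));
    }
  }
  PutRNGstate();

  Rcpp::NumericVector motility = Rcpp::NumericVector::create(
      Rcpp::Named("attempted") = (double)mv_att,
      Rcpp::Named("aborted_gate") = (double)mv_gate,
      Rcpp::Named("aborted_adhesion") = (double)mv_adh,
      Rcpp::Named("aborted_boundary") = (double)mv_bnd,
      Rcpp::Named("aborted_crowding") = (double)mv_crowd,
      Rcpp::Named("moved") = (double)mv_ok);
  Rcpp::NumericVector proliferation = Rcpp::NumericVector::create(
      Rcpp::Named("attempted") = (double)pr_att,
      Rcpp::Named("aborted_gate") = (double)pr_gate,
      Rcpp::Named("aborted_crowding") = (double)pr_crowd,
      Rcpp::Named("births") = (double)pr_ok);

  return Rcpp::List::create(
      Rcpp::Named("final") = Rcpp::List::create(
          Rcpp::Named("step") = n_steps,
          Rcpp::Named("i") = Rcpp::IntegerVector(e.ai.begin(), e.ai.end()),
          Rcpp::Named("j") = Rcpp::IntegerVector(e.aj.begin(), e.aj.end()),
          Rcpp::Named("k") = Rcpp::IntegerVector(e.ak.begin(), e.ak.end()),
          Rcpp::Named("species") =
              Rcpp::IntegerVector(e.asp.begin(), e.asp.end())),
      Rcpp::Named("snapshots") = snapshots,
      Rcpp::Named("tallies") = Rcpp::List::create(
          Rcpp::Named("motility") = motility,
          Rcpp::Named("proliferation") = proliferation));
}
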