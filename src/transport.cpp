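#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Voxelized Monte Carlo photon transport (mcxyz lineage).
//
// The engine works in a grid-local frame: voxel (i,j,k), 0-based, occupies
// [i*hx, (i+1)*hx) x [j*hy, ...) x [k*hz, ...). Callers convert world
// coordinates to this frame. All lengths are mm; tallies are returned raw
// (sum of weight*pathlength in mm, and absorbed weight) and scaled in R.
//
// RNG: R's generator via unif_rand(), so a set.seed() in the calling R code
// makes the whole simulation bit-reproducible.

static const double BOUNDARY_EPS = 1e-9; // mm, nudge across voxel faces

static inline double hg_cosine(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct < -1.0) ct = -1.0;
  if (ct > 1.0) ct = 1.0;
  return ct;
}

// Rotate unit vector u by polar angle acos(ct) and azimuth psi (standard
// local-frame update used by MCML/mcxyz).
static inline void spin(double *ux, double *uy, double *uz,
                        double ct, double psi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(psi), sp = std::sin(psi);
  double x = *ux, y = *uy, z = *uz;
  if (std::fabs(z) > 0.999999) {
    *ux = st * cp;
    *uy = st * sp;
    *uz = (z >= 0.0) ? ct : -ct;
  } else {
    double den = std::sqrt(1.0 - z * z);
    *ux = st * (x * z * cp - y * sp) / den + x * ct;
    *uy = st * (y * z * cp + x * sp) / den + y * ct;
    *uz = -den * st * cp + z * ct;
  }
  // renormalize to keep error from accumulating over ~1e3 scatters
  double nrm = std::sqrt(*ux * *ux + *uy * *uy + *uz * *uz);
  *ux /= nrm; *uy /= nrm; *uz /= nrm;
}

// distance along (positive) direction u from position p (inside voxel i) to
// the voxel face; +inf when the component is 0
static inline double face_distance(double p, double u, int i, double h) {
  if (u > 0.0)      return ((i + 1) * h - p) / u;
  else if (u < 0.0) return (i * h - p) / u;
  return R_PosInf;
}

// Move a position sitting on (or at) a voxel face strictly across it.
// Relying on a fixed path-length nudge is not enough: a packet exactly on
// a face with a tiny direction component toward it would advance that
// coordinate by less than one ulp and loop forever. Snapping the crossed
// coordinate guarantees progress regardless of the direction.
static inline void cross_face(double *p, double u, int i, double h) {
  if (u > 0.0) *p = (i + 1) * h + BOUNDARY_EPS * h;
  else         *p = i * h - BOUNDARY_EPS * h;
}

// [[Rcpp::export]]
List mc_transport_cpp(IntegerVector dims, NumericVector vox,
                      IntegerVector labels, NumericMatrix props,
                      NumericMatrix pos0, NumericMatrix dir0,
                      bool roulette, double roulette_threshold,
                      double roulette_psurv, double max_interactions) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = vox[0], hy = vox[1], hz = vox[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int n_packets = pos0.nrow();
  const int n_labels = props.nrow(); // row l = (mu_a, mu_s, g) for label l

  std::vector<double> track(nvox, 0.0), absorbed(nvox, 0.0);
  double escaped = 0.0, rouletted = 0.0, lost = 0.0;
  double total_interactions = 0.0;

  GetRNGstate();
  for (int ip = 0; ip < n_packets; ++ip) {
    double px = pos0(ip, 0), py = pos0(ip, 1), pz = pos0(ip, 2);
    double ux = dir0(ip, 0), uy = dir0(ip, 1), uz = dir0(ip, 2);
    double w = 1.0;
    bool alive = true;
    double n_inter = 0.0;

    while (alive) {
      double s = -std::log(1.0 - unif_rand()); // dimensionless step

      while (s > 0.0) {
        int i = (int)std::floor(px / hx);
        int j = (int)std::floor(py / hy);
        int k = (int)std::floor(pz / hz);
        if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) {
          escaped += w; alive = false; break;
        }
        R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        int lab = labels[idx];
        if (lab <= 0 || lab >= n_labels) { // background terminates as escape
          escaped += w; alive = false; break;
        }
        double mu_a = props(lab, 0), mu_s = props(lab, 1), g = props(lab, 2);
        double mu_t = mu_a + mu_s;

        double dbx = face_distance(px, ux, i, hx);
        double dby = face_distance(py, uy, j, hy);
        double dbz = face_distance(pz, uz, k, hz);
        double db = std::min(dbx, std::min(dby, dbz));
        int axis = (db == dbx) ? 0 : (db == dby ? 1 : 2);
        if (db < 0.0) db = 0.0;

        if (mu_t <= 0.0) { // transparent voxel: free flight, no optical depth
          track[idx] += w * db; // fluence is still tallied along the chord
          px += db * ux; py += db * uy; pz += db * uz;
          if (axis == 0)      cross_face(&px, ux, i, hx);
          else if (axis == 1) cross_face(&py, uy, j, hy);
          else                cross_face(&pz, uz, k, hz);
          continue;
        }

        double di = s / mu_t; // physical distance to the sampled interaction
        if (di <= db) {
          px += di * ux; py += di * uy; pz += di * uz;
          track[idx] += w * di;
          s = 0.0;
          // interaction: partial absorption then Henyey-Greenstein scatter
          double dep = w * mu_a / mu_t;
          absorbed[idx] += dep;
          w -= dep;
          n_inter += 1.0;
          if (w <= 0.0) { alive = false; break; } // fully absorbed
          double ct = hg_cosine(g, unif_rand());
          double psi = 2.0 * M_PI * unif_rand();
          spin(&ux, &uy, &uz, ct, psi);
          if (roulette && w < roulette_threshold) {
            if (unif_rand() < roulette_psurv) w /= roulette_psurv;
            else { rouletted += w; alive = false; }
          }
          if (n_inter >= max_interactions) { // safety valve, off by default
            lost += w; alive = false;
          }
        } else {
          px += db * ux; py += db * uy; pz += db * uz;
          if (axis == 0)      cross_face(&px, ux, i, hx);
          else if (axis == 1) cross_face(&py, uy, j, hy);
          else                cross_face(&pz, uz, k, hz);
          track[idx] += w * db;
          s -= db * mu_t;
        }
      }
    }
    total_interactions += n_inter;
    if ((ip & 0x3ff) == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  return List::create(
    _["track"] = NumericVector(track.begin(), track.end()),
    _["absorbed"] = NumericVector(absorbed.begin(), absorbed.end()),
    _["escaped_weight"] = escaped,
    _["rouletted_weight"] = rouletted,
    _["lost_weight"] = lost,
    _["n_interactions"] = total_interactions);
}

// Exact ray/voxel traversal: voxels crossed by a ray from a point inside the
// grid, with the chord length in each, until the ray leaves the grid.
// [[Rcpp::export]]
List traverse_voxels_cpp(NumericVector origin, NumericVector direction,
                         IntegerVector dims, NumericVector vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = vox[0], hy = vox[1], hz = vox[2];
  double px = origin[0], py = origin[1], pz = origin[2];
  double ux = direction[0], uy = direction[1], uz = direction[2];

  std::vector<int> vi, vj, vk;
  std::vector<double> len;
  for (;;) {
    int i = (int)std::floor(px / hx);
    int j = (int)std::floor(py / hy);
    int k = (int)std::floor(pz / hz);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) break;
    double dbx = face_distance(px, ux, i, hx);
    double dby = face_distance(py, uy, j, hy);
    double dbz = face_distance(pz, uz, k, hz);
    double db = std::min(dbx, std::min(dby, dbz));
    int axis = (db == dbx) ? 0 : (db == dby ? 1 : 2);
    if (!R_FINITE(db)) break; // zero direction: degenerate, stop
    if (db < 0.0) db = 0.0;
    vi.push_back(i); vj.push_back(j); vk.push_back(k);
    len.push_back(db);
    px += db * ux; py += db * uy; pz += db * uz;
    if (axis == 0)      cross_face(&px, ux, i, hx);
    else if (axis == 1) cross_face(&py, uy, j, hy);
    else                cross_face(&pz, uz, k, hz);
    if (len.size() > (size_t)(nx + ny + nz + 3)) break; // cannot recur
  }
  return List::create(_["i"] = IntegerVector(vi.begin(), vi.end()),
                      _["j"] = IntegerVector(vj.begin(), vj.end()),
                      _["k"] = IntegerVector(vk.begin(), vk.end()),
                      _["length"] = NumericVector(len.begin(), len.end()));
}
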