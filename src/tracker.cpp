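// FACT-style probabilistic streamline propagation core.
//
// Conventions (shared with the R layer):
//  - voxel indices are 1-based, voxel centers sit at integer coordinates,
//    voxel v spans [v - 0.5, v + 0.5) along each axis (isotropic voxels);
//  - a direction is sampled once per voxel visit and held until the exit
//    face, where the position is nudged 1e-6 voxel into the next voxel;
//  - the per-(voxel, stream) RNG substream is derived deterministically
//    from (baseSeed, stage, voxel linear index, stream id), so cached and
//    regenerated streamlines are bit-identical.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double NUDGE = 1e-6;

// -- counter-free splitmix64 RNG: small, fast, keyable -----------------------

inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t nextu() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {  // in (0, 1)
    return ((nextu() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  int unif_int(int n) {  // in [0, n)
    return (int)(unif() * n) % n;
  }
  double halfnormal(double sigma) {
    double u1 = unif(), u2 = unif();
    return sigma * std::fabs(std::sqrt(-2.0 * std::log(u1)) *
                             std::cos(6.283185307179586 * u2));
  }
};

inline uint64_t substream_seed(uint64_t base, uint64_t stage, uint64_t voxel,
                               uint64_t stream) {
  uint64_t h = mix64(base ^ 0x853C49E6748FEA9BULL);
  h = mix64(h ^ stage);
  h = mix64(h ^ voxel);
  h = mix64(h ^ stream);
  return h;
}

// -- small vector helpers ----------------------------------------------------

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

inline void normalize3(double* v) {
  double n = std::sqrt(dot3(v, v));
  if (n > 0) { v[0] /= n; v[1] /= n; v[2] /= n; }
}

// Rotate unit vector b away from itself by angle theta about a uniformly
// random perpendicular axis: b' = cos(theta) b + sin(theta) w, |w| = 1, w _|_ b.
inline void perturb(double* b, double sigma_rad, Rng& rng) {
  if (sigma_rad <= 0) return;
  double theta = rng.halfnormal(sigma_rad);
  double phi = 6.283185307179586 * rng.unif();
  // perpendicular frame (u1, u2)
  double e[3] = {0, 0, 0};
  if (std::fabs(b[0]) < 0.9) e[0] = 1.0; else e[1] = 1.0;
  double u1[3] = {e[1] * b[2] - e[2] * b[1],
                  e[2] * b[0] - e[0] * b[2],
                  e[0] * b[1] - e[1] * b[0]};
  normalize3(u1);
  double u2[3] = {b[1] * u1[2] - b[2] * u1[1],
                  b[2] * u1[0] - b[0] * u1[2],
                  b[0] * u1[1] - b[1] * u1[0]};
  double ct = std::cos(theta), st = std::sin(theta);
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int a = 0; a < 3; ++a)
    b[a] = ct * b[a] + st * (cp * u1[a] + sp * u2[a]);
  normalize3(b);
}

// Field view over flat R arrays.
struct Field {
  int nx, ny, nz;
  const int* npop;
  const double* dir1;   // length 3N, axis-major blocks (R array [nx,ny,nz,3])
  const double* dir2;
  const double* disp1;  // radians
  const double* disp2;
  const int* mask;
  long N() const { return (long)nx * ny * nz; }
  long lin(int x, int y, int z) const {  // 0-based result from 1-based voxel
    return (long)(x - 1) + (long)nx * ((y - 1) + (long)ny * (z - 1));
  }
  void popdir(long l, int p, double* out) const {
    const double* d = (p == 0) ? dir1 : dir2;
    long N_ = N();
    out[0] = d[l]; out[1] = d[l + N_]; out[2] = d[l + 2 * N_];
  }
  double popdisp(long l, int p) const { return (p == 0) ? disp1[l] : disp2[l]; }
};

// Sample a propagation direction in voxel l.
// Returns 0 on success, 1 if curvature excludes every population.
// With no incoming direction (first step): uniform population, uniform sign.
int sample_dir(const Field& F, long l, const double* incoming, double ipThresh,
               Rng& rng, double* out) {
  int np = F.npop[l];
  double base[3];
  if (incoming == nullptr) {
    int p = (np > 1) ? rng.unif_int(np) : 0;
    F.popdir(l, p, base);
    double sign = (rng.unif() < 0.5) ? 1.0 : -1.0;
    for (int a = 0; a < 3; ++a) base[a] *= sign;
    perturb(base, F.popdisp(l, p), rng);
    out[0] = base[0]; out[1] = base[1]; out[2] = base[2];
    return 0;
  }
  int qual[2]; double qsign[2]; int nq = 0;
  for (int p = 0; p < np; ++p) {
    double d[3];
    F.popdir(l, p, d);
    double dp = dot3(d, incoming);
    double s = (dp >= 0) ? 1.0 : -1.0;
    if (s * dp >= ipThresh) { qual[nq] = p; qsign[nq] = s; ++nq; }
  }
  if (nq == 0) return 1;
  int k = (nq > 1) ? rng.unif_int(nq) : 0;
  int p = qual[k];
  F.popdir(l, p, base);
  for (int a = 0; a < 3; ++a) base[a] *= qsign[k];
  perturb(base, F.popdisp(l, p), rng);
  if (dot3(base, incoming) < ipThresh) return 1;  // dispersion broke curvature
  out[0] = base[0]; out[1] = base[1]; out[2] = base[2];
  return 0;
}

// Termination status codes (kept in sync with .trackStatusLevels in R).
enum Status { EXITED_MASK = 1, NO_POPULATION = 2, CURVATURE_STOP = 3,
              MAX_STEPS = 4 };

struct HalfTrack {
  std::vector<long> voxels;       // 0-based linear indices, in visit order
  std::vector<double> points;     // x,y,z triplets, voxel units
  int status;
  bool moved;                     // at least one step taken
  double first_dir[3];
};

// Propagate one half-track from the center of seed voxel (sx, sy, sz).
// first_incoming: nullptr for a free first step, otherwise the direction the
// first within-seed sample must respect (used to launch the reverse half).
void propagate_half(const Field& F, int sx, int sy, int sz,
                    const double* first_incoming, double ipThresh,
                    int maxSteps, Rng& rng, HalfTrack& out) {
  double pos[3] = {(double)sx, (double)sy, (double)sz};
  int vox[3] = {sx, sy, sz};
  long l = F.lin(sx, sy, sz);
  out.voxels.push_back(l);
  out.points.insert(out.points.end(), pos, pos + 3);
  out.moved = false;
  const double* incoming = first_incoming;
  double cur[3];
  int steps = 0;
  for (;;) {
    if (F.npop[l] == 0) { out.status = NO_POPULATION; return; }
    double d[3];
    if (sample_dir(F, l, incoming, ipThresh, rng, d)) {
      out.status = CURVATURE_STOP; return;
    }
    if (!out.moved) { out.first_dir[0] = d[0]; out.first_dir[1] = d[1];
                      out.first_dir[2] = d[2]; }
    // distance to the exit face of the current voxel
    double t = 1e300;
    for (int a = 0; a < 3; ++a) {
      if (d[a] > 1e-12)       t = std::min(t, (vox[a] + 0.5 - pos[a]) / d[a]);
      else if (d[a] < -1e-12) t = std::min(t, (vox[a] - 0.5 - pos[a]) / d[a]);
    }
    if (t < 0) t = 0;
    double np_[3]; int nv[3];
    for (int a = 0; a < 3; ++a) {
      np_[a] = pos[a] + (t + NUDGE) * d[a];
      nv[a] = (int)std::lround(np_[a]);
    }
    if (nv[0] < 1 || nv[0] > F.nx || nv[1] < 1 || nv[1] > F.ny ||
        nv[2] < 1 || nv[2] > F.nz) { out.status = EXITED_MASK; return; }
    long nl = F.lin(nv[0], nv[1], nv[2]);
    if (!F.mask[nl]) { out.status = EXITED_MASK; return; }
    pos[0] = np_[0]; pos[1] = np_[1]; pos[2] = np_[2];
    vox[0] = nv[0]; vox[1] = nv[1]; vox[2] = nv[2];
    l = nl;
    out.voxels.push_back(l);
    out.points.insert(out.points.end(), pos, pos + 3);
    out.moved = true;
    cur[0] = d[0]; cur[1] = d[1]; cur[2] = d[2];
    incoming = cur;
    if (++steps >= maxSteps) { out.status = MAX_STEPS; return; }
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cppEmitStreamlines")]]
List cppEmitStreamlines(IntegerVector dims, IntegerVector npop,
                        NumericVector dir1, NumericVector dir2,
                        NumericVector disp1, NumericVector disp2,
                        IntegerVector mask, IntegerMatrix seeds,
                        int streamsPerVoxel, double ipThresh, int maxSteps,
                        bool bidirectional, double baseSeed, int stage,
                        int streamIdOffset, bool storePoints) {
  Field F;
  F.nx = dims[0]; F.ny = dims[1]; F.nz = dims[2];
  F.npop = INTEGER(npop);
  F.dir1 = REAL(dir1); F.dir2 = REAL(dir2);
  F.disp1 = REAL(disp1); F.disp2 = REAL(disp2);
  F.mask = INTEGER(mask);

  int nseed = seeds.nrow();
  long ntot = (long)nseed * streamsPerVoxel;
  List paths(ntot);
  List pts(storePoints ? ntot : 0);
  IntegerVector status(ntot), seedLin(ntot), streamId(ntot);

  long idx = 0;
  for (int s = 0; s < nseed; ++s) {
    int sx = seeds(s, 0), sy = seeds(s, 1), sz = seeds(s, 2);
    long sl = F.lin(sx, sy, sz);
    for (int k = 0; k < streamsPerVoxel; ++k, ++idx) {
      int sid = streamIdOffset + k;
      Rng rng(substream_seed((uint64_t)baseSeed, (uint64_t)stage,
                             (uint64_t)sl, (uint64_t)sid));
      HalfTrack fwd;
      fwd.status = NO_POPULATION;
      propagate_half(F, sx, sy, sz, nullptr, ipThresh, maxSteps, rng, fwd);

      std::vector<long> vlin;
      std::vector<double> vpts;
      if (bidirectional && fwd.moved) {
        double rev_in[3] = {-fwd.first_dir[0], -fwd.first_dir[1],
                            -fwd.first_dir[2]};
        HalfTrack bwd;
        bwd.status = NO_POPULATION;
        propagate_half(F, sx, sy, sz, rev_in, ipThresh, maxSteps, rng, bwd);
        // reversed backward half (excluding its seed point), then forward half
        size_t nb = bwd.voxels.size();
        for (size_t i = nb; i-- > 1;) {
          vlin.push_back(bwd.voxels[i]);
          vpts.insert(vpts.end(), bwd.points.begin() + 3 * i,
                      bwd.points.begin() + 3 * i + 3);
        }
      }
      vlin.insert(vlin.end(), fwd.voxels.begin(), fwd.voxels.end());
      vpts.insert(vpts.end(), fwd.points.begin(), fwd.points.end());

      size_t m = vlin.size();
      IntegerVector pv(m);
      for (size_t i = 0; i < m; ++i) pv[i] = (int)(vlin[i] + 1);  // 1-based
      paths[idx] = pv;
      if (storePoints) {
        NumericMatrix pm(m, 3);
        for (size_t i = 0; i < m; ++i)
          for (int a = 0; a < 3; ++a) pm(i, a) = vpts[3 * i + a];
        pts[idx] = pm;
      }
      status[idx] = fwd.status;
      seedLin[idx] = (int)(sl + 1);
      streamId[idx] = sid;
    }
  }
  List out = List::create(_["paths"] = paths, _["status"] = status,
                          _["seedVoxel"] = seedLin, _["streamId"] = streamId);
  if (storePoints) out["points"] = pts;
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cppSampleStepDirection")]]
SEXP cppSampleStepDirection(NumericMatrix populations, NumericVector dispersions,
                            Nullable<NumericVector> incoming, double ipThresh,
                            double seed) {
  int np = populations.nrow();
  if (np < 1 || np > 2) stop("1 or 2 populations required");
  // adapt the matrix into a tiny Field with one voxel
  std::vector<double> d1(3), d2(3, 0.0);
  for (int a = 0; a < 3; ++a) d1[a] = populations(0, a);
  if (np == 2) for (int a = 0; a < 3; ++a) d2[a] = populations(1, a);
  double s1 = dispersions[0], s2 = (np == 2) ? dispersions[1] : 0.0;
  int npv = np, maskv = 1;
  Field F;
  F.nx = F.ny = F.nz = 1;
  F.npop = &npv;
  F.dir1 = d1.data(); F.dir2 = d2.data();
  F.disp1 = &s1; F.disp2 = &s2;
  F.mask = &maskv;
  Rng rng(substream_seed((uint64_t)seed, 0, 0, 0));
  double out[3];
  int fail;
  if (incoming.isNotNull()) {
    NumericVector inc(incoming);
    double iv[3] = {inc[0], inc[1], inc[2]};
    fail = sample_dir(F, 0, iv, ipThresh, rng, out);
  } else {
    fail = sample_dir(F, 0, nullptr, ipThresh, rng, out);
  }
  if (fail) return R_NilValue;
  return NumericVector::create(out[0], out[1], out[2]);
}
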