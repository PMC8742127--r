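// Voxel Monte-Carlo photon transport with per-medium partial pathlengths.
//
// Packets are launched from a fiber face on the -z boundary, refracted into
// the tissue (Fresnel at entry), propagated with scattering-length free-path
// sampling (Henyey-Greenstein phase function), voxel-by-voxel ray traversal,
// Fresnel reflection/refraction at internal voxel faces where the refractive
// index changes, and continuous Beer-law weight attenuation. Packets
// crossing the -z face inside the detector acceptance cone are recorded with
// their per-medium pathlengths so that diffuse reflectance can be re-rendered
// for arbitrary absorption maps in post-processing. Lateral and +z faces are
// open (escaping packets are tallied, not reflected), emulating a laterally
// and in-depth semi-infinite tissue. Russian roulette terminates low-weight
// packets unbiasedly.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EPS_DIR = 1e-12;

// counter-based per-photon RNG: splitmix64 output function over a Weyl
// sequence; photon streams start at seed + (index+1) * WEYL and advance by
// GAMMA, giving negligible overlap between streams
struct PhotonRNG {
  uint64_t c;
  static const uint64_t GAMMA = 0x9E3779B97F4A7C15ULL;
  static const uint64_t WEYL = 0xD1B54A32D192ED03ULL;
  PhotonRNG(uint64_t seed, uint64_t index) {
    c = seed * 0xBF58476D1CE4E5B9ULL + (index + 1) * WEYL;
  }
  inline double next() {
    c += GAMMA;
    uint64_t z = c;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z ^= z >> 31;
    double u = (z >> 11) * (1.0 / 9007199254740992.0);
    return u > 0 ? u : 5e-324;   // open interval (0, 1)
  }
};

// unpolarized Fresnel reflectance; cosi, cost are cosines of incidence and
// transmission angles (both positive)
static inline double fresnelR(double n1, double n2, double cosi,
                              double cost) {
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine
static inline double sampleHG(double g, PhotonRNG &rng) {
  double u = rng.next();
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// rotate direction u by deflection cosine ct and azimuth phi (MCML spin)
static inline void spin(double *u, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) > 0.99999) {
    u[0] = st * cp;
    u[1] = st * sp;
    u[2] = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    u[0] = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    u[1] = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    u[2] = -den * st * cp + uz * ct;
  }
  double norm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= norm; u[1] /= norm; u[2] /= norm;
}

// sample a launch position on the fiber core and a direction uniform in
// solid angle within the emission cone (half-angle asin(NA / nExt))
static inline void sampleLaunch(double srcX, double srcY, double coreDiam,
                                double srcNA, double nExt, double *pos,
                                double *dir, PhotonRNG &rng) {
  double r = 0.5 * coreDiam * std::sqrt(rng.next());
  double a = 2.0 * M_PI * rng.next();
  pos[0] = srcX + r * std::cos(a);
  pos[1] = srcY + r * std::sin(a);
  pos[2] = 0.0;
  double sinMax = srcNA / nExt;
  double cosMin = std::sqrt(std::max(0.0, 1.0 - sinMax * sinMax));
  double ct = 1.0 - rng.next() * (1.0 - cosMin);
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double psi = 2.0 * M_PI * rng.next();
  dir[0] = st * std::cos(psi);
  dir[1] = st * std::sin(psi);
  dir[2] = ct;
}

// [[Rcpp::export(name = ".mc_sample_launch")]]
NumericMatrix mc_sample_launch(int n, double srcX, double srcY,
                               double coreDiam, double srcNA, double nExt,
                               double seed) {
  NumericMatrix out(n, 6);
  double pos[3], dir[3];
  for (int i = 0; i < n; ++i) {
    PhotonRNG rng((uint64_t)seed, (uint64_t)i);
    sampleLaunch(srcX, srcY, coreDiam, srcNA, nExt, pos, dir, rng);
    out(i, 0) = pos[0]; out(i, 1) = pos[1]; out(i, 2) = pos[2];
    out(i, 3) = dir[0]; out(i, 4) = dir[1]; out(i, 5) = dir[2];
  }
  return out;
}

// [[Rcpp::export(name = ".mc_simulate")]]
List mc_simulate(IntegerVector labels, IntegerVector dims, double voxel,
                 NumericMatrix media,      // nMedia x 4: mua, mus (per um), g, n
                 IntegerVector labelMedium, // label -> medium (1-based)
                 double srcX, double srcY, double coreDiam, double srcNA,
                 double detNA, double nExt, int nPhotons,
                 double rrThreshold, double rrFactor, double maxSteps,
                 bool mirrorSides, double seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nMedia = media.nrow();
  if (srcNA >= nExt) stop("source NA must be smaller than the external n");
  if (detNA > nExt) stop("detector NA must not exceed the external n");
  const double detSinMax = detNA / nExt;
  const double logThresh = std::log(rrThreshold);
  const double invRR = 1.0 / rrFactor;
  const double logRR = std::log(rrFactor);

  std::vector<double> mua(nMedia), mus(nMedia), gg(nMedia), nn(nMedia);
  for (int m = 0; m < nMedia; ++m) {
    mua[m] = media(m, 0); mus[m] = media(m, 1);
    gg[m] = media(m, 2); nn[m] = media(m, 3);
  }
  std::vector<int> lab2med(labelMedium.size());
  for (int i = 0; i < labelMedium.size(); ++i)
    lab2med[i] = labelMedium[i] - 1;
  const int *lab = INTEGER(labels);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;

  // detected-photon storage
  std::vector<double> dX, dY, dUx, dUy, dUz, dW, dRf, dL;
  double wDetected = 0, wTop = 0, wTrans = 0, wSide = 0, wKilled = 0;

  std::vector<double> L(nMedia);
  double pos[3], dir[3];

  for (int ph = 0; ph < nPhotons; ++ph) {
    if ((ph & 0x3FF) == 0) R_CheckUserInterrupt();
    PhotonRNG rng((uint64_t)seed, (uint64_t)ph);
    sampleLaunch(srcX, srcY, coreDiam, srcNA, nExt, pos, dir, rng);
    std::fill(L.begin(), L.end(), 0.0);
    double A = 0.0;       // accumulated absorption exponent sum(mua * l)
    double rfac = 1.0;    // roulette weight multiplier
    double logRfac = 0.0;

    int ix = (int)std::floor(pos[0] / voxel);
    int iy = (int)std::floor(pos[1] / voxel);
    int iz = 0;
    ix = std::min(std::max(ix, 0), nx - 1);
    iy = std::min(std::max(iy, 0), ny - 1);

    // entry interface: Fresnel between external medium and first voxel
    int med = lab2med[lab[(R_xlen_t)iz * nxy + (R_xlen_t)iy * nx + ix] - 1];
    {
      double n1 = nn[med];
      double cosi = dir[2];
      double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
      double sint = nExt * sini / n1;
      double cost = std::sqrt(std::max(0.0, 1.0 - sint * sint));
      double R = (std::fabs(nExt - n1) < 1e-12) ? 0.0
                                                : fresnelR(nExt, n1, cosi, cost);
      if (rng.next() < R) {
        // specular reflection at the surface: exits along -z
        double sinExit = sini;
        if (sinExit <= detSinMax + 1e-12) {
          dX.push_back(pos[0]); dY.push_back(pos[1]);
          dUx.push_back(dir[0]); dUy.push_back(dir[1]);
          dUz.push_back(-dir[2]);
          dW.push_back(1.0); dRf.push_back(1.0);
          for (int m = 0; m < nMedia; ++m) dL.push_back(0.0);
          wDetected += 1.0;
        } else {
          wTop += 1.0;
        }
        continue;
      }
      // refract into the tissue
      double scale = nExt / n1;
      dir[0] *= scale; dir[1] *= scale; dir[2] = cost;
      double norm = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] +
                              dir[2] * dir[2]);
      dir[0] /= norm; dir[1] /= norm; dir[2] /= norm;
    }

    double tau = -std::log(rng.next());
    double steps = 0;
    int fate = 0;  // 0 in flight, 1 detected, 2 top, 3 trans, 4 side, 5 killed
    while (fate == 0) {
      if (++steps > maxSteps)
        stop("photon %d exceeded the step budget (position %.3f %.3f %.3f)",
             ph + 1, pos[0], pos[1], pos[2]);
      // distance to the next voxel face
      double tb = R_PosInf;
      int axis = -1;
      for (int a = 0; a < 3; ++a) {
        double t;
        int ia = (a == 0) ? ix : (a == 1) ? iy : iz;
        if (dir[a] > EPS_DIR)
          t = ((ia + 1) * voxel - pos[a]) / dir[a];
        else if (dir[a] < -EPS_DIR)
          t = (ia * voxel - pos[a]) / dir[a];
        else
          continue;
        if (t < tb) { tb = t; axis = a; }
      }
      if (axis < 0) stop("degenerate photon direction");
      if (tb < 0) tb = 0;

      double sScat = (mus[med] > 0) ? tau / mus[med] : R_PosInf;
      double ds = (sScat < tb) ? sScat : tb;

      pos[0] += dir[0] * ds; pos[1] += dir[1] * ds; pos[2] += dir[2] * ds;
      L[med] += ds;
      A += mua[med] * ds;
      tau -= mus[med] * ds;

      if (sScat < tb) {
        // scattering event
        double ct = sampleHG(gg[med], rng);
        spin(dir, ct, 2.0 * M_PI * rng.next());
        tau = -std::log(rng.next());
      } else {
        // voxel-face crossing
        int jx = ix, jy = iy, jz = iz;
        int dirSign = dir[axis] > 0 ? 1 : -1;
        if (axis == 0) jx += dirSign;
        else if (axis == 1) jy += dirSign;
        else jz += dirSign;

        bool outside = (jx < 0 || jx >= nx || jy < 0 || jy >= ny ||
                        jz < 0 || jz >= nz);
        if (outside) {
          if (axis == 2 && dirSign < 0) {
            // detection face: Fresnel into the external medium
            double n1 = nn[med];
            double cosi = -dir[2];
            double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
            double sint = n1 * sini / nExt;
            if (sint >= 1.0) {           // total internal reflection
              dir[2] = -dir[2];
            } else {
              double cost = std::sqrt(1.0 - sint * sint);
              double R = (std::fabs(nExt - n1) < 1e-12)
                             ? 0.0 : fresnelR(n1, nExt, cosi, cost);
              if (rng.next() < R) {
                dir[2] = -dir[2];
              } else {
                double scale = n1 / nExt;
                double ux = dir[0] * scale, uy = dir[1] * scale;
                double uz = -cost;
                double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
                ux /= norm; uy /= norm; uz /= norm;
                double w = rfac * std::exp(-A);
                double sinExit = std::sqrt(ux * ux + uy * uy);
                if (sinExit <= detSinMax + 1e-12) {
                  dX.push_back(pos[0]); dY.push_back(pos[1]);
                  dUx.push_back(ux); dUy.push_back(uy); dUz.push_back(uz);
                  dW.push_back(w); dRf.push_back(rfac);
                  for (int m = 0; m < nMedia; ++m) dL.push_back(L[m]);
                  wDetected += w;
                  fate = 1;
                } else {
                  wTop += w;
                  fate = 2;
                }
              }
            }
          } else if (axis != 2 && mirrorSides) {
            // mirror boundary: emulates a laterally semi-infinite medium
            dir[axis] = -dir[axis];
          } else {
            // open boundary: the packet leaves the volume
            double w = rfac * std::exp(-A);
            if (axis == 2) { wTrans += w; fate = 3; }
            else { wSide += w; fate = 4; }
          }
        } else {
          int med2 = lab2med[lab[(R_xlen_t)jz * nxy +
                                 (R_xlen_t)jy * nx + jx] - 1];
          double n1 = nn[med], n2 = nn[med2];
          if (std::fabs(n1 - n2) > 1e-12) {
            double cosi = std::fabs(dir[axis]);
            double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
            double sint = n1 * sini / n2;
            if (sint >= 1.0) {
              dir[axis] = -dir[axis];  // total internal reflection
            } else {
              double cost = std::sqrt(1.0 - sint * sint);
              if (rng.next() < fresnelR(n1, n2, cosi, cost)) {
                dir[axis] = -dir[axis];
              } else {
                double scale = n1 / n2;
                for (int a = 0; a < 3; ++a)
                  if (a != axis) dir[a] *= scale;
                dir[axis] = (dir[axis] > 0 ? 1.0 : -1.0) * cost;
                double norm = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] +
                                        dir[2] * dir[2]);
                dir[0] /= norm; dir[1] /= norm; dir[2] /= norm;
                ix = jx; iy = jy; iz = jz; med = med2;
              }
            }
          } else {
            ix = jx; iy = jy; iz = jz; med = med2;
          }
        }
      }

      if (fate == 0) {
        if (!std::isfinite(pos[0]) || !std::isfinite(pos[1]) ||
            !std::isfinite(pos[2]) || !std::isfinite(A))
          stop("non-finite photon state (photon %d)", ph + 1);
        // russian roulette on the in-flight weight rfac * exp(-A)
        if (logRfac - A < logThresh) {
          if (rng.next() < invRR) {
            rfac *= rrFactor;
            logRfac += logRR;
          } else {
            wKilled += rfac * std::exp(-A);
            fate = 5;
          }
        }
      }
    }
  }

  int nDet = (int)dX.size();
  NumericMatrix photons(nDet, 7);
  NumericMatrix paths(nDet, nMedia);
  for (int i = 0; i < nDet; ++i) {
    photons(i, 0) = dX[i]; photons(i, 1) = dY[i];
    photons(i, 2) = dUx[i]; photons(i, 3) = dUy[i]; photons(i, 4) = dUz[i];
    photons(i, 5) = dW[i]; photons(i, 6) = dRf[i];
    for (int m = 0; m < nMedia; ++m)
      paths(i, m) = dL[(R_xlen_t)i * nMedia + m];
  }
  colnames(photons) = CharacterVector::create("x", "y", "ux", "uy", "uz",
                                              "weight", "rouletteFactor");
  NumericVector tallies = NumericVector::create(
      _["detected"] = wDetected, _["top"] = wTop, _["transmitted"] = wTrans,
      _["side"] = wSide, _["killed"] = wKilled);
  return List::create(_["photons"] = photons, _["pathlengths"] = paths,
                      _["tallies"] = tallies, _["nLaunched"] = nPhotons);
}
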