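// Voxel-level numerical core: 3D convolution (+ adjoint for gradients),
// connected-component labeling, the physicochemical potential sums, the
// sphere-box ligand truth mask and small neighbor-search helpers.
//
// Arrays follow R's column-major layout: linear index = i + nx*(j + ny*k),
// 0-based here, with voxel (i,j,k) centered at origin + (i+1/2, j+1/2,
// k+1/2) * spacing.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

// out(x) = sum_t K(t) f(x - t), zero padding outside the grid.
// Kernel dims must be odd; tap offset t runs over [-r, r]^3.
// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector field, IntegerVector fdim,
                         NumericVector kern, IntegerVector kdim) {
  const int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int rx = kx / 2, ry = ky / 2, rz = kz / 2;
  NumericVector out(field.size());
  const double *f = field.begin();
  const double *K = kern.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z) {
    const int tz0 = std::max(-rz, z - nz + 1), tz1 = std::min(rz, z);
    for (int y = 0; y < ny; ++y) {
      const int ty0 = std::max(-ry, y - ny + 1), ty1 = std::min(ry, y);
      for (int x = 0; x < nx; ++x) {
        const int tx0 = std::max(-rx, x - nx + 1), tx1 = std::min(rx, x);
        double acc = 0.0;
        for (int tz = tz0; tz <= tz1; ++tz) {
          for (int ty = ty0; ty <= ty1; ++ty) {
            const double *Kp = K + (tx0 + rx) + kx * ((ty + ry) + ky * (tz + rz));
            const double *fp = f + (x - tx0) + nx * ((y - ty) + ny * (z - tz));
            for (int tx = tx0; tx <= tx1; ++tx, ++Kp, --fp)
              acc += (*Kp) * (*fp);
          }
        }
        o[x + nx * (y + (size_t)ny * z)] = acc;
      }
    }
  }
  out.attr("dim") = fdim;
  return out;
}

// Gradient of the convolution with respect to the kernel taps:
// dL/dK(t) = sum_x g(x) f(x - t), g being dL/d(out).
// [[Rcpp::export]]
NumericVector cpp_conv3d_adjoint(NumericVector g, NumericVector field,
                                 IntegerVector fdim, IntegerVector kdim) {
  const int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int rx = kx / 2, ry = ky / 2, rz = kz / 2;
  NumericVector out(kx * ky * (size_t)kz);
  const double *f = field.begin();
  const double *gp = g.begin();
  for (int tz = -rz; tz <= rz; ++tz) {
    for (int ty = -ry; ty <= ry; ++ty) {
      for (int tx = -rx; tx <= rx; ++tx) {
        double acc = 0.0;
        const int x0 = std::max(0, tx), x1 = std::min(nx - 1, nx - 1 + tx);
        const int y0 = std::max(0, ty), y1 = std::min(ny - 1, ny - 1 + ty);
        const int z0 = std::max(0, tz), z1 = std::min(nz - 1, nz - 1 + tz);
        for (int z = z0; z <= z1; ++z)
          for (int y = y0; y <= y1; ++y) {
            const double *ga = gp + x0 + nx * (y + (size_t)ny * z);
            const double *fa = f + (x0 - tx) + nx * ((y - ty) + (size_t)ny * (z - tz));
            for (int x = x0; x <= x1; ++x, ++ga, ++fa)
              acc += (*ga) * (*fa);
          }
        out[(tx + rx) + kx * ((ty + ry) + (size_t)ky * (tz + rz))] = acc;
      }
    }
  }
  out.attr("dim") = kdim;
  return out;
}

// Connected components of a binary field; labels assigned in scan order
// (column-major), background 0. connectivity in {6, 18, 26}.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<int> offs_dx, offs_dy, offs_dz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        offs_dx.push_back(dx); offs_dy.push_back(dy); offs_dz.push_back(dz);
      }
  IntegerVector lab(n);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((size_t)nx * ny));
      for (size_t q = 0; q < offs_dx.size(); ++q) {
        int xx = x + offs_dx[q], yy = y + offs_dy[q], zz = z + offs_dz[q];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        size_t w = xx + nx * (yy + (size_t)ny * zz);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Distance channel: value at each voxel center x is d(x, nearest atom
// center) - radius(nearest atom).
// [[Rcpp::export]]
NumericVector cpp_distance_field(NumericMatrix coords, NumericVector radii,
                                 NumericVector origin, double spacing,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = coords.nrow();
  NumericVector out((size_t)nx * ny * nz);
  std::vector<double> ax(na), ay(na), az(na);
  for (int a = 0; a < na; ++a) {
    ax[a] = coords(a, 0); ay[a] = coords(a, 1); az[a] = coords(a, 2);
  }
  size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double cz = origin[2] + (k + 0.5) * spacing;
    for (int j = 0; j < ny; ++j) {
      double cy = origin[1] + (j + 0.5) * spacing;
      for (int i = 0; i < nx; ++i, ++idx) {
        double cx = origin[0] + (i + 0.5) * spacing;
        double best = R_PosInf;
        int arg = 0;
        for (int a = 0; a < na; ++a) {
          double d2 = sq(cx - ax[a]) + sq(cy - ay[a]) + sq(cz - az[a]);
          if (d2 < best) { best = d2; arg = a; }
        }
        out[idx] = std::sqrt(best) - radii[arg];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Inverse-distance potential: sum over atoms within `cutoff` of
// coef(a) / max(d, dmin). Atoms with zero coefficient are skipped.
// [[Rcpp::export]]
NumericVector cpp_invdist_field(NumericMatrix coords, NumericVector coef,
                                NumericVector origin, double spacing,
                                IntegerVector dims, double cutoff,
                                double dmin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> ax, ay, az, cf;
  for (int a = 0; a < coords.nrow(); ++a) {
    if (coef[a] == 0.0) continue;
    ax.push_back(coords(a, 0)); ay.push_back(coords(a, 1));
    az.push_back(coords(a, 2)); cf.push_back(coef[a]);
  }
  const int na = (int)ax.size();
  const double cut2 = cutoff * cutoff;
  NumericVector out((size_t)nx * ny * nz);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double cz = origin[2] + (k + 0.5) * spacing;
    for (int j = 0; j < ny; ++j) {
      double cy = origin[1] + (j + 0.5) * spacing;
      for (int i = 0; i < nx; ++i, ++idx) {
        double cx = origin[0] + (i + 0.5) * spacing;
        double acc = 0.0;
        for (int a = 0; a < na; ++a) {
          double d2 = sq(cx - ax[a]) + sq(cy - ay[a]) + sq(cz - az[a]);
          if (d2 > cut2) continue;
          double d = std::sqrt(d2);
          if (d < dmin) d = dmin;
          acc += cf[a] / d;
        }
        out[idx] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

static inline double hb_radial(double d, double eps, double rmin,
                               double dmin, double rcap) {
  if (d < dmin) d = dmin;
  double R = rmin / d + 0.96;
  if (R > rcap) R = rcap;
  double R2 = R * R, R4 = R2 * R2;
  return -eps * (R4 * R2 - 2.0 * R4);
}

// Hydrogen-bond acceptor potential.
// [[Rcpp::export]]
NumericVector cpp_hb_acceptor_field(NumericMatrix coords, NumericVector eps,
                                    NumericVector rmin, NumericVector origin,
                                    double spacing, IntegerVector dims,
                                    double cutoff, double dmin, double rcap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = coords.nrow();
  const double cut2 = cutoff * cutoff;
  NumericVector out((size_t)nx * ny * nz);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double cz = origin[2] + (k + 0.5) * spacing;
    for (int j = 0; j < ny; ++j) {
      double cy = origin[1] + (j + 0.5) * spacing;
      for (int i = 0; i < nx; ++i, ++idx) {
        double cx = origin[0] + (i + 0.5) * spacing;
        double acc = 0.0;
        for (int a = 0; a < na; ++a) {
          double d2 = sq(cx - coords(a, 0)) + sq(cy - coords(a, 1)) +
                      sq(cz - coords(a, 2));
          if (d2 > cut2) continue;
          acc += hb_radial(std::sqrt(d2), eps[a], rmin[a], dmin, rcap);
        }
        out[idx] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Hydrogen-bond donor potential. For donor D with bonded hydrogens H and
// heavy-atom antecedent A, the radial acceptor-style term (distance taken
// from D) is modulated by cos^2(ang1) * cos^2(ang2) where ang1 is the angle
// between D->H and H->x (zeroed beyond 90 degrees) and ang2 the angle
// between A->D and D->x (factor 1 when no antecedent). The angular factor
// is maximized over the donor's hydrogens.
// [[Rcpp::export]]
NumericVector cpp_hb_donor_field(NumericMatrix donors, NumericVector eps,
                                 NumericVector rmin, NumericMatrix ants,
                                 LogicalVector has_ant, NumericMatrix hyd,
                                 IntegerVector hyd_start, NumericVector origin,
                                 double spacing, IntegerVector dims,
                                 double cutoff, double dmin, double rcap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nd = donors.nrow();
  const double cut2 = cutoff * cutoff;
  NumericVector out((size_t)nx * ny * nz);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double cz = origin[2] + (k + 0.5) * spacing;
    for (int j = 0; j < ny; ++j) {
      double cy = origin[1] + (j + 0.5) * spacing;
      for (int i = 0; i < nx; ++i, ++idx) {
        double cx = origin[0] + (i + 0.5) * spacing;
        double acc = 0.0;
        for (int d = 0; d < nd; ++d) {
          double vx = cx - donors(d, 0), vy = cy - donors(d, 1),
                 vz = cz - donors(d, 2);
          double d2 = vx * vx + vy * vy + vz * vz;
          if (d2 > cut2) continue;
          double dist = std::sqrt(d2);
          double radial = hb_radial(dist, eps[d], rmin[d], dmin, rcap);
          // angle at the donor against the antecedent direction
          double c2sq = 1.0;
          if (has_ant[d]) {
            double ux = donors(d, 0) - ants(d, 0),
                   uy = donors(d, 1) - ants(d, 1),
                   uz = donors(d, 2) - ants(d, 2);
            double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
            if (nu > 0 && dist > 0) {
              double c = (ux * vx + uy * vy + uz * vz) / (nu * dist);
              c2sq = c * c;
            }
          }
          // best hydrogen
          double best = 0.0;
          for (int h = hyd_start[d]; h < hyd_start[d + 1]; ++h) {
            double bx = hyd(h, 0) - donors(d, 0),
                   by = hyd(h, 1) - donors(d, 1),
                   bz = hyd(h, 2) - donors(d, 2);
            double nb = std::sqrt(bx * bx + by * by + bz * bz);
            double wx = cx - hyd(h, 0), wy = cy - hyd(h, 1),
                   wz = cz - hyd(h, 2);
            double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
            double c1;
            if (nb == 0.0 || nw == 0.0) c1 = 1.0;
            else c1 = (bx * wx + by * wy + bz * wz) / (nb * nw);
            if (c1 < 0.0) continue;  // beyond 90 degrees
            double f = c1 * c1 * c2sq;
            if (f > best) best = f;
          }
          acc += radial * best;
        }
        out[idx] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Ligand truth mask: voxel is 1 iff some atom sphere intersects its cube
// with positive overlap (strict sphere-box test), or the atom center lies
// inside the voxel's half-open cube (covers zero-radius corner cases).
// [[Rcpp::export]]
LogicalVector cpp_truth_mask(NumericMatrix coords, NumericVector radii,
                             NumericVector origin, double spacing,
                             IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((size_t)nx * ny * nz);
  for (int a = 0; a < coords.nrow(); ++a) {
    double c0 = coords(a, 0), c1 = coords(a, 1), c2 = coords(a, 2);
    double r = radii[a], r2 = r * r;
    int i0 = std::max(0, (int)std::floor((c0 - r - origin[0]) / spacing) - 1);
    int j0 = std::max(0, (int)std::floor((c1 - r - origin[1]) / spacing) - 1);
    int k0 = std::max(0, (int)std::floor((c2 - r - origin[2]) / spacing) - 1);
    int i1 = std::min(nx - 1, (int)std::floor((c0 + r - origin[0]) / spacing) + 1);
    int j1 = std::min(ny - 1, (int)std::floor((c1 + r - origin[1]) / spacing) + 1);
    int k1 = std::min(nz - 1, (int)std::floor((c2 + r - origin[2]) / spacing) + 1);
    for (int k = k0; k <= k1; ++k) {
      double lz = origin[2] + k * spacing, hz = lz + spacing;
      for (int j = j0; j <= j1; ++j) {
        double ly = origin[1] + j * spacing, hy = ly + spacing;
        for (int i = i0; i <= i1; ++i) {
          double lx = origin[0] + i * spacing, hx = lx + spacing;
          double px = std::min(std::max(c0, lx), hx);
          double py = std::min(std::max(c1, ly), hy);
          double pz = std::min(std::max(c2, lz), hz);
          double d2 = sq(c0 - px) + sq(c1 - py) + sq(c2 - pz);
          bool inside = (c0 >= lx && c0 < hx && c1 >= ly && c1 < hy &&
                         c2 >= lz && c2 < hz);
          if (d2 < r2 || inside)
            out[i + nx * (j + (size_t)ny * k)] = true;
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// For each row of `a`, the minimum Euclidean distance to any row of `b`.
// [[Rcpp::export]]
NumericVector cpp_min_dist_each(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double d2 = sq(a(i, 0) - b(j, 0)) + sq(a(i, 1) - b(j, 1)) +
                  sq(a(i, 2) - b(j, 2));
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Covalent bonds: pairs (i, j), 1-based, with d <= covr_i + covr_j + tol.
// [[Rcpp::export]]
IntegerMatrix cpp_bond_pairs(NumericMatrix coords, NumericVector covr,
                             double tol) {
  const int n = coords.nrow();
  std::vector<int> pi, pj;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double lim = covr[i] + covr[j] + tol;
      double dx = coords(i, 0) - coords(j, 0);
      if (std::fabs(dx) > lim) continue;
      double d2 = dx * dx + sq(coords(i, 1) - coords(j, 1)) +
                  sq(coords(i, 2) - coords(j, 2));
      if (d2 <= lim * lim && d2 > 1e-12) {
        pi.push_back(i + 1);
        pj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out((int)pi.size(), 2);
  for (size_t q = 0; q < pi.size(); ++q) {
    out(q, 0) = pi[q];
    out(q, 1) = pj[q];
  }
  return out;
}
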