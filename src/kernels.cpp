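#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// All 3D arrays are column-major with dim (nz, ny, nx), linear index
// i = z + nz * (y + ny * x); borders are handled by symmetric reflection
// (edge sample repeated: -1 -> 0, n -> n-1).

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * n;
  i %= p;
  if (i < 0) i += p;
  if (i >= n) i = p - 1 - i;
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_median_filter3d(NumericVector x, IntegerVector dim, int h) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(x.size());
  const int w = 2 * h + 1;
  std::vector<double> buf(w * w * w);
  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      for (int iz = 0; iz < nz; ++iz) {
        int k = 0;
        for (int dx = -h; dx <= h; ++dx) {
          const int jx = reflect_idx(ix + dx, nx);
          for (int dy = -h; dy <= h; ++dy) {
            const int jy = reflect_idx(iy + dy, ny);
            const size_t base = (size_t)nz * (jy + (size_t)ny * jx);
            for (int dz = -h; dz <= h; ++dz) {
              buf[k++] = x[reflect_idx(iz + dz, nz) + base];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + buf.size() / 2, buf.end());
        out[iz + (size_t)nz * (iy + (size_t)ny * ix)] = buf[buf.size() / 2];
      }
    }
  }
  return out;
}

// Mean over the cubic window of radius r, separable sliding sums on a
// reflect-padded copy. Window size is always (2r+1)^3.
// [[Rcpp::export]]
NumericVector cpp_box_mean3d(NumericVector x, IntegerVector dim, int r) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int Nz = nz + 2 * r, Ny = ny + 2 * r, Nx = nx + 2 * r;
  std::vector<double> p0((size_t)Nz * Ny * Nx);
  for (int ix = 0; ix < Nx; ++ix) {
    const int jx = reflect_idx(ix - r, nx);
    for (int iy = 0; iy < Ny; ++iy) {
      const int jy = reflect_idx(iy - r, ny);
      const size_t src = (size_t)nz * (jy + (size_t)ny * jx);
      const size_t dst = (size_t)Nz * (iy + (size_t)Ny * ix);
      for (int iz = 0; iz < Nz; ++iz)
        p0[iz + dst] = x[reflect_idx(iz - r, nz) + src];
    }
  }
  // slide along z: (Nz,Ny,Nx) -> (nz,Ny,Nx)
  std::vector<double> p1((size_t)nz * Ny * Nx);
  for (size_t line = 0; line < (size_t)Ny * Nx; ++line) {
    const double *in = &p0[line * Nz];
    double *out = &p1[line * nz];
    double s = 0.0;
    for (int k = 0; k < 2 * r + 1; ++k) s += in[k];
    out[0] = s;
    for (int z = 1; z < nz; ++z) { s += in[z + 2 * r] - in[z - 1]; out[z] = s; }
  }
  // slide along y: (nz,Ny,Nx) -> (nz,ny,Nx)
  std::vector<double> p2((size_t)nz * ny * Nx);
  for (int ix = 0; ix < Nx; ++ix) {
    for (int iz = 0; iz < nz; ++iz) {
      double s = 0.0;
      for (int k = 0; k < 2 * r + 1; ++k) s += p1[iz + (size_t)nz * (k + (size_t)Ny * ix)];
      p2[iz + (size_t)nz * (0 + (size_t)ny * ix)] = s;
      for (int y = 1; y < ny; ++y) {
        s += p1[iz + (size_t)nz * (y + 2 * r + (size_t)Ny * ix)]
           - p1[iz + (size_t)nz * (y - 1 + (size_t)Ny * ix)];
        p2[iz + (size_t)nz * (y + (size_t)ny * ix)] = s;
      }
    }
  }
  // slide along x: (nz,ny,Nx) -> (nz,ny,nx)
  NumericVector out((size_t)nz * ny * nx);
  const double w3 = std::pow(2.0 * r + 1.0, 3);
  const size_t plane = (size_t)nz * ny;
  for (size_t i = 0; i < plane; ++i) {
    double s = 0.0;
    for (int k = 0; k < 2 * r + 1; ++k) s += p2[i + plane * k];
    out[i] = s / w3;
    for (int xo = 1; xo < nx; ++xo) {
      s += p2[i + plane * (xo + 2 * r)] - p2[i + plane * (xo - 1)];
      out[i + plane * xo] = s / w3;
    }
  }
  return out;
}

// 1D correlation along one axis (0 = z, 1 = y, 2 = x), reflected borders.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector x, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int h = kl / 2;
  NumericVector out(x.size());
  const int n = dim[axis];
  if (axis == 0) {
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy) {
        const size_t b = (size_t)nz * (iy + (size_t)ny * ix);
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int k = -h; k <= h; ++k)
            s += kernel[k + h] * x[b + reflect_idx(i + k, n)];
          out[b + i] = s;
        }
      }
  } else if (axis == 1) {
    for (int ix = 0; ix < nx; ++ix)
      for (int iz = 0; iz < nz; ++iz) {
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int k = -h; k <= h; ++k)
            s += kernel[k + h] * x[iz + (size_t)nz * (reflect_idx(i + k, n) + (size_t)ny * ix)];
          out[iz + (size_t)nz * (i + (size_t)ny * ix)] = s;
        }
      }
  } else {
    const size_t plane = (size_t)nz * ny;
    for (size_t p = 0; p < plane; ++p)
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int k = -h; k <= h; ++k)
          s += kernel[k + h] * x[p + plane * reflect_idx(i + k, n)];
        out[p + plane * i] = s;
      }
  }
  return out;
}

struct WsNode {
  double v;
  long long seq;
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.v != b.v) return a.v > b.v;      // min-heap on value
    return a.seq > b.seq;                  // FIFO among equal values
  }
};

// Marker-controlled immersion watershed, 26-connectivity, restricted to mask.
// Ties flood in FIFO order of queue insertion; markers are enqueued in
// increasing linear-index order and neighbours in expand.grid(dz,dy,dx) order
// (dz varying fastest).
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector x, IntegerVector markers,
                            IntegerVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const size_t ntot = (size_t)nz * ny * nx;
  IntegerVector labels(ntot);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> q;
  long long seq = 0;
  for (size_t i = 0; i < ntot; ++i) {
    if (markers[i] > 0) {
      if (!mask[i]) stop("marker outside mask");
      labels[i] = markers[i];
      q.push(WsNode{x[i], seq++, (int)i});
    }
  }
  while (!q.empty()) {
    WsNode nd = q.top();
    q.pop();
    const int i = nd.idx;
    const int iz = i % nz;
    const int iy = (i / nz) % ny;
    const int ix = i / (nz * ny);
    const int lab = labels[i];
    for (int dx = -1; dx <= 1; ++dx) {
      const int jx = ix + dx;
      if (jx < 0 || jx >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int jy = iy + dy;
        if (jy < 0 || jy >= ny) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          if (dz == 0 && dy == 0 && dx == 0) continue;
          const int jz = iz + dz;
          if (jz < 0 || jz >= nz) continue;
          const size_t j = jz + (size_t)nz * (jy + (size_t)ny * jx);
          if (mask[j] && labels[j] == 0) {
            labels[j] = lab;
            q.push(WsNode{x[j], seq++, (int)j});
          }
        }
      }
    }
  }
  return labels;
}

// Grayscale opening of one 2D slice with a non-flat ball structuring element
// of the given radius (height sqrt(r^2 - d^2) over the disc d <= r).
// Out-of-image samples are ignored (+Inf for erosion, -Inf for dilation).
// [[Rcpp::export]]
NumericMatrix cpp_ball_opening2d(NumericMatrix slice, int radius) {
  const int ny = slice.nrow(), nx = slice.ncol();
  std::vector<int> offy, offx;
  std::vector<double> height;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx) {
      const double d2 = (double)dy * dy + (double)dx * dx;
      if (d2 <= (double)radius * radius) {
        offy.push_back(dy);
        offx.push_back(dx);
        height.push_back(std::sqrt((double)radius * radius - d2));
      }
    }
  const int m = offy.size();
  NumericMatrix ero(ny, nx), out(ny, nx);
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      double e = R_PosInf;
      for (int k = 0; k < m; ++k) {
        const int jy = iy + offy[k], jx = ix + offx[k];
        if (jy < 0 || jy >= ny || jx < 0 || jx >= nx) continue;
        const double v = slice(jy, jx) - height[k];
        if (v < e) e = v;
      }
      ero(iy, ix) = e;
    }
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      double d = R_NegInf;
      for (int k = 0; k < m; ++k) {
        const int jy = iy + offy[k], jx = ix + offx[k];
        if (jy < 0 || jy >= ny || jx < 0 || jx >= nx) continue;
        const double v = ero(jy, jx) + height[k];
        if (v > d) d = v;
      }
      out(iy, ix) = d;
    }
  return out;
}

// Strict local maxima of a 4D scale-space response (ns, nz, ny, nx):
// greater than every existing neighbour in the 3x3x3x3 hypercube
// (adjacent scales included), and >= thresh. Returns 1-based (s,z,y,x).
// [[Rcpp::export]]
List cpp_scale_maxima(NumericVector resp, IntegerVector dim4, double thresh) {
  const int ns = dim4[0], nz = dim4[1], ny = dim4[2], nx = dim4[3];
  std::vector<int> ms, mz, my, mx;
  std::vector<double> mv;
  const size_t sz = (size_t)ns;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz)
        for (int is = 0; is < ns; ++is) {
          const double v = resp[is + sz * (iz + (size_t)nz * (iy + (size_t)ny * ix))];
          if (!(v >= thresh)) continue;
          bool ok = true;
          for (int dx = -1; dx <= 1 && ok; ++dx) {
            const int jx = ix + dx;
            if (jx < 0 || jx >= nx) continue;
            for (int dy = -1; dy <= 1 && ok; ++dy) {
              const int jy = iy + dy;
              if (jy < 0 || jy >= ny) continue;
              for (int dz = -1; dz <= 1 && ok; ++dz) {
                const int jz = iz + dz;
                if (jz < 0 || jz >= nz) continue;
                for (int ds = -1; ds <= 1; ++ds) {
                  const int js = is + ds;
                  if (js < 0 || js >= ns) continue;
                  if (ds == 0 && dz == 0 && dy == 0 && dx == 0) continue;
                  if (resp[js + sz * (jz + (size_t)nz * (jy + (size_t)ny * jx))] >= v) {
                    ok = false;
                    break;
                  }
                }
              }
            }
          }
          if (ok) {
            ms.push_back(is + 1); mz.push_back(iz + 1);
            my.push_back(iy + 1); mx.push_back(ix + 1);
            mv.push_back(v);
          }
        }
  const int n = ms.size();
  IntegerMatrix pts(n, 4);
  NumericVector vals(n);
  for (int i = 0; i < n; ++i) {
    pts(i, 0) = ms[i]; pts(i, 1) = mz[i]; pts(i, 2) = my[i]; pts(i, 3) = mx[i];
    vals[i] = mv[i];
  }
  return List::create(_["points"] = pts, _["values"] = vals);
}
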