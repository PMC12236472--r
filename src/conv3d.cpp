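#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D "same" convolution kernels operating on channels-first flattened
// volumes: x is Cin x V with V = d1*d2*d3 voxels stored column-major in
// (i1, i2, i3) order (linear index v = i1 + d1*(i2 + d2*i3)). Weights are
// Cout x (Cin*k^3) with column index ci + Cin*(o1 + k*(o2 + k*o3)), where
// o1/o2/o3 in [0, k) are kernel offsets along the three axes and the kernel
// is centered (displacement o - (k-1)/2). Zero padding outside the volume.
//
// Internally the volumes are transposed to voxel-major (V x C) scratch
// buffers so that, for a fixed kernel offset and channel pair, the update
// is a contiguous axpy/dot over runs of voxels along the first axis.

static void transpose_to_vmajor(const double* x, int C, R_xlen_t V,
                                std::vector<double>& xt) {
  xt.resize((size_t)C * V);
  for (R_xlen_t v = 0; v < V; ++v)
    for (int c = 0; c < C; ++c)
      xt[(size_t)c * V + v] = x[(size_t)C * v + c];
}

static void transpose_from_vmajor(const std::vector<double>& yt, int C,
                                  R_xlen_t V, double* y) {
  for (R_xlen_t v = 0; v < V; ++v)
    for (int c = 0; c < C; ++c)
      y[(size_t)C * v + c] = yt[(size_t)c * V + v];
}

// [[Rcpp::export]]
NumericMatrix conv3d_fw(const NumericMatrix& x, const IntegerVector& sp,
                        const NumericMatrix& w, const NumericVector& b,
                        int k) {
  const int cin = x.nrow();
  const int d1 = sp[0], d2 = sp[1], d3 = sp[2];
  const R_xlen_t V = (R_xlen_t)d1 * d2 * d3;
  const int cout = w.nrow();
  const int p = (k - 1) / 2;
  NumericMatrix y(cout, V);
  const double* pw = REAL(w);

  std::vector<double> xt, yt((size_t)cout * V, 0.0);
  transpose_to_vmajor(REAL(x), cin, V, xt);
  for (int co = 0; co < cout; ++co)
    std::fill(yt.begin() + (size_t)co * V, yt.begin() + (size_t)(co + 1) * V,
              b[co]);

  for (int o3 = 0; o3 < k; ++o3) {
    const int s3 = o3 - p;
    const int i3lo = std::max(0, -s3), i3hi = std::min(d3, d3 - s3);
    for (int o2 = 0; o2 < k; ++o2) {
      const int s2 = o2 - p;
      const int i2lo = std::max(0, -s2), i2hi = std::min(d2, d2 - s2);
      for (int o1 = 0; o1 < k; ++o1) {
        const int s1 = o1 - p;
        const int i1lo = std::max(0, -s1), i1hi = std::min(d1, d1 - s1);
        const int run = i1hi - i1lo;
        if (run <= 0) continue;
        const double* wslice =
          pw + (size_t)cout * cin * (o1 + k * (o2 + k * o3));
        for (int ci = 0; ci < cin; ++ci) {
          const double* xc = xt.data() + (size_t)ci * V;
          for (int co = 0; co < cout; ++co) {
            const double wv = wslice[co + (size_t)cout * ci];
            if (wv == 0.0) continue;
            double* yc = yt.data() + (size_t)co * V;
            for (int i3 = i3lo; i3 < i3hi; ++i3) {
              for (int i2 = i2lo; i2 < i2hi; ++i2) {
                const R_xlen_t v0 =
                  i1lo + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
                const R_xlen_t u0 = v0 + s1 +
                  (R_xlen_t)d1 * (s2 + (R_xlen_t)d2 * s3);
                double* yp = yc + v0;
                const double* xp = xc + u0;
                for (int t = 0; t < run; ++t) yp[t] += wv * xp[t];
              }
            }
          }
        }
      }
    }
  }
  transpose_from_vmajor(yt, cout, V, REAL(y));
  return y;
}

// gradient w.r.t. the input: gx(ci, u) += sum_co gy(co, v) * w(co, ci, off)
// [[Rcpp::export]]
NumericMatrix conv3d_bw_x(const NumericMatrix& gy, const IntegerVector& sp,
                          const NumericMatrix& w, int cin, int k) {
  const int d1 = sp[0], d2 = sp[1], d3 = sp[2];
  const R_xlen_t V = (R_xlen_t)d1 * d2 * d3;
  const int cout = gy.nrow();
  const int p = (k - 1) / 2;
  NumericMatrix gx(cin, V);
  const double* pw = REAL(w);

  std::vector<double> gt, xt((size_t)cin * V, 0.0);
  transpose_to_vmajor(REAL(gy), cout, V, gt);

  for (int o3 = 0; o3 < k; ++o3) {
    const int s3 = o3 - p;
    const int i3lo = std::max(0, -s3), i3hi = std::min(d3, d3 - s3);
    for (int o2 = 0; o2 < k; ++o2) {
      const int s2 = o2 - p;
      const int i2lo = std::max(0, -s2), i2hi = std::min(d2, d2 - s2);
      for (int o1 = 0; o1 < k; ++o1) {
        const int s1 = o1 - p;
        const int i1lo = std::max(0, -s1), i1hi = std::min(d1, d1 - s1);
        const int run = i1hi - i1lo;
        if (run <= 0) continue;
        const double* wslice =
          pw + (size_t)cout * cin * (o1 + k * (o2 + k * o3));
        for (int ci = 0; ci < cin; ++ci) {
          double* xc = xt.data() + (size_t)ci * V;
          for (int co = 0; co < cout; ++co) {
            const double wv = wslice[co + (size_t)cout * ci];
            if (wv == 0.0) continue;
            const double* gc = gt.data() + (size_t)co * V;
            for (int i3 = i3lo; i3 < i3hi; ++i3) {
              for (int i2 = i2lo; i2 < i2hi; ++i2) {
                const R_xlen_t v0 =
                  i1lo + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
                const R_xlen_t u0 = v0 + s1 +
                  (R_xlen_t)d1 * (s2 + (R_xlen_t)d2 * s3);
                const double* gp = gc + v0;
                double* xp = xc + u0;
                for (int t = 0; t < run; ++t) xp[t] += wv * gp[t];
              }
            }
          }
        }
      }
    }
  }
  transpose_from_vmajor(xt, cin, V, REAL(gx));
  return gx;
}

// gradients w.r.t. weights and bias
// [[Rcpp::export]]
List conv3d_bw_w(const NumericMatrix& gy, const NumericMatrix& x,
                 const IntegerVector& sp, int k) {
  const int cin = x.nrow();
  const int d1 = sp[0], d2 = sp[1], d3 = sp[2];
  const R_xlen_t V = (R_xlen_t)d1 * d2 * d3;
  const int cout = gy.nrow();
  const int p = (k - 1) / 2;
  NumericMatrix gw(cout, cin * k * k * k);
  NumericVector gb(cout);
  double* pw = REAL(gw);

  std::vector<double> gt, xt;
  transpose_to_vmajor(REAL(gy), cout, V, gt);
  transpose_to_vmajor(REAL(x), cin, V, xt);

  for (int co = 0; co < cout; ++co) {
    const double* gc = gt.data() + (size_t)co * V;
    double acc = 0.0;
    for (R_xlen_t v = 0; v < V; ++v) acc += gc[v];
    gb[co] = acc;
  }

  for (int o3 = 0; o3 < k; ++o3) {
    const int s3 = o3 - p;
    const int i3lo = std::max(0, -s3), i3hi = std::min(d3, d3 - s3);
    for (int o2 = 0; o2 < k; ++o2) {
      const int s2 = o2 - p;
      const int i2lo = std::max(0, -s2), i2hi = std::min(d2, d2 - s2);
      for (int o1 = 0; o1 < k; ++o1) {
        const int s1 = o1 - p;
        const int i1lo = std::max(0, -s1), i1hi = std::min(d1, d1 - s1);
        const int run = i1hi - i1lo;
        if (run <= 0) continue;
        double* wslice = pw + (size_t)cout * cin * (o1 + k * (o2 + k * o3));
        for (int ci = 0; ci < cin; ++ci) {
          const double* xc = xt.data() + (size_t)ci * V;
          for (int co = 0; co < cout; ++co) {
            const double* gc = gt.data() + (size_t)co * V;
            double acc = 0.0;
            for (int i3 = i3lo; i3 < i3hi; ++i3) {
              for (int i2 = i2lo; i2 < i2hi; ++i2) {
                const R_xlen_t v0 =
                  i1lo + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
                const R_xlen_t u0 = v0 + s1 +
                  (R_xlen_t)d1 * (s2 + (R_xlen_t)d2 * s3);
                const double* gp = gc + v0;
                const double* xp = xc + u0;
                for (int t = 0; t < run; ++t) acc += gp[t] * xp[t];
              }
            }
            wslice[co + (size_t)cout * ci] += acc;
          }
        }
      }
    }
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}
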