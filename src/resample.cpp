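#include <Rcpp.h>
using namespace Rcpp;

// Trilinear resampling of a 3-D volume onto a target grid.
// M is a 3x4 matrix mapping 0-based target voxel indices (i,j,k,1) to
// continuous 0-based source voxel indices. Values outside the source
// field of view are set to 0.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector sdim,
                                  IntegerVector tdim, NumericMatrix M) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out(static_cast<R_xlen_t>(tx) * ty * tz);
  const double *s = src.begin();
  double *o = out.begin();

  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);

  R_xlen_t idx = 0;
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      const double bx = m01*j + m02*k + m03;
      const double by = m11*j + m12*k + m13;
      const double bz = m21*j + m22*k + m23;
      for (int i = 0; i < tx; ++i, ++idx) {
        const double x = m00*i + bx;
        const double y = m10*i + by;
        const double z = m20*i + bz;
        const int x0 = static_cast<int>(std::floor(x));
        const int y0 = static_cast<int>(std::floor(y));
        const int z0 = static_cast<int>(std::floor(z));
        if (x0 < -1 || x0 >= sx || y0 < -1 || y0 >= sy ||
            z0 < -1 || z0 >= sz) { o[idx] = 0.0; continue; }
        const double fx = x - x0, fy = y - y0, fz = z - z0;
        double acc = 0.0;
        for (int dz = 0; dz <= 1; ++dz) {
          const int zz = z0 + dz;
          if (zz < 0 || zz >= sz) continue;
          const double wz = dz ? fz : 1.0 - fz;
          for (int dy = 0; dy <= 1; ++dy) {
            const int yy = y0 + dy;
            if (yy < 0 || yy >= sy) continue;
            const double wy = dy ? fy : 1.0 - fy;
            for (int dx = 0; dx <= 1; ++dx) {
              const int xx = x0 + dx;
              if (xx < 0 || xx >= sx) continue;
              const double wx = dx ? fx : 1.0 - fx;
              acc += wx * wy * wz *
                s[xx + static_cast<R_xlen_t>(sx) * (yy + static_cast<R_xlen_t>(sy) * zz)];
            }
          }
        }
        o[idx] = acc;
      }
    }
  }
  return out;
}
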