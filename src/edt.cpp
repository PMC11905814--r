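#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

// Exact Euclidean distance transform of a 3-D binary mask, honouring
// per-axis voxel spacing (Felzenszwalb & Huttenlocher lower-envelope
// algorithm applied separably to the squared distance).

static const double BIG = 1e30;  // finite stand-in for "no foreground yet"
static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform on a grid with spacing w.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w) {
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; q++) {
        double xq = q * w;
        double s;
        for (;;) {
            double xv = v[k] * w;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
            if (s <= z[k]) k--; else break;
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        double xq = q * w;
        while (z[k + 1] < xq) k++;
        double dx = xq - v[k] * w;
        d[q] = dx * dx + f[v[k]];
    }
}

// [[Rcpp::export(name = ".edt3d")]]
Rcpp::NumericVector edt3d(Rcpp::LogicalVector mask, Rcpp::IntegerVector dim,
                          Rcpp::NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
    if (mask.size() != ntot)
        Rcpp::stop("mask length does not match dim");
    Rcpp::NumericVector out(ntot);
    for (R_xlen_t i = 0; i < ntot; i++)
        out[i] = (mask[i] == TRUE) ? 0.0 : BIG;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (fastest-varying index)
    for (int kz = 0; kz < nz; kz++)
        for (int jy = 0; jy < ny; jy++) {
            R_xlen_t base = (R_xlen_t)nx * (jy + (R_xlen_t)ny * kz);
            for (int i = 0; i < nx; i++) f[i] = out[base + i];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; i++) out[base + i] = d[i];
        }
    // pass along y
    for (int kz = 0; kz < nz; kz++)
        for (int ix = 0; ix < nx; ix++) {
            R_xlen_t base = ix + (R_xlen_t)nx * ny * kz;
            for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
        }
    // pass along z
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int jy = 0; jy < ny; jy++)
        for (int ix = 0; ix < nx; ix++) {
            R_xlen_t base = ix + (R_xlen_t)nx * jy;
            for (int k = 0; k < nz; k++) f[k] = out[base + nxy * k];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; k++) out[base + nxy * k] = d[k];
        }

    for (R_xlen_t i = 0; i < ntot; i++) out[i] = std::sqrt(out[i]);
    return out;
}

// Minimum over t in [0,1] of |p - (a + t d)| - (r0 + t dr) for one
// segment: the function is convex in t (norm minus linear), so the
// minimum is at an endpoint or at a root of the stationarity condition
// t*L2 - d.w = dr * |w - t d|, which squares to a quadratic in t.
static inline double seg_surface_dist(double wx, double wy, double wz,
                                      double dx, double dy, double dz,
                                      double L2, double r0, double dr) {
    const double dw = dx * wx + dy * wy + dz * wz;
    const double W2 = wx * wx + wy * wy + wz * wz;
    double ts[4];
    int nt = 0;
    ts[nt++] = 0.0;
    ts[nt++] = 1.0;
    if (dr != 0.0 && L2 > 0.0) {
        const double A = L2 * (L2 - dr * dr);
        const double B = -2.0 * dw * (L2 - dr * dr);
        const double C = dw * dw - dr * dr * W2;
        if (std::fabs(A) > 1e-300) {
            const double disc = B * B - 4.0 * A * C;
            if (disc >= 0.0) {
                const double sq = std::sqrt(disc);
                for (int s = -1; s <= 1; s += 2) {
                    double t = (-B + s * sq) / (2.0 * A);
                    if (t > 0.0 && t < 1.0) ts[nt++] = t;
                }
            }
        }
    } else if (L2 > 0.0) {
        double t = dw / L2;  // plain projection when the radius is constant
        if (t > 0.0 && t < 1.0) ts[nt++] = t;
    }
    double best = R_PosInf;
    for (int i = 0; i < nt; i++) {
        const double t = ts[i];
        const double qx = wx - t * dx, qy = wy - t * dy, qz = wz - t * dz;
        const double g = std::sqrt(qx * qx + qy * qy + qz * qz) -
            (r0 + t * dr);
        if (g < best) best = g;
    }
    return best;
}

// Minimum distance from each query point to a set of polyline segments
// with linearly interpolated per-vertex radii (distance to the vessel
// surface, not floored). Used both for bulk polyline queries and to
// sample exact vessel-distance fields at voxel centers.
// [[Rcpp::export(name = ".poly_min_dist")]]
Rcpp::NumericVector poly_min_dist(Rcpp::NumericMatrix pts,
                                  Rcpp::NumericMatrix a,
                                  Rcpp::NumericMatrix b,
                                  Rcpp::NumericVector ra,
                                  Rcpp::NumericVector rb) {
    const R_xlen_t n = pts.nrow();
    const R_xlen_t m = a.nrow();
    // hoist segment data into flat arrays (precompute direction and 1/len2)
    std::vector<double> ax(m), ay(m), az(m), dx(m), dy(m), dz(m),
        inv_len2(m), r0(m), dr(m);
    for (R_xlen_t s = 0; s < m; s++) {
        ax[s] = a(s, 0); ay[s] = a(s, 1); az[s] = a(s, 2);
        dx[s] = b(s, 0) - ax[s];
        dy[s] = b(s, 1) - ay[s];
        dz[s] = b(s, 2) - az[s];
        double len2 = dx[s] * dx[s] + dy[s] * dy[s] + dz[s] * dz[s];
        inv_len2[s] = (len2 > 0.0) ? 1.0 / len2 : 0.0;
        r0[s] = ra[s];
        dr[s] = rb[s] - ra[s];
    }
    std::vector<double> rmax(m), L2(m);
    for (R_xlen_t s = 0; s < m; s++) {
        rmax[s] = std::max(r0[s], r0[s] + dr[s]);
        L2[s] = dx[s] * dx[s] + dy[s] * dy[s] + dz[s] * dz[s];
    }
    Rcpp::NumericVector out(n);
    for (R_xlen_t i = 0; i < n; i++) {
        const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
        double best = R_PosInf;
        for (R_xlen_t s = 0; s < m; s++) {
            const double wx = px - ax[s], wy = py - ay[s], wz = pz - az[s];
            // conservative prune: centerline distance minus the largest
            // radius bounds the surface distance from below
            double t = (wx * dx[s] + wy * dy[s] + wz * dz[s]) * inv_len2[s];
            if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
            const double qx = wx - t * dx[s], qy = wy - t * dy[s],
                         qz = wz - t * dz[s];
            const double d2 = qx * qx + qy * qy + qz * qz;
            const double bound = best + rmax[s];
            if (bound > 0.0 && d2 >= bound * bound) continue;
            const double d = (dr[s] == 0.0)
                ? std::sqrt(d2) - r0[s]
                : seg_surface_dist(wx, wy, wz, dx[s], dy[s], dz[s], L2[s],
                                   r0[s], dr[s]);
            if (d < best) best = d;
        }
        out[i] = best;
    }
    return out;
}
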