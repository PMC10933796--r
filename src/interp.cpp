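#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cubic convolution kernel (Keys, a = -0.5). Used for "spline" interpolation.
static inline double cubic_w(double t) {
    const double a = -0.5;
    t = std::fabs(t);
    if (t < 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
    if (t < 2.0) return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
    return 0.0;
}

static inline double clampi(double v, double lo, double hi) {
    return v < lo ? lo : (v > hi ? hi : v);
}

// method: 0 nearest, 1 linear, 3 cubic. Coordinates are 0-based grid indices.
// Out-of-bounds queries return `fill`; for cubic, border taps are clamped once
// the query itself is inside the grid.
// [[Rcpp::export(name = ".interp2_cpp")]]
NumericVector interp2_cpp(NumericMatrix img, NumericVector xi, NumericVector yi,
                          int method, double fill) {
    const int nx = img.nrow(), ny = img.ncol(), n = xi.size();
    NumericVector out(n);
    for (int q = 0; q < n; ++q) {
        double x = xi[q], y = yi[q];
        if (!std::isfinite(x) || !std::isfinite(y) ||
            x < -1e-6 || y < -1e-6 || x > nx - 1.0 + 1e-6 ||
            y > ny - 1.0 + 1e-6) {
            out[q] = fill;
            continue;
        }
        x = clampi(x, 0.0, nx - 1.0);
        y = clampi(y, 0.0, ny - 1.0);
        if (method == 0) {
            int i = (int)std::lround(x), j = (int)std::lround(y);
            out[q] = img(i, j);
        } else if (method == 1) {
            int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
            if (i0 == nx - 1) i0--;
            if (j0 == ny - 1) j0--;
            if (i0 < 0) i0 = 0;
            if (j0 < 0) j0 = 0;
            double fx = x - i0, fy = y - j0;
            out[q] = img(i0, j0) * (1 - fx) * (1 - fy) +
                     img(i0 + 1, j0) * fx * (1 - fy) +
                     img(i0, j0 + 1) * (1 - fx) * fy +
                     img(i0 + 1, j0 + 1) * fx * fy;
        } else {
            int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
            double acc = 0.0, wsum = 0.0;
            for (int dj = -1; dj <= 2; ++dj) {
                int j = (int)clampi(j0 + dj, 0, ny - 1);
                double wy = cubic_w(y - (j0 + dj));
                for (int di = -1; di <= 2; ++di) {
                    int i = (int)clampi(i0 + di, 0, nx - 1);
                    double w = cubic_w(x - (i0 + di)) * wy;
                    acc += w * img(i, j);
                    wsum += w;
                }
            }
            out[q] = acc / wsum;
        }
    }
    return out;
}

// [[Rcpp::export(name = ".interp3_cpp")]]
NumericVector interp3_cpp(NumericVector vol, IntegerVector dim,
                          NumericVector xi, NumericVector yi, NumericVector zi,
                          int method, double fill) {
    const int nx = dim[0], ny = dim[1], nz = dim[2], n = xi.size();
    const double *v = REAL(vol);
    NumericVector out(n);
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    for (int q = 0; q < n; ++q) {
        double x = xi[q], y = yi[q], z = zi[q];
        if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z) ||
            x < -1e-6 || y < -1e-6 || z < -1e-6 ||
            x > nx - 1.0 + 1e-6 || y > ny - 1.0 + 1e-6 ||
            z > nz - 1.0 + 1e-6) {
            out[q] = fill;
            continue;
        }
        x = clampi(x, 0.0, nx - 1.0);
        y = clampi(y, 0.0, ny - 1.0);
        z = clampi(z, 0.0, nz - 1.0);
        if (method == 0) {
            R_xlen_t i = (R_xlen_t)std::lround(x), j = (R_xlen_t)std::lround(y),
                     k = (R_xlen_t)std::lround(z);
            out[q] = v[i * sx + j * sy + k * sz];
        } else if (method == 1) {
            int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
            if (i0 >= nx - 1) i0 = nx - 2;
            if (j0 >= ny - 1) j0 = ny - 2;
            if (k0 >= nz - 1) k0 = nz - 2;
            if (i0 < 0) i0 = 0;
            if (j0 < 0) j0 = 0;
            if (k0 < 0) k0 = 0;
            double fx = x - i0, fy = y - j0, fz = z - k0;
            const double *b = v + i0 * sx + j0 * sy + k0 * sz;
            double c00 = b[0] * (1 - fx) + b[sx] * fx;
            double c10 = b[sy] * (1 - fx) + b[sy + sx] * fx;
            double c01 = b[sz] * (1 - fx) + b[sz + sx] * fx;
            double c11 = b[sz + sy] * (1 - fx) + b[sz + sy + sx] * fx;
            out[q] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                     (c01 * (1 - fy) + c11 * fy) * fz;
        } else {
            int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
            double acc = 0.0, wsum = 0.0;
            for (int dk = -1; dk <= 2; ++dk) {
                int k = (int)clampi(k0 + dk, 0, nz - 1);
                double wz = cubic_w(z - (k0 + dk));
                if (wz == 0.0) continue;
                for (int dj = -1; dj <= 2; ++dj) {
                    int j = (int)clampi(j0 + dj, 0, ny - 1);
                    double wy = cubic_w(y - (j0 + dj)) * wz;
                    if (wy == 0.0) continue;
                    for (int di = -1; di <= 2; ++di) {
                        int i = (int)clampi(i0 + di, 0, nx - 1);
                        double w = cubic_w(x - (i0 + di)) * wy;
                        acc += w * v[i * sx + j * sy + k * sz];
                        wsum += w;
                    }
                }
            }
            out[q] = acc / wsum;
        }
    }
    return out;
}

// 4-connected component labelling of a logical matrix (BFS).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
    const int nx = mask.nrow(), ny = mask.ncol();
    IntegerMatrix lab(nx, ny);
    int next = 0;
    std::vector<int> stack;
    for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
            if (!mask(i, j) || lab(i, j)) continue;
            ++next;
            stack.push_back(i + j * nx);
            lab(i, j) = next;
            while (!stack.empty()) {
                int p = stack.back();
                stack.pop_back();
                int pi = p % nx, pj = p / nx;
                const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
                for (int d = 0; d < 4; ++d) {
                    int qi = pi + di[d], qj = pj + dj[d];
                    if (qi < 0 || qj < 0 || qi >= nx || qj >= ny) continue;
                    if (mask(qi, qj) && !lab(qi, qj)) {
                        lab(qi, qj) = next;
                        stack.push_back(qi + qj * nx);
                    }
                }
            }
        }
    }
    return lab;
}

// MIND descriptor for a 2D image: 8 immediate-neighbour channels of
// exp(-Dp/V), Dp a 3x3 mean patch distance, V the mean of the 8 distances
// floored at vfloor; each pixel's descriptor rescaled to max 1.
// Returns an (nx*ny) x 8 matrix; `valid` marks pixels with full 5x5 support.
// [[Rcpp::export(name = ".mind_cpp")]]
List mind_cpp(NumericMatrix img, double vfloor) {
    const int nx = img.nrow(), ny = img.ncol();
    const int roff[8][2] = {{-1, -1}, {0, -1}, {1, -1}, {-1, 0},
                            {1, 0},   {-1, 1}, {0, 1},  {1, 1}};
    NumericMatrix desc((R_xlen_t)nx * ny, 8);
    LogicalVector valid((R_xlen_t)nx * ny);
    // padded (replicate) image, margin 2
    const int px = nx + 4, py = ny + 4;
    std::vector<double> P((size_t)px * py);
    for (int j = 0; j < py; ++j) {
        int jj = (int)clampi(j - 2, 0, ny - 1);
        for (int i = 0; i < px; ++i) {
            int ii = (int)clampi(i - 2, 0, nx - 1);
            P[(size_t)i + (size_t)j * px] = img(ii, jj);
        }
    }
    std::vector<double> D((size_t)nx * ny * 8);
    // patch distance per neighbour: mean over 3x3 patch of squared diffs
    for (int r = 0; r < 8; ++r) {
        int rx = roff[r][0], ry = roff[r][1];
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                double s = 0.0;
                for (int tj = -1; tj <= 1; ++tj) {
                    for (int ti = -1; ti <= 1; ++ti) {
                        double a = P[(size_t)(i + 2 + ti) + (size_t)(j + 2 + tj) * px];
                        double b = P[(size_t)(i + 2 + ti + rx) + (size_t)(j + 2 + tj + ry) * px];
                        s += (a - b) * (a - b);
                    }
                }
                D[((size_t)i + (size_t)j * nx) * 8 + r] = s / 9.0;
            }
        }
    }
    for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
            size_t p = (size_t)i + (size_t)j * nx;
            double V = 0.0;
            for (int r = 0; r < 8; ++r) V += D[p * 8 + r];
            V /= 8.0;
            if (V < vfloor) V = vfloor;
            double mx = 0.0;
            double d8[8];
            for (int r = 0; r < 8; ++r) {
                d8[r] = std::exp(-D[p * 8 + r] / V);
                if (d8[r] > mx) mx = d8[r];
            }
            for (int r = 0; r < 8; ++r) desc(p, r) = d8[r] / mx;
            valid[p] = (i >= 2 && j >= 2 && i < nx - 2 && j < ny - 2);
        }
    }
    return List::create(_["desc"] = desc, _["valid"] = valid);
}
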