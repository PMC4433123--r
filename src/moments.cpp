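#include <Rcpp.h>
using namespace Rcpp;

// First-order moments (mean, skewness, non-excess kurtosis) of the raw
// intensity values in the (2r+1)^3 neighbourhood of every in-mask voxel.
// Neighbourhoods are clipped at volume borders and restricted to in-mask
// voxels; out-of-mask output voxels are 0. Fewer than 2 in-mask neighbours
// (or zero variance) falls back to (value, 0, 0).
// [[Rcpp::export]]
List local_moments_cpp(NumericVector vol, LogicalVector mask, int radius) {
    IntegerVector dims = vol.attr("dim");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    NumericVector mu(vol.length()), skew(vol.length()), kurt(vol.length());
    mu.attr("dim") = dims; skew.attr("dim") = dims; kurt.attr("dim") = dims;

    std::vector<double> buf((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));

    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
                if (!mask[idx]) continue;
                int n = 0;
                double s = 0.0;
                const int k0 = std::max(0, k - radius), k1 = std::min(nz - 1, k + radius);
                const int j0 = std::max(0, j - radius), j1 = std::min(ny - 1, j + radius);
                const int i0 = std::max(0, i - radius), i1 = std::min(nx - 1, i + radius);
                for (int kk = k0; kk <= k1; ++kk)
                    for (int jj = j0; jj <= j1; ++jj)
                        for (int ii = i0; ii <= i1; ++ii) {
                            const R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
                            if (mask[q]) { buf[n++] = vol[q]; s += vol[q]; }
                        }
                if (n < 2) { mu[idx] = vol[idx]; continue; }
                const double m = s / n;
                double m2 = 0.0, m3 = 0.0, m4 = 0.0;
                for (int q = 0; q < n; ++q) {
                    const double d = buf[q] - m, d2 = d * d;
                    m2 += d2; m3 += d2 * d; m4 += d2 * d2;
                }
                m2 /= n; m3 /= n; m4 /= n;
                mu[idx] = m;
                if (m2 > 0.0) {
                    const double sd = std::sqrt(m2);
                    skew[idx] = m3 / (sd * sd * sd);
                    kurt[idx] = m4 / (m2 * m2);
                }
            }
        }
    }
    return List::create(_["mean"] = mu, _["skewness"] = skew, _["kurtosis"] = kurt);
}
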