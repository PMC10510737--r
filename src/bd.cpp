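// Overdamped-Langevin (Brownian dynamics) integrator for ions in a model
// channel: axial Gaussian binding wells (optionally off-axis), a smoothed
// flat-bottom radial confinement inside the pore slab, a constant axial
// field, screened-Coulomb ion-ion repulsion, and periodic boundaries.
// Euler-Maruyama update; draws come from R's RNG so set.seed() governs.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double d, double L) {
  if (L <= 0.0) return d;
  return d - L * std::round(d / L);
}

// smoothstep on [0,1]
static inline double sstep(double t) {
  if (t <= 0.0) return 0.0;
  if (t >= 1.0) return 1.0;
  return t * t * (3.0 - 2.0 * t);
}
static inline double sstep_d(double t) {
  if (t <= 0.0 || t >= 1.0) return 0.0;
  return 6.0 * t * (1.0 - t);
}

// [[Rcpp::export]]
List bd_core(NumericMatrix pos0,       // n_ions x 3, coords in [-L/2, L/2)
             NumericVector D,          // A^2/ns per ion
             NumericVector fz_field,   // constant axial force per ion, kJ/mol/A
             NumericVector q,          // elementary charges per ion
             NumericVector box,        // Lx, Ly, Lz
             double kT,                // kJ/mol
             int n_steps, double dt, int stride,
             NumericMatrix well_depth, // n_wells x n_ions effective depths (>= 0)
             NumericVector well_z, NumericVector well_w,
             NumericVector well_rc, NumericVector well_rw,
             double k_conf, double pore_r,
             double z_bottom, double z_top, double edge_a,
             double coul_pref,         // kJ*A/mol/e^2, dielectric-scaled
             double lambda_d, double r_cap,
             int bias_ion,             // 0-based tagged ion, -1 for none
             double bias_k, double bias_c,
             double fb_k, double fb_r) {
  const int n_ions = pos0.nrow();
  const int n_wells = well_z.size();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double max_disp = 5.0;

  std::vector<double> x(n_ions), y(n_ions), z(n_ions);
  for (int i = 0; i < n_ions; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  std::vector<int> down_cross(n_ions, 0), up_cross(n_ions, 0);
  std::vector<double> fx(n_ions), fy(n_ions), fz(n_ions);

  const int n_frames = n_steps / stride + 1;
  NumericVector frames(static_cast<R_xlen_t>(n_frames) * n_ions * 3);
  frames.attr("dim") = IntegerVector::create(n_frames, n_ions, 3);
  auto record = [&](int f) {
    for (int i = 0; i < n_ions; ++i) {
      frames[f + n_frames * (i + (R_xlen_t)n_ions * 0)] = x[i];
      frames[f + n_frames * (i + (R_xlen_t)n_ions * 1)] = y[i];
      frames[f + n_frames * (i + (R_xlen_t)n_ions * 2)] = z[i];
    }
  };
  record(0);
  int next_frame = 1;

  for (int step = 1; step <= n_steps; ++step) {
    // --- forces ---
    for (int i = 0; i < n_ions; ++i) {
      fx[i] = 0.0; fy[i] = 0.0; fz[i] = fz_field[i];
    }
    for (int i = 0; i < n_ions; ++i) {
      const double R = std::sqrt(x[i] * x[i] + y[i] * y[i]);
      // binding wells
      for (int w = 0; w < n_wells; ++w) {
        const double d = well_depth(w, i);
        if (d <= 0.0) continue;
        const double wz = well_w[w];
        const double dz = min_image(z[i] - well_z[w], Lz);
        const double gz = std::exp(-dz * dz / (2.0 * wz * wz));
        double gr = 1.0;
        if (well_rw[w] > 0.0) {  // radial Gaussian (rc = 0: centered on axis)
          const double rw = well_rw[w];
          const double dr = R - well_rc[w];
          gr = std::exp(-dr * dr / (2.0 * rw * rw));
          if (R > 1e-9) {
            const double fR = -d * gz * gr * dr / (rw * rw); // -dU/dR
            fx[i] += fR * x[i] / R;
            fy[i] += fR * y[i] / R;
          }
        }
        fz[i] += -d * gz * gr * dz / (wz * wz); // -dU/dz, attraction to center
      }
      // pore-wall confinement, smooth in z across the membrane slab
      if (k_conf > 0.0) {
        const double tb = (z[i] - z_bottom) / edge_a;
        const double tt = (z_top - z[i]) / edge_a;
        const double W = sstep(tb) * sstep(tt);
        if (W > 0.0) {
          const double excess = R - pore_r;
          if (excess > 0.0) {
            if (R > 1e-9) {
              const double fR = -k_conf * excess * W;
              fx[i] += fR * x[i] / R;
              fy[i] += fR * y[i] / R;
            }
            const double dW = sstep_d(tb) / edge_a * sstep(tt)
                            - sstep(tb) * sstep_d(tt) / edge_a;
            fz[i] += -0.5 * k_conf * excess * excess * dW;
          }
        }
      }
      // umbrella bias + flat-bottom cylinder on the tagged ion
      if (i == bias_ion) {
        fz[i] += -bias_k * min_image(z[i] - bias_c, Lz);
        if (fb_k > 0.0 && R > fb_r && R > 1e-9) {
          const double fR = -fb_k * (R - fb_r);
          fx[i] += fR * x[i] / R;
          fy[i] += fR * y[i] / R;
        }
      }
    }
    // screened-Coulomb pair forces, minimum image, capped below r_cap
    if (coul_pref != 0.0) {
      for (int i = 0; i < n_ions - 1; ++i) {
        for (int j = i + 1; j < n_ions; ++j) {
          double dx = min_image(x[i] - x[j], Lx);
          double dy = min_image(y[i] - y[j], Ly);
          double dz = min_image(z[i] - z[j], Lz);
          double r2 = dx * dx + dy * dy + dz * dz;
          double r = std::sqrt(r2);
          if (r < 1e-6) continue; // coincident: no defined direction
          const double re = (r < r_cap) ? r_cap : r;
          const double pref = coul_pref * q[i] * q[j];
          const double fmag = pref * std::exp(-re / lambda_d)
                              * (1.0 / (re * re) + 1.0 / (re * lambda_d));
          const double s = fmag / r;
          fx[i] += s * dx; fy[i] += s * dy; fz[i] += s * dz;
          fx[j] -= s * dx; fy[j] -= s * dy; fz[j] -= s * dz;
        }
      }
    }
    // --- Euler-Maruyama update + periodic wrap ---
    for (int i = 0; i < n_ions; ++i) {
      const double mob = D[i] / kT * dt;
      const double sig = std::sqrt(2.0 * D[i] * dt);
      const double ddx = mob * fx[i] + sig * R::norm_rand();
      const double ddy = mob * fy[i] + sig * R::norm_rand();
      const double ddz = mob * fz[i] + sig * R::norm_rand();
      if (std::fabs(ddx) > max_disp || std::fabs(ddy) > max_disp ||
          std::fabs(ddz) > max_disp) {
        stop("BD integration unstable at step %d, ion %d: displacement "
             "exceeds 5 A in one step; reduce dt", step, i + 1);
      }
      x[i] += ddx; y[i] += ddy; z[i] += ddz;
      if (x[i] >= Lx / 2) x[i] -= Lx; else if (x[i] < -Lx / 2) x[i] += Lx;
      if (y[i] >= Ly / 2) y[i] -= Ly; else if (y[i] < -Ly / 2) y[i] += Ly;
      if (z[i] >= Lz / 2) { z[i] -= Lz; up_cross[i]++; }
      else if (z[i] < -Lz / 2) { z[i] += Lz; down_cross[i]++; }
    }
    if (step % stride == 0 && next_frame < n_frames) {
      record(next_frame);
      ++next_frame;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["frames"] = frames,
    _["down_cross"] = IntegerVector(down_cross.begin(), down_cross.end()),
    _["up_cross"] = IntegerVector(up_cross.begin(), up_cross.end()));
}
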