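geom0 <- channel_geometry(z_top = 15, z_bottom = -15)

test_that("R-z density normalizes exactly and localizes point masses", {
  # single ion fixed at (R0, z0): all mass in one bin, integral 1
  pos <- array(rep(c(2.2, 0, 3.3), each = 10), c(10, 1, 3))
  tr <- ion_trajectory((0:9) * 0.1, c(30, 30, 70), pos,
                       data.frame(ion_id = 1L, species = "Na"),
                       species_table_default())
  m <- density_rz(tr, geom0, R_edges = seq(0, 6, 0.5), z_edges = seq(-5, 5, 0.5))
  expect_equal(sum(m$counts > 0), 1L)
  expect_equal(sum(m$rho * m$bin_volume), 1, tolerance = 1e-12)
  expect_equal(m$n_overflow, 0L)

  # full-coverage normalization on random clouds (exact invariant)
  set.seed(21)
  for (rep in 1:5) {
    tr <- random_walk_traj(60, 3)
    m <- density_rz(tr, geom0, R_edges = seq(0, 40, 1),
                    z_edges = seq(-35, 35, 1))
    expect_equal(m$n_overflow, 0L)
    expect_equal(sum(m$rho * m$bin_volume), 1, tolerance = 1e-9)
    expect_true(all(m$rho >= 0))
  }
})

test_that("uniform cylinder cloud recovers constant density within 3 SE", {
  set.seed(31)
  n <- 20000L
  Rmax <- 6; L <- 20
  Rv <- Rmax * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  pos <- array(0, c(n, 1, 3))
  pos[, 1, 1] <- Rv * cos(th)
  pos[, 1, 2] <- Rv * sin(th)
  pos[, 1, 3] <- stats::runif(n, -L / 2, L / 2)
  tr <- ion_trajectory((seq_len(n) - 1) * 1e-3, c(30, 30, 70), pos,
                       data.frame(ion_id = 1L, species = "Na"),
                       species_table_default())
  m <- density_rz(tr, geom0, R_edges = seq(0, Rmax, 1),
                  z_edges = seq(-L / 2, L / 2, 2.5))
  rho_true <- 1 / (pi * Rmax^2 * L)
  # per-bin Poisson 3-SE band around the analytic uniform density
  exp_counts <- rho_true * m$bin_volume * n
  dev <- abs(m$counts - exp_counts) / sqrt(exp_counts)
  expect_lt(mean(dev > 3), 0.02)          # ~binomial(0.003) allowance
  expect_equal(sum(m$rho * m$bin_volume), 1, tolerance = 1e-9)
})

test_that("cylindrical estimator equals the collapsed Cartesian histogram", {
  set.seed(32)
  tr <- random_walk_traj(80, 2)
  R_edges <- seq(0, 40, 2)
  z_edges <- seq(-35, 35, 2)
  m <- density_rz(tr, geom0, R_edges, z_edges)
  # direct 2-D histogram of (R, z) with the same Jacobian division
  R <- sqrt(as.vector(tr$pos[, , 1])^2 + as.vector(tr$pos[, , 2])^2)
  z <- as.vector(tr$pos[, , 3])
  iR <- findInterval(R, R_edges)
  iz <- findInterval(z, z_edges)
  cnt <- matrix(0, length(R_edges) - 1, length(z_edges) - 1)
  for (s in seq_along(R)) cnt[iR[s], iz[s]] <- cnt[iR[s], iz[s]] + 1
  vol <- outer(pi * (R_edges[-1]^2 - R_edges[-length(R_edges)]^2),
               diff(z_edges))
  rho_ref <- cnt / (vol * 2 * 80)
  expect_equal(m$rho, rho_ref, tolerance = 1e-12)
})

test_that("axial density marginalizes the on-axis cylinder correctly", {
  # all samples on-axis at z = 0: single-bin spike
  tr <- traj_from_z(matrix(0, 20, 1))
  p <- axial_density(tr, geom0, z_edges = seq(-5, 5, 1))
  expect_equal(sum(p$density > 0), 1L)
  expect_equal(sum(p$density * diff(seq(-5, 5, 1))), 1)

  # uniform in z: flat within 3 SE per bin
  set.seed(33)
  n <- 30000L
  z <- matrix(stats::runif(n, -10, 10), ncol = 1)
  tr <- traj_from_z(z, dt = 1e-3)
  p <- axial_density(tr, geom0, z_edges = seq(-10, 10, 2))
  expect_equal(sum(p$counts), n)
  exp_per_bin <- n / 10
  expect_true(all(abs(p$counts - exp_per_bin) < 3 * sqrt(exp_per_bin) + 1))

  # equals the r-selected z histogram computed by hand
  set.seed(34)
  tr <- random_walk_traj(100, 2)
  z_edges <- seq(-35, 35, 1)
  p <- axial_density(tr, geom0, z_edges, r_select = 3)
  R <- sqrt(as.vector(tr$pos[, , 1])^2 + as.vector(tr$pos[, , 2])^2)
  zz <- as.vector(tr$pos[, , 3])[R < 3]
  cnt <- tabulate(findInterval(zz, z_edges), nbins = length(z_edges) - 1)
  expect_equal(p$counts, cnt)
  expect_equal(p$density, cnt / (sum(cnt) * diff(z_edges)))

  # empty selection warns
  far <- traj_from_z(matrix(0, 5, 1), x = matrix(20, 5, 1))
  expect_warning(axial_density(far, geom0, seq(-5, 5, 1)), "empty")
})

test_that("density differences are linear and grid-checked", {
  set.seed(35)
  tr1 <- random_walk_traj(50, 2)
  tr2 <- random_walk_traj(50, 2)
  R_edges <- seq(0, 40, 2); z_edges <- seq(-35, 35, 2)
  m1 <- density_rz(tr1, geom0, R_edges, z_edges)
  m2 <- density_rz(tr2, geom0, R_edges, z_edges)
  d <- density_difference(m1, m2)
  expect_equal(d$rho, m1$rho - m2$rho)
  # map minus itself is identically zero
  expect_true(all(density_difference(m1, m1)$rho == 0))
  # both normalized on the same support: difference integrates to ~0
  expect_equal(sum(d$rho * m1$bin_volume), 0, tolerance = 1e-9)
  m3 <- density_rz(tr2, geom0, seq(0, 40, 4), z_edges)
  expect_error(density_difference(m1, m3), "mismatch")
})

test_that("3-D grids conserve counts and round-trip through OpenDX", {
  # one ion fixed inside one voxel
  pos <- array(rep(c(1.2, 2.2, 3.2), each = 8), c(8, 1, 3))
  tr <- ion_trajectory((0:7) * 0.1, c(30, 30, 70), pos,
                       data.frame(ion_id = 1L, species = "Na"),
                       species_table_default())
  g <- density_grid3d(tr, origin = c(0, 0, 0), spacing = 1, dims = c(5, 5, 5))
  expect_equal(sum(g$values > 0), 1L)
  expect_equal(g$values[2, 3, 4], 1)      # 1 / voxel volume, always present
  # grid integral equals mean in-grid ion count per frame
  set.seed(36)
  tr <- random_walk_traj(40, 3)
  g <- density_grid3d(tr, origin = c(-15, -15, -35), spacing = 2.5,
                      dims = c(12, 12, 28))
  in_grid <- mean(vapply(seq_along(tr$times), function(f) {
    p <- tr$pos[f, , , drop = FALSE]
    sum(p[1, , 1] >= -15 & p[1, , 1] < 15 &
        p[1, , 2] >= -15 & p[1, , 2] < 15 &
        p[1, , 3] >= -35 & p[1, , 3] < 35)
  }, 0))
  expect_equal(sum(g$values) * 2.5^3, in_grid, tolerance = 1e-6)
  # DX round-trip to printed precision
  path <- tempfile(fileext = ".dx")
  export_dx(g, path)
  back <- read_dx(path)
  expect_equal(back$dims, g$dims)
  expect_equal(back$origin, g$origin, tolerance = 1e-6)
  expect_equal(back$values, g$values, tolerance = 1e-5)
  expect_error(density_grid3d(tr, c(0, 0, 0), 1, c(0, 5, 5)), "zero-extent")
})

test_that("convergence blocks flag drifting density and pass stationary runs", {
  # stationary BD run in a single well: window profiles agree
  sys <- single_well_system(depth = 8, width = 2)
  run <- simulate_bd(sys, n_steps = 4e5, stride = 20, seed = 9,
                     init = matrix(c(0, 0, 0), 1))
  tr <- run$traj
  span <- range(tr$times)
  wins <- list(c(0, 2), c(1, 3), c(2, 4))
  cb <- convergence_blocks(tr, geom0, z_edges = seq(-10, 10, 1),
                           windows = wins, r_select = 30)
  expect_equal(length(cb$profiles), 3L)
  expect_lt(cb$max_discrepancy, 0.08)
  # identical windows give identical profiles and zero discrepancy
  cb2 <- convergence_blocks(tr, geom0, seq(-10, 10, 1),
                            list(c(0, 2), c(0, 2)), r_select = 30)
  expect_equal(cb2$max_discrepancy, 0)
  # constructed non-stationary fixture: ion teleported mid-run
  z <- c(rep(-5, 300), rep(5, 300)) + stats::rnorm(600, 0, 0.3)
  trd <- traj_from_z(matrix(z, ncol = 1), dt = 0.01)
  cbd <- convergence_blocks(trd, geom0, seq(-10, 10, 1),
                            list(c(0, 2.9), c(3, 5.9)), r_select = 30)
  expect_gt(cbd$max_discrepancy, 0.5)
  expect_error(convergence_blocks(tr, geom0, seq(-10, 10, 1),
                                  list(c(100, 101))), "empty window")
})
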