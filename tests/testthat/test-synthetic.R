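test_that("presets encode the documented channel architectures", {
  sys6 <- bd_preset("trpv6_like")
  labs <- vapply(sys6$wells, function(w) w$label, "")
  expect_setequal(labs, c("S1", "S2", "P"))
  zc <- vapply(sys6$wells, function(w) w$z_center, 0)
  expect_equal(abs(zc[labs == "S1"] - zc[labs == "S2"]), 11)  # site separation
  p <- sys6$wells[[which(labs == "P")]]
  expect_gt(p$r_center, 0)                                    # peripheral
  # divalent species bind the S sites more strongly; P is unselective
  for (w in sys6$wells) {
    if (w$label %in% c("S1", "S2")) expect_lt(w$scale[["Na"]], w$scale[["Ca"]])
    else expect_null(w$scale)
  }
  expect_equal(sys6$conditions$temperature, 310)
  expect_equal(sys6$conditions$voltage, 500)
  expect_equal(sys6$conditions$field, 500 / sys6$box[3])

  sys1 <- bd_preset("trpv1_like")
  expect_equal(length(sys1$wells), 1L)                        # one site only

  sysf <- bd_preset("free")
  expect_equal(length(sysf$wells), 0L)
  expect_equal(sysf$k_conf, 0)
  expect_error(bd_preset("nope"))
})

test_that("system invariants are enforced", {
  na <- ion_species("Na", 1, diffusion = 133)
  cond <- simulation_conditions(voltage = 0, temperature = 310, Lz = 70)
  mk <- function(dt, depth = 5, z0 = 0) {
    bd_system(species = list(list(species = na, count = 1L)),
              box = c(30, 30, 70),
              pore = list(z_bottom = -15, z_top = 15, radius = 5),
              wells = list(list(label = "W", z_center = z0, depth = depth,
                                width = 1.0)),
              conditions = cond, dt = dt)
  }
  expect_error(mk(dt = 1e-3), "stability")
  expect_error(mk(dt = 1e-5, depth = -2), "depth")
  expect_error(mk(dt = 1e-5, z0 = 50), "outside the box")
  expect_s3_class(mk(dt = 1e-5), "bd_system")
})

test_that("the same seed reproduces a trajectory bit-exactly", {
  sys <- bd_preset("trpv6_like", n_ca = 2, n_na = 2)
  r1 <- simulate_bd(sys, n_steps = 5000, stride = 50, seed = 77)
  r2 <- simulate_bd(sys, n_steps = 5000, stride = 50, seed = 77)
  expect_identical(r1$traj$pos, r2$traj$pos)
  expect_identical(r1$log$per_ion, r2$log$per_ion)
  r3 <- simulate_bd(sys, n_steps = 5000, stride = 50, seed = 78)
  expect_false(identical(r1$traj$pos, r3$traj$pos))
})

test_that("compiled forces agree with the exposed potential surface", {
  # paired-seed construction: two single-step runs from the same seed
  # share their Gaussian draws, so the displacement difference between
  # the interacting system and a free copy is exactly mob * F(p) * dt.
  # Compare against the numerical gradient of bd_potential.
  sys <- bd_preset("trpv6_like", n_ca = 1, n_na = 0)
  free <- sys
  free$wells <- list()
  free$k_conf <- 0
  free$conditions <- simulation_conditions(voltage = 0, temperature = 310,
                                           Lz = sys$box[3])
  kT <- sys$conditions$kT
  D <- 79
  mob_dt <- D / kT * sys$dt
  pts <- rbind(c(0.5, 0.3, 7.2), c(1.5, -1, -3.8), c(3.9, 0.4, 10.1),
               c(0.2, 0.1, 12.5), c(5.4, 0.8, 0), c(6.2, 0.5, -9))
  h <- 1e-5
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    init <- matrix(p, 1)
    d_int <- simulate_bd(sys, n_steps = 1, stride = 1, seed = 99,
                         init = init)$traj$pos[2, 1, ]
    d_free <- simulate_bd(free, n_steps = 1, stride = 1, seed = 99,
                          init = init)$traj$pos[2, 1, ]
    f_step <- (d_int - d_free) / mob_dt
    gnum <- vapply(1:3, function(d) {
      e <- c(0, 0, 0); e[d] <- h
      (bd_potential(sys, "Ca", p[1] + e[1], p[2] + e[2], p[3] + e[3]) -
       bd_potential(sys, "Ca", p[1] - e[1], p[2] - e[2], p[3] - e[3])) / (2 * h)
    }, 0)
    expect_equal(f_step, -gnum, tolerance = 1e-4)
  }
  # well minima along the axis sit at the advertised centers
  zg <- seq(-14, 14, 0.01)
  U <- bd_potential(sys, "Ca", 0, 0, zg) -
       2 * sys$conditions$field * 0.0964853321233 * zg  # remove field tilt
  for (w in sys$wells[1:2]) {
    local_min <- zg[which.min(ifelse(abs(zg - w$z_center) < 2, U, Inf))]
    expect_lt(abs(local_min - w$z_center), 0.05)
  }
})


test_that("free diffusion satisfies the Einstein relation within 3 SE", {
  sys <- bd_preset("free")
  D <- 133
  n_rep <- 250L
  slopes <- vapply(seq_len(n_rep), function(s) {
    run <- simulate_bd(sys, n_steps = 1500, stride = 10, seed = 1000 + s)
    tr <- unwrap_axial(run$traj)
    z <- tr$pos[, 1, 3]
    dt <- tr$times[2] - tr$times[1]
    mean(diff(z)^2) / dt          # per-replica MSD slope estimate
  }, 0)
  se <- stats::sd(slopes) / sqrt(n_rep)
  expect_lt(abs(mean(slopes) - 2 * D), 3 * se)
})

test_that("drift under a field matches mobility * force within 3 SE", {
  sys <- bd_preset("free", voltage = 500)
  D <- 133
  kT <- 0.0083144626 * 310
  f_z <- -1 * (500 / 70) * 0.0964853321233    # q E, kJ/mol/A, downward
  v_expect <- D * f_z / kT
  n_rep <- 250L
  vels <- vapply(seq_len(n_rep), function(s) {
    run <- simulate_bd(sys, n_steps = 3000, stride = 30, seed = 2000 + s)
    tr <- unwrap_axial(run$traj)
    z <- tr$pos[, 1, 3]
    (z[length(z)] - z[1]) / (tr$times[length(z)] - tr$times[1])
  }, 0)
  se <- stats::sd(vels) / sqrt(n_rep)
  expect_lt(abs(mean(vels) - v_expect), 3 * se)
})

test_that("single-well residence matches the Boltzmann ratio within 3 SE", {
  kT <- 0.0083144626 * 310
  depth <- 4 * kT
  width <- 1.5
  sys <- single_well_system(depth = depth, width = width)
  Ufun <- function(z) -depth * exp(-z^2 / (2 * width^2))
  frac_exp <- boltzmann_fraction(Ufun, -3, 3, Lz = 70)
  n_rep <- 10L
  fracs <- vapply(seq_len(n_rep), function(s) {
    run <- simulate_bd(sys, n_steps = 5e5, stride = 25, seed = 3000 + s)
    z <- run$traj$pos[, 1, 3]
    mean(z >= -3 & z < 3)
  }, 0)
  se <- stats::sd(fracs) / sqrt(n_rep)
  expect_lt(abs(mean(fracs) - frac_exp), 3 * se)
})

test_that("zero-field axial density obeys detailed balance (chi-squared)", {
  kT <- 0.0083144626 * 310
  depth <- 2 * kT
  sys <- single_well_system(depth = depth, width = 2, D = 400)
  run <- simulate_bd(sys, n_steps = 2e7, stride = 1000, seed = 5)
  z <- run$traj$pos[, 1, 3]
  edges <- seq(-35, 35, 10)
  Ufun <- function(zz) -depth * exp(-zz^2 / (2 * 4))
  probs <- vapply(seq_len(length(edges) - 1), function(b)
    stats::integrate(function(zz) exp(-Ufun(zz) / kT), edges[b],
                     edges[b + 1])$value, 0)
  probs <- probs / sum(probs)
  # thin to approximately independent samples: frames are 0.01 ns apart
  # and box-scale relaxation is ~(Lz/2)^2 / 2D ~ 1.5 ns -> keep every
  # 2 ns (one sample per 200 frames)
  keep <- seq(1, length(z), by = 200)
  obs_t <- tabulate(findInterval(z[keep], edges), nbins = length(edges) - 1)
  pval <- stats::chisq.test(obs_t, p = probs)$p.value
  expect_gt(pval, 0.01)
})

test_that("ion-ion repulsion suppresses same-well co-occupancy", {
  # two divalent ions confined to a two-well tube (pore spanning the
  # box, zero field) vs two independent single-ion runs: joint same-well
  # occupancy < product of the single-ion marginals
  tube <- function(n) {
    sp <- ion_species("X", 2L, diffusion = 150)
    cond <- simulation_conditions(voltage = 0, temperature = 310, Lz = 70)
    bd_system(species = list(list(species = sp, count = n)),
              box = c(20, 20, 70),
              pore = list(z_bottom = -30, z_top = 30, radius = 4),
              wells = list(list(label = "S1", z_center = 7, depth = 10,
                                width = 1.5, r_center = 0, r_width = 2),
                           list(label = "S2", z_center = -4, depth = 10,
                                width = 1.5, r_center = 0, r_width = 2)),
              conditions = cond, k_conf = 20, dt = 1e-5)
  }
  in_s2 <- function(run, i) {
    z <- run$traj$pos[, i, 3]
    R <- sqrt(run$traj$pos[, i, 1]^2 + run$traj$pos[, i, 2]^2)
    abs(z - (-4)) < 2 & R < 3
  }
  # well exchange is slow; pool several independent single-ion runs for
  # a stable marginal
  p_single <- mean(vapply(61:64, function(sd) {
    r <- simulate_bd(tube(1), n_steps = 8e6, stride = 200, seed = sd,
                     init = matrix(c(0, 0, 0), 1))
    mean(in_s2(r, 1))
  }, 0))
  expect_gt(p_single, 0.03)
  r_j <- simulate_bd(tube(2), n_steps = 8e6, stride = 200, seed = 70,
                     init = rbind(c(0, 0, 0), c(0, 0, 10)))
  p_both <- mean(in_s2(r_j, 1) & in_s2(r_j, 2))
  expect_lt(p_both, p_single^2)
})

test_that("instability is detected and aborted with a diagnostic", {
  na <- ion_species("Na", 1, diffusion = 133)
  cond <- simulation_conditions(voltage = 0, temperature = 310, Lz = 70)
  sys <- bd_system(species = list(list(species = na, count = 2L)),
                   box = c(30, 30, 70),
                   pore = list(z_bottom = -15, z_top = 15, radius = 5),
                   wells = list(), conditions = cond, k_conf = 0,
                   r_cap = 1e-4, lambda_d = 50, eps_scale = 1e-4, dt = 1e-5)
  init <- rbind(c(0, 0, 0), c(0.02, 0, 0))   # near-contact, huge repulsion
  expect_error(simulate_bd(sys, n_steps = 100, seed = 1, init = init),
               "unstable")
})
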