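# Shared fixture builders and independent oracles for the suite.

.kB_t <- 0.0083144626

species_table_default <- function() {
  list(Ca = ion_species("Ca", 2, diffusion = 79),
       Na = ion_species("Na", 1, diffusion = 133))
}

# Build a trajectory from an [n_frames, n_ions] matrix of z (x, y optional)
traj_from_z <- function(z, box = c(30, 30, 70), species = "Na",
                        x = NULL, y = NULL, dt = 0.01) {
  z <- as.matrix(z)
  n_f <- nrow(z); n_i <- ncol(z)
  pos <- array(0, c(n_f, n_i, 3))
  if (!is.null(x)) pos[, , 1] <- x
  if (!is.null(y)) pos[, , 2] <- y
  pos[, , 3] <- z
  species <- rep_len(species, n_i)
  ion_trajectory(times = (seq_len(n_f) - 1) * dt, box = box, pos = pos,
                 ions = data.frame(ion_id = seq_len(n_i), species = species),
                 species_table = species_table_default())
}

# Random-walk fixture: continuous walks wrapped into the box, with
# optional lateral wandering so the gate-cylinder condition gets exercised.
random_walk_traj <- function(n_frames, n_ions, box = c(30, 30, 70),
                             step_sd = 2, lateral_sd = 0.8,
                             start_spread = TRUE) {
  zc <- matrix(0, n_frames, n_ions)
  xc <- matrix(0, n_frames, n_ions)
  yc <- matrix(0, n_frames, n_ions)
  lateral_ou <- function() {
    x <- numeric(n_frames)
    x[1] <- stats::runif(1, -4, 4)
    for (f in 2:n_frames)
      x[f] <- 0.95 * x[f - 1] + stats::rnorm(1, 0, lateral_sd)
    x
  }
  for (i in seq_len(n_ions)) {
    z0 <- if (start_spread) stats::runif(1, -box[3] / 2, box[3] / 2) else 20
    zc[, i] <- z0 + cumsum(c(0, stats::rnorm(n_frames - 1, 0, step_sd)))
    xc[, i] <- lateral_ou()
    yc[, i] <- lateral_ou()
  }
  # wrap z into [-Lz/2, Lz/2)
  zw <- zc - box[3] * floor((zc + box[3] / 2) / box[3])
  traj_from_z(zw, box = box, x = xc, y = yc)
}

# Independent brute-force event scan: run-length analysis over "levels".
# Level 2k = pore interval of periodic cell k, level 2k+1 = the bulk slab
# above it. A down event is a pore run entered from the slab above and
# left to the slab below with every in-run frame inside the gate
# cylinder; up events mirror it. Structurally different from the
# package's per-frame state machine.
oracle_events <- function(traj, geom) {
  tu <- unwrap_axial(traj)
  cc <- cylindrical_coords(tu, geom)
  Lz <- traj$box[3]
  out <- list()
  for (i in seq_len(nrow(traj$ions))) {
    zu <- cc$z[, i]; R <- cc$R[, i]
    cell <- floor((zu - geom$z_bottom) / Lz)
    phase <- zu - cell * Lz
    level <- 2L * cell + as.integer(phase >= geom$z_top)
    r <- rle(level)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    if (length(r$values) < 3L) next
    for (j in 2:(length(r$values) - 1L)) {
      lv <- r$values[j]
      if (lv %% 2L != 0L) next            # not a pore run
      prev <- r$values[j - 1L]
      nxt <- r$values[j + 1L]
      if (any(R[starts[j]:ends[j]] >= geom$gate_radius)) next
      if (prev == lv + 1L && nxt == lv - 1L) {
        out[[length(out) + 1L]] <- data.frame(
          ion_id = traj$ions$ion_id[i], species = traj$ions$species[i],
          frame_enter = starts[j] - 1L, frame_exit = ends[j] + 1L,
          direction = "down")
      } else if (prev == lv - 1L && nxt == lv + 1L) {
        out[[length(out) + 1L]] <- data.frame(
          ion_id = traj$ions$ion_id[i], species = traj$ions$species[i],
          frame_enter = starts[j] - 1L, frame_exit = ends[j] + 1L,
          direction = "up")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ion_id = integer(), species = character(),
                      frame_enter = integer(), frame_exit = integer(),
                      direction = character()))
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$frame_exit, ev$ion_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Boltzmann fraction of a 1-D axial potential over a periodic box, by
# numerical quadrature.
boltzmann_fraction <- function(Ufun, z_lo, z_hi, Lz, temperature = 310) {
  kT <- .kB_t * temperature
  num <- stats::integrate(function(z) exp(-Ufun(z) / kT), z_lo, z_hi,
                          subdivisions = 2000L, rel.tol = 1e-10)$value
  den <- stats::integrate(function(z) exp(-Ufun(z) / kT), -Lz / 2, Lz / 2,
                          subdivisions = 2000L, rel.tol = 1e-10)$value
  num / den
}

# A single-well test system on a flat landscape (no confinement, no
# field): U depends on z only, so 1-D quadrature is exact.
single_well_system <- function(depth, width = 1.5, z0 = 0, voltage = 0,
                               D = 79, seed = 1L) {
  sp <- ion_species("X", 2L, diffusion = D)
  cond <- simulation_conditions(voltage = voltage, temperature = 310, Lz = 70)
  bd_system(species = list(list(species = sp, count = 1L)),
            box = c(30, 30, 70),
            pore = list(z_bottom = -15, z_top = 15, radius = 5),
            wells = list(list(label = "W", z_center = z0, depth = depth,
                              width = width)),
            conditions = cond, k_conf = 0, dt = 1e-5, seed = seed)
}
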