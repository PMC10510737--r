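#' Parameterize a Brownian-dynamics model channel
#'
#' Full specification of the overdamped-Langevin synthetic channel: ion
#' species with counts, a periodic box, a membrane-spanning pore with
#' smooth flat-bottom radial confinement, axial Gaussian binding wells
#' (optionally off-axis, with per-species depth scale factors), an applied
#' transmembrane field, and screened-Coulomb ion-ion repulsion. The bulk
#' slabs above and below the pore have no confinement and act as
#' reservoirs; z-periodicity recycles permeated ions so concentration
#' stays stationary.
#'
#' @param species List of entries \code{list(species = ion_species, count = n)}.
#' @param box Numeric length-3 box (Lx, Ly, Lz) in A; coordinates live in
#'   \code{[-L/2, L/2)}.
#' @param pore List with \code{z_bottom}, \code{z_top}, \code{radius} (A).
#' @param wells List of wells, each \code{list(label, z_center, depth,
#'   width, r_center = 0, r_width = 1, scale = c(...))}; \code{depth} in
#'   kJ/mol (>= 0), \code{width} the axial Gaussian sigma in A,
#'   \code{r_center > 0} makes the well an off-axis annulus with radial
#'   Gaussian sigma \code{r_width}, and \code{scale} an optional named
#'   per-species multiplier on the depth (selectivity).
#' @param conditions A \code{\link{simulation_conditions}}.
#' @param k_conf Radial confinement constant inside the pore slab,
#'   kJ/mol/A^2 (0 disables the wall).
#' @param lambda_d Debye screening length for ion-ion repulsion (A).
#' @param eps_scale Dielectric scale dividing the vacuum Coulomb prefactor
#'   (default 80, water-like).
#' @param r_cap Pair distance below which the repulsive force is clamped
#'   to its value at \code{r_cap} (avoids singularities; default 2 A).
#' @param edge_a Smoothing length (A) of the confinement window at the
#'   pore mouths.
#' @param dt Integration time step in ns. Must satisfy the stability rule
#'   \code{dt <= 0.01 * min(width^2) / max(D)}.
#' @param seed Default RNG seed for \code{\link{simulate_bd}}.
#' @return Object of class \code{bd_system}.
#' @export
bd_system <- function(species, box, pore, wells = list(),
                      conditions, k_conf = 20, lambda_d = 8,
                      eps_scale = 80, r_cap = 2, edge_a = 1,
                      dt = 1e-5, seed = 1L) {
  stopifnot(is.list(species), length(species) >= 1L,
            inherits(conditions, "simulation_conditions"))
  box <- as.numeric(box)
  if (dt <= 0) stop("dt must be positive")
  if (lambda_d <= 0) stop("lambda_d must be positive")
  Dmax <- max(vapply(species, function(s) s$species$diffusion, 0))
  if (length(wells)) {
    widths <- unlist(lapply(wells, function(w)
      c(w$width, if (!is.null(w$r_width) && w$r_width > 0) w$r_width)))
    if (dt > 0.01 * min(widths^2) / Dmax)
      stop(sprintf("dt violates the stability rule dt <= 0.01*min(width^2)/max(D) = %.3g ns",
                   0.01 * min(widths^2) / Dmax))
    for (w in wells) {
      if (w$depth < 0) stop("well depths must be >= 0")
      if (abs(w$z_center) > box[3] / 2)
        stop("well center outside the box")
    }
  }
  structure(list(species = species, box = box, pore = pore, wells = wells,
                 conditions = conditions, k_conf = k_conf,
                 lambda_d = lambda_d, eps_scale = eps_scale,
                 r_cap = r_cap, edge_a = edge_a, dt = dt,
                 seed = as.integer(seed)),
            class = "bd_system")
}

#' @export
print.bd_system <- function(x, ...) {
  n <- sum(vapply(x$species, function(s) s$count, 0L))
  cat(sprintf("bd_system: %d ions, box %.0fx%.0fx%.0f A, pore z [%.1f, %.1f] r %.1f A\n",
              n, x$box[1], x$box[2], x$box[3],
              x$pore$z_bottom, x$pore$z_top, x$pore$radius))
  cat(sprintf("  %d wells, %g mV, %g K, dt %g ns\n", length(x$wells),
              x$conditions$voltage, x$conditions$temperature, x$dt))
  invisible(x)
}

# expand per-ion species info: data.frame(ion_id, species, D, q)
.bd_ions <- function(system) {
  rows <- lapply(system$species, function(s)
    data.frame(species = rep(s$species$name, s$count),
               D = s$species$diffusion, q = s$species$valence))
  out <- do.call(rbind, rows)
  out$ion_id <- seq_len(nrow(out))
  out[, c("ion_id", "species", "D", "q")]
}

.bd_species_table <- function(system) {
  st <- lapply(system$species, function(s) s$species)
  names(st) <- vapply(st, function(s) s$name, "")
  st
}

# effective depth matrix (n_wells x n_ions) applying selectivity scales
.bd_well_depths <- function(system, ions) {
  n_w <- length(system$wells)
  m <- matrix(0, nrow = max(n_w, 1L), ncol = nrow(ions))
  if (n_w == 0L) return(m[0, , drop = FALSE])
  for (w in seq_len(n_w)) {
    well <- system$wells[[w]]
    sc <- rep(1, nrow(ions))
    if (!is.null(well$scale)) {
      hit <- match(ions$species, names(well$scale))
      sc[!is.na(hit)] <- well$scale[hit[!is.na(hit)]]
    }
    m[w, ] <- well$depth * sc
  }
  m[seq_len(n_w), , drop = FALSE]
}

#' Channel presets for the synthetic channel
#'
#' \code{"trpv6_like"}: two on-axis binding wells S1 and S2 in the
#' selectivity filter separated by 11 A, plus a peripheral off-axis well P
#' at the filter entrance; divalent (Ca-type) ions see deeper S wells than
#' monovalent (Na-type) ions, while P binds both equally.
#' \code{"trpv1_like"}: a single on-axis binding well in the filter.
#' \code{"free"}: no wells and no confinement, zero field; used for
#' drift/diffusion oracles. Defaults are 310 K and a 500 mV transmembrane
#' potential (field = voltage / Lz) for the channel presets.
#'
#' @param name One of \code{"trpv6_like"}, \code{"trpv1_like"},
#'   \code{"free"}.
#' @param n_ca,n_na Ion counts for the divalent and monovalent species.
#' @param voltage Transmembrane voltage in mV (overrides the preset
#'   default).
#' @param seed Default seed stored in the system.
#' @return A \code{\link{bd_system}}.
#' @examples
#' sys <- bd_preset("trpv6_like")
#' vapply(sys$wells, function(w) w$label, "")
#' @export
bd_preset <- function(name = c("trpv6_like", "trpv1_like", "free"),
                      n_ca = 4L, n_na = 4L, voltage = NULL, seed = 1L) {
  name <- match.arg(name)
  ca <- ion_species("Ca", 2L, diffusion = 79, radius = 1.00)
  na <- ion_species("Na", 1L, diffusion = 133, radius = 0.95)
  box <- c(30, 30, 70)
  if (name == "free") {
    cond <- simulation_conditions(voltage = if (is.null(voltage)) 0 else voltage,
                                  temperature = 310, Lz = box[3])
    return(bd_system(species = list(list(species = na, count = max(n_na, 1L))),
                     box = box,
                     pore = list(z_bottom = -15, z_top = 15, radius = 5),
                     wells = list(), conditions = cond, k_conf = 0,
                     eps_scale = 80, dt = 1e-5, seed = seed))
  }
  cond <- simulation_conditions(voltage = if (is.null(voltage)) 500 else voltage,
                                temperature = 310, Lz = box[3])
  sel <- c(Ca = 1, Na = 0.5)
  wells <- if (name == "trpv6_like") {
    list(
      list(label = "S1", z_center = 7,  depth = 14, width = 1.5,
           r_center = 0, r_width = 2.0, scale = sel),
      list(label = "S2", z_center = -4, depth = 16, width = 1.5,
           r_center = 0, r_width = 2.0, scale = sel),
      list(label = "P",  z_center = 10, depth = 8,  width = 1.5,
           r_center = 4, r_width = 1.0)
    )
  } else {
    list(list(label = "S", z_center = 6, depth = 12, width = 1.8,
              r_center = 0, r_width = 2.5, scale = sel))
  }
  species <- list()
  if (n_ca > 0) species <- c(species, list(list(species = ca, count = as.integer(n_ca))))
  if (n_na > 0) species <- c(species, list(list(species = na, count = as.integer(n_na))))
  bd_system(species = species, box = box,
            pore = list(z_bottom = -15, z_top = 15,
                        radius = if (name == "trpv6_like") 5 else 6),
            wells = wells, conditions = cond, k_conf = 20,
            lambda_d = 8, eps_scale = 80, dt = 1e-5, seed = seed)
}

#' Channel geometry matching a BD system
#'
#' @param system A \code{\link{bd_system}}.
#' @param gate_radius Gate cylinder radius (A); default 8.
#' @param inset Axial inset (A) of the analysis boundaries relative to the
#'   physical pore span. The confinement wall ramps on smoothly at the
#'   pore mouths, so ions there can still sit outside the gate cylinder;
#'   placing the analysis boundaries \code{inset} A inside the pore (where
#'   the wall is fully engaged) keeps the gate-cylinder condition
#'   meaningful. Default 2.
#' @return A \code{\link{channel_geometry}} whose pore boundaries match the
#'   system and whose \code{SF} region spans the binding wells (when any).
#' @export
bd_geometry <- function(system, gate_radius = 8, inset = 2) {
  regions <- list()
  if (length(system$wells)) {
    zc <- vapply(system$wells, function(w) w$z_center, 0)
    regions$SF <- c(min(zc) - 2.5, max(zc) + 2.5, 0, gate_radius)
  }
  channel_geometry(z_top = system$pore$z_top - inset,
                   z_bottom = system$pore$z_bottom + inset,
                   gate_radius = gate_radius, regions = regions)
}

#' Binding-site definitions matching a BD preset
#'
#' Axial interval x radial annulus per well: on-axis wells get a disc of
#' radius 2.5 A around their center, the peripheral well an annulus
#' covering its radial shell, and a \code{cavity} site spans the pore
#' below the lowest well (the sink region for transition statistics).
#'
#' @param system A \code{\link{bd_system}} with at least one well.
#' @return List of \code{\link{binding_site}} definitions.
#' @export
bd_sites <- function(system) {
  if (!length(system$wells)) stop("system has no wells")
  sites <- list()
  z_lowest <- Inf
  for (w in system$wells) {
    on_axis <- is.null(w$r_center) || w$r_center == 0
    if (on_axis) {
      sites[[w$label]] <- binding_site(w$label, w$z_center - 1.5,
                                       w$z_center + 1.5, 0, 2.5)
      z_lowest <- min(z_lowest, w$z_center - 1.5)
    } else {
      sites[[w$label]] <- binding_site(w$label, w$z_center - 1.5,
                                       w$z_center + 1.5,
                                       2.5, w$r_center + 1.5)
    }
  }
  sites$cavity <- binding_site("cavity", system$pore$z_bottom, z_lowest,
                               0, system$pore$radius + 1)
  sites
}

#' Single-ion potential energy surface of a BD system
#'
#' Evaluates the deterministic one-ion potential (wells + confinement +
#' field work term) for a given species at arbitrary points. This is the
#' exact energy the integrator differentiates, exposed for ground-truth
#' quadrature (Boltzmann occupancies, detailed-balance checks) and for
#' force-consistency tests.
#'
#' @param system A \code{\link{bd_system}}.
#' @param species Species name the depths/scales apply to.
#' @param x,y,z Coordinates (recycled to common length), A.
#' @return Potential energy in kJ/mol at each point (field contribution
#'   \code{+q*E*z} so that the force is \code{-q*E} along z under positive
#'   voltage).
#' @export
bd_potential <- function(system, species, x, y, z) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  U <- numeric(n)
  R <- sqrt(x^2 + y^2)
  for (w in system$wells) {
    depth <- w$depth
    if (!is.null(w$scale) && species %in% names(w$scale))
      depth <- depth * w$scale[[species]]
    gz <- exp(-(z - w$z_center)^2 / (2 * w$width^2))
    rc <- if (is.null(w$r_center)) 0 else w$r_center
    gr <- if (!is.null(w$r_width) && w$r_width > 0)
      exp(-(R - rc)^2 / (2 * w$r_width^2)) else 1
    U <- U - depth * gz * gr
  }
  if (system$k_conf > 0) {
    ss <- function(t) ifelse(t <= 0, 0, ifelse(t >= 1, 1, t^2 * (3 - 2 * t)))
    W <- ss((z - system$pore$z_bottom) / system$edge_a) *
         ss((system$pore$z_top - z) / system$edge_a)
    U <- U + 0.5 * system$k_conf * pmax(0, R - system$pore$radius)^2 * W
  }
  qv <- NA_real_
  for (s in system$species) if (s$species$name == species) qv <- s$species$valence
  if (is.na(qv)) stop("species not in system: ", species)
  U + qv * system$conditions$field * .e_mV * z
}

#' Run the Brownian-dynamics channel simulator
#'
#' Euler-Maruyama integration of overdamped Langevin dynamics,
#' \code{dr = (D/kT) F dt + sqrt(2 D dt) eta}, with periodic wrapping in
#' all three box dimensions. The same (system, seed, n_steps) triple
#' always yields a bit-identical trajectory. Output positions are
#' subsampled at \code{stride} steps; the full-resolution path informs the
#' ground-truth crossing log.
#'
#' @param system A \code{\link{bd_system}}.
#' @param n_steps Number of integration steps.
#' @param stride Output stride in steps (default 100).
#' @param seed RNG seed; defaults to the system's seed.
#' @param bias Optional umbrella bias: \code{list(ion, k, center,
#'   fb_k, fb_radius)} adds \code{0.5 k (z - center)^2} (minimum image in
#'   z) on one ion plus a flat-bottom radial restraint.
#' @param init Optional \code{[n_ions, 3]} matrix of initial positions;
#'   by default ions start uniformly in the bulk reservoir slabs.
#' @return List with \code{traj}, an \code{\link{ion_trajectory}} of
#'   wrapped coordinates, and \code{log}, a ground-truth record with
#'   per-ion counts of downward/upward periodic boundary crossings (each
#'   net winding corresponds to one full pore passage).
#' @export
simulate_bd <- function(system, n_steps, stride = 100L,
                        seed = system$seed, bias = NULL, init = NULL) {
  stopifnot(inherits(system, "bd_system"), n_steps >= 1)
  ions <- .bd_ions(system)
  n_i <- nrow(ions)
  set.seed(seed)
  if (is.null(init)) {
    init <- matrix(0, n_i, 3)
    init[, 1] <- stats::runif(n_i, -system$box[1] / 2, system$box[1] / 2)
    init[, 2] <- stats::runif(n_i, -system$box[2] / 2, system$box[2] / 2)
    # start in the bulk slabs (outside the membrane) when a pore exists
    lo <- system$pore$z_top + 1
    hi <- system$box[3] / 2
    span <- hi - lo
    if (system$k_conf > 0 && span > 1) {
      u <- stats::runif(n_i, 0, 2 * span)
      init[, 3] <- ifelse(u < span, lo + u, -hi + (u - span))
    } else {
      init[, 3] <- stats::runif(n_i, -hi, hi)
    }
  }
  depths <- .bd_well_depths(system, ions)
  wz <- vapply(system$wells, function(w) w$z_center, 0)
  ww <- vapply(system$wells, function(w) w$width, 0)
  wrc <- vapply(system$wells, function(w)
    if (is.null(w$r_center)) 0 else w$r_center, 0)
  wrw <- vapply(system$wells, function(w)
    if (is.null(w$r_width)) 0 else w$r_width, 0)
  kT <- system$conditions$kT
  fz_field <- -ions$q * system$conditions$field * .e_mV
  b_ion <- -1L; b_k <- 0; b_c <- 0; fb_k <- 0; fb_r <- 0
  if (!is.null(bias)) {
    b_ion <- as.integer(bias$ion) - 1L
    b_k <- bias$k; b_c <- bias$center
    fb_k <- if (is.null(bias$fb_k)) 0 else bias$fb_k
    fb_r <- if (is.null(bias$fb_radius)) 0 else bias$fb_radius
  }
  res <- bd_core(pos0 = init, D = ions$D, fz_field = fz_field,
                 q = as.numeric(ions$q), box = system$box, kT = kT,
                 n_steps = as.integer(n_steps), dt = system$dt,
                 stride = as.integer(stride),
                 well_depth = depths, well_z = wz, well_w = ww,
                 well_rc = wrc, well_rw = wrw,
                 k_conf = system$k_conf, pore_r = system$pore$radius,
                 z_bottom = system$pore$z_bottom, z_top = system$pore$z_top,
                 edge_a = system$edge_a,
                 coul_pref = .coulomb / system$eps_scale,
                 lambda_d = system$lambda_d, r_cap = system$r_cap,
                 bias_ion = b_ion, bias_k = b_k, bias_c = b_c,
                 fb_k = fb_k, fb_r = fb_r)
  n_frames <- dim(res$frames)[1]
  times <- (seq_len(n_frames) - 1L) * system$dt * stride
  traj <- ion_trajectory(times = times, box = system$box, pos = res$frames,
                         ions = ions[, c("ion_id", "species")],
                         species_table = .bd_species_table(system))
  log <- data.frame(ion_id = ions$ion_id, species = ions$species,
                    down_crossings = res$down_cross,
                    up_crossings = res$up_cross)
  per_species <- stats::aggregate(
    cbind(down_crossings, up_crossings) ~ species, data = log, FUN = sum)
  list(traj = traj,
       log = structure(list(per_ion = log, per_species = per_species,
                            n_steps = n_steps, dt = system$dt, seed = seed),
                       class = "bd_log"))
}

#' Generate umbrella-sampling windows with the BD simulator
#'
#' For each window center a harmonic bias \code{0.5 k (z - c)^2} is added
#' on one tagged ion together with a flat-bottom cylinder restraint that
#' keeps it near the pore axis; the tagged ion's z samples are recorded
#' after discarding an equilibration fraction. Mirrors the umbrella
#' protocol the PMF solver expects: ~1 A window spacing and a force
#' constant of 10 kJ/mol/A^2 (= 1000 kJ/mol/nm^2) are typical.
#'
#' @param system A \code{\link{bd_system}}; the first ion is tagged.
#' @param centers Sorted window centers along z (A).
#' @param k_umbrella Bias force constant, kJ/mol/A^2.
#' @param steps_per_window Integration steps per window.
#' @param stride Sampling stride in steps.
#' @param equil_fraction Fraction of each window discarded as
#'   equilibration (default 0.1).
#' @param fb_radius,fb_k Flat-bottom cylinder radius (A) and force
#'   constant.
#' @param seed Base seed; window w uses \code{seed + w}.
#' @return A \code{\link{wham_input}} with one sample vector per window.
#' @export
sample_umbrella_windows <- function(system, centers, k_umbrella = 10,
                                    steps_per_window = 20000L, stride = 10L,
                                    equil_fraction = 0.1,
                                    fb_radius = 5, fb_k = 10,
                                    seed = system$seed) {
  stopifnot(k_umbrella > 0, !is.unsorted(centers))
  ions <- .bd_ions(system)
  windows <- vector("list", length(centers))
  for (w in seq_along(centers)) {
    cw <- centers[w]
    init <- matrix(0, nrow(ions), 3)
    set.seed(seed + w)
    init[, 1] <- stats::runif(nrow(ions), -2, 2)
    init[, 2] <- stats::runif(nrow(ions), -2, 2)
    init[, 3] <- stats::runif(nrow(ions), -system$box[3] / 2, system$box[3] / 2)
    init[1, ] <- c(0, 0, cw)
    run <- simulate_bd(system, n_steps = steps_per_window, stride = stride,
                       seed = seed + w,
                       bias = list(ion = 1L, k = k_umbrella, center = cw,
                                   fb_k = fb_k, fb_radius = fb_radius),
                       init = init)
    zs <- run$traj$pos[, 1, 3]
    keep <- zs[-seq_len(max(1L, floor(length(zs) * equil_fraction)))]
    if (length(keep) < 10L)
      stop(sprintf("window %d retained fewer than 10 samples", w))
    windows[[w]] <- list(center = cw, k = k_umbrella, samples = keep)
  }
  wham_input(windows = windows,
             temperature = system$conditions$temperature,
             periodic = TRUE, period = system$box[3])
}
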