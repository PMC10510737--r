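#' Load channel geometry and site definitions from a YAML config
#'
#' Keys: \code{geometry} (\code{z_top}, \code{z_bottom},
#' \code{gate_radius}, optional \code{regions} as label -> [z_lo, z_hi,
#' r_lo, r_hi]) and optional \code{sites} (label -> [z_lo, z_hi, r_lo,
#' r_hi]).
#'
#' @param path YAML file path.
#' @return List with \code{geometry} (\code{\link{channel_geometry}}) and
#'   \code{sites} (list of \code{\link{binding_site}}, possibly empty).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry
  if (is.null(g)) stop("config lacks a 'geometry' section")
  regions <- lapply(g$regions, as.numeric)
  geom <- channel_geometry(z_top = g$z_top, z_bottom = g$z_bottom,
                           gate_radius = if (is.null(g$gate_radius)) 8
                                         else g$gate_radius,
                           regions = if (is.null(regions)) list() else regions)
  sites <- list()
  for (lab in names(cfg$sites)) {
    v <- as.numeric(cfg$sites[[lab]])
    sites[[lab]] <- binding_site(lab, v[1], v[2], v[3], v[4])
  }
  list(geometry = geom, sites = sites)
}

.provenance <- function(seed, extra = "") {
  sprintf("# ionflux %s seed=%s %s",
          as.character(utils::packageVersion("ionflux")), seed, extra)
}

#' Generate the canonical analysis fixtures
#'
#' Writes small, seeded, regenerable fixtures used throughout the test
#' suite, with a JSON manifest of each fixture's expected value:
#' a straight-path permeation track (exactly one down event), a
#' wrap-around track crossing the periodic boundary, the 2,3,3,2,3
#' occupancy pattern (two concerted episodes at k = 3), a uniform
#' cylinder density cloud, and quadratic-landscape umbrella windows.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed RNG seed; identical seeds regenerate identical files.
#' @return Invisibly, the manifest list.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  st <- list(Ca = ion_species("Ca", 2, 79), Na = ion_species("Na", 1, 133))
  manifest <- list(seed = seed)

  # straight permeation path: one ion, on-axis, +20 -> -20 in a 70 A box
  n_f <- 41L
  pos <- array(0, c(n_f, 1L, 3L))
  pos[, 1, 3] <- seq(20, -20, length.out = n_f)
  tr <- ion_trajectory(times = seq(0, 0.4, length.out = n_f), box = c(30, 30, 70),
                       pos = pos, ions = data.frame(ion_id = 1L, species = "Ca"),
                       species_table = st)
  write_tracks(tr, file.path(out_dir, "straight_path.tracks"))
  manifest$straight_path <- list(file = "straight_path.tracks",
                                 expected_down_events = 1L)

  # wrap-around drift: ion drifts -1 A/frame through the periodic boundary
  n_f <- 120L
  zu <- 30 - (seq_len(n_f) - 1)           # continuous downward drift
  zw <- zu - 70 * floor((zu + 35) / 70)   # wrapped into [-35, 35)
  pos <- array(0, c(n_f, 1L, 3L))
  pos[, 1, 3] <- zw
  tr <- ion_trajectory(times = (seq_len(n_f) - 1) * 0.01, box = c(30, 30, 70),
                       pos = pos, ions = data.frame(ion_id = 1L, species = "Na"),
                       species_table = st)
  write_tracks(tr, file.path(out_dir, "wrap_around.tracks"))
  manifest$wrap_around <- list(file = "wrap_around.tracks",
                               expected_down_events = 2L,
                               note = "drift crosses the pore twice via the periodic image")

  # 2,3,3,2,3 occupancy pattern in region SF: two episodes at k=3
  patt <- c(2L, 3L, 3L, 2L, 3L)
  n_f <- length(patt)
  n_i <- 3L
  pos <- array(0, c(n_f, n_i, 3L))
  pos[, , 3] <- 30   # park everyone in bulk
  for (f in seq_len(n_f)) pos[f, seq_len(patt[f]), 3] <- 0  # in SF
  pos[, , 1] <- rep(seq_len(n_i), each = n_f) * 0.5
  tr <- ion_trajectory(times = (seq_len(n_f) - 1) * 0.01, box = c(30, 30, 70),
                       pos = pos,
                       ions = data.frame(ion_id = 1:3, species = "Ca"),
                       species_table = st)
  write_tracks(tr, file.path(out_dir, "occupancy_pattern.tracks"))
  manifest$occupancy_pattern <- list(file = "occupancy_pattern.tracks",
                                     pattern = patt, k = 3L,
                                     expected_episodes = list(c(2L, 3L), c(5L, 5L)),
                                     expected_max_occupancy = 3L)

  # uniform cylinder cloud: R uniform in area, z uniform
  n <- 4000L
  Rmax <- 6; L <- 20
  Rv <- Rmax * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  pos <- array(0, c(n, 1L, 3L))
  pos[, 1, 1] <- Rv * cos(th)
  pos[, 1, 2] <- Rv * sin(th)
  pos[, 1, 3] <- stats::runif(n, -L / 2, L / 2)
  tr <- ion_trajectory(times = (seq_len(n) - 1) * 0.001, box = c(30, 30, 70),
                       pos = pos, ions = data.frame(ion_id = 1L, species = "Na"),
                       species_table = st)
  write_tracks(tr, file.path(out_dir, "uniform_cylinder.tracks"))
  manifest$uniform_cylinder <- list(file = "uniform_cylinder.tracks",
                                    R_max = Rmax, length = L,
                                    expected_density = 1 / (pi * Rmax^2 * L))

  # quadratic-landscape umbrella windows: exact Boltzmann samples of
  # U = 0.5 a z^2 under each bias (Gaussian, so sampled in closed form)
  a <- 2; kbias <- 10; Tref <- 310
  kT <- .kB * Tref
  centers <- seq(-4, 4, by = 1)
  for (i in seq_along(centers)) {
    c0 <- centers[i]
    var <- kT / (a + kbias)
    mu <- kbias * c0 / (a + kbias)
    s <- stats::rnorm(400, mu, sqrt(var))
    utils::write.table(
      data.frame(z = s),
      file.path(out_dir, sprintf("window_%02d.tsv", i)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest$quadratic_windows <- list(files = sprintf("window_%02d.tsv",
                                                     seq_along(centers)),
                                     centers = centers, k = kbias,
                                     temperature = Tref, a = a,
                                     note = "samples drawn from the exact biased Boltzmann distribution")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the full synthetic pipeline and write a report
#'
#' One-shot demonstration pipeline: simulates a preset channel, detects
#' permeation events, computes conductances and the event ratio, the R-z
#' density of the divalent species, binding-site occupancies and
#' transition probabilities, and writes TSV/JSON outputs with provenance
#' headers. Identical seeds give byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param preset Preset name for \code{\link{bd_preset}}.
#' @param seed RNG seed.
#' @param n_steps Integration steps (default 2e6, i.e. 20 ns at the
#'   default dt).
#' @return Invisibly, a list with the main results.
#' @export
run_report <- function(out_dir, preset = "trpv6_like", seed = 1L,
                       n_steps = 2e6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sys <- bd_preset(preset, seed = seed)
  geom <- bd_geometry(sys)
  run <- simulate_bd(sys, n_steps = n_steps, seed = seed)
  traj <- run$traj
  total_time <- diff(range(traj$times))
  hdr <- .provenance(seed, paste0("preset=", preset))

  ev <- detect_events(traj, geom)
  f <- file.path(out_dir, "events.tsv")
  writeLines(hdr, f)
  suppressWarnings(utils::write.table(ev, f, sep = "\t", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  st <- .bd_species_table(sys)
  cond <- list()
  for (nm in names(st)) {
    cr <- conductance(ev, total_time, sys$conditions, st[[nm]])
    cond[[nm]] <- list(conductance_pS = cr$conductance,
                       n_events = cr$n_events)
  }
  ratio <- if (all(c("Ca", "Na") %in% names(st)) && nrow(ev))
    tryCatch(event_ratio(ev, "Ca", "Na")$ratio, error = function(e) NA)
  else NA
  jsonlite::write_json(
    list(provenance = hdr, preset = preset, seed = seed,
         total_time_ns = total_time, conductance = cond,
         ca_na_event_ratio = ratio),
    file.path(out_dir, "conductance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  dens <- density_rz(traj, geom, R_edges = seq(0, 8, 0.5),
                     z_edges = seq(-20, 20, 0.5),
                     species = names(st)[1])
  dd <- expand.grid(R_mid = dens$R_mid, z_mid = dens$z_mid)
  dd$counts <- as.vector(dens$counts)
  dd$rho <- as.vector(dens$rho)
  f <- file.path(out_dir, "density_rz.tsv")
  writeLines(hdr, f)
  suppressWarnings(utils::write.table(dd, f, sep = "\t", row.names = FALSE,
                                      quote = FALSE, append = TRUE))

  results <- list(events = ev, conductance = cond, ratio = ratio)
  if (length(sys$wells)) {
    sites <- bd_sites(sys)
    track <- assign_sites(traj, geom, sites)
    occ <- lapply(stats::setNames(nm = names(sites)),
                  function(s) occupancy(track, s))
    tp <- if (all(c("S1", "P") %in% names(sites)))
      transition_probabilities(track) else NULL
    jsonlite::write_json(
      list(provenance = hdr, occupancy = occ,
           transitions = if (!is.null(tp))
             list(probabilities = as.list(tp$probabilities),
                  counts = as.list(tp$counts), n_other = tp$n_other)
           else NULL),
      file.path(out_dir, "sites.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    results$occupancy <- occ
    results$transitions <- tp
  }
  invisible(results)
}
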