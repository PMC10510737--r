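#' Detect permeation events
#'
#' A permeation event is one ion traversing the pore from the
#' extracellular side (above \code{z_top}) to the cytosolic side (below
#' \code{z_bottom}) while staying inside the gate cylinder
#' (\code{R < gate_radius}) for every frame strictly between entry and
#' exit. Detection runs a per-ion finite-state machine over the axially
#' unwrapped coordinate, so re-entry through the periodic image never
#' double-counts a crossing; upward traversals are detected symmetrically
#' and labeled \code{"up"}.
#'
#' @param traj An \code{\link{ion_trajectory}} (raw wrapped coordinates
#'   are unwrapped internally).
#' @param geom A \code{\link{channel_geometry}}; its pore interval must
#'   fit inside the box.
#' @param species Optional species filter (character vector).
#' @return Data frame with columns \code{ion_id}, \code{species},
#'   \code{frame_enter} (last frame on the entry side),
#'   \code{frame_exit} (first frame on the far side) and
#'   \code{direction} (\code{"down"}/\code{"up"}), sorted by
#'   \code{frame_exit}.
#' @export
detect_events <- function(traj, geom, species = NULL) {
  stopifnot(inherits(traj, "ion_trajectory"), inherits(geom, "channel_geometry"))
  Lz <- traj$box[3]
  if (geom$z_top - geom$z_bottom >= Lz)
    stop("geometry pore interval does not fit inside the box")
  tu <- unwrap_axial(traj)
  cc <- cylindrical_coords(tu, geom)
  sel <- seq_len(nrow(traj$ions))
  if (!is.null(species)) sel <- which(traj$ions$species %in% species)
  out <- list()
  for (i in sel) {
    zu <- cc$z[, i]
    R <- cc$R[, i]
    cell <- floor((zu - geom$z_bottom) / Lz)
    phase <- zu - cell * Lz
    in_pore <- phase < geom$z_top
    state <- "NONE"; s_cell <- NA_integer_; enter <- NA_integer_
    n_f <- length(zu)
    # initial state
    if (in_pore[1]) { state <- "LOST"; s_cell <- cell[1] }
    else { state <- "SLAB"; s_cell <- cell[1] }
    for (f in seq_len(n_f)[-1]) {
      k <- cell[f]
      if (!in_pore[f]) {                      # now in bulk slab k
        if (state == "PORE_DOWN" && k == s_cell - 1L) {
          out[[length(out) + 1L]] <- list(i = i, enter = enter, exit = f,
                                          dir = "down")
        } else if (state == "PORE_UP" && k == s_cell) {
          out[[length(out) + 1L]] <- list(i = i, enter = enter, exit = f,
                                          dir = "up")
        }
        state <- "SLAB"; s_cell <- k
      } else {                                 # now in pore k
        if (state == "SLAB") {
          if (k == s_cell && R[f] < geom$gate_radius) {
            state <- "PORE_DOWN"; s_cell <- k; enter <- f - 1L
          } else if (k == s_cell + 1L && R[f] < geom$gate_radius) {
            state <- "PORE_UP"; s_cell <- k; enter <- f - 1L
          } else {
            state <- "LOST"; s_cell <- k
          }
        } else if (state %in% c("PORE_DOWN", "PORE_UP")) {
          if (k != s_cell || R[f] >= geom$gate_radius) {
            state <- "LOST"; s_cell <- k
          }
        } else {
          state <- "LOST"; s_cell <- k
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ion_id = integer(), species = character(),
                      frame_enter = integer(), frame_exit = integer(),
                      direction = character()))
  }
  ev <- data.frame(
    ion_id = traj$ions$ion_id[vapply(out, function(e) e$i, 0L)],
    species = traj$ions$species[vapply(out, function(e) e$i, 0L)],
    frame_enter = vapply(out, function(e) e$enter, 0L),
    frame_exit = vapply(out, function(e) e$exit, 0L),
    direction = vapply(out, function(e) e$dir, ""))
  ev[order(ev$frame_exit, ev$ion_id), , drop = FALSE]
}

#' Channel conductance from permeation event counts
#'
#' Conductance C = N_event * Q_ion / (t * V_tm), converted to pS from
#' counts (N), elementary charges (Q), ns (t) and mV (V). Downward events
#' count by default (extracellular to cytosolic under positive voltage);
#' \code{mode = "net"} uses down minus up.
#'
#' @param events Event data frame from \code{\link{detect_events}}, or a
#'   list of such data frames (one per replica trajectory).
#' @param total_time Trajectory length in ns (recycled across replicas).
#' @param conditions A \code{\link{simulation_conditions}} (nonzero
#'   voltage required).
#' @param species An \code{\link{ion_species}} giving the charge; its
#'   name also filters the events.
#' @param mode \code{"down"} (default) or \code{"net"}.
#' @return Object of class \code{conductance_result}: \code{conductance}
#'   (pS; replica mean when replicas are given), \code{sd} (SD over
#'   replicas, NA for a single trajectory), \code{per_replica},
#'   \code{n_events}, \code{total_time}, \code{voltage}.
#' @examples
#' cond <- simulation_conditions(voltage = 500, Lz = 100)
#' ev <- data.frame(ion_id = 1L, species = "Na", frame_enter = 1L,
#'                  frame_exit = 2L, direction = "down")
#' conductance(ev, total_time = 500, cond, ion_species("Na", 1))$conductance
#' @export
conductance <- function(events, total_time, conditions, species,
                        mode = c("down", "net")) {
  mode <- match.arg(mode)
  stopifnot(inherits(conditions, "simulation_conditions"),
            inherits(species, "ion_species"))
  if (conditions$voltage == 0) stop("conductance undefined at V=0")
  if (any(total_time <= 0)) stop("total_time must be positive")
  reps <- if (is.data.frame(events)) list(events) else events
  total_time <- rep_len(total_time, length(reps))
  count1 <- function(ev) {
    ev <- ev[ev$species == species$name, , drop = FALSE]
    n_down <- sum(ev$direction == "down")
    n_up <- sum(ev$direction == "up")
    if (mode == "down") n_down else n_down - n_up
  }
  n <- vapply(reps, count1, 0)
  c_ps <- n * abs(species$valence) * .e_C * 1e24 /
    (total_time * abs(conditions$voltage))
  structure(list(conductance = mean(c_ps),
                 sd = if (length(c_ps) > 1L) stats::sd(c_ps) else NA_real_,
                 per_replica = c_ps, n_events = sum(n),
                 total_time = sum(total_time),
                 voltage = conditions$voltage,
                 species = species$name, mode = mode),
            class = "conductance_result")
}

#' @export
print.conductance_result <- function(x, ...) {
  if (is.na(x$sd)) {
    cat(sprintf("%s conductance: %.4g pS (%d events / %g ns at %g mV)\n",
                x$species, x$conductance, x$n_events, x$total_time, x$voltage))
  } else {
    cat(sprintf("%s conductance: %.3g +/- %.2g pS (%d replicas, %d events)\n",
                x$species, x$conductance, x$sd, length(x$per_replica),
                x$n_events))
  }
  invisible(x)
}

#' Permeation-event ratio between two species
#'
#' Reports N_a : N_b reduced to b = 1, e.g. counts (4, 2) give 2.0. A zero
#' denominator with a nonzero numerator reports Inf.
#'
#' @param events Event data frame, or a named count vector.
#' @param species_a,species_b Species names (numerator, denominator).
#' @return List with \code{counts}, \code{ratio} and \code{label}
#'   (one-decimal \code{"a:1"} string).
#' @export
event_ratio <- function(events, species_a, species_b) {
  if (is.data.frame(events)) {
    counts <- c(sum(events$species == species_a),
                sum(events$species == species_b))
  } else {
    counts <- c(if (species_a %in% names(events)) events[[species_a]] else 0,
                if (species_b %in% names(events)) events[[species_b]] else 0)
  }
  names(counts) <- c(species_a, species_b)
  if (sum(counts) == 0) stop("no events for either species")
  ratio <- if (counts[2] == 0) Inf else unname(counts[1] / counts[2])
  list(counts = counts, ratio = ratio,
       label = if (is.finite(ratio)) sprintf("%.1f:1", ratio) else "Inf:1")
}

#' Divalent-block factor
#'
#' Fold decrease of a species' conductance when a blocking cation is
#' added: single-species conductance divided by its conductance in the
#' mixed system. A zero mixed conductance is reported as Inf (complete
#' block).
#'
#' @param conductance_single,conductance_mixed Conductances in pS.
#' @return Fold decrease (numeric).
#' @export
block_factor <- function(conductance_single, conductance_mixed) {
  if (conductance_single <= 0) stop("single-species conductance must be positive")
  if (conductance_mixed < 0) stop("mixed conductance must be non-negative")
  if (conductance_mixed == 0) return(Inf)
  conductance_single / conductance_mixed
}

# per-frame in-region ion indicator matrix for a named geometry region
.region_membership <- function(traj, geom, region_label, species = NULL) {
  reg <- geom$regions[[region_label]]
  if (is.null(reg)) stop("unknown region label: ", region_label)
  cc <- cylindrical_coords(traj, geom)
  inside <- cc$z >= reg[1] & cc$z < reg[2] & cc$R >= reg[3] & cc$R < reg[4]
  if (!is.null(species)) inside[, !(traj$ions$species %in% species)] <- FALSE
  inside
}

#' Concerted multi-ion occupancy episodes
#'
#' Maximal frame intervals during which at least k ions of the selected
#' species are simultaneously inside a named region (e.g. three divalent
#' ions in the selectivity filter). Adjacent episodes are separated by at
#' least one frame below threshold.
#'
#' @param traj An \code{\link{ion_trajectory}}.
#' @param geom A \code{\link{channel_geometry}} defining the region.
#' @param region_label Name of a region in \code{geom$regions}.
#' @param k Minimum simultaneous occupancy (>= 2 for concerted episodes;
#'   k = 1 reduces to residence intervals).
#' @param species Optional species filter.
#' @return Data frame with \code{frame_start}, \code{frame_end},
#'   \code{max_count}, and a list-column \code{ion_ids} of ions seen in
#'   the region during the episode.
#' @export
concerted_episodes <- function(traj, geom, region_label, k, species = NULL) {
  inside <- .region_membership(traj, geom, region_label, species)
  occ <- rowSums(inside)
  hit <- occ >= k
  if (!any(hit)) {
    return(data.frame(frame_start = integer(), frame_end = integer(),
                      max_count = integer()))
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  eps <- data.frame(frame_start = starts[idx], frame_end = ends[idx],
                    max_count = vapply(idx, function(j)
                      as.integer(max(occ[starts[j]:ends[j]])), 0L))
  eps$ion_ids <- lapply(seq_len(nrow(eps)), function(j) {
    fr <- eps$frame_start[j]:eps$frame_end[j]
    traj$ions$ion_id[colSums(inside[fr, , drop = FALSE]) > 0]
  })
  eps
}

#' Maximum simultaneous region occupancy
#'
#' @inheritParams concerted_episodes
#' @return Integer: the maximum over frames of the in-region ion count.
#' @export
max_simultaneous_occupancy <- function(traj, geom, region_label,
                                       species = NULL) {
  inside <- .region_membership(traj, geom, region_label, species)
  as.integer(max(rowSums(inside), 0))
}

#' Cumulative permeation-event count over time
#'
#' Step series of the number of completed events (timestamped at
#' \code{frame_exit}) up to each frame.
#'
#' @param events Event data frame from \code{\link{detect_events}}.
#' @param frame_times Frame times in ns.
#' @return Data frame with \code{frame}, \code{time} and
#'   \code{n_events}; non-decreasing with final value \code{nrow(events)}.
#' @export
cumulative_event_series <- function(events, frame_times) {
  exits <- sort(events$frame_exit)
  data.frame(frame = seq_along(frame_times), time = frame_times,
             n_events = findInterval(seq_along(frame_times), exits))
}
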