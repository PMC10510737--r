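#' First-shell coordination number
#'
#' Number of oxygen atoms inside the ion's first solvation shell, defined
#' as all oxygens at distance less than or equal to \code{r_shell}
#' (default 3.0 A for both monovalent and divalent cations). The boundary
#' is inclusive. Minimum-image distances are used when a box is supplied.
#'
#' @param ion_position Numeric length-3 (A).
#' @param oxygen_positions Matrix \code{[n, 3]} of oxygen coordinates.
#' @param r_shell Shell radius in A (default 3.0).
#' @param box Optional length-3 periodic box for minimum-image distances.
#' @return Integer count.
#' @examples
#' coordination_number(c(0, 0, 0), rbind(c(2.5, 0, 0), c(3.5, 0, 0)))
#' @export
coordination_number <- function(ion_position, oxygen_positions,
                                r_shell = 3.0, box = NULL) {
  if (r_shell <= 0) stop("r_shell must be positive")
  if (is.null(oxygen_positions) || NROW(oxygen_positions) == 0L) return(0L)
  oxygen_positions <- matrix(oxygen_positions, ncol = 3L)
  d <- sweep(oxygen_positions, 2L, ion_position)
  if (!is.null(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  sum(rowSums(d^2) <= r_shell^2)
}

#' Axial coordination (dehydration) profile
#'
#' Mean first-shell oxygen count of in-pore ions as a function of z,
#' decomposed by oxygen source (water vs protein; tags starting with
#' \code{"water"} count as water). The mean is taken over ion-frames:
#' every frame in which a selected ion lies in a z bin with
#' \code{R < r_max} contributes one sample to that bin. With multiple
#' replica trajectories the error is the standard deviation of the
#' replica means per bin.
#'
#' @param traj An \code{\link{ion_trajectory}} with tagged oxygen atom
#'   sets, or a list of replica trajectories.
#' @param geom A \code{\link{channel_geometry}}.
#' @param z_edges Axial bin edges (A).
#' @param species Optional ion species filter.
#' @param r_shell Shell radius (A), default 3.0.
#' @param r_max Radial conditioning: only ions with R below this enter
#'   the profile (default the gate radius).
#' @param box Periodic box for minimum-image shell distances; defaults to
#'   the trajectory box, NULL disables imaging.
#' @return Data frame of class \code{coordination_profile} with
#'   \code{z_mid}, \code{total}, \code{protein}, \code{water},
#'   \code{sem_total}, \code{n}; \code{total = protein + water} exactly.
#'   Bins without samples carry NA means.
#' @export
coordination_profile <- function(traj, geom, z_edges, species = NULL,
                                 r_shell = 3.0, r_max = geom$gate_radius,
                                 box = "traj") {
  reps <- if (inherits(traj, "ion_trajectory")) list(traj) else traj
  nb <- length(z_edges) - 1L
  acc <- lapply(reps, function(tr) {
    if (is.null(tr$atoms)) stop("trajectory carries no tagged oxygen sets")
    use_box <- if (identical(box, "traj")) tr$box else box
    cc <- cylindrical_coords(tr, geom)
    sel <- if (is.null(species)) seq_len(nrow(tr$ions))
           else which(tr$ions$species %in% species)
    is_water <- startsWith(tr$atoms$tag, "water")
    sum_tot <- sum_wat <- n <- numeric(nb)
    for (f in seq_along(tr$times)) {
      ox <- matrix(tr$atoms$coords[f, , ], ncol = 3L)
      for (i in sel) {
        if (cc$R[f, i] >= r_max) next
        bin <- findInterval(cc$z[f, i], z_edges)
        if (bin < 1L || bin > nb) next
        d <- sweep(ox, 2L, tr$pos[f, i, ])
        if (!is.null(use_box)) {
          for (k in 1:3) d[, k] <- d[, k] - use_box[k] * round(d[, k] / use_box[k])
        }
        in_shell <- rowSums(d^2) <= r_shell^2
        sum_tot[bin] <- sum_tot[bin] + sum(in_shell)
        sum_wat[bin] <- sum_wat[bin] + sum(in_shell & is_water)
        n[bin] <- n[bin] + 1
      }
    }
    list(tot = sum_tot, wat = sum_wat, n = n)
  })
  n_all <- Reduce(`+`, lapply(acc, `[[`, "n"))
  tot_all <- Reduce(`+`, lapply(acc, `[[`, "tot"))
  wat_all <- Reduce(`+`, lapply(acc, `[[`, "wat"))
  mean_tot <- ifelse(n_all > 0, tot_all / n_all, NA_real_)
  mean_wat <- ifelse(n_all > 0, wat_all / n_all, NA_real_)
  sem <- rep(NA_real_, nb)
  if (length(acc) > 1L) {
    rep_means <- sapply(acc, function(a) ifelse(a$n > 0, a$tot / a$n, NA_real_))
    if (!is.matrix(rep_means)) rep_means <- matrix(rep_means, nrow = nb)
    sem <- apply(rep_means, 1L, stats::sd, na.rm = TRUE)
  }
  out <- data.frame(z_mid = (z_edges[-1] + z_edges[-(nb + 1L)]) / 2,
                    total = mean_tot, protein = mean_tot - mean_wat,
                    water = mean_wat, sem_total = sem, n = n_all)
  class(out) <- c("coordination_profile", "data.frame")
  out
}
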