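#' Define a binding site
#'
#' A labeled spatial region: axial interval x radial annulus, with the
#' half-open membership convention \code{[z_lo, z_hi) x [r_lo, r_hi)} so
#' that geometrically disjoint sites give mutually exclusive labels.
#'
#' @param label Site label, e.g. \code{"S1"}, \code{"S2"}, \code{"P"}.
#' @param z_lo,z_hi Axial bounds (A).
#' @param r_lo,r_hi Radial bounds (A); \code{r_lo > 0} makes the site a
#'   peripheral annulus.
#' @return Object of class \code{binding_site}.
#' @export
binding_site <- function(label, z_lo, z_hi, r_lo = 0, r_hi = Inf) {
  if (z_lo >= z_hi || r_lo >= r_hi || r_lo < 0)
    stop("binding site '", label, "' bounds are not well ordered")
  structure(list(label = label, z_lo = z_lo, z_hi = z_hi,
                 r_lo = r_lo, r_hi = r_hi),
            class = "binding_site")
}

.sites_overlap <- function(a, b) {
  (a$z_lo < b$z_hi && b$z_lo < a$z_hi) &&
  (a$r_lo < b$r_hi && b$r_lo < a$r_hi)
}

#' Assign each ion-frame to a binding site
#'
#' Deterministic label per ion and frame by region membership. Sites must
#' be pairwise geometrically disjoint (checked at configuration time).
#' Space not covered by any site falls back to \code{bulk_top} (above the
#' pore), \code{bulk_bottom} (below), \code{cavity} when inside the gate
#' cylinder within the pore span and no explicit \code{cavity} site is
#' defined, and \code{other} elsewhere.
#'
#' @param traj An \code{\link{ion_trajectory}}.
#' @param geom A \code{\link{channel_geometry}}.
#' @param sites List of \code{\link{binding_site}} definitions.
#' @return Object of class \code{site_track}: \code{labels} (character
#'   matrix \code{[n_frames, n_ions]}), \code{dwells} (data frame of
#'   maximal constant-label segments: \code{ion_id}, \code{site},
#'   \code{frame_start}, \code{frame_end}), \code{ions}, \code{sites}.
#' @export
assign_sites <- function(traj, geom, sites) {
  stopifnot(length(sites) >= 1L)
  for (i in seq_along(sites)) {
    for (j in seq_len(i - 1L)) {
      if (.sites_overlap(sites[[i]], sites[[j]]))
        stop("binding sites '", sites[[i]]$label, "' and '",
             sites[[j]]$label, "' overlap geometrically")
    }
  }
  cc <- cylindrical_coords(traj, geom)
  n_f <- length(traj$times)
  n_i <- nrow(traj$ions)
  labels <- matrix(NA_character_, n_f, n_i)
  for (s in sites) {
    hit <- cc$z >= s$z_lo & cc$z < s$z_hi & cc$R >= s$r_lo & cc$R < s$r_hi
    labels[hit & is.na(labels)] <- s$label
  }
  un <- is.na(labels)
  labels[un & cc$z >= geom$z_top] <- "bulk_top"
  un <- is.na(labels)
  labels[un & cc$z < geom$z_bottom] <- "bulk_bottom"
  un <- is.na(labels)
  has_cavity <- any(vapply(sites, function(s) s$label == "cavity", TRUE))
  if (!has_cavity) {
    labels[un & cc$R < geom$gate_radius] <- "cavity"
    un <- is.na(labels)
  }
  labels[un] <- "other"
  dwells <- list()
  for (i in seq_len(n_i)) {
    r <- rle(labels[, i])
    ends <- cumsum(r$lengths)
    dwells[[i]] <- data.frame(ion_id = traj$ions$ion_id[i],
                              site = r$values,
                              frame_start = ends - r$lengths + 1L,
                              frame_end = ends)
  }
  structure(list(labels = labels, dwells = do.call(rbind, dwells),
                 ions = traj$ions, sites = sites, n_frames = n_f),
            class = "site_track")
}

#' @export
print.site_track <- function(x, ...) {
  cat(sprintf("site_track: %d frames x %d ions, %d dwell segments\n",
              x$n_frames, nrow(x$ions), nrow(x$dwells)))
  print(round(100 * table(x$labels) / length(x$labels), 1))
  invisible(x)
}

#' Site occupancy fraction
#'
#' Fraction of frames in which at least one ion (of the selected species)
#' occupies the site; equals one minus the fraction of frames with zero
#' in-site ions.
#'
#' @param track A \code{\link{site_track}}.
#' @param site Site label.
#' @param species Optional species filter.
#' @return Numeric in [0, 1].
#' @export
occupancy <- function(track, site, species = NULL) {
  stopifnot(inherits(track, "site_track"))
  known <- c(vapply(track$sites, function(s) s$label, ""),
             "bulk_top", "bulk_bottom", "cavity", "other")
  if (!site %in% known) stop("unknown site: ", site)
  m <- track$labels == site
  if (!is.null(species)) m[, !(track$ions$species %in% species)] <- FALSE
  mean(rowSums(m) >= 1L)
}

#' Permeation-path transition probabilities into a target site
#'
#' Implements the permeation-path statistic: every ion dwell in the
#' target site (default S2) that is eventually followed by entry into the
#' sink (default the cavity) is attributed to the last source-set site
#' the ion visited before that target dwell. With sources S1 and P the
#' probabilities are N_S1/(N_S1+N_P) and N_P/(N_S1+N_P). Transits whose
#' last pre-target site is outside the source set are tallied under
#' \code{other} and excluded from the printed-formula probabilities.
#'
#' @param track A \code{\link{site_track}}.
#' @param target Target site label (default \code{"S2"}).
#' @param sources Source site labels (default \code{c("S1", "P")}).
#' @param sink Sink label marking completion of the transit (default
#'   \code{"cavity"}).
#' @param species Optional species filter.
#' @return List with \code{probabilities} (named, over sources; NA when
#'   no attributable transit exists), \code{counts}, \code{n_other} and
#'   \code{n_transits}.
#' @export
transition_probabilities <- function(track, target = "S2",
                                     sources = c("S1", "P"),
                                     sink = "cavity", species = NULL) {
  stopifnot(inherits(track, "site_track"))
  labs <- unique(track$dwells$site)
  if (!target %in% labs && !target %in% vapply(track$sites, `[[`, "", "label"))
    stop("track does not contain target site: ", target)
  counts <- stats::setNames(numeric(length(sources)), sources)
  n_other <- 0L
  ions <- track$ions$ion_id
  if (!is.null(species)) ions <- ions[track$ions$species %in% species]
  for (id in ions) {
    dw <- track$dwells[track$dwells$ion_id == id, , drop = FALSE]
    dw <- dw[order(dw$frame_start), , drop = FALSE]
    last_source <- NA_character_
    pending <- NULL   # source attribution of an open target dwell
    for (r in seq_len(nrow(dw))) {
      s <- dw$site[r]
      if (s == target) {
        pending <- if (is.na(last_source)) "other" else last_source
      } else if (s == sink) {
        if (!is.null(pending)) {
          if (pending %in% sources) counts[pending] <- counts[pending] + 1
          else n_other <- n_other + 1L
          pending <- NULL
        }
      }
      if (s %in% sources) last_source <- s
    }
  }
  n_attr <- sum(counts)
  probs <- if (n_attr > 0) counts / n_attr
           else stats::setNames(rep(NA_real_, length(sources)), sources)
  list(probabilities = probs, counts = counts,
       n_other = n_other, n_transits = n_attr + n_other)
}
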