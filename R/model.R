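#' Define an ion species
#'
#' @param name Short label, e.g. \code{"Ca"} or \code{"Na"}.
#' @param valence Integer charge in elementary units; must be nonzero so
#'   that permeation charge accounting is defined.
#' @param diffusion Diffusion coefficient in A^2/ns (used only by the
#'   Brownian-dynamics simulator).
#' @param radius Ionic radius in A (simulator metadata).
#' @return Object of class \code{ion_species}.
#' @examples
#' ion_species("Ca", 2, diffusion = 79)
#' @export
ion_species <- function(name, valence, diffusion = NA_real_, radius = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  valence <- as.integer(valence)
  if (is.na(valence) || valence == 0L)
    stop("valence must be a nonzero integer")
  if (!is.na(diffusion) && diffusion <= 0)
    stop("diffusion coefficient must be positive")
  structure(list(name = name, valence = valence,
                 diffusion = diffusion, radius = radius),
            class = "ion_species")
}

#' Construct an ion trajectory
#'
#' Time-ordered per-frame positions of tagged ions in a periodic box; the
#' substrate of every estimator in the package. Frame times must be
#' uniformly spaced (analyses use frame counts times the time step).
#'
#' @param times Frame times in ns, strictly increasing, uniform spacing.
#' @param box Numeric length-3, box edge lengths (Lx, Ly, Lz) in A. The box
#'   is taken as constant over the trajectory (fixed-volume convention).
#' @param pos Numeric array \code{[n_frames, n_ions, 3]} of (x, y, z) in A.
#' @param ions Data frame with columns \code{ion_id} (integer) and
#'   \code{species} (character).
#' @param species_table Named list of \code{\link{ion_species}} resolving
#'   every species label in \code{ions}.
#' @param atoms Optional tagged atom sets (e.g. oxygen atoms for
#'   coordination analysis, or named atoms for distance series): a list
#'   with \code{coords}, an array \code{[n_frames, n_atoms, 3]}, and
#'   \code{tag}, a character vector of length \code{n_atoms}. Tags starting
#'   with \code{"water"} are classed as water oxygens; any other tag is a
#'   protein source.
#' @return Object of class \code{ion_trajectory}.
#' @export
ion_trajectory <- function(times, box, pos, ions, species_table, atoms = NULL) {
  times <- as.numeric(times)
  n_f <- length(times)
  if (n_f < 1L) stop("trajectory needs at least one frame")
  if (n_f > 1L) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("frame times must be strictly increasing")
    if (max(abs(dts - dts[1])) > 1e-6 * max(dts[1], 1e-12))
      stop("frame times must be uniformly spaced (1e-6 relative tolerance)")
  }
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive finite edge lengths")
  if (length(dim(pos)) != 3L || dim(pos)[1] != n_f || dim(pos)[3] != 3L)
    stop("pos must be an [n_frames, n_ions, 3] array")
  if (any(!is.finite(pos))) stop("all positions must be finite")
  ions <- as.data.frame(ions)
  if (nrow(ions) != dim(pos)[2])
    stop("ions table does not match the position array")
  if (anyDuplicated(ions$ion_id)) stop("duplicate ion_id")
  missing_sp <- setdiff(unique(ions$species), names(species_table))
  if (length(missing_sp))
    stop("species not in species_table: ", paste(missing_sp, collapse = ", "))
  if (!is.null(atoms)) {
    stopifnot(length(dim(atoms$coords)) == 3L,
              dim(atoms$coords)[1] == n_f,
              dim(atoms$coords)[2] == length(atoms$tag))
  }
  structure(list(times = times, box = box, pos = pos, ions = ions,
                 species_table = species_table, atoms = atoms),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("ion_trajectory: %d frames x %d ions, box %.1f x %.1f x %.1f A\n",
              length(x$times), nrow(x$ions), x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  time span %.4f ns, dt %.5f ns\n",
              diff(range(x$times)),
              if (length(x$times) > 1) x$times[2] - x$times[1] else NA))
  sp <- table(x$ions$species)
  cat("  species:", paste(sprintf("%s x%d", names(sp), sp), collapse = ", "), "\n")
  if (!is.null(x$atoms))
    cat(sprintf("  tagged atoms: %d\n", length(x$atoms$tag)))
  invisible(x)
}

#' Channel geometry
#'
#' Pore axis, axial boundaries of the membrane-spanning pore, the gating
#' cylinder radius within which an ion counts as in the pore, and named
#' axial regions (e.g. the selectivity filter).
#'
#' @param z_top Extracellular boundary of the pore along the axis (A).
#'   Convention: +z is the extracellular side; cations under positive
#'   voltage permeate toward decreasing z.
#' @param z_bottom Cytosolic boundary (A), must be below \code{z_top}.
#' @param gate_radius Cylinder radius (A) within which an ion is in the
#'   pore; default 8.
#' @param axis_origin,axis_direction Axis anchor point and unit direction
#'   (default +z). The direction is normalised; a near-zero vector errors.
#' @param regions Named list of numeric length-4 vectors
#'   \code{c(z_lo, z_hi, r_lo, r_hi)} defining labeled regions such as
#'   \code{SF}.
#' @return Object of class \code{channel_geometry}.
#' @examples
#' channel_geometry(z_top = 15, z_bottom = -15,
#'                  regions = list(SF = c(-6.5, 9.5, 0, 8)))
#' @export
channel_geometry <- function(z_top, z_bottom, gate_radius = 8,
                             axis_origin = c(0, 0, 0),
                             axis_direction = c(0, 0, 1),
                             regions = list()) {
  if (!(z_top > z_bottom)) stop("z_top must exceed z_bottom")
  if (gate_radius <= 0) stop("gate_radius must be positive")
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm < 1e-9) stop("axis_direction must be a nonzero vector")
  axis_direction <- axis_direction / nrm
  for (lab in names(regions)) {
    r <- regions[[lab]]
    if (length(r) != 4L || r[1] >= r[2] || r[3] >= r[4] || r[3] < 0)
      stop("region '", lab, "' must be c(z_lo, z_hi, r_lo, r_hi), well ordered")
  }
  structure(list(z_top = z_top, z_bottom = z_bottom,
                 gate_radius = gate_radius,
                 axis_origin = as.numeric(axis_origin),
                 axis_direction = axis_direction,
                 regions = regions),
            class = "channel_geometry")
}

#' Simulation conditions: voltage, temperature and derived field
#'
#' The transmembrane field follows the constant-field convention: field
#' (mV/A) equals the applied voltage divided by the box length in z.
#'
#' @param voltage Transmembrane voltage in mV, extracellular side positive.
#' @param temperature Temperature in K (default 310).
#' @param Lz Box length along z in A (sets the field).
#' @return Object of class \code{simulation_conditions} with elements
#'   \code{voltage}, \code{temperature}, \code{field} (mV/A) and \code{kT}
#'   (kJ/mol).
#' @export
simulation_conditions <- function(voltage = 500, temperature = 310, Lz) {
  if (temperature <= 0) stop("temperature must be positive")
  if (Lz <= 0) stop("Lz must be positive")
  structure(list(voltage = voltage, temperature = temperature,
                 Lz = Lz, field = voltage / Lz, kT = .kB * temperature),
            class = "simulation_conditions")
}

#' Write an ion trajectory to the plain-text track format
#'
#' One row per frame per ion: \code{frame time_ns ion_id species x y z},
#' whitespace-separated, positions printed with 6 decimals, preceded by
#' header lines \code{# box Lx Ly Lz} and \code{# species name valence}.
#'
#' @param traj An \code{\link{ion_trajectory}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_tracks <- function(traj, path) {
  stopifnot(inherits(traj, "ion_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# box %.6f %.6f %.6f",
                     traj$box[1], traj$box[2], traj$box[3]), con)
  for (sp in traj$species_table[unique(traj$ions$species)]) {
    writeLines(sprintf("# species %s %d", sp$name, sp$valence), con)
  }
  writeLines("frame time_ns ion_id species x y z", con)
  n_f <- length(traj$times)
  n_i <- nrow(traj$ions)
  frame <- rep(seq_len(n_f), times = n_i)
  ion_row <- rep(seq_len(n_i), each = n_f)
  lines <- sprintf("%d %.6f %d %s %.6f %.6f %.6f",
                   frame, traj$times[frame],
                   traj$ions$ion_id[ion_row], traj$ions$species[ion_row],
                   traj$pos[cbind(frame, ion_row, 1L)],
                   traj$pos[cbind(frame, ion_row, 2L)],
                   traj$pos[cbind(frame, ion_row, 3L)])
  writeLines(lines, con)
  invisible(path)
}

#' Read an ion trajectory from the plain-text track format
#'
#' Inverse of \code{\link{write_tracks}}. Every ion must be present in
#' every frame and frame times must be uniformly spaced; violations are
#' hard errors naming the offending frame and ion.
#'
#' @param path File in the documented track format.
#' @param species_table Optional named list of \code{\link{ion_species}};
#'   when omitted, species are built from the file's \code{# species}
#'   headers.
#' @return An \code{\link{ion_trajectory}}.
#' @export
read_tracks <- function(path, species_table = NULL) {
  hdr <- character()
  con <- file(path, "r")
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  box <- NULL
  file_species <- list()
  for (ln in hdr) {
    tok <- strsplit(trimws(sub("^#", "", ln)), "\\s+")[[1]]
    if (tok[1] == "box") {
      box <- as.numeric(tok[2:4])
    } else if (tok[1] == "species") {
      file_species[[tok[2]]] <- ion_species(tok[2], as.integer(tok[3]))
    }
  }
  if (is.null(box)) stop("track file lacks a '# box Lx Ly Lz' header")
  if (is.null(species_table)) species_table <- file_species
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           colClasses = c("integer", "numeric", "integer",
                                          "character", "numeric", "numeric",
                                          "numeric"))
  frames <- sort(unique(tab$frame))
  ids <- sort(unique(tab$ion_id))
  n_f <- length(frames)
  n_i <- length(ids)
  # completeness: every ion in every frame
  cnt <- table(factor(tab$frame, levels = frames),
               factor(tab$ion_id, levels = ids))
  if (any(cnt != 1L)) {
    bad <- which(cnt == 0L, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("ion %s absent at frame %s",
                   ids[bad[1, 2]], frames[bad[1, 1]]))
    }
    dup <- which(cnt > 1L, arr.ind = TRUE)
    stop(sprintf("ion %s duplicated at frame %s",
                 ids[dup[1, 2]], frames[dup[1, 1]]))
  }
  fi <- match(tab$frame, frames)
  ii <- match(tab$ion_id, ids)
  times <- numeric(n_f)
  times[fi] <- tab$time_ns
  pos <- array(NA_real_, c(n_f, n_i, 3))
  pos[cbind(fi, ii, 1L)] <- tab$x
  pos[cbind(fi, ii, 2L)] <- tab$y
  pos[cbind(fi, ii, 3L)] <- tab$z
  sp <- character(n_i)
  sp[ii] <- tab$species
  missing_sp <- setdiff(unique(sp), names(species_table))
  if (length(missing_sp))
    stop("unresolvable species in track file: ",
         paste(missing_sp, collapse = ", "))
  ion_trajectory(times = times, box = box, pos = pos,
                 ions = data.frame(ion_id = ids, species = sp),
                 species_table = species_table)
}

#' Unwrap axial coordinates across the periodic boundary
#'
#' Makes each ion's z coordinate continuous in time by the minimum-image
#' rule: any frame-to-frame axial displacement larger than Lz/2 in
#' magnitude is corrected by the appropriate multiple of Lz. x and y are
#' untouched and the first frame is unchanged. Idempotent on already
#' continuous trajectories whose per-frame displacements stay below Lz/2.
#'
#' @param traj An \code{\link{ion_trajectory}} with wrapped (or already
#'   continuous) coordinates.
#' @return The trajectory with continuous z.
#' @export
unwrap_axial <- function(traj) {
  stopifnot(inherits(traj, "ion_trajectory"))
  Lz <- traj$box[3]
  n_f <- length(traj$times)
  if (n_f < 2L) return(traj)
  z <- traj$pos[, , 3, drop = FALSE]
  dim(z) <- dim(traj$pos)[1:2]
  dz <- z[-1L, , drop = FALSE] - z[-n_f, , drop = FALSE]
  if (any(abs(dz) > Lz)) {
    bad <- which(abs(dz) > Lz, arr.ind = TRUE)[1L, ]
    stop(sprintf("ion %s moved more than one box per frame (frame %d)",
                 traj$ions$ion_id[bad[2]], bad[1] + 1L))
  }
  dz_c <- dz - Lz * round(dz / Lz)
  cs <- apply(dz_c, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = 1L)  # two-frame case
  zu <- rbind(z[1L, , drop = FALSE], sweep(cs, 2L, z[1L, ], "+"))
  traj$pos[, , 3] <- zu
  traj
}

#' Cylindrical coordinates relative to the channel axis
#'
#' R is the distance from the pore axis; z is the signed coordinate along
#' the axis direction measured from the axis origin.
#'
#' @param traj An \code{\link{ion_trajectory}}.
#' @param geom A \code{\link{channel_geometry}}.
#' @return List with matrices \code{R} and \code{z}, each
#'   \code{[n_frames, n_ions]}.
#' @export
cylindrical_coords <- function(traj, geom) {
  stopifnot(inherits(traj, "ion_trajectory"), inherits(geom, "channel_geometry"))
  u <- geom$axis_direction
  o <- geom$axis_origin
  dx <- traj$pos[, , 1, drop = FALSE] - o[1]
  dy <- traj$pos[, , 2, drop = FALSE] - o[2]
  dz <- traj$pos[, , 3, drop = FALSE] - o[3]
  dims <- dim(traj$pos)[1:2]
  dim(dx) <- dims; dim(dy) <- dims; dim(dz) <- dims
  z <- dx * u[1] + dy * u[2] + dz * u[3]
  r2 <- (dx - z * u[1])^2 + (dy - z * u[2])^2 + (dz - z * u[3])^2
  list(R = sqrt(pmax(r2, 0)), z = z)
}

#' Distance time series between two tagged atoms
#'
#' Supports the in-plane (x-y) variant used for diagonal pore-width
#' diagnostics, where the z component is ignored.
#'
#' @param traj An \code{\link{ion_trajectory}} carrying tagged atom sets.
#' @param tag_a,tag_b Atom tags; both must resolve to exactly one atom
#'   present in every frame.
#' @param in_plane If TRUE, the distance is taken in the x-y plane.
#' @return Numeric vector of length \code{n_frames} (A).
#' @export
distance_series <- function(traj, tag_a, tag_b, in_plane = FALSE) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (is.null(traj$atoms)) stop("trajectory carries no tagged atom sets")
  ia <- which(traj$atoms$tag == tag_a)
  ib <- which(traj$atoms$tag == tag_b)
  if (length(ia) != 1L) stop("unknown or ambiguous atom tag: ", tag_a)
  if (length(ib) != 1L) stop("unknown or ambiguous atom tag: ", tag_b)
  d <- traj$atoms$coords[, ia, , drop = FALSE] -
       traj$atoms$coords[, ib, , drop = FALSE]
  dim(d) <- c(dim(traj$atoms$coords)[1], 3L)
  if (in_plane) sqrt(d[, 1]^2 + d[, 2]^2) else sqrt(rowSums(d^2))
}
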