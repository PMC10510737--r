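#' Cylindrical ion probability density on the R-z plane
#'
#' Histograms (R, z) samples of the selected ions over all frames and
#' converts counts to a probability density per ion per frame:
#' each bin count is divided by the exact annulus volume
#' 2*pi*R_mid*dR*dz = pi*(R2^2 - R1^2)*dz (R_mid the arithmetic bin
#' midpoint) times N_i*N_f. This makes the estimator exactly unbiased for
#' a uniform cloud in every bin, including the innermost one, and when
#' the grid covers all samples rho integrates to exactly 1 over the grid
#' (sum of rho * 2*pi*R_mid*dR*dz).
#'
#' @param traj An \code{\link{ion_trajectory}}.
#' @param geom A \code{\link{channel_geometry}}.
#' @param R_edges,z_edges Strictly increasing bin edges (A).
#' @param species Optional species filter.
#' @return Object of class \code{density_map_rz}: \code{R_edges},
#'   \code{z_edges}, \code{counts} and \code{rho} matrices
#'   (nR x nz), \code{n_ions}, \code{n_frames} and \code{n_overflow}
#'   (samples outside the grid, excluded from the normalization claim).
#' @export
density_rz <- function(traj, geom, R_edges, z_edges, species = NULL) {
  stopifnot(length(traj$times) >= 1L,
            !is.unsorted(R_edges, strictly = TRUE),
            !is.unsorted(z_edges, strictly = TRUE))
  cc <- cylindrical_coords(traj, geom)
  sel <- if (is.null(species)) seq_len(nrow(traj$ions))
         else which(traj$ions$species %in% species)
  if (!length(sel)) stop("no ions of the requested species")
  Rv <- as.vector(cc$R[, sel])
  zv <- as.vector(cc$z[, sel])
  n_i <- length(sel)
  n_f <- length(traj$times)
  iR <- findInterval(Rv, R_edges, left.open = FALSE, rightmost.closed = FALSE)
  iz <- findInterval(zv, z_edges, left.open = FALSE, rightmost.closed = FALSE)
  nR <- length(R_edges) - 1L
  nz <- length(z_edges) - 1L
  ok <- iR >= 1L & iR <= nR & iz >= 1L & iz <= nz
  counts <- matrix(0L, nR, nz)
  if (any(ok)) {
    tb <- table(factor(iR[ok], levels = seq_len(nR)),
                factor(iz[ok], levels = seq_len(nz)))
    counts <- matrix(as.integer(tb), nR, nz)
  }
  R1 <- R_edges[-length(R_edges)]; R2 <- R_edges[-1]
  R_mid <- (R1 + R2) / 2
  dR <- R2 - R1
  dz <- diff(z_edges)
  vol <- outer(2 * pi * R_mid * dR, dz)   # bin shell area x height
  rho <- counts / (vol * n_i * n_f)
  structure(list(R_edges = R_edges, z_edges = z_edges,
                 counts = counts, rho = rho, R_mid = R_mid,
                 z_mid = (z_edges[-1] + z_edges[-length(z_edges)]) / 2,
                 bin_volume = vol, n_ions = n_i, n_frames = n_f,
                 n_overflow = sum(!ok)),
            class = "density_map_rz")
}

#' @export
print.density_map_rz <- function(x, ...) {
  cat(sprintf("density_map_rz: %d x %d bins, %d ions x %d frames, %d overflow samples\n",
              nrow(x$counts), ncol(x$counts), x$n_ions, x$n_frames,
              x$n_overflow))
  cat(sprintf("  integral of rho over grid: %.6f\n",
              sum(x$rho * x$bin_volume)))
  invisible(x)
}

#' Axial density profile near the pore axis
#'
#' Histogram over z of samples with R below \code{r_select} (default 3 A,
#' the on-axis selection used for convergence analysis), normalized to
#' unit integral over z.
#'
#' @inheritParams density_rz
#' @param r_select Radial selection cutoff (A).
#' @param frames Optional frame index subset.
#' @return Data frame with \code{z_mid}, \code{counts}, \code{density}
#'   (1/A). Warns and returns zero density when no sample falls inside
#'   the cylinder.
#' @export
axial_density <- function(traj, geom, z_edges, species = NULL,
                          r_select = 3, frames = NULL) {
  stopifnot(r_select > 0)
  cc <- cylindrical_coords(traj, geom)
  sel <- if (is.null(species)) seq_len(nrow(traj$ions))
         else which(traj$ions$species %in% species)
  if (is.null(frames)) frames <- seq_along(traj$times)
  Rv <- as.vector(cc$R[frames, sel])
  zv <- as.vector(cc$z[frames, sel])
  zv <- zv[Rv < r_select]
  nb <- length(z_edges) - 1L
  iz <- findInterval(zv, z_edges)
  iz <- iz[iz >= 1L & iz <= nb]
  counts <- tabulate(iz, nbins = nb)
  dz <- diff(z_edges)
  total <- sum(counts)
  if (total == 0L) {
    warning("no samples inside the selection cylinder; empty profile")
    dens <- rep(0, nb)
  } else {
    dens <- counts / (total * dz)
  }
  data.frame(z_mid = (z_edges[-1] + z_edges[-(nb + 1L)]) / 2,
             counts = counts, density = dens)
}

#' Difference of two cylindrical density maps
#'
#' Element-wise rho difference (e.g. dicationic minus single-cation
#' system); carries no normalization claim and may be negative.
#'
#' @param map_a,map_b \code{density_map_rz} objects on identical grids.
#' @return A \code{density_map_rz}-shaped object whose \code{rho} is
#'   \code{map_a$rho - map_b$rho} (counts set to NA).
#' @export
density_difference <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "density_map_rz"), inherits(map_b, "density_map_rz"))
  if (!isTRUE(all.equal(map_a$R_edges, map_b$R_edges)) ||
      !isTRUE(all.equal(map_a$z_edges, map_b$z_edges)))
    stop("density maps have mismatched grids")
  out <- map_a
  out$rho <- map_a$rho - map_b$rho
  out$counts <- matrix(NA_integer_, nrow(map_a$counts), ncol(map_a$counts))
  out$n_ions <- NA_integer_
  out$n_frames <- NA_integer_
  class(out) <- c("density_difference", "density_map_rz")
  out
}

#' Time-averaged 3-D number density grid
#'
#' Voxel values are mean in-voxel ion counts per frame divided by the
#' voxel volume (number density in 1/A^3), the convention under which an
#' isosurface threshold such as 0.1 1/A^3 is meaningful. This differs
#' deliberately from the per-ion-frame probability normalization of
#' \code{\link{density_rz}}.
#'
#' @param traj An \code{\link{ion_trajectory}}.
#' @param origin Grid origin (corner), length-3 (A).
#' @param spacing Voxel edge length (A), scalar or length-3.
#' @param dims Integer length-3 voxel counts per axis.
#' @param species Optional species filter.
#' @return Object of class \code{density_grid3d} with \code{origin},
#'   \code{spacing}, \code{dims} and \code{values} (3-D array, 1/A^3).
#' @export
density_grid3d <- function(traj, origin, spacing, dims, species = NULL) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  dims <- as.integer(rep_len(dims, 3L))
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (any(dims < 1L)) stop("zero-extent grid")
  sel <- if (is.null(species)) seq_len(nrow(traj$ions))
         else which(traj$ions$species %in% species)
  n_f <- length(traj$times)
  counts <- array(0L, dims)
  idx <- sapply(1:3, function(d)
    floor((as.vector(traj$pos[, sel, d]) - origin[d]) / spacing[d]) + 1)
  if (!is.matrix(idx)) idx <- matrix(idx, ncol = 3L)
  ok <- idx[, 1] >= 1L & idx[, 1] <= dims[1] &
        idx[, 2] >= 1L & idx[, 2] <= dims[2] &
        idx[, 3] >= 1L & idx[, 3] <= dims[3]
  if (any(ok)) {
    lin <- (idx[ok, 3] - 1L) * dims[1] * dims[2] +
           (idx[ok, 2] - 1L) * dims[1] + idx[ok, 1]
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- array(tab, dims)
  }
  vox <- prod(spacing)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, values = counts / (n_f * vox),
                 n_frames = n_f),
            class = "density_grid3d")
}

#' Write a 3-D density grid as OpenDX
#'
#' Plain-text OpenDX scalar field readable by standard molecular viewers;
#' values are written in C (z-fastest) order with 6 significant digits.
#'
#' @param grid A \code{\link{density_grid3d}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
export_dx <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid3d"))
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1] + grid$spacing[1] / 2,
            grid$origin[2] + grid$spacing[2] / 2,
            grid$origin[3] + grid$spacing[3] / 2),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing[1]),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing[2]),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX data order: x slowest, z fastest
  flat <- numeric(prod(d))
  k <- 1L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    flat[k:(k + d[3] - 1L)] <- grid$values[i, j, ]
    k <- k + d[3]
  }
  n3 <- (length(flat) %/% 3L) * 3L
  if (n3 > 0) {
    m <- matrix(flat[seq_len(n3)], ncol = 3L, byrow = TRUE)
    writeLines(sprintf("%.6g %.6g %.6g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (length(flat) > n3)
    writeLines(paste(sprintf("%.6g", flat[(n3 + 1L):length(flat)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar grid written by \code{\link{export_dx}}
#'
#' @param path OpenDX file path.
#' @return A \code{\link{density_grid3d}}.
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  g1 <- strsplit(trimws(lines[grep("gridpositions", lines)[1]]), "\\s+")[[1]]
  dims <- as.integer(utils::tail(g1, 3))
  orig_ln <- strsplit(trimws(lines[grep("^origin", lines)[1]]), "\\s+")[[1]]
  center0 <- as.numeric(orig_ln[2:4])
  deltas <- lines[grep("^delta", lines)]
  dmat <- t(sapply(strsplit(trimws(deltas), "\\s+"),
                   function(x) as.numeric(x[2:4])))
  spacing <- diag(dmat)
  data_start <- grep("data follows", lines)[1] + 1L
  n <- prod(dims)
  vals <- numeric(0)
  i <- data_start
  while (length(vals) < n && i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    suppressWarnings(num <- as.numeric(tok))
    if (any(is.na(num))) break
    vals <- c(vals, num)
    i <- i + 1L
  }
  if (length(vals) != n) stop("DX data block has wrong length")
  arr <- array(0, dims)
  k <- 1L
  for (ii in seq_len(dims[1])) for (jj in seq_len(dims[2])) {
    arr[ii, jj, ] <- vals[k:(k + dims[3] - 1L)]
    k <- k + dims[3]
  }
  structure(list(origin = center0 - spacing / 2, spacing = spacing,
                 dims = dims, values = arr, n_frames = NA_integer_),
            class = "density_grid3d")
}

#' Block-wise convergence check of the axial density
#'
#' Computes one axial profile per time window (e.g. overlapping 200-ns
#' blocks) and a scalar discrepancy metric: the maximum sup-norm
#' difference between successive window profiles. A stationary process
#' gives a small metric; a drifting one is flagged by a large value.
#'
#' @inheritParams axial_density
#' @param windows List of \code{c(t_lo, t_hi)} time windows in ns, within
#'   the trajectory span.
#' @return List with \code{profiles} (one data frame per window) and
#'   \code{max_discrepancy}.
#' @export
convergence_blocks <- function(traj, geom, z_edges, windows,
                               species = NULL, r_select = 3) {
  profiles <- lapply(windows, function(w) {
    fr <- which(traj$times >= w[1] & traj$times <= w[2])
    if (!length(fr)) stop("empty window [", w[1], ", ", w[2], "] ns")
    axial_density(traj, geom, z_edges, species = species,
                  r_select = r_select, frames = fr)
  })
  disc <- 0
  if (length(profiles) > 1L) {
    for (i in seq_len(length(profiles) - 1L)) {
      disc <- max(disc, max(abs(profiles[[i + 1]]$density -
                                profiles[[i]]$density)))
    }
  }
  list(profiles = profiles, max_discrepancy = disc)
}
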