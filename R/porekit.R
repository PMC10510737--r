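#' Pore-radius profile from atom coordinates
#'
#' Simplified planar-slice pore profiling: for each z slice, the pore
#' radius is the largest hard-sphere probe radius that fits, found by
#' maximizing over the in-plane probe center c of
#' min over nearby atoms of (|atom_xy - c| - vdW_atom). The optimizer is
#' a multi-start Nelder-Mead seeded at the previous slice's center, the
#' axis, and four fixed lateral offsets, so the profile is deterministic.
#' This planar algorithm matches spherical-probe profilers for straight,
#' roughly axial pores; it does not trace curved axes.
#'
#' @param atoms Data frame with columns \code{x}, \code{y}, \code{z} and
#'   \code{radius} (vdW, A), e.g. from \code{\link{pore_atoms_from_pdb}}.
#' @param z_grid Slice positions along the pore axis (A).
#' @param slice_half_width Half-width of the atom selection window per
#'   slice (A); atoms with \code{|z_atom - z_slice|} below this plus the
#'   maximum vdW radius participate.
#' @param max_radius Cap for slices with no confining atoms
#'   (\code{unbounded} flag set).
#' @return Data frame of class \code{pore_profile}: \code{z_mid},
#'   \code{radius} (floored at 0), \code{cx}, \code{cy}, \code{n_atoms},
#'   \code{unbounded}.
#' @examples
#' th <- 2 * pi * (0:11) / 12
#' ring <- data.frame(x = 5 * cos(th), y = 5 * sin(th), z = 0, radius = 1.5)
#' pore_radius_profile(ring, z_grid = 0)$radius  # ~3.5
#' @export
pore_radius_profile <- function(atoms, z_grid, slice_half_width = 1.5,
                                max_radius = 10) {
  stopifnot(all(c("x", "y", "z", "radius") %in% names(atoms)))
  max_vdw <- max(atoms$radius)
  prev_center <- c(0, 0)
  rows <- lapply(z_grid, function(zs) {
    sel <- abs(atoms$z - zs) <= slice_half_width + max_vdw
    if (!any(sel)) {
      return(data.frame(z_mid = zs, radius = max_radius,
                        cx = prev_center[1], cy = prev_center[2],
                        n_atoms = 0L, unbounded = TRUE))
    }
    ax <- atoms$x[sel]; ay <- atoms$y[sel]; ar <- atoms$radius[sel]
    obj <- function(c2) {
      -(min(sqrt((ax - c2[1])^2 + (ay - c2[2])^2) - ar))
    }
    starts <- rbind(prev_center, c(0, 0),
                    prev_center + c(1, 0), prev_center - c(1, 0),
                    prev_center + c(0, 1), prev_center - c(0, 1))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      fit <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 500))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    r <- min(max(-best$value, 0), max_radius)
    prev_center <<- best$par
    data.frame(z_mid = zs, radius = r, cx = best$par[1], cy = best$par[2],
               n_atoms = sum(sel), unbounded = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' Mean pore profile with per-slice standard deviation
#'
#' Element-wise mean and population standard deviation (divide by n, so
#' two profiles differing by 2 A in a slice give SD 1.0 there) across
#' profiles on identical z grids, e.g. simulation snapshots.
#'
#' @param profiles List of \code{pore_profile} data frames.
#' @return Data frame with \code{z_mid}, \code{radius} (mean), \code{sd}.
#' @export
mean_profile_with_sd <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  z0 <- profiles[[1]]$z_mid
  for (p in profiles) {
    if (!isTRUE(all.equal(p$z_mid, z0))) stop("profiles have mismatched z grids")
  }
  m <- sapply(profiles, `[[`, "radius")
  if (!is.matrix(m)) m <- matrix(m, nrow = length(z0))
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))   # population SD
  data.frame(z_mid = z0, radius = mu, sd = sdv)
}

# built-in vdW radii (A) by element; config-overridable
.vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Extract pore-lining atoms from a PDB file
#'
#' Reads atom coordinates via the bio3d package and attaches vdW radii
#' from a small built-in element table (overridable).
#'
#' @param path PDB file path.
#' @param vdw Named vector of per-element radii overriding the defaults.
#' @return Data frame with \code{x}, \code{y}, \code{z}, \code{radius},
#'   \code{element}.
#' @export
pore_atoms_from_pdb <- function(path, vdw = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("pore_atoms_from_pdb requires the bio3d package")
  tab <- .vdw_table
  if (!is.null(vdw)) tab[names(vdw)] <- vdw
  pdb <- bio3d::read.pdb(path)
  el <- pdb$atom$elesy
  el[is.na(el) | el == ""] <- substr(trimws(pdb$atom$elety[is.na(el) | el == ""]), 1, 1)
  r <- tab[el]
  r[is.na(r)] <- 1.7
  data.frame(x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z,
             radius = unname(r), element = el)
}
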