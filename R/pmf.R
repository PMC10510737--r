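#' Assemble umbrella-sampling windows for WHAM
#'
#' @param windows List of windows, each \code{list(center, k, samples)}
#'   with the harmonic bias center (A), force constant (kJ/mol/A^2,
#'   positive) and the window's z samples (>= 10 per window).
#' @param temperature Temperature in K.
#' @param periodic If TRUE the reaction coordinate is cyclic with the
#'   given \code{period} and bias distances wrap by minimum image.
#' @param period Period (box length) in A, required when periodic.
#' @return Object of class \code{wham_input}. Warns when adjacent windows
#'   share no histogram support (zero overlap).
#' @export
wham_input <- function(windows, temperature = 310, periodic = FALSE,
                       period = NULL) {
  stopifnot(length(windows) >= 1L)
  for (w in windows) {
    if (w$k <= 0) stop("window force constants must be positive")
    if (length(w$samples) < 10L)
      stop("every window needs at least 10 samples")
  }
  if (periodic && (is.null(period) || period <= 0))
    stop("periodic mode requires a positive period")
  centers <- vapply(windows, `[[`, 0, "center")
  if (length(centers) > 2L) {
    for (i in seq_len(length(centers) - 1L)) {
      a <- range(windows[[i]]$samples)
      b <- range(windows[[i + 1]]$samples)
      if (a[2] < b[1] || b[2] < a[1])
        warning(sprintf("windows %d and %d have no histogram overlap", i, i + 1))
    }
  }
  structure(list(windows = windows, temperature = temperature,
                 periodic = periodic, period = period),
            class = "wham_input")
}

.logsumexp <- function(m) {
  # column-wise logsumexp of a matrix
  mx <- apply(m, 2L, max)
  mx + log(colSums(exp(sweep(m, 2L, mx))))
}

#' Weighted histogram analysis (WHAM) of umbrella windows
#'
#' Standard self-consistent WHAM: iterate the window free energies f_k
#' and the consensus density until \code{max |delta f_k| < tol}, then
#' G(z) = -kT log rho(z) plus an anchor shift. In periodic mode the bias
#' distance to each window center wraps by minimum image over the
#' period. The result is invariant (within tol) to adding a constant to
#' all window biases. Bins never visited by any window are masked (NA).
#'
#' @param input A \code{\link{wham_input}}.
#' @param grid Bin edges for the reaction coordinate; by default ~0.2 A
#'   bins spanning the sampled range (or the full period when periodic).
#' @param tol Convergence tolerance on the window free energies, kJ/mol.
#' @param max_iter Maximum iterations; non-convergence is an error
#'   reporting the residual.
#' @param reference Optional \code{c(lo, hi)} interval; the mean G over
#'   it is shifted to zero (bulk anchoring). Default anchors min(G) = 0.
#' @return Object of class \code{pmf_profile}: \code{z_mid}, \code{G}
#'   (kJ/mol), \code{sd} (NA until bootstrapped), plus the converged
#'   window free energies \code{f} and iteration count.
#' @export
wham <- function(input, grid = NULL, tol = 1e-8, max_iter = 100000L,
                 reference = NULL) {
  stopifnot(inherits(input, "wham_input"))
  kT <- .kB * input$temperature
  K <- length(input$windows)
  if (is.null(grid)) {
    if (input$periodic) {
      grid <- seq(-input$period / 2, input$period / 2,
                  length.out = max(25L, ceiling(input$period / 0.2)) + 1L)
    } else {
      rng <- range(unlist(lapply(input$windows, `[[`, "samples")))
      grid <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out =
                    max(25L, ceiling(diff(rng) / 0.2)))
    }
  }
  nb <- length(grid) - 1L
  mid <- (grid[-1] + grid[-(nb + 1L)]) / 2
  dz <- diff(grid)
  wrap <- function(d) if (input$periodic)
    d - input$period * round(d / input$period) else d
  n_j <- numeric(nb)
  N_k <- numeric(K)
  for (k in seq_len(K)) {
    s <- input$windows[[k]]$samples
    gc <- (grid[1] + grid[nb + 1L]) / 2
    if (input$periodic) s <- wrap(s - gc) + gc  # fold into grid span
    idx <- findInterval(s, grid, rightmost.closed = TRUE)
    idx <- idx[idx >= 1L & idx <= nb]
    n_j <- n_j + tabulate(idx, nbins = nb)
    N_k[k] <- length(input$windows[[k]]$samples)
  }
  # bias matrix B[k, j], kJ/mol
  B <- matrix(0, K, nb)
  for (k in seq_len(K)) {
    w <- input$windows[[k]]
    B[k, ] <- 0.5 * w$k * wrap(mid - w$center)^2
  }
  logNe <- log(N_k)       # K
  negBb <- -B / kT        # K x nb
  f <- numeric(K)         # window free energies, kJ/mol
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # log denominator per bin: logsumexp_k [log N_k + (f_k - B_kj)/kT]
    Lden <- .logsumexp(negBb + (logNe + f / kT))
    log_rho <- ifelse(n_j > 0, log(n_j) - Lden, -Inf)
    # f_k = -kT log sum_j rho_j dz_j exp(-B_kj/kT)
    lw <- sweep(negBb, 2L, log_rho + log(dz), `+`)
    mx <- apply(lw, 1L, max)
    f_new <- -kT * (mx + log(rowSums(exp(lw - mx))))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf("WHAM failed to converge in %d iterations (residual %.3g kJ/mol)",
                   max_iter, delta))
  }
  G <- ifelse(is.finite(log_rho), -kT * log_rho, NA_real_)
  if (!is.null(reference)) {
    in_ref <- mid >= reference[1] & mid <= reference[2]
    if (!any(in_ref & !is.na(G)))
      stop("reference interval contains no resolved bins")
    G <- G - mean(G[in_ref], na.rm = TRUE)
  } else {
    G <- G - min(G, na.rm = TRUE)
  }
  structure(list(z_mid = mid, G = G, sd = rep(NA_real_, nb),
                 grid = grid, f = f, counts = n_j, iterations = iter,
                 temperature = input$temperature,
                 periodic = input$periodic, reference = reference),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("pmf_profile: %d bins over [%.2f, %.2f] A, %d WHAM iterations\n",
              length(x$z_mid), min(x$grid), max(x$grid), x$iterations))
  cat(sprintf("  G range: [%.2f, %.2f] kJ/mol%s\n",
              min(x$G, na.rm = TRUE), max(x$G, na.rm = TRUE),
              if (any(!is.na(x$sd))) " (bootstrap sd attached)" else ""))
  invisible(x)
}

#' Bootstrap uncertainties for a WHAM profile
#'
#' Resamples each window's samples with replacement (window identity
#' preserved), reruns WHAM, and reports the per-bin standard deviation
#' over resamples. Seeded and reproducible. WHAM failures among
#' resamples are tolerated up to 10%.
#'
#' @param input A \code{\link{wham_input}}.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @param ... Passed to \code{\link{wham}} (grid, tol, reference, ...).
#' @return A \code{pmf_profile} (the full-data solution) whose \code{sd}
#'   holds the bootstrap standard deviation per bin.
#' @export
bootstrap_pmf <- function(input, n_boot = 100L, seed = 1L, ...) {
  stopifnot(n_boot >= 2L)
  base <- wham(input, ...)
  dots <- list(...)
  dots$grid <- base$grid   # resamples share the full-data grid
  set.seed(seed)
  Gs <- matrix(NA_real_, length(base$z_mid), n_boot)
  failures <- 0L
  for (b in seq_len(n_boot)) {
    wb <- lapply(input$windows, function(w) {
      w$samples <- sample(w$samples, length(w$samples), replace = TRUE)
      w
    })
    ib <- structure(list(windows = wb, temperature = input$temperature,
                         periodic = input$periodic, period = input$period),
                    class = "wham_input")
    res <- tryCatch(do.call(wham, c(list(ib), dots)),
                    error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else Gs[, b] <- res$G
  }
  if (failures > 0.1 * n_boot)
    stop(sprintf("%d of %d bootstrap WHAM runs failed", failures, n_boot))
  base$sd <- apply(Gs, 1L, stats::sd, na.rm = TRUE)
  base$n_boot <- n_boot
  base
}

#' Well depth of a PMF relative to a reference plateau
#'
#' Minimum G over the well interval minus mean G over the reference
#' (bulk) interval; negative values mean binding.
#'
#' @param profile A \code{pmf_profile}.
#' @param well_interval \code{c(lo, hi)} interval containing the well (A).
#' @param reference_interval \code{c(lo, hi)} bulk interval (A).
#' @return Depth in kJ/mol.
#' @export
well_depth <- function(profile, well_interval, reference_interval) {
  stopifnot(inherits(profile, "pmf_profile"))
  in_well <- profile$z_mid >= well_interval[1] & profile$z_mid <= well_interval[2]
  in_ref <- profile$z_mid >= reference_interval[1] &
            profile$z_mid <= reference_interval[2]
  if (!any(in_well)) stop("well interval outside the profile support")
  if (!any(in_ref)) stop("reference interval outside the profile support")
  if (any(is.na(profile$G[in_well])))
    stop("masked (unresolved) bins span the well interval")
  min(profile$G[in_well]) - mean(profile$G[in_ref], na.rm = TRUE)
}

#' Binding preference between two species from their well depths
#'
#' ddE_bind = depth_b - depth_a; positive means species a binds more
#' strongly (its well is deeper, i.e. more negative).
#'
#' @param depth_a,depth_b Well depths in kJ/mol (negative = binding),
#'   e.g. the divalent and monovalent species.
#' @return ddE in kJ/mol.
#' @examples
#' binding_preference(-213.5, -121.9)  # 91.6
#' @export
binding_preference <- function(depth_a, depth_b) {
  stopifnot(is.finite(depth_a), is.finite(depth_b))
  depth_b - depth_a
}

#' Write a PMF profile as TSV
#'
#' Columns z, G, sd; compatible with generic xy-plotters.
#'
#' @param profile A \code{pmf_profile}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pmf <- function(profile, path) {
  utils::write.table(
    data.frame(z = profile$z_mid, G = profile$G, sd = profile$sd),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
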