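#' Non-negative least squares
#'
#' Solves `min ||basis %*% x - signal||^2` subject to `x >= 0` with the
#' Lawson-Hanson active-set algorithm, returning the exact constrained
#' minimizer (certified by the Karush-Kuhn-Tucker conditions: the gradient
#' is ~0 on positive coefficients and >= 0 on zero ones).
#'
#' @param basis Numeric matrix (rows = echoes) or a `decay_basis`.
#' @param signal Numeric vector, length `nrow(basis)`.
#' @param tol Relative dual tolerance.
#' @return Non-negative coefficient vector of length `ncol(basis)`.
#' @export
nnls_solve <- function(basis, signal, tol = 1e-10) {
  A <- if (inherits(basis, "decay_basis")) basis$matrix else as.matrix(basis)
  if (length(signal) != nrow(A))
    stop_param("signal length must equal the number of basis rows")
  if (all(signal == 0)) return(numeric(ncol(A)))
  as.numeric(.nnls_cpp(A, as.numeric(signal), tol))
}

#' Tikhonov-regularized NNLS with a chi-square window criterion
#'
#' Solves `min ||A x - b||^2 + mu^2 ||x||^2, x >= 0` through the augmented
#' stacked system `[A; mu I] x = [b; 0]`, choosing `mu` by bisection on
#' `log(mu)` so that the misfit ratio `chi2(mu) / chi2(0)` lands inside
#' `chi2_window`. The misfit is a continuous non-decreasing function of
#' `mu`, so the bisection is well posed. Degenerate inputs (zero signal, or
#' an essentially exact unregularized fit for which any `mu > 0` overshoots
#' the window) return the unregularized solution with `mu = 0`, flagged.
#'
#' @param basis Numeric matrix or `decay_basis`.
#' @param signal Numeric vector of echo amplitudes.
#' @param chi2_window Length-2 vector `(low, high)`, `1 < low < high`.
#' @param max_iter Maximum bisection steps.
#' @return List with `coefficients`, `mu`, `chi2` (misfit at the returned
#'   solution), `chi2_unreg`, `chi2_ratio`, and `flag` (`"ok"`,
#'   `"degenerate"` or `"window_missed"`).
#' @export
regularized_nnls <- function(basis, signal, chi2_window = c(1.02, 1.025),
                             max_iter = 100L) {
  A <- if (inherits(basis, "decay_basis")) basis$matrix else as.matrix(basis)
  signal <- as.numeric(signal)
  if (length(signal) != nrow(A))
    stop_param("signal length must equal the number of basis rows")
  if (length(chi2_window) != 2L || chi2_window[1] <= 1 ||
      chi2_window[2] <= chi2_window[1])
    stop_param("chi2_window must satisfy 1 < low < high")

  misfit <- function(x) sum((A %*% x - signal)^2)
  solve_mu <- function(mu) {
    Aaug <- rbind(A, diag(mu, ncol(A)))
    baug <- c(signal, numeric(ncol(A)))
    nnls_solve(Aaug, baug)
  }

  x0 <- nnls_solve(A, signal)
  chi0 <- misfit(x0)
  out0 <- list(coefficients = x0, mu = 0, chi2 = chi0, chi2_unreg = chi0,
               chi2_ratio = 1, flag = "degenerate")
  if (all(signal == 0)) {
    out0$chi2_ratio <- NA_real_
    return(out0)
  }
  # essentially exact fit: any positive mu overshoots the narrow window
  if (chi0 <= 1e-18 * sum(signal^2)) return(out0)

  ratio_of <- function(x) misfit(x) / chi0
  # bracket: grow mu until the ratio exceeds the window top
  mu_lo <- 1e-8 * max(abs(signal))
  x_lo <- solve_mu(mu_lo)
  r_lo <- ratio_of(x_lo)
  if (r_lo > chi2_window[2]) {
    out0$flag <- "degenerate"
    return(out0)
  }
  mu_hi <- mu_lo
  r_hi <- r_lo
  x_hi <- x_lo
  for (i in seq_len(60L)) {
    mu_hi <- mu_hi * 4
    x_hi <- solve_mu(mu_hi)
    r_hi <- ratio_of(x_hi)
    if (r_hi >= chi2_window[1]) break
  }
  best <- list(x = x_hi, mu = mu_hi, r = r_hi)
  if (r_hi >= chi2_window[1] && r_hi <= chi2_window[2]) {
    return(list(coefficients = best$x, mu = best$mu, chi2 = r_hi * chi0,
                chi2_unreg = chi0, chi2_ratio = r_hi, flag = "ok"))
  }
  target <- mean(chi2_window)
  for (i in seq_len(max_iter)) {
    mu_mid <- sqrt(mu_lo * mu_hi)
    x_mid <- solve_mu(mu_mid)
    r_mid <- ratio_of(x_mid)
    if (abs(r_mid - target) < abs(best$r - target))
      best <- list(x = x_mid, mu = mu_mid, r = r_mid)
    if (r_mid >= chi2_window[1] && r_mid <= chi2_window[2]) {
      return(list(coefficients = x_mid, mu = mu_mid, chi2 = r_mid * chi0,
                  chi2_unreg = chi0, chi2_ratio = r_mid, flag = "ok"))
    }
    if (r_mid < chi2_window[1]) mu_lo <- mu_mid else mu_hi <- mu_mid
  }
  list(coefficients = best$x, mu = best$mu, chi2 = best$r * chi0,
       chi2_unreg = chi0, chi2_ratio = best$r, flag = "window_missed")
}

#' Fit the refocusing flip angle of one voxel
#'
#' Finds the flip angle alpha whose EPG decay basis best explains the echo
#' train in the unregularized NNLS sense: a coarse scan over
#' `n_coarse` equispaced angles in `alpha_range`, then golden-section
#' refinement of the bracketing interval down to `tol` degrees. Run before
#' regularization and held fixed afterwards.
#'
#' @param signal Echo amplitude vector.
#' @param params `sequence_params` (its `refocus_deg` is ignored).
#' @param grid `t2_grid` on which candidate bases are built.
#' @param alpha_range Search range in degrees, within [90, 180].
#' @param n_coarse Number of coarse-scan angles.
#' @param tol Refinement precision in degrees.
#' @param coarse_bases Optional precomputed list of `decay_basis` objects at
#'   the coarse angles (shared across voxels; results are identical to
#'   recomputation).
#' @return List with `flip_deg`, `chi2` at the optimum, and `flag`
#'   (`"ok"` or `"flat"` for an all-zero signal, where the range midpoint is
#'   returned).
#' @export
estimate_flip_angle <- function(signal, params, grid,
                                alpha_range = c(90, 180), n_coarse = 8L,
                                tol = 0.5, coarse_bases = NULL) {
  if (alpha_range[1] < 90 || alpha_range[2] > 180 ||
      alpha_range[1] >= alpha_range[2])
    stop_param("alpha_range must lie within [90, 180]")
  signal <- as.numeric(signal)
  if (all(signal == 0)) {
    return(list(flip_deg = mean(alpha_range), chi2 = 0, flag = "flat"))
  }
  angles <- seq(alpha_range[1], alpha_range[2], length.out = n_coarse)
  basis_at <- function(alpha) {
    p <- params
    p$refocus_deg <- alpha
    .epg_basis_cpp(grid$values, alpha, p$n_echoes, p$echo_spacing,
                   p$t1_assumed)
  }
  chi2_at <- function(A) {
    x <- nnls_solve(A, signal)
    sum((A %*% x - signal)^2)
  }
  if (is.null(coarse_bases)) coarse_bases <- lapply(angles, basis_at)
  coarse_chi2 <- vapply(coarse_bases, function(b) {
    A <- if (inherits(b, "decay_basis")) b$matrix else b
    chi2_at(A)
  }, numeric(1))
  i <- which.min(coarse_chi2)
  lo <- angles[max(i - 1L, 1L)]
  hi <- angles[min(i + 1L, n_coarse)]
  # golden-section search on [lo, hi]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- chi2_at(basis_at(x1)); f2 <- chi2_at(basis_at(x2))
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- chi2_at(basis_at(x1))
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- chi2_at(basis_at(x2))
    }
  }
  alpha_hat <- if (f1 <= f2) x1 else x2
  chi2_hat <- min(f1, f2)
  # keep the coarse-scan winner if refinement did not beat it (flat edges)
  if (coarse_chi2[i] < chi2_hat) {
    alpha_hat <- angles[i]
    chi2_hat <- coarse_chi2[i]
  }
  list(flip_deg = alpha_hat, chi2 = chi2_hat, flag = "ok")
}

#' Fitting configuration
#'
#' @param chi2_window Misfit-ratio window for the regularization search.
#' @param alpha_range Flip-angle search range in degrees.
#' @param n_coarse_alpha Coarse flip-angle scan size.
#' @param alpha_tol Flip-angle refinement precision, degrees.
#' @param snr_cap Ceiling applied when the residual standard deviation is 0.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(chi2_window = c(1.02, 1.025),
                       alpha_range = c(90, 180), n_coarse_alpha = 8L,
                       alpha_tol = 0.5, snr_cap = 1e6) {
  structure(list(chi2_window = chi2_window, alpha_range = alpha_range,
                 n_coarse_alpha = as.integer(n_coarse_alpha),
                 alpha_tol = alpha_tol, snr_cap = snr_cap),
            class = "fit_config")
}

#' Fit one voxel's T2 spectrum
#'
#' Full voxel pipeline: estimate the refocusing flip angle, build the EPG
#' basis at that angle, solve the regularized NNLS inversion, and derive
#' residual diagnostics. The voxelwise SNR is the sum of the spectral
#' amplitudes divided by the standard deviation of the fit residual.
#'
#' @param signal Echo amplitude vector (non-negative magnitude data).
#' @param params `sequence_params`.
#' @param grid `t2_grid`.
#' @param config `fit_config`.
#' @param coarse_bases Optional precomputed coarse-angle bases.
#' @return List of class `voxel_fit`: `spectrum` (amplitudes on the grid),
#'   `grid`, `flip_deg`, `residuals`, `chi2`, `mu`, `snr`, `background`,
#'   `flags`.
#' @export
fit_voxel <- function(signal, params, grid, config = fit_config(),
                      coarse_bases = NULL) {
  signal <- as.numeric(signal)
  if (length(signal) != params$n_echoes)
    stop_param("signal length must equal params$n_echoes")
  if (any(signal < 0))
    stop_param("magnitude signal must be non-negative")
  if (all(signal == 0)) {
    return(structure(list(
      spectrum = numeric(length(grid$values)), grid = grid,
      flip_deg = NA_real_, residuals = numeric(params$n_echoes),
      chi2 = 0, mu = 0, chi2_ratio = NA_real_, snr = 0, background = TRUE,
      flags = "background"), class = "voxel_fit"))
  }
  af <- estimate_flip_angle(signal, params, grid,
                            alpha_range = config$alpha_range,
                            n_coarse = config$n_coarse_alpha,
                            tol = config$alpha_tol,
                            coarse_bases = coarse_bases)
  p <- params
  p$refocus_deg <- af$flip_deg
  basis <- build_decay_basis(grid, p)
  reg <- regularized_nnls(basis, signal, chi2_window = config$chi2_window)
  res <- as.numeric(signal - basis$matrix %*% reg$coefficients)
  s <- sd(res)
  snr <- if (is.na(s) || s == 0) config$snr_cap
         else min(sum(reg$coefficients) / s, config$snr_cap)
  structure(list(
    spectrum = reg$coefficients, grid = grid, flip_deg = af$flip_deg,
    residuals = res, chi2 = sum(res^2), mu = reg$mu,
    chi2_ratio = reg$chi2_ratio, snr = snr, background = FALSE,
    flags = if (reg$flag == "ok") character(0) else reg$flag),
    class = "voxel_fit")
}

#' Fit every in-mask voxel of a 4-D echo volume
#'
#' Applies [fit_voxel()] to each voxel where `mask` is `TRUE`; out-of-mask
#' voxels carry a background result. Coarse flip-angle bases are precomputed
#' once and shared across voxels (identical results to per-voxel
#' recomputation, since the basis depends only on the angle).
#'
#' @param echo_volume 4-D array, echoes along the 4th dimension.
#' @param mask 3-D logical array matching the spatial dimensions.
#' @param params `sequence_params`.
#' @param grid `t2_grid`.
#' @param config `fit_config`.
#' @param verbose Log progress every `verbose` voxels (0 = silent).
#' @return Object of class `volume_fit`: `dim` (spatial), `grid`, `params`,
#'   `voxels` (matrix of in-mask voxel indices), `spectra`
#'   (n_voxels x n_grid), `flip_deg`, `chi2`, `mu`, `snr`, `residual_sd`
#'   vectors, `background` 3-D array, `flags`.
#' @export
fit_volume <- function(echo_volume, mask, params, grid,
                       config = fit_config(), verbose = 0L) {
  dm <- dim(echo_volume)
  if (length(dm) != 4L || dm[4] != params$n_echoes)
    stop_param("echo_volume must be 4-D with n_echoes along dimension 4")
  if (!identical(dim(mask), dm[1:3]))
    stop_param("mask shape must equal the spatial shape of echo_volume")
  angles <- seq(config$alpha_range[1], config$alpha_range[2],
                length.out = config$n_coarse_alpha)
  coarse_bases <- lapply(angles, function(a)
    .epg_basis_cpp(grid$values, a, params$n_echoes, params$echo_spacing,
                   params$t1_assumed))
  idx <- which(mask)
  nvox <- length(idx)
  ng <- length(grid$values)
  nspat <- prod(dm[1:3])
  sig_mat <- matrix(echo_volume, nrow = nspat, ncol = dm[4])
  spectra <- matrix(0, nvox, ng)
  flip <- chi2 <- mu <- snr <- rsd <- ratio <- rep(NA_real_, nvox)
  flags <- character(nvox)
  background <- array(TRUE, dm[1:3])
  for (v in seq_len(nvox)) {
    fit <- fit_voxel(sig_mat[idx[v], ], params, grid, config,
                     coarse_bases = coarse_bases)
    spectra[v, ] <- fit$spectrum
    flip[v] <- fit$flip_deg
    chi2[v] <- fit$chi2
    mu[v] <- fit$mu
    ratio[v] <- fit$chi2_ratio
    snr[v] <- fit$snr
    rsd[v] <- sd(fit$residuals)
    flags[v] <- paste(fit$flags, collapse = ";")
    background[idx[v]] <- fit$background
    if (verbose > 0L && v %% verbose == 0L)
      message(sprintf("fit_volume: %d / %d voxels", v, nvox))
  }
  structure(list(dim = dm[1:3], grid = grid, params = params,
                 voxels = idx, spectra = spectra, flip_deg = flip,
                 chi2 = chi2, mu = mu, chi2_ratio = ratio, snr = snr,
                 residual_sd = rsd,
                 background = background, flags = flags),
            class = "volume_fit")
}

#' @export
print.volume_fit <- function(x, ...) {
  cat(sprintf("volume_fit: %d voxels fitted in a %s volume, %d-point grid\n",
              length(x$voxels), paste(x$dim, collapse = "x"),
              length(x$grid$values)))
  invisible(x)
}
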