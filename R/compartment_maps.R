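#' Water-pool boundaries on the T2 axis
#'
#' Spectral mass below `mw_upper` is myelin water (Mw), between `mw_upper`
#' and `fw_lower` intra/extracellular water (IEw), above `fw_lower`
#' cerebrospinal-fluid-like free water (Fw). Edge convention: the Mw window
#' is half-open `[grid_min, mw_upper)`, the IEw window closed
#' `[mw_upper, fw_lower]`, the Fw window open `(fw_lower, grid_max]`; grid
#' points rarely sit exactly on a boundary, and the convention is fixed and
#' tested.
#'
#' @param mw_upper Mw/IEw boundary, ms (default 40).
#' @param fw_lower IEw/Fw boundary, ms (default 250).
#' @return List of class `compartment_boundaries`.
#' @export
compartment_boundaries <- function(mw_upper = 40, fw_lower = 250) {
  if (!is.finite(mw_upper) || !is.finite(fw_lower) || mw_upper <= 0 ||
      fw_lower <= mw_upper)
    stop_param("need 0 < mw_upper < fw_lower")
  structure(list(mw_upper = mw_upper, fw_lower = fw_lower),
            class = "compartment_boundaries")
}

#' Reduce one spectrum to three-pool fractions and T2-IEw
#'
#' Window masses are sums of spectral amplitudes over the three T2 windows;
#' fractions are masses normalized to the total spectral mass (so
#' Mw + IEw + Fw = 1 in every non-background voxel). The IEw T2 (T2-IEw) is
#' the amplitude-weighted geometric mean T2 over the IEw window,
#' `exp(sum(a * log(T2)) / sum(a))`; it is undefined (NA) when the window is
#' empty. Pool T2 times for Mw and Fw are deliberately not estimated: the
#' sampled echo times do not constrain them.
#'
#' @param spectrum Non-negative amplitude vector on `grid$values`, or a
#'   `voxel_fit`.
#' @param grid `t2_grid` (ignored when `spectrum` is a `voxel_fit`).
#' @param boundaries `compartment_boundaries`.
#' @return List with `mw`, `iew`, `fw` (fractions), `t2_iew` (ms, NA when
#'   undefined) and `background` (TRUE when the spectrum has zero mass).
#' @export
compartmentalize <- function(spectrum, grid = NULL,
                             boundaries = compartment_boundaries()) {
  if (inherits(spectrum, "voxel_fit")) {
    grid <- spectrum$grid
    spectrum <- spectrum$spectrum
  }
  if (is.null(grid)) stop_param("grid is required for a bare spectrum")
  t2 <- grid$values
  a <- as.numeric(spectrum)
  if (length(a) != length(t2))
    stop_param("spectrum length must equal grid length")
  if (any(a < 0)) stop_param("spectral amplitudes must be non-negative")
  total <- sum(a)
  if (total == 0) {
    return(list(mw = NA_real_, iew = NA_real_, fw = NA_real_,
                t2_iew = NA_real_, background = TRUE))
  }
  in_mw <- t2 < boundaries$mw_upper
  in_iew <- t2 >= boundaries$mw_upper & t2 <= boundaries$fw_lower
  in_fw <- t2 > boundaries$fw_lower
  iew_mass <- sum(a[in_iew])
  t2_iew <- if (iew_mass > 0)
    exp(sum(a[in_iew] * log(t2[in_iew])) / iew_mass) else NA_real_
  list(mw = sum(a[in_mw]) / total, iew = iew_mass / total,
       fw = sum(a[in_fw]) / total, t2_iew = t2_iew, background = FALSE)
}

#' Voxelwise SNR of a spectrum fit
#'
#' Sum of the spectral amplitudes divided by the sample standard deviation
#' of the fit residual. A zero residual (perfect fit) is capped at `cap`.
#'
#' @param spectrum Amplitude vector.
#' @param residuals Signed per-echo residual vector.
#' @param cap Ceiling for degenerate (zero-residual) fits.
#' @return Scalar SNR (0 for a zero spectrum).
#' @export
snr_of_fit <- function(spectrum, residuals, cap = 1e6) {
  total <- sum(spectrum)
  if (total == 0) return(0)
  s <- sd(residuals)
  if (is.na(s) || s == 0) return(cap)
  min(total / s, cap)
}

#' Assemble 3-D quantitative maps from a fitted volume
#'
#' Applies [compartmentalize()] per fitted voxel and collects the Mw, IEw,
#' Fw fraction maps, the T2-IEw map, the SNR map and the flip-angle map.
#'
#' @param fit A `volume_fit` from [fit_volume()].
#' @param boundaries `compartment_boundaries`.
#' @return Object of class `compartment_maps`: 3-D arrays `mw_frac`,
#'   `iew_frac`, `fw_frac`, `t2_iew`, `snr`, `flip_deg`, logical
#'   `background`, plus `grid` and `boundaries`. Background voxels are NA in
#'   every metric map (SNR 0).
#' @export
assemble_maps <- function(fit, boundaries = compartment_boundaries()) {
  if (!inherits(fit, "volume_fit")) stop_param("fit must be a volume_fit")
  dm <- fit$dim
  empty <- array(NA_real_, dm)
  maps <- list(mw_frac = empty, iew_frac = empty, fw_frac = empty,
               t2_iew = empty, snr = array(0, dm), flip_deg = empty,
               background = fit$background, grid = fit$grid,
               boundaries = boundaries)
  for (v in seq_along(fit$voxels)) {
    i <- fit$voxels[v]
    comp <- compartmentalize(fit$spectra[v, ], fit$grid, boundaries)
    if (!comp$background) {
      maps$mw_frac[i] <- comp$mw
      maps$iew_frac[i] <- comp$iew
      maps$fw_frac[i] <- comp$fw
      maps$t2_iew[i] <- comp$t2_iew
      maps$flip_deg[i] <- fit$flip_deg[v]
      maps$snr[i] <- fit$snr[v]
    }
  }
  structure(maps, class = "compartment_maps")
}

#' @export
print.compartment_maps <- function(x, ...) {
  nb <- sum(!x$background)
  cat(sprintf("compartment_maps: %s volume, %d non-background voxels\n",
              paste(dim(x$background), collapse = "x"), nb))
  if (nb > 0) {
    ok <- !x$background
    cat(sprintf("  median Mw %.3f | IEw %.3f | Fw %.3f | T2-IEw %.1f ms\n",
                median(x$mw_frac[ok]), median(x$iew_frac[ok]),
                median(x$fw_frac[ok]), median(x$t2_iew[ok], na.rm = TRUE)))
  }
  invisible(x)
}

#' Write compartment maps as NIfTI files
#'
#' One 3-D volume per metric (`mw.nii.gz`, `iew.nii.gz`, `fw.nii.gz`,
#' `t2_iew.nii.gz`, `snr.nii.gz`, `flip.nii.gz`) in `dir`; names are fixed
#' for downstream stages. Background voxels are written as 0.
#'
#' @param maps `compartment_maps`.
#' @param dir Output directory (created if missing).
#' @param voxel_size Voxel edge lengths (dx, dy, dz) in mm.
#' @return Invisibly, the vector of file paths.
#' @export
write_maps <- function(maps, dir, voxel_size = c(1.64, 1.64, 2.5)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(mw_frac = "mw.nii.gz", iew_frac = "iew.nii.gz",
             fw_frac = "fw.nii.gz", t2_iew = "t2_iew.nii.gz",
             snr = "snr.nii.gz", flip_deg = "flip.nii.gz")
  paths <- character(0)
  for (metric in names(files)) {
    arr <- maps[[metric]]
    arr[is.na(arr)] <- 0
    p <- file.path(dir, files[[metric]])
    write_nifti(arr, p, voxel_size = voxel_size)
    paths <- c(paths, p)
  }
  invisible(paths)
}
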