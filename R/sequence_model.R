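#' Multi-echo spin-echo sequence parameters
#'
#' Describes a CPMG-like multi-echo train: number of echoes, echo spacing,
#' the longitudinal relaxation time assumed by the signal model, and the
#' excitation/refocusing flip angles. Defaults mirror a 32-echo GraSE
#' acquisition with 10 ms spacing and TR 1000 ms; the assumed T1 of 1000 ms
#' is a convention (echo amplitudes are nearly insensitive to it at
#' refocusing angles close to 180 degrees).
#'
#' @param n_echoes Number of echoes (>= 1).
#' @param echo_spacing Echo spacing in ms (> 0).
#' @param t1_assumed Longitudinal relaxation time assumed by the EPG model,
#'   ms (> 0).
#' @param excitation_deg Excitation flip angle, degrees (fixed at 90).
#' @param refocus_deg Refocusing flip angle alpha, degrees, in (0, 180].
#' @return An object of class `sequence_params`.
#' @export
#' @examples
#' p <- sequence_params()
#' epg_echo_amplitudes(100, p)[1:4]
sequence_params <- function(n_echoes = 32L, echo_spacing = 10,
                            t1_assumed = 1000, excitation_deg = 90,
                            refocus_deg = 180) {
  n_echoes <- as.integer(n_echoes)
  if (length(n_echoes) != 1L || is.na(n_echoes) || n_echoes < 1L)
    stop_param("n_echoes must be a single integer >= 1")
  if (!is.finite(echo_spacing) || echo_spacing <= 0)
    stop_param("echo_spacing must be > 0")
  if (!is.finite(t1_assumed) || t1_assumed <= 0)
    stop_param("t1_assumed must be > 0")
  if (!isTRUE(all.equal(excitation_deg, 90)))
    stop_param("excitation_deg is fixed at 90 degrees")
  if (!is.finite(refocus_deg) || refocus_deg <= 0 || refocus_deg > 180)
    stop_param("refocus_deg must lie in (0, 180]")
  structure(
    list(n_echoes = n_echoes, echo_spacing = echo_spacing,
         t1_assumed = t1_assumed, excitation_deg = 90,
         refocus_deg = refocus_deg),
    class = "sequence_params")
}

#' @export
print.sequence_params <- function(x, ...) {
  cat(sprintf(
    "sequence_params: %d echoes, spacing %g ms (TE %g-%g ms), T1 %g ms, alpha %g deg\n",
    x$n_echoes, x$echo_spacing, x$echo_spacing,
    x$n_echoes * x$echo_spacing, x$t1_assumed, x$refocus_deg))
  invisible(x)
}

#' Echo times of a sequence
#' @param params A `sequence_params` object.
#' @return Echo times in ms.
#' @export
echo_times <- function(params) {
  params$echo_spacing * seq_len(params$n_echoes)
}

#' Logarithmically spaced T2 grid
#'
#' The grid on which T2 spectra are estimated. The default spans 8-2000 ms
#' with 40 points: wide enough that spectral mass below the shortest sampled
#' echo time (myelin water) and above the longest (free water) has edge
#' bins to be absorbed into, even though T2 *times* in those edge windows are
#' not individually accurate.
#'
#' @param n Number of grid points (>= 2).
#' @param t2_min,t2_max Grid bounds in ms (0 < t2_min < t2_max).
#' @return An object of class `t2_grid` with elements `values` and `bounds`.
#' @export
t2_grid <- function(n = 40L, t2_min = 8, t2_max = 2000) {
  n <- as.integer(n)
  if (n < 2L) stop_param("t2 grid needs at least 2 points")
  if (!is.finite(t2_min) || !is.finite(t2_max) || t2_min <= 0 ||
      t2_max <= t2_min)
    stop_param("need 0 < t2_min < t2_max")
  structure(
    list(values = exp(seq(log(t2_min), log(t2_max), length.out = n)),
         bounds = c(t2_min, t2_max)),
    class = "t2_grid")
}

#' @export
print.t2_grid <- function(x, ...) {
  cat(sprintf("t2_grid: %d log-spaced points, %g-%g ms\n",
              length(x$values), x$bounds[1], x$bounds[2]))
  invisible(x)
}

#' EPG echo amplitudes for one T2 species
#'
#' Computes the amplitudes of the spin/stimulated-echo train of a single-T2
#' species under a CPMG sequence with refocusing flip angle
#' `params$refocus_deg`, via the extended-phase-graph (EPG) recursion. At
#' exactly 180 degrees this collapses to pure mono-exponential decay
#' `exp(-TE_n / T2)`; below 180 degrees stimulated-echo pathways redistribute
#' signal between echoes (odd echoes attenuated, even echoes partially
#' rebuilt), which is the effect the flip-angle fit corrects for.
#'
#' @param t2 Transverse relaxation time in ms (> 0).
#' @param params A `sequence_params` object (alpha taken from
#'   `params$refocus_deg`).
#' @return Numeric vector of `params$n_echoes` echo amplitudes in (0, 1],
#'   for unit equilibrium magnetization.
#' @export
epg_echo_amplitudes <- function(t2, params) {
  if (!inherits(params, "sequence_params"))
    stop_param("params must be a sequence_params object")
  if (length(t2) != 1L || !is.finite(t2) || t2 <= 0)
    stop_param("t2 must be a single positive time in ms")
  as.numeric(.epg_cpmg_cpp(t2, params$refocus_deg, params$n_echoes,
                           params$echo_spacing, params$t1_assumed))
}

#' Decay-basis matrix over a T2 grid
#'
#' Assembles the n_echoes x n_grid matrix whose column j holds the EPG echo
#' amplitudes of grid T2 j; the voxel signal model is this matrix times a
#' non-negative spectrum.
#'
#' @param grid A `t2_grid` object.
#' @param params A `sequence_params` object.
#' @return An object of class `decay_basis`: list with `matrix`, `grid`,
#'   `params`.
#' @export
build_decay_basis <- function(grid, params) {
  if (!inherits(grid, "t2_grid")) stop_param("grid must be a t2_grid object")
  if (!inherits(params, "sequence_params"))
    stop_param("params must be a sequence_params object")
  m <- .epg_basis_cpp(grid$values, params$refocus_deg, params$n_echoes,
                      params$echo_spacing, params$t1_assumed)
  structure(list(matrix = m, grid = grid, params = params),
            class = "decay_basis")
}
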