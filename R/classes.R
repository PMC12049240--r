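# S3 containers for trajectories, signals, mode bases and spectra.

#' Construct a Cartesian MD trajectory
#'
#' A time-ordered set of atomic positions and velocities in the internal
#' atomic-unit system (bohr, atomic time units).  Frames are rows; the 3N
#' coordinates of one frame are a row of the `positions` / `velocities`
#' matrices, ordered x1 y1 z1 x2 y2 z2 ...
#'
#' @param labels character vector of element labels, one per atom.
#' @param velocities numeric matrix, frames x 3N, bohr per atomic time unit.
#' @param positions numeric matrix, frames x 3N, in bohr, or `NULL` when the
#'   source file carries velocities only (e.g. Tinker velocity dumps).
#' @param timestep time between frames, atomic units.
#' @param source_units named list recording the declared time/space units of
#'   the source file (metadata only).
#' @return an object of class `md_trajectory`.
#' @export
md_trajectory <- function(labels, velocities, positions = NULL,
                          timestep, source_units = list()) {
  n_atoms <- length(labels)
  stopifnot(n_atoms >= 1)
  velocities <- as.matrix(velocities)
  if (ncol(velocities) != 3L * n_atoms)
    stop("velocities must have 3 * n_atoms columns", call. = FALSE)
  if (nrow(velocities) < 2L)
    stop("a trajectory needs at least 2 frames", call. = FALSE)
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (!all(dim(positions) == dim(velocities)))
      stop("positions and velocities must have identical dimensions",
           call. = FALSE)
  }
  if (!is.numeric(timestep) || length(timestep) != 1L || timestep <= 0)
    stop("timestep must be a single positive number", call. = FALSE)
  structure(
    list(n_atoms = n_atoms, labels = labels, timestep = timestep,
         positions = positions, velocities = velocities,
         source_units = source_units),
    class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("Cartesian MD trajectory\n")
  cat(sprintf("  atoms:     %d (%s)\n", x$n_atoms,
              paste(x$labels, collapse = " ")))
  cat(sprintf("  frames:    %d\n", nrow(x$velocities)))
  cat(sprintf("  timestep:  %g a.u. (%.4f fs)\n", x$timestep,
              x$timestep * .vs_const$fs_per_au_time))
  cat(sprintf("  positions: %s\n",
              if (is.null(x$positions)) "absent (velocity-only source)"
              else "present"))
  invisible(x)
}

#' Number of frames in a trajectory-like object
#' @param x an `md_trajectory`, `nm_trajectory` or `md_signal`.
#' @return integer frame/sample count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "md_trajectory")) nrow(x$velocities)
  else if (inherits(x, "nm_trajectory")) nrow(x$momenta)
  else if (inherits(x, "md_signal")) length(x$values)
  else stop("unsupported class", call. = FALSE)
}

#' Construct a normal-mode momentum trajectory
#'
#' Stores the per-frame vector of mode momenta p_j(t) produced either by an
#' MD run carried out directly in normal-mode coordinates or by projecting a
#' Cartesian trajectory with [project_to_modes()].
#'
#' @param momenta numeric matrix, frames x n_modes, atomic units.
#' @param timestep time per frame, atomic units.
#' @return an object of class `nm_trajectory` with fields `n_modes`,
#'   `timestep`, `momenta` and `total_time` (= timestep * (frames - 1)).
#' @export
nm_trajectory <- function(momenta, timestep) {
  momenta <- as.matrix(momenta)
  if (nrow(momenta) < 2L)
    stop("a normal-mode trajectory needs at least 2 frames", call. = FALSE)
  if (!is.numeric(timestep) || length(timestep) != 1L || timestep <= 0)
    stop("timestep must be a single positive number", call. = FALSE)
  structure(
    list(n_modes = ncol(momenta), timestep = timestep, momenta = momenta,
         total_time = timestep * (nrow(momenta) - 1)),
    class = "nm_trajectory")
}

#' @export
print.nm_trajectory <- function(x, ...) {
  cat("Normal-mode momentum trajectory\n")
  cat(sprintf("  modes:      %d\n", x$n_modes))
  cat(sprintf("  frames:     %d\n", nrow(x$momenta)))
  cat(sprintf("  timestep:   %g a.u.\n", x$timestep))
  cat(sprintf("  total time: %g a.u. (%.4f ps)\n", x$total_time,
              x$total_time * .vs_const$fs_per_au_time / 1000))
  invisible(x)
}

#' Construct a generic scalar signal
#'
#' A plain scalar time series with a sampling interval.  This is the most
#' general input to the spectral engine: a single mode momentum, one
#' velocity component, or any autocorrelatable observable such as a dipole
#' component.
#'
#' @param values numeric vector, length >= 2.
#' @param timestep sampling interval, atomic time units.
#' @return an object of class `md_signal`.
#' @export
md_signal <- function(values, timestep) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a signal needs at least 2 samples", call. = FALSE)
  if (!is.numeric(timestep) || length(timestep) != 1L || timestep <= 0)
    stop("timestep must be a single positive number", call. = FALSE)
  structure(list(values = values, timestep = timestep), class = "md_signal")
}

#' @export
print.md_signal <- function(x, ...) {
  cat(sprintf("Scalar signal: %d samples, timestep %g a.u.\n",
              length(x$values), x$timestep))
  invisible(x)
}

#' Construct a normal-mode basis
#'
#' Holds the orthogonal matrix C whose columns are the mass-weighted Hessian
#' eigenvectors with nonzero eigenvalue, ordered by ascending harmonic
#' frequency, together with the masses and reference geometry needed to
#' project Cartesian velocities onto the modes.
#'
#' @param masses per-atom masses, atomic units (electron masses).
#' @param reference_geometry numeric vector of 3N equilibrium coordinates,
#'   bohr.
#' @param C numeric 3N x n_modes matrix with orthonormal columns.
#' @param harmonic_frequencies per-mode harmonic wavenumbers, cm^-1.
#' @param linear logical; `TRUE` when 3N-5 modes are retained (linear
#'   molecule) instead of 3N-6.
#' @return an object of class `mode_basis`.
#' @export
mode_basis <- function(masses, reference_geometry, C, harmonic_frequencies,
                       linear = FALSE) {
  C <- as.matrix(C)
  if (length(reference_geometry) != nrow(C))
    stop("reference_geometry length must match nrow(C)", call. = FALSE)
  if (length(harmonic_frequencies) != ncol(C))
    stop("one harmonic frequency per retained mode required", call. = FALSE)
  ortho <- max(abs(crossprod(C) - diag(ncol(C))))
  if (ortho > 1e-10)
    stop(sprintf("mode matrix columns not orthonormal (max |C'C - I| = %.2e)",
                 ortho), call. = FALSE)
  structure(
    list(masses = masses, reference_geometry = as.numeric(reference_geometry),
         C = C, harmonic_frequencies = as.numeric(harmonic_frequencies),
         linear_flag = isTRUE(linear)),
    class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  cat("Normal-mode basis\n")
  cat(sprintf("  atoms: %d, retained modes: %d%s\n",
              length(x$masses), ncol(x$C),
              if (x$linear_flag) " (linear molecule)" else ""))
  f <- x$harmonic_frequencies
  cat(sprintf("  harmonic frequencies: %.1f .. %.1f cm^-1\n",
              min(f), max(f)))
  invisible(x)
}

#' @export
summary.mode_basis <- function(object, ...) {
  cat("Harmonic frequencies (cm^-1), ascending:\n")
  print(round(object$harmonic_frequencies, 1))
  invisible(object$harmonic_frequencies)
}
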