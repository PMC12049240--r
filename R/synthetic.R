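# Synthetic trajectory generators with known analytic spectral content.
# These stand in for real MD engines in tests: harmonic systems are evolved
# with the exact cosine/sine solution (no integrator error), the Morse
# oscillator with a high-accuracy adaptive integrator.

kB_hartree <- 3.166811563e-6  # Boltzmann constant, hartree / K

# Orthonormal basis (mass-weighted coordinates) of the 6-dimensional
# translation + rotation space of a nonlinear geometry.
.vs_tr_space <- function(geometry, masses_atom) {
  na <- length(masses_atom)
  X <- matrix(geometry, ncol = 3L, byrow = TRUE)
  com <- colSums(X * masses_atom) / sum(masses_atom)
  Xc <- sweep(X, 2L, com)
  sqm <- sqrt(masses_atom)
  vecs <- matrix(0, 3L * na, 6L)
  for (k in 1:3) {                      # translations
    v <- matrix(0, na, 3L); v[, k] <- sqm
    vecs[, k] <- as.vector(t(v))
  }
  ax <- diag(3)
  for (k in 1:3) {                      # rotations about the COM
    v <- t(vapply(seq_len(na), function(i)
      sqm[i] * pracma_cross(ax[k, ], Xc[i, ]), numeric(3)))
    vecs[, 3L + k] <- as.vector(t(v))
  }
  qr.Q(qr(vecs))[, 1:6, drop = FALSE]
}

# 3-vector cross product (kept local; no dependency needed for this).
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Random orthonormal 3N x n_modes embedding orthogonal to the
# translation/rotation space: the columns of C for a fictitious molecule.
.vs_embed_basis <- function(geometry, masses_atom, n_modes) {
  n3 <- 3L * length(masses_atom)
  tr <- .vs_tr_space(geometry, masses_atom)
  G <- matrix(stats::rnorm(n3 * n_modes), n3, n_modes)
  G <- G - tr %*% crossprod(tr, G)
  Q <- qr.Q(qr(G))[, seq_len(n_modes), drop = FALSE]
  # orthogonalize once more against TR space to kill rounding leakage
  Q <- Q - tr %*% crossprod(tr, Q)
  qr.Q(qr(Q))[, seq_len(n_modes), drop = FALSE]
}

#' Generate a harmonic (optionally bilinearly coupled) trajectory
#'
#' Builds a set of harmonic modes with the given nominal wavenumbers,
#' optionally coupled through a symmetric bilinear term, and evolves the
#' system analytically (exact cosine/sine solution, no integrator error).
#' The mode coordinates are embedded into the Cartesian space of a
#' fictitious molecule through a random orthonormal completion orthogonal
#' to the translations and rotations of a random reference geometry, so the
#' mass-weighting and projection code is exercised nontrivially.  Atom
#' labels are drawn from H/C/N/O so that element masses resolve through the
#' standard table.
#'
#' Initial conditions follow the chosen energy scheme with uniformly random
#' phases; the default quasi-classical scheme gives every eigenmode a total
#' energy of \eqn{\omega_a/2} (its harmonic zero-point energy), the scheme
#' used to launch quasi-classical MD runs.
#'
#' @param frequencies nominal mode wavenumbers, cm^-1 (sorted ascending
#'   internally; the coupling matrix is permuted along).
#' @param dt time step, atomic units.
#' @param n_steps number of frames.
#' @param coupling optional symmetric bilinear coupling matrix with zero
#'   diagonal, in cm^-2 (same scale as the squared wavenumbers it
#'   perturbs).
#' @param n_atoms atoms of the embedding molecule; default is the smallest
#'   count with 3N - 6 >= n_modes.
#' @param energy_scheme `"quasiclassical"` (energy \eqn{\omega_a/2} per
#'   eigenmode), `"thermal"` (\eqn{k_B T} per eigenmode) or `"explicit"`
#'   (mass-weighted position amplitudes given directly).
#' @param temperature kelvin, for the thermal scheme.
#' @param amplitudes per-eigenmode amplitudes, for the explicit scheme.
#' @param seed integer seed; the same seed reproduces the trajectory
#'   exactly.
#' @return a list with components `trajectory` ([md_trajectory]), `basis`
#'   ([mode_basis] holding the exact embedding C), `nm` ([nm_trajectory]
#'   of the exact mode momenta) and `eigenfrequencies` (the analytic
#'   eigenmode wavenumbers of the coupled quadratic form, cm^-1,
#'   ascending).
#' @export
generate_harmonic_trajectory <- function(frequencies, dt, n_steps,
                                         coupling = NULL, n_atoms = NULL,
                                         energy_scheme = c("quasiclassical",
                                                           "thermal",
                                                           "explicit"),
                                         temperature = 300,
                                         amplitudes = NULL, seed = 1) {
  energy_scheme <- match.arg(energy_scheme)
  if (any(frequencies <= 0)) stop("frequencies must be positive",
                                  call. = FALSE)
  if (dt <= 0 || n_steps < 2) stop("need dt > 0 and n_steps >= 2",
                                   call. = FALSE)
  nm <- length(frequencies)
  ord <- order(frequencies)
  frequencies <- frequencies[ord]
  omega <- cm1_to_angfreq(frequencies)
  K <- diag(omega^2, nm)
  if (!is.null(coupling)) {
    coupling <- as.matrix(coupling)[ord, ord, drop = FALSE]
    if (max(abs(coupling - t(coupling))) > 1e-12 * max(abs(coupling), 1))
      stop("coupling matrix must be symmetric", call. = FALSE)
    if (any(abs(diag(coupling)) > 0))
      stop("coupling matrix must have zero diagonal", call. = FALSE)
    K <- K + coupling / .vs_const$cm1_per_au_angfreq^2
  }
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- rev(eig$values)
  U <- eig$vectors[, rev(seq_len(nm)), drop = FALSE]
  if (any(lam <= 0))
    stop("coupled quadratic form is not positive definite", call. = FALSE)
  Omega <- sqrt(lam)

  set.seed(seed)
  phases <- stats::runif(nm, 0, 2 * pi)
  A <- switch(energy_scheme,
    quasiclassical = sqrt(2 * (Omega / 2)) / Omega,   # E_a = Omega_a / 2
    thermal = sqrt(2 * kB_hartree * temperature) / Omega,
    explicit = {
      if (is.null(amplitudes) || length(amplitudes) != nm)
        stop("explicit scheme needs one amplitude per mode", call. = FALSE)
      as.numeric(amplitudes)
    })

  tgrid <- (seq_len(n_steps) - 1L) * dt
  arg <- outer(tgrid, Omega) + matrix(phases, n_steps, nm, byrow = TRUE)
  qa <- sweep(cos(arg), 2L, A, "*")                    # eigenmode positions
  pa <- sweep(-sin(arg), 2L, A * Omega, "*")           # eigenmode momenta
  Q <- qa %*% t(U)                                     # nominal-mode coords
  P <- pa %*% t(U)

  if (is.null(n_atoms)) n_atoms <- ceiling((nm + 6L) / 3)
  if (3L * n_atoms - 6L < nm)
    stop("n_atoms too small to embed the requested modes", call. = FALSE)
  labels <- sample(c("H", "C", "N", "O"), n_atoms, replace = TRUE)
  masses <- atomic_masses(labels)
  geometry <- stats::rnorm(3L * n_atoms, sd = 2)
  C <- .vs_embed_basis(geometry, masses, nm)
  sqm <- rep(sqrt(masses), each = 3L)

  vel <- t(C %*% t(P)) / matrix(sqm, n_steps, 3L * n_atoms, byrow = TRUE)
  pos <- t(C %*% t(Q)) / matrix(sqm, n_steps, 3L * n_atoms, byrow = TRUE)
  pos <- sweep(pos, 2L, geometry, "+")

  list(
    trajectory = md_trajectory(labels = labels, velocities = vel,
                               positions = pos, timestep = dt,
                               source_units = list(generator = "harmonic",
                                                   seed = seed)),
    basis = mode_basis(masses = masses, reference_geometry = geometry,
                       C = C, harmonic_frequencies = frequencies),
    nm = nm_trajectory(P, timestep = dt),
    eigenfrequencies = angfreq_to_cm1(Omega))
}

#' Generate a classical Morse-oscillator velocity signal
#'
#' Integrates the 1D Morse oscillator
#' \eqn{V(x) = D_e (1 - e^{-a x})^2} at a fixed total energy with an
#' adaptive high-accuracy integrator (relative energy conservation is part
#' of the contract, checked by the test suite at 1e-10).  The classical
#' oscillation frequency at energy E is the analytic
#' \eqn{\omega(E) = \omega_0\sqrt{1 - E/D_e}}, so the generated signal has
#' a known red-shifted peak: the mechanism behind anharmonic band shifts.
#'
#' @param omega0 harmonic wavenumber at the well bottom, cm^-1.
#' @param dissociation_energy well depth D_e, hartree.
#' @param mass reduced mass, atomic units (electron masses).
#' @param energy total energy, hartree; must lie in (0, D_e) for bound
#'   motion.
#' @param dt sampling interval, atomic units.
#' @param n_steps number of samples.
#' @param seed integer; sets the sign of the initial momentum.
#' @return an [md_signal] of velocities with attributes
#'   `analytic_frequency_cm1` (the classical \eqn{\omega(E)}) and `energy`
#'   (the per-sample total energy, for conservation checks).
#' @export
generate_morse_trajectory <- function(omega0, dissociation_energy, mass,
                                      energy, dt, n_steps, seed = 1) {
  De <- dissociation_energy
  if (energy >= De)
    stop("energy >= dissociation energy: motion is unbound", call. = FALSE)
  if (energy <= 0) stop("energy must be positive", call. = FALSE)
  w0 <- cm1_to_angfreq(omega0)
  a <- w0 * sqrt(mass / (2 * De))
  set.seed(seed)
  p0 <- sample(c(-1, 1), 1L) * sqrt(2 * mass * energy)  # launch from x = 0
  deriv <- function(t, y, parms) {
    expax <- exp(-a * y[1])
    list(c(y[2] / mass, -2 * De * a * expax * (1 - expax)))
  }
  times <- (seq_len(n_steps) - 1L) * dt
  sol <- deSolve::ode(y = c(x = 0, p = p0), times = times, func = deriv,
                      parms = NULL, method = "ode45",
                      rtol = 5e-14, atol = 1e-16)
  x <- sol[, "x"]; p <- sol[, "p"]
  etot <- p^2 / (2 * mass) + De * (1 - exp(-a * x))^2
  sig <- md_signal(p / mass, timestep = dt)
  attr(sig, "analytic_frequency_cm1") <- omega0 * sqrt(1 - energy / De)
  attr(sig, "energy") <- etot
  sig
}

#' Random positive-definite toy Hessian with an exact zero-mode block
#'
#' Builds a Cartesian Hessian for a fictitious nonlinear molecule whose
#' mass-weighted form has an exact 6-dimensional translation/rotation null
#' space and 3N - 6 positive eigenvalues drawn from a vibrational
#' wavenumber range.  Used to exercise mode counting and basis
#' construction at realistic molecular sizes.
#'
#' @param n_atoms number of atoms (>= 3).
#' @param seed integer seed.
#' @param freq_range wavenumber range (cm^-1) from which the vibrational
#'   eigenfrequencies are drawn uniformly.
#' @return a list with `hessian`, `labels`, `masses` (atomic units),
#'   `geometry` (3N bohr) and `frequencies` (the planted wavenumbers,
#'   ascending).
#' @export
synthetic_hessian <- function(n_atoms, seed = 1, freq_range = c(500, 3500)) {
  if (n_atoms < 3L) stop("need at least 3 atoms", call. = FALSE)
  set.seed(seed)
  labels <- sample(c("H", "C", "N", "O"), n_atoms, replace = TRUE)
  masses <- atomic_masses(labels)
  geometry <- stats::rnorm(3L * n_atoms, sd = 2)
  nvib <- 3L * n_atoms - 6L
  B <- .vs_embed_basis(geometry, masses, nvib)
  freqs <- sort(stats::runif(nvib, freq_range[1], freq_range[2]))
  lam <- cm1_to_angfreq(freqs)^2
  S <- B %*% (lam * t(B))              # mass-weighted Hessian, exact nulls
  sqm <- rep(sqrt(masses), each = 3L)
  H <- S * tcrossprod(sqm)
  list(hessian = (H + t(H)) / 2, labels = labels, masses = masses,
       geometry = geometry, frequencies = freqs)
}
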