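# Normal-mode machinery: mass-weighted Hessian, the orthogonal C matrix,
# Eckart alignment and the Cartesian -> mode-momentum projection
# P = C' (sqrt(m) v).

# Expand per-atom masses to per-coordinate masses when needed.
.vs_coord_masses <- function(masses, ncoord) {
  if (length(masses) == ncoord) return(as.numeric(masses))
  if (3L * length(masses) == ncoord) return(rep(as.numeric(masses), each = 3L))
  stop(sprintf(
    "mass vector (length %d) matches neither the coordinate count %d nor one mass per atom",
    length(masses), ncoord), call. = FALSE)
}

#' Mass-weight a Hessian matrix
#'
#' Divides element (i, j) of the Hessian by \eqn{\sqrt{m_i m_j}}, where
#' \eqn{m_i} is the mass of the atom owning coordinate i.  The eigenvalues
#' of the result are the squared harmonic angular frequencies.
#'
#' @param hessian symmetric numeric matrix (atomic units, hartree/bohr^2).
#' @param masses masses in atomic units, one per atom (expanded threefold)
#'   or one per coordinate.
#' @return the mass-weighted matrix, same dimensions.
#' @export
#' @examples
#' mass_weight_hessian(matrix(c(1, -1, -1, 1), 2), masses = c(4, 4))
mass_weight_hessian <- function(hessian, masses) {
  hessian <- as.matrix(hessian)
  n <- nrow(hessian)
  if (ncol(hessian) != n)
    stop("hessian must be square", call. = FALSE)
  scale <- max(abs(hessian), 1e-300)
  if (max(abs(hessian - t(hessian))) > 1e-8 * scale)
    stop("hessian is not symmetric (relative asymmetry above 1e-8)",
         call. = FALSE)
  m <- .vs_coord_masses(masses, n)
  if (any(m <= 0)) stop("masses must be positive", call. = FALSE)
  s <- 1 / sqrt(m)
  hessian * tcrossprod(s)
}

#' Build a normal-mode basis from a Hessian
#'
#' Mass-weights the Hessian, diagonalizes it, discards the `n_zero`
#' eigenvalues of smallest magnitude (the translations and rotations: 6 for
#' a nonlinear molecule, 5 for a linear one) and keeps the remaining
#' eigenvectors, ordered by ascending eigenvalue, as the columns of the
#' orthogonal matrix C.  Harmonic wavenumbers are
#' \eqn{\tilde\nu_j = \sqrt{\lambda_j}} converted to cm^-1.
#'
#' Zero modes are removed by count, not by a numeric threshold, which is
#' robust to the numerical noise typical of force-field Hessians; if the
#' discarded block is not clearly separated from the retained one a warning
#' lists the smallest eigenvalues.  A retained negative eigenvalue (a
#' saddle point) is an error.  Each eigenvector's sign is fixed so that its
#' largest-magnitude component is positive, making C reproducible across
#' linear-algebra backends.
#'
#' @inheritParams mass_weight_hessian
#' @param reference_geometry equilibrium coordinates (bohr), one value per
#'   Hessian row.
#' @param linear logical; retain 3N-5 modes instead of 3N-6.
#' @param n_zero number of zero modes to discard; defaults to 6 (5 when
#'   `linear`).  Settable explicitly for reduced-dimensional models.
#' @return a [mode_basis].
#' @export
build_mode_basis <- function(hessian, masses, reference_geometry,
                             linear = FALSE, n_zero = NULL) {
  mw <- mass_weight_hessian(hessian, masses)
  n <- nrow(mw)
  if (length(reference_geometry) != n)
    stop("reference_geometry must have one coordinate per Hessian row",
         call. = FALSE)
  if (is.null(n_zero)) n_zero <- if (isTRUE(linear)) 5L else 6L
  if (n_zero < 0L || n_zero >= n)
    stop("n_zero must be in [0, ncol(hessian))", call. = FALSE)
  eig <- eigen((mw + t(mw)) / 2, symmetric = TRUE)
  ev <- eig$values            # descending
  ord_mag <- order(abs(ev))
  drop_idx <- ord_mag[seq_len(n_zero)]
  keep_idx <- setdiff(seq_len(n), drop_idx)
  # ascending eigenvalue among the retained modes
  keep_idx <- keep_idx[order(ev[keep_idx])]
  lam <- ev[keep_idx]
  if (any(lam <= 0)) {
    bad <- which(lam <= 0)[1]
    stop(sprintf(
      "retained mode %d has non-positive eigenvalue %.3e: not a potential minimum",
      bad, lam[bad]), call. = FALSE)
  }
  if (n_zero > 0L) {
    gap_ok <- max(abs(ev[drop_idx])) < 1e-6 * max(lam)
    if (!gap_ok) {
      small <- sort(abs(ev))[seq_len(min(6L, n))]
      warning(sprintf(
        "discarded zero-mode block not well separated; smallest |eigenvalues|: %s",
        paste(sprintf("%.3e", small), collapse = ", ")), call. = FALSE)
    }
  }
  C <- eig$vectors[, keep_idx, drop = FALSE]
  for (j in seq_len(ncol(C))) {
    imax <- which.max(abs(C[, j]))
    if (C[imax, j] < 0) C[, j] <- -C[, j]
  }
  mode_basis(masses = masses, reference_geometry = reference_geometry,
             C = C, harmonic_frequencies = angfreq_to_cm1(sqrt(lam)),
             linear = linear)
}

#' Eckart alignment of a frame onto a reference geometry
#'
#' Removes the mass-weighted center of mass and applies the mass-weighted
#' least-squares (Kabsch) rotation that best superimposes the frame on the
#' reference.  Applying it to the reference itself returns the reference.
#'
#' @param frame_positions numeric 3N vector, bohr.
#' @param reference_geometry numeric 3N vector, bohr.
#' @param masses per-atom masses (atomic units).
#' @return the aligned 3N coordinate vector, with the fitted 3x3 rotation
#'   attached as attribute `"rotation"`.
#' @export
eckart_align <- function(frame_positions, reference_geometry, masses) {
  n3 <- length(reference_geometry)
  if (length(frame_positions) != n3)
    stop("frame and reference must have the same number of coordinates",
         call. = FALSE)
  if (n3 %% 3L != 0L) stop("coordinate count must be a multiple of 3",
                           call. = FALSE)
  na <- n3 %/% 3L
  m <- .vs_coord_masses(masses, n3)[seq(1, n3, by = 3L)]
  X <- matrix(frame_positions, ncol = 3L, byrow = TRUE)
  Y <- matrix(reference_geometry, ncol = 3L, byrow = TRUE)
  comX <- colSums(X * m) / sum(m)
  comY <- colSums(Y * m) / sum(m)
  Xc <- sweep(X, 2L, comX)
  Yc <- sweep(Y, 2L, comY)
  H <- t(Xc * m) %*% Yc
  sv <- svd(H)
  if (sum(sv$d < 1e-10 * max(sv$d, 1e-300)) >= 2L)
    stop("degenerate (collinear) geometry: Eckart rotation is undetermined",
         call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- sweep(Xc %*% t(R), 2L, comY, "+")
  out <- as.vector(t(aligned))
  attr(out, "rotation") <- R
  out
}

#' Project a Cartesian trajectory onto normal modes
#'
#' Per frame, velocities are mass-weighted (each component multiplied by
#' the square root of its atom's mass) and multiplied by C' to give the
#' mode momenta \eqn{p_j = (C^T \sqrt{m}\,v)_j}, the conjugate momenta of
#' the mass-weighted normal coordinates.  With `align = TRUE` the Eckart
#' rotation fitted on the frame's positions is applied to the velocities
#' first; by default alignment is on exactly when positions are present
#' (velocity-only sources such as Tinker dumps are projected as-is).
#'
#' @param traj an [md_trajectory].
#' @param basis a [mode_basis] for the same atom count.
#' @param align logical or `NULL` (auto).
#' @return an [nm_trajectory] of per-frame mode momenta.
#' @export
project_to_modes <- function(traj, basis, align = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(basis, "mode_basis"))
  n3 <- nrow(basis$C)
  if (ncol(traj$velocities) != n3)
    stop(sprintf("trajectory has %d coordinates but the basis expects %d",
                 ncol(traj$velocities), n3), call. = FALSE)
  if (is.null(traj$velocities))
    stop("trajectory has no velocities", call. = FALSE)
  if (is.null(align)) align <- !is.null(traj$positions)
  if (align && is.null(traj$positions))
    stop("align = TRUE requires positions (velocity-only input)",
         call. = FALSE)
  sqm <- sqrt(.vs_coord_masses(basis$masses, n3))
  nfr <- nrow(traj$velocities)
  if (align) {
    mom <- matrix(0, nfr, ncol(basis$C))
    for (f in seq_len(nfr)) {
      al <- eckart_align(traj$positions[f, ], basis$reference_geometry,
                         basis$masses)
      R <- attr(al, "rotation")
      V <- matrix(traj$velocities[f, ], ncol = 3L, byrow = TRUE) %*% t(R)
      mom[f, ] <- crossprod(basis$C, sqm * as.vector(t(V)))
    }
  } else {
    mom <- t(crossprod(basis$C, t(traj$velocities) * sqm))
  }
  nm_trajectory(mom, timestep = traj$timestep)
}
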