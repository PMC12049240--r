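# Physical constants (CODATA 2014) and unit conversion helpers.
# Internal canonical unit system is Hartree atomic units: lengths in bohr,
# time in atomic time units, masses in electron masses.  All conversions
# happen at the I/O boundary; everything downstream assumes atomic units.

#' @keywords internal
.vs_const <- list(
  bohr_per_angstrom = 1 / 0.52917721067,
  angstrom_per_bohr = 0.52917721067,
  fs_per_au_time    = 2.418884326509e-2,
  amu_per_me        = 1 / 1822.888486209,
  me_per_amu        = 1822.888486209,
  # wavenumber (cm^-1) per unit angular frequency (rad / a.u. time);
  # numerically identical to the hartree -> cm^-1 energy conversion
  cm1_per_au_angfreq = 219474.6313705
)

#' Convert a time value to atomic time units
#'
#' @param x numeric value(s).
#' @param unit one of `"au"`, `"fs"`, `"ps"`.
#' @return numeric, in atomic time units.
#' @keywords internal
time_to_au <- function(x, unit) {
  unit <- match.arg(unit, c("au", "fs", "ps"))
  switch(unit,
    au = x,
    fs = x / .vs_const$fs_per_au_time,
    ps = x * 1000 / .vs_const$fs_per_au_time
  )
}

#' Convert a length value to bohr
#'
#' @param x numeric value(s).
#' @param unit one of `"au"` (bohr), `"angstrom"`, `"nm"`.
#' @return numeric, in bohr.
#' @keywords internal
length_to_au <- function(x, unit) {
  unit <- match.arg(unit, c("au", "angstrom", "nm"))
  switch(unit,
    au = x,
    angstrom = x * .vs_const$bohr_per_angstrom,
    nm = x * 10 * .vs_const$bohr_per_angstrom
  )
}

#' Velocity conversion factor to bohr per atomic time unit
#'
#' @param space_unit one of `"au"`, `"angstrom"`, `"nm"`.
#' @param time_unit one of `"au"`, `"fs"`, `"ps"`.
#' @return scalar multiplicative factor.
#' @keywords internal
velocity_factor <- function(space_unit, time_unit) {
  length_to_au(1, space_unit) / time_to_au(1, time_unit)
}

#' Angular frequency (a.u.) to wavenumber (cm^-1)
#' @keywords internal
angfreq_to_cm1 <- function(omega) omega * .vs_const$cm1_per_au_angfreq

#' Wavenumber (cm^-1) to angular frequency (a.u.)
#' @keywords internal
cm1_to_angfreq <- function(nu) nu / .vs_const$cm1_per_au_angfreq

# Isotope-averaged atomic masses in amu (IUPAC 2021 standard weights,
# abridged).  Labels are matched case-insensitively after stripping digits,
# so "H1", "CA" and "Cl" all resolve.
.vs_masses_amu <- c(
  H = 1.008, D = 2.014, He = 4.0026,
  Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305, Al = 26.982,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Sc = 44.956, Ti = 47.867, V = 50.942,
  Cr = 51.996, Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693,
  Cu = 63.546, Zn = 65.38, Ga = 69.723, Ge = 72.630, As = 74.922,
  Se = 78.971, Br = 79.904, Kr = 83.798, Rb = 85.468, Sr = 87.62,
  Ag = 107.87, I = 126.904, Xe = 131.29, Au = 196.97, Hg = 200.59
)

#' Look up atomic masses from element labels
#'
#' Resolves element symbols to isotope-averaged atomic masses.  Numeric
#' suffixes in labels (e.g. `"H1"`, `"C6"`) are ignored, and matching is
#' case-insensitive.  Unknown labels raise an error: masses enter the
#' Hessian weighting and must never be silently defaulted.
#'
#' @param labels character vector of element labels.
#' @param unit `"au"` (electron masses, the internal unit) or `"amu"`.
#' @return numeric vector of masses, one per label.
#' @export
#' @examples
#' atomic_masses(c("O", "H", "H"))
atomic_masses <- function(labels, unit = c("au", "amu")) {
  unit <- match.arg(unit)
  sym <- gsub("[0-9_]+$", "", trimws(labels))
  key <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, nchar(sym))))
  m <- .vs_masses_amu[key]
  if (anyNA(m)) {
    bad <- unique(labels[is.na(m)])
    stop("unknown element label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- unname(m)
  if (unit == "au") m * .vs_const$me_per_amu else m
}
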