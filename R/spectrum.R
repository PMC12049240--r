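# Core spectral engine: biased time-averaged autocorrelation and the
# positive-definite power spectrum I(w) = |p~(w)|^2 / (2T).
#
# Discrete conventions (fixed so the Wiener-Khinchin and Parseval
# identities hold exactly on the sampled grid):
#   p~(w_k) = dt * sum_n s(n) exp(i w_k t_n),  w_k = 2 pi k / (M dt)
#   I(w_k)  = |p~(w_k)|^2 / (2 T),             T = N dt
# with N samples zero-padded to M = pad_factor * N points.  The spectrum is
# reported on the one-sided grid [0, Nyquist] in cm^-1.

#' Internal power-spectrum constructor
#' @keywords internal
new_power_spectrum <- function(frequencies, intensities, total_time,
                               window_meta = list()) {
  intensities <- as.matrix(intensities)
  stopifnot(length(frequencies) == nrow(intensities))
  structure(
    list(frequencies = as.numeric(frequencies), intensities = intensities,
         total_time = total_time, window_meta = window_meta),
    class = "power_spectrum")
}

#' Biased time-averaged autocorrelation of a scalar signal
#'
#' Computes the biased, zero-extended estimator
#' \deqn{C(k\Delta t) = \frac{1}{N}\sum_{n=0}^{N-1-k} s_n s_{n+k},}
#' the discrete analogue of the time average
#' \eqn{(1/T)\int_0^T s(t_0) s(t_0+t)\,dt_0} with the integration limit
#' extended past the end of the run (samples beyond the run contribute
#' zero).  This biased convention is what makes the Fourier transform of
#' the autocorrelation agree exactly with the squared-magnitude spectrum.
#'
#' @param signal an [md_signal].
#' @param max_lag_fraction largest lag as a fraction of the signal duration,
#'   in (0, 1].
#' @return an object of class `autocorrelation` with fields `lags` (atomic
#'   time units, starting at 0), `values` and `normalization = "biased"`.
#' @export
#' @examples
#' s <- md_signal(c(1, 1, 1, 1), timestep = 1)
#' autocorrelate(s)$values   # 1, 0.75, 0.5, 0.25
autocorrelate <- function(signal, max_lag_fraction = 1) {
  stopifnot(inherits(signal, "md_signal"))
  if (!is.numeric(max_lag_fraction) || length(max_lag_fraction) != 1L ||
      max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("max_lag_fraction must be in (0, 1]", call. = FALSE)
  s <- signal$values
  N <- length(s)
  K <- floor(max_lag_fraction * (N - 1))
  # biased estimator via FFT of the zero-padded signal
  M <- stats::nextn(2L * N, 2)
  ft <- stats::fft(c(s, numeric(M - N)))
  cfull <- Re(stats::fft(Mod(ft)^2, inverse = TRUE)) / M / N
  structure(
    list(lags = (0:K) * signal$timestep, values = cfull[1:(K + 1L)],
         normalization = "biased"),
    class = "autocorrelation")
}

#' @export
print.autocorrelation <- function(x, ...) {
  cat(sprintf("Biased autocorrelation: %d lags, C(0) = %g\n",
              length(x$lags), x$values[1]))
  invisible(x)
}

# Shared grid/window setup.  Returns the padded length, the one-sided bin
# indices inside the requested window and their wavenumbers.
.vs_grid <- function(N, dt, freq_window, pad_factor) {
  if (!is.numeric(freq_window) || length(freq_window) != 2L)
    stop("freq_window must be c(lower, upper) in cm^-1", call. = FALSE)
  if (freq_window[1] >= freq_window[2])
    stop("freq_window: lower bound must be below the upper bound",
         call. = FALSE)
  if (pad_factor < 1) stop("pad_factor must be >= 1", call. = FALSE)
  nyq <- angfreq_to_cm1(pi / dt)
  if (freq_window[2] > nyq * (1 + 1e-12))
    stop(sprintf(
      "upper frequency %.1f cm^-1 exceeds the Nyquist limit %.1f cm^-1 for timestep %g a.u.",
      freq_window[2], nyq, dt), call. = FALSE)
  M <- as.integer(round(pad_factor * N))
  k <- 0:(M %/% 2L)
  freq <- angfreq_to_cm1(2 * pi * k / (M * dt))
  keep <- which(freq >= freq_window[1] - 1e-9 & freq <= freq_window[2] + 1e-9)
  list(M = M, k = k[keep], freq = freq[keep], nyquist = nyq)
}

.vs_prepare <- function(s, taper, remove_mean) {
  if (remove_mean) s <- s - mean(s)
  if (taper == "hann") {
    n <- length(s)
    s <- s * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
  }
  s
}

# One column of the FFT-route spectrum on a precomputed grid.
.vs_spectrum_column <- function(s, dt, grid, taper, remove_mean) {
  s <- .vs_prepare(s, taper, remove_mean)
  N <- length(s)
  ft <- stats::fft(c(s, numeric(grid$M - N)))
  (dt^2 * Mod(ft[grid$k + 1L])^2) / (2 * N * dt)
}

#' Time-averaged power spectrum
#'
#' `power_spectrum()` is the package's central estimator.  It computes the
#' positive-definite, time-averaged power spectrum
#' \deqn{I(\omega) = \frac{1}{2T}\,|\tilde p(\omega)|^2,\qquad
#'       \tilde p(\omega) = \int_0^T p(t)\,e^{i\omega t}\,dt,}
#' the Fourier transform of the biased time-averaged autocorrelation of the
#' input.  Peaks of \eqn{I(\omega)} mark the classical vibrational
#' frequencies sampled by the trajectory.  Methods exist for
#' \itemize{
#'   \item [md_signal] — one spectrum of a generic scalar series (a dipole
#'     component, one velocity component, ...);
#'   \item [nm_trajectory] — per-mode spectra \eqn{I_j(\omega)} of the mode
#'     momenta, with `modes = "sum"`, `"all"` or an explicit index list;
#'   \item [md_trajectory] — the summed Cartesian spectrum of all
#'     \eqn{\sqrt m}-weighted velocity components, or, when a
#'     [mode_basis] is supplied, the per-mode spectra of the projected
#'     momenta.
#' }
#'
#' @param x the input object.
#' @param ... passed to methods.
#' @return an object of class `power_spectrum`: an ascending wavenumber
#'   grid (cm^-1) with one or more columns of nonnegative intensities, plus
#'   the resolved analysis options in `$window_meta`.
#' @seealso [power_spectrum_direct()], [find_peaks()], [write_spectrum()]
#' @export
power_spectrum <- function(x, ...) UseMethod("power_spectrum")

#' @rdname power_spectrum
#' @param freq_window numeric `c(lower, upper)` window in cm^-1; the upper
#'   bound must not exceed the Nyquist frequency `1/(2 dt)`.
#' @param pad_factor zero-padding factor for the FFT grid (default 8); the
#'   padded grid spacing, and hence the peak localization, is
#'   `1 / (pad_factor * N * dt)` in frequency.
#' @param taper `"rect"` (none, the default) or `"hann"`.
#' @param remove_mean subtract the time mean before transforming (default
#'   `TRUE`); suppresses the zero-frequency artifact from drift.
#' @export
power_spectrum.md_signal <- function(x, freq_window = c(0, 4000),
                                     pad_factor = 8,
                                     taper = c("rect", "hann"),
                                     remove_mean = TRUE, ...) {
  taper <- match.arg(taper)
  N <- length(x$values)
  grid <- .vs_grid(N, x$timestep, freq_window, pad_factor)
  I <- .vs_spectrum_column(x$values, x$timestep, grid, taper, remove_mean)
  new_power_spectrum(
    frequencies = grid$freq,
    intensities = matrix(I, ncol = 1L, dimnames = list(NULL, "signal")),
    total_time = N * x$timestep,
    window_meta = list(pad_factor = pad_factor, taper = taper,
                       remove_mean = remove_mean, timestep = x$timestep,
                       n_samples = N, padded_length = grid$M,
                       nyquist_cm1 = grid$nyquist,
                       freq_window = freq_window))
}

#' @rdname power_spectrum
#' @param modes `"sum"` (single column summing all per-mode spectra),
#'   `"all"` (one column per mode) or an integer vector of 1-based mode
#'   indices in ascending-frequency order.
#' @export
power_spectrum.nm_trajectory <- function(x, modes = "sum",
                                         freq_window = c(0, 4000),
                                         pad_factor = 8,
                                         taper = c("rect", "hann"),
                                         remove_mean = TRUE, ...) {
  taper <- match.arg(taper)
  nm <- x$n_modes
  if (identical(modes, "sum") || identical(modes, "all")) {
    sel <- seq_len(nm)
  } else {
    sel <- as.integer(modes)
    if (length(sel) == 0L || anyNA(sel) || any(sel < 1L | sel > nm))
      stop(sprintf("mode selection out of range: valid mode indices are 1..%d",
                   nm), call. = FALSE)
  }
  N <- nrow(x$momenta)
  grid <- .vs_grid(N, x$timestep, freq_window, pad_factor)
  cols <- vapply(sel, function(j)
    .vs_spectrum_column(x$momenta[, j], x$timestep, grid, taper, remove_mean),
    numeric(length(grid$freq)))
  cols <- matrix(cols, nrow = length(grid$freq))
  if (identical(modes, "sum")) {
    I <- matrix(rowSums(cols), ncol = 1L, dimnames = list(NULL, "sum"))
  } else {
    colnames(cols) <- paste0("mode_", sel)
    I <- cols
  }
  new_power_spectrum(
    frequencies = grid$freq, intensities = I, total_time = N * x$timestep,
    window_meta = list(pad_factor = pad_factor, taper = taper,
                       remove_mean = remove_mean, timestep = x$timestep,
                       n_samples = N, padded_length = grid$M,
                       nyquist_cm1 = grid$nyquist, freq_window = freq_window,
                       selection = modes))
}

#' @rdname power_spectrum
#' @param basis optional [mode_basis]; when supplied the trajectory is first
#'   projected onto the modes with [project_to_modes()] and the normal-mode
#'   method is applied.
#' @param align Eckart-align frames before projection; `NULL` (default)
#'   aligns exactly when positions are present.  Ignored without `basis`.
#' @export
power_spectrum.md_trajectory <- function(x, basis = NULL, align = NULL,
                                         modes = "sum",
                                         freq_window = c(0, 4000),
                                         pad_factor = 8,
                                         taper = c("rect", "hann"),
                                         remove_mean = TRUE, ...) {
  taper <- match.arg(taper)
  if (!is.null(basis)) {
    nmtraj <- project_to_modes(x, basis, align = align)
    return(power_spectrum(nmtraj, modes = modes, freq_window = freq_window,
                          pad_factor = pad_factor, taper = taper,
                          remove_mean = remove_mean))
  }
  masses <- atomic_masses(x$labels)
  sqm <- rep(sqrt(masses), each = 3L)
  N <- nrow(x$velocities)
  grid <- .vs_grid(N, x$timestep, freq_window, pad_factor)
  total <- numeric(length(grid$freq))
  for (i in seq_len(ncol(x$velocities))) {
    total <- total + .vs_spectrum_column(x$velocities[, i] * sqm[i],
                                         x$timestep, grid, taper, remove_mean)
  }
  new_power_spectrum(
    frequencies = grid$freq,
    intensities = matrix(total, ncol = 1L,
                         dimnames = list(NULL, "cartesian_sum")),
    total_time = N * x$timestep,
    window_meta = list(pad_factor = pad_factor, taper = taper,
                       remove_mean = remove_mean, timestep = x$timestep,
                       n_samples = N, padded_length = grid$M,
                       nyquist_cm1 = grid$nyquist, freq_window = freq_window,
                       selection = "cartesian"))
}

#' Power spectrum via explicit transform of the autocorrelation
#'
#' Computes \eqn{I(\omega)} by Fourier-transforming the biased
#' autocorrelation directly:
#' \deqn{I(\omega) = \frac{\Delta t}{2}\Big(C(0) +
#'   2\sum_{k\ge 1} C(k\Delta t)\cos(\omega k \Delta t)\Big).}
#' By the discrete Wiener-Khinchin theorem this equals the squared-magnitude
#' route of [power_spectrum()] on the same grid; it exists as the
#' independent cross-check of that equivalence and is O(N * bins), so use it
#' on short signals.
#'
#' @inheritParams power_spectrum.md_signal
#' @return a single-column `power_spectrum`.
#' @export
power_spectrum_direct <- function(x, freq_window = c(0, 4000),
                                  pad_factor = 8,
                                  taper = c("rect", "hann"),
                                  remove_mean = TRUE) {
  stopifnot(inherits(x, "md_signal"))
  taper <- match.arg(taper)
  dt <- x$timestep
  s <- .vs_prepare(x$values, taper, remove_mean)
  N <- length(s)
  grid <- .vs_grid(N, dt, freq_window, pad_factor)
  cvals <- autocorrelate(md_signal(s, dt), max_lag_fraction = 1)$values
  omega <- cm1_to_angfreq(grid$freq)
  lags <- (1:(N - 1)) * dt
  I <- (dt / 2) * (cvals[1] +
        2 * as.numeric(cos(outer(omega, lags)) %*% cvals[-1]))
  I <- pmax(I, 0)  # clamp rounding noise; analytically I >= 0
  new_power_spectrum(
    frequencies = grid$freq,
    intensities = matrix(I, ncol = 1L, dimnames = list(NULL, "signal")),
    total_time = N * dt,
    window_meta = list(pad_factor = pad_factor, taper = taper,
                       remove_mean = remove_mean, timestep = dt,
                       n_samples = N, padded_length = grid$M,
                       nyquist_cm1 = grid$nyquist, freq_window = freq_window,
                       route = "autocorrelation"))
}

#' Two-sided spectral integral
#'
#' Evaluates \eqn{\int I(\omega)\,d\omega / (2\pi)} over the full two-sided
#' frequency axis by doubling the interior one-sided bins.  On the full
#' window, with no taper and no mean removal, this equals half the mean
#' squared signal \eqn{\langle s^2\rangle/2} (Parseval).
#'
#' @param spectrum a [power_spectrum] covering `[0, Nyquist]`.
#' @param column column index (default 1).
#' @return scalar, atomic units.
#' @export
spectrum_integral <- function(spectrum, column = 1L) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  meta <- spectrum$window_meta
  M <- meta$padded_length
  dt <- meta$timestep
  if (is.null(M) || is.null(dt))
    stop("spectrum lacks grid metadata", call. = FALSE)
  I <- spectrum$intensities[, column]
  k <- as.integer(round(spectrum$frequencies /
                          angfreq_to_cm1(2 * pi / (M * dt))))
  w <- ifelse(k == 0L | (M %% 2L == 0L & k == M %/% 2L), 1, 2)
  domega <- 2 * pi / (M * dt)
  sum(w * I) * domega / (2 * pi)
}

#' Locate spectral peaks
#'
#' Returns every strict local maximum whose intensity reaches
#' `min_relative_height` times the global maximum, sorted by frequency.
#' The global maximum itself is always included (also when it sits on a
#' window edge).  A flat spectrum has no peaks.
#'
#' @param spectrum a [power_spectrum].
#' @param column column index or name (default 1).
#' @param min_relative_height height threshold relative to the global
#'   maximum, in (0, 1].
#' @return a data frame with columns `frequency` (cm^-1) and `intensity`.
#' @export
find_peaks <- function(spectrum, column = 1L, min_relative_height = 0.1) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (min_relative_height <= 0 || min_relative_height > 1)
    stop("min_relative_height must be in (0, 1]", call. = FALSE)
  I <- spectrum$intensities[, column]
  f <- spectrum$frequencies
  n <- length(I)
  gmax <- max(I)
  if (gmax <= 0 || diff(range(I)) == 0)
    return(data.frame(frequency = numeric(0), intensity = numeric(0)))
  idx <- integer(0)
  if (n >= 3L) {
    interior <- 2:(n - 1L)
    idx <- interior[I[interior] > I[interior - 1L] &
                    I[interior] > I[interior + 1L]]
  }
  idx <- union(idx, which(I == gmax))
  idx <- sort(idx[I[idx] >= min_relative_height * gmax])
  data.frame(frequency = f[idx], intensity = I[idx])
}

#' Dominant peak of a spectrum column
#'
#' The peak of greatest intensity; on an exact intensity tie the lower
#' frequency wins, for determinism.
#'
#' @inheritParams find_peaks
#' @return named numeric vector `c(frequency, intensity)`.
#' @export
dominant_peak <- function(spectrum, column = 1L) {
  pk <- find_peaks(spectrum, column, min_relative_height = 1)
  if (nrow(pk) == 0L)
    return(c(frequency = NA_real_, intensity = NA_real_))
  c(frequency = pk$frequency[1], intensity = pk$intensity[1])
}

#' @export
print.power_spectrum <- function(x, ...) {
  f <- x$frequencies
  cat("Time-averaged power spectrum\n")
  cat(sprintf("  grid:    %d bins, %.2f .. %.2f cm^-1 (spacing %.3f)\n",
              length(f), min(f), max(f), if (length(f) > 1) f[2] - f[1] else NA))
  cat(sprintf("  columns: %s\n",
              paste(colnames(x$intensities), collapse = ", ")))
  if (!is.na(x$total_time))
    cat(sprintf("  T:       %g a.u.\n", x$total_time))
  invisible(x)
}

#' @export
summary.power_spectrum <- function(object, min_relative_height = 0.1, ...) {
  cat("Peaks per column (threshold ", min_relative_height, " x max):\n",
      sep = "")
  for (j in seq_len(ncol(object$intensities))) {
    pk <- find_peaks(object, j, min_relative_height)
    cat(sprintf("  %s: %s\n", colnames(object$intensities)[j],
                if (nrow(pk) == 0) "(flat)"
                else paste(sprintf("%.1f", pk$frequency), collapse = ", ")))
  }
  invisible(object)
}

#' @export
as.data.frame.power_spectrum <- function(x, ...) {
  data.frame(frequency = x$frequencies, x$intensities, check.names = FALSE)
}

#' @export
plot.power_spectrum <- function(x, ...) {
  graphics::matplot(x$frequencies, x$intensities, type = "l", lty = 1,
                    xlab = expression(tilde(nu) ~ (cm^-1)),
                    ylab = expression(I(omega)), ...)
  if (ncol(x$intensities) > 1L)
    graphics::legend("topright", colnames(x$intensities),
                     col = seq_len(ncol(x$intensities)), lty = 1, bty = "n")
  invisible(x)
}
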