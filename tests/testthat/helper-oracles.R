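# Independent oracles and small fixture builders used across the suite.

# Brute-force biased autocorrelation: direct double loop, the reference
# for the FFT-based estimator.
brute_autocorr <- function(s, K = length(s) - 1L) {
  N <- length(s)
  vapply(0:K, function(k)
    sum(s[seq_len(N - k)] * s[seq_len(N - k) + k]) / N, numeric(1))
}

# Direct DFT of the biased zero-extended autocorrelation on an arbitrary
# wavenumber grid: the Wiener-Khinchin route written independently of the
# package's own implementation.
brute_wk_spectrum <- function(s, dt, freq_cm1) {
  ac <- brute_autocorr(s)
  omega <- freq_cm1 / 219474.6313705
  vapply(omega, function(w) {
    k <- seq_along(ac) - 1L
    (dt / 2) * sum(ac * ifelse(k == 0L, 1, 2) * cos(w * k * dt))
  }, numeric(1))
}

# Write a tiny block-dialect trajectory file literally, for parser tests.
write_lines_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

# Nominal Angstrom/fs -> bohr per atomic time conversion used by fixtures.
ang_fs <- function() (1 / 0.52917721067) * 2.418884326509e-2
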