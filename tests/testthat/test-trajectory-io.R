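# Parsers and writers for the three trajectory dialects and the spectrum
# output, plus the unit conversions applied at the I/O boundary.

test_that("block trajectory is parsed and converted to atomic units", {
  f <- write_lines_tmp(c(
    "2",
    "O 0.0 0.0 0.0 0.1 0.0 0.0",
    "H 1.0 0.0 0.0 0.1 0.0 0.0",
    "",
    "2",
    "O 0.0 0.0 0.1 0.1 0.0 0.0",
    "H 1.0 0.0 0.1 0.1 0.0 0.0"))
  tr <- read_block_trajectory(f, timestep = 0.5, timestep_unit = "fs",
                              time_unit = "fs", space_unit = "angstrom")
  expect_s3_class(tr, "md_trajectory")
  expect_equal(tr$n_atoms, 2L)
  expect_equal(nrow(tr$velocities), 2L)
  expect_equal(tr$velocities[1, 1], 0.1 * ang_fs(), tolerance = 1e-14)
  expect_equal(tr$positions[1, 4], 1 / 0.52917721067, tolerance = 1e-14)
  expect_equal(tr$timestep, 0.5 / 2.418884326509e-2, tolerance = 1e-14)
})

test_that("malformed block files raise named format/parse errors", {
  short <- write_lines_tmp(c("3",
                             "H 0 0 0 0 0 0",
                             "H 0 0 0 0 0 0"))
  expect_error(read_block_trajectory(short, 1), class = "vibspec_format_error")

  bad <- write_lines_tmp(c("1", "H 0 0 0 0 zero 0",
                           "1", "H 0 0 0 0 0 0"))
  expect_error(read_block_trajectory(bad, 1),
               regexp = "line", class = "vibspec_parse_error")

  varying <- write_lines_tmp(c("1", "H 0 0 0 0 0 0",
                               "2", "H 0 0 0 0 0 0", "H 0 0 0 1 1 1"))
  expect_error(read_block_trajectory(varying, 1),
               class = "vibspec_format_error")

  one <- write_lines_tmp(c("1", "H 0 0 0 0 0 0"))
  expect_error(read_block_trajectory(one, 1),
               class = "vibspec_insufficient_data")
})

test_that("block write -> read round trip is the identity", {
  set.seed(7)
  tr <- md_trajectory(labels = c("C", "H", "O"),
                      velocities = matrix(rnorm(9 * 4), 4, 9),
                      positions = matrix(rnorm(9 * 4), 4, 9),
                      timestep = 10)
  f <- tempfile()
  write_block_trajectory(tr, f)
  tr2 <- read_block_trajectory(f, timestep = 10)
  expect_identical(tr2$labels, tr$labels)
  expect_equal(tr2$velocities, tr$velocities, tolerance = 0)
  expect_equal(tr2$positions, tr$positions, tolerance = 0)
})

test_that("normal-mode dialect parses declared fixtures, wraps and errors", {
  f <- write_lines_tmp(c("2", "1 0", "2", "0 1", "2", "-1 0"))
  nm <- read_normal_mode_trajectory(f, timestep = 10)
  expect_equal(nm$n_modes, 2L)
  expect_equal(nm$momenta,
               matrix(c(1, 0, -1, 0, 1, 0), 3, 2), tolerance = 0)
  expect_equal(nm$total_time, 20)

  wrapped <- write_lines_tmp(c("3", "1 2", "3", "3", "4 5 6"))
  nmw <- read_normal_mode_trajectory(wrapped, timestep = 1)
  expect_equal(nmw$momenta, matrix(c(1, 4, 2, 5, 3, 6), 2, 3), tolerance = 0)

  over <- write_lines_tmp(c("2", "1 2 3", "2", "1 2"))
  expect_error(read_normal_mode_trajectory(over, 1),
               class = "vibspec_format_error")

  varying <- write_lines_tmp(c("2", "1 2", "3", "1 2 3"))
  expect_error(read_normal_mode_trajectory(varying, 1),
               class = "vibspec_format_error")

  empty <- write_lines_tmp(character(0))
  expect_error(read_normal_mode_trajectory(empty, 1),
               class = "vibspec_insufficient_data")
})

test_that("normal-mode write -> read round trip is the identity", {
  set.seed(11)
  nm <- nm_trajectory(matrix(rnorm(3 * 8), 3, 8), timestep = 5)
  f <- tempfile()
  write_normal_mode_trajectory(nm, f)
  nm2 <- read_normal_mode_trajectory(f, timestep = 5)
  expect_equal(nm2$momenta, nm$momenta, tolerance = 0)
})

test_that("Tinker dialect converts A/ps, accepts D-exponents, flags errors", {
  f <- write_lines_tmp(c(
    "2  molecule",
    "1 O  1.0 0.0 0.0",
    "2 H  0.0 1.0D+00 0.0",
    "2  molecule",
    "1 O  1.0 0.0 0.0",
    "2 H  0.0 0.0 2.5D-01"))
  tr <- read_tinker_velocities(f, timestep = 10)
  apsfac <- (1 / 0.52917721067) * 2.418884326509e-2 / 1000
  expect_null(tr$positions)
  expect_equal(tr$velocities[1, 1], 1.0 * apsfac, tolerance = 1e-14)
  expect_equal(tr$velocities[1, 5], 1.0 * apsfac, tolerance = 1e-14)
  expect_equal(tr$velocities[2, 6], 0.25 * apsfac, tolerance = 1e-14)

  missingcol <- write_lines_tmp(c("1 t", "1 O 1.0 2.0", "1 t", "1 O 1 2 3"))
  expect_error(read_tinker_velocities(missingcol, 1),
               class = "vibspec_parse_error")

  disorder <- write_lines_tmp(c("2 t", "2 O 1 2 3", "1 H 1 2 3"))
  expect_error(read_tinker_velocities(disorder, 1),
               class = "vibspec_format_error")

  wrongcount <- write_lines_tmp(c("1 t", "1 O 1 2 3",
                                  "2 t", "1 O 1 2 3"))
  expect_error(read_tinker_velocities(wrongcount, 1),
               class = "vibspec_format_error")
})

test_that("Tinker write -> read round trip is the identity", {
  set.seed(3)
  tr <- md_trajectory(labels = c("N", "H"),
                      velocities = matrix(rnorm(12), 2, 6), timestep = 10)
  f <- tempfile()
  write_tinker_velocities(tr, f)
  tr2 <- read_tinker_velocities(f, timestep = 10)
  expect_equal(tr2$velocities, tr$velocities, tolerance = 1e-15)
})

test_that("spectrum files round trip and honour the column selection", {
  sys <- generate_harmonic_trajectory(c(800, 1600, 2400), dt = 10,
                                      n_steps = 200, seed = 2)
  sp <- power_spectrum(sys$nm, modes = "all", freq_window = c(0, 3000))
  f <- tempfile()
  write_spectrum(sp, f, selection = c(1L, 3L))
  sp2 <- read_spectrum(f)
  expect_identical(colnames(sp2$intensities), c("mode_1", "mode_3"))
  expect_equal(sp2$frequencies, sp$frequencies, tolerance = 1e-10)
  expect_equal(sp2$intensities[, "mode_3"], unname(sp$intensities[, "mode_3"]),
               tolerance = 1e-9)

  fsum <- tempfile()
  write_spectrum(sp, fsum, selection = "sum")
  spsum <- read_spectrum(fsum)
  expect_equal(ncol(spsum$intensities), 1L)
  expect_equal(spsum$intensities[, 1], unname(rowSums(sp$intensities)),
               tolerance = 1e-9)

  expect_error(write_spectrum(sp, tempfile(), selection = integer(0)),
               class = "vibspec_format_error")
})

test_that("unit conversions compose to the identity", {
  for (u in c("fs", "ps")) {
    x <- 0.484
    back <- vibspec:::time_to_au(x, u) /
      vibspec:::time_to_au(1, u)
    expect_equal(back, x, tolerance = 1e-12)
  }
  expect_equal(vibspec:::length_to_au(vibspec:::length_to_au(1, "angstrom"),
                                      "au") / vibspec:::length_to_au(1, "angstrom"),
               1, tolerance = 1e-12)
})

test_that("geometry and Hessian readers parse plain text", {
  g <- write_lines_tmp(c("# comment", "O 0 0 0", "H 0.9572 0 0"))
  geo <- read_geometry(g, unit = "angstrom")
  expect_identical(geo$labels, c("O", "H"))
  expect_equal(geo$coords[4], 0.9572 / 0.52917721067, tolerance = 1e-12)

  h <- write_lines_tmp(c("1 -1", "-1 1"))
  expect_equal(read_hessian(h), matrix(c(1, -1, -1, 1), 2), tolerance = 0)
  bad <- write_lines_tmp(c("1 2 3"))
  expect_error(read_hessian(bad), class = "vibspec_format_error")
})

test_that("element labels resolve to masses; unknown labels are an error", {
  m <- atomic_masses(c("O", "h", "H1"), unit = "amu")
  expect_equal(m, c(15.999, 1.008, 1.008))
  expect_gt(atomic_masses("C") / atomic_masses("C", "amu"), 1822)
  expect_error(atomic_masses(c("H", "Xx")), regexp = "Xx")
})
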