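# Readers and writers for the three trajectory dialects and the spectrum
# output.  All readers convert to internal atomic units on the way in; all
# values downstream of this file are bohr / atomic time / electron masses.

vs_error <- function(msg, class) {
  stop(structure(class = c(class, "vibspec_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Tokenize a line: split on whitespace, normalize Fortran D-exponents.
.vs_tokens <- function(line) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1]]
  toks[nzchar(toks)]
}

.vs_numeric <- function(tokens, lineno) {
  x <- suppressWarnings(as.numeric(gsub("[dD]([+-]?[0-9])", "e\\1", tokens)))
  if (anyNA(x))
    vs_error(sprintf("non-numeric field '%s' at line %d",
                     tokens[which(is.na(x))[1]], lineno),
             "vibspec_parse_error")
  x
}

.vs_read_lines <- function(path) {
  if (!file.exists(path))
    vs_error(sprintf("file not found: %s", path), "vibspec_io_error")
  readLines(path, warn = FALSE)
}

#' Read a block-format Cartesian trajectory
#'
#' The block dialect carries one block per MD step: a first line with the
#' atom count, then one line per atom holding the element label, the three
#' Cartesian coordinates and the three velocity components
#' (`label x y z vx vy vz`).  Blank lines between blocks are ignored.
#'
#' @param path path to the trajectory file.
#' @param timestep MD time step (required; never inferred from the file).
#' @param timestep_unit unit of `timestep`: `"au"` or `"fs"`.
#' @param time_unit,space_unit units of the stored velocities (and, for
#'   `space_unit`, positions): time in `"au"`, `"fs"` or `"ps"`; space in
#'   `"au"` (bohr), `"nm"` or `"angstrom"`.
#' @return an [md_trajectory] in atomic units.
#' @export
read_block_trajectory <- function(path, timestep,
                                  timestep_unit = c("au", "fs"),
                                  time_unit = c("au", "fs", "ps"),
                                  space_unit = c("au", "nm", "angstrom")) {
  timestep_unit <- match.arg(timestep_unit)
  time_unit <- match.arg(time_unit)
  space_unit <- match.arg(space_unit)
  lines <- .vs_read_lines(path)
  nonblank <- which(nzchar(trimws(lines)))

  blocks <- list()
  labels0 <- NULL
  i <- 1L
  while (i <= length(nonblank)) {
    ln <- nonblank[i]
    head_tok <- .vs_tokens(lines[ln])
    count <- suppressWarnings(as.integer(head_tok[1]))
    if (is.na(count) || count < 1L)
      vs_error(sprintf("expected an atom count at line %d, got '%s'",
                       ln, head_tok[1]), "vibspec_format_error")
    if (i + count > length(nonblank))
      vs_error(sprintf("block %d declares %d atoms but the file ends early",
                       length(blocks) + 1L, count), "vibspec_format_error")
    lab <- character(count)
    xyzv <- matrix(NA_real_, count, 6L)
    for (a in seq_len(count)) {
      la <- nonblank[i + a]
      tok <- .vs_tokens(lines[la])
      if (length(tok) < 7L) {
        # a short line is either a malformed atom record or the count line
        # of the next block (block came up short)
        vs_error(sprintf(
          "block %d: expected %d atom lines of 'label x y z vx vy vz', bad record at line %d",
          length(blocks) + 1L, count, la), "vibspec_format_error")
      }
      lab[a] <- tok[1]
      xyzv[a, ] <- .vs_numeric(tok[2:7], la)
    }
    if (is.null(labels0)) {
      labels0 <- lab
    } else if (length(lab) != length(labels0) || any(lab != labels0)) {
      vs_error(sprintf("block %d: atom count or labels differ from block 1",
                       length(blocks) + 1L), "vibspec_format_error")
    }
    blocks[[length(blocks) + 1L]] <- xyzv
    i <- i + count + 1L
  }
  if (length(blocks) < 2L)
    vs_error("fewer than 2 trajectory blocks: not enough data for a spectrum",
             "vibspec_insufficient_data")

  nfr <- length(blocks)
  n <- length(labels0)
  pos <- matrix(0, nfr, 3L * n)
  vel <- matrix(0, nfr, 3L * n)
  for (f in seq_len(nfr)) {
    pos[f, ] <- as.vector(t(blocks[[f]][, 1:3, drop = FALSE]))
    vel[f, ] <- as.vector(t(blocks[[f]][, 4:6, drop = FALSE]))
  }
  md_trajectory(
    labels = labels0,
    velocities = vel * velocity_factor(space_unit, time_unit),
    positions = pos * length_to_au(1, space_unit),
    timestep = time_to_au(timestep, timestep_unit),
    source_units = list(time = time_unit, space = space_unit,
                        timestep = timestep_unit))
}

#' Write a block-format Cartesian trajectory
#'
#' Writes positions and velocities in atomic units at full double precision,
#' so that a write/read round trip is the identity.
#'
#' @param traj an [md_trajectory] with positions present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_block_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(traj$positions))
    vs_error("trajectory has no positions; block format requires them",
             "vibspec_format_error")
  con <- file(path, "w")
  on.exit(close(con))
  n <- traj$n_atoms
  for (f in seq_len(nrow(traj$velocities))) {
    writeLines(as.character(n), con)
    p <- matrix(traj$positions[f, ], ncol = 3L, byrow = TRUE)
    v <- matrix(traj$velocities[f, ], ncol = 3L, byrow = TRUE)
    writeLines(sprintf("%s % .17g % .17g % .17g % .17g % .17g % .17g",
                       traj$labels, p[, 1], p[, 2], p[, 3],
                       v[, 1], v[, 2], v[, 3]), con)
  }
  invisible(path)
}

#' Read a normal-mode momentum trajectory
#'
#' One block per MD step: a first line with the mode count, then that many
#' momenta, which may wrap over several lines.  A block holding more values
#' than declared is a format error.
#'
#' @inheritParams read_block_trajectory
#' @param time_unit,space_unit units in which the momenta were printed;
#'   momenta are treated as mass-weighted velocities on the internal
#'   (electron-mass) scale, so only the velocity factor is applied.
#' @return an [nm_trajectory] in atomic units.
#' @export
read_normal_mode_trajectory <- function(path, timestep,
                                        timestep_unit = c("au", "fs"),
                                        time_unit = c("au", "fs", "ps"),
                                        space_unit = c("au", "nm", "angstrom")) {
  timestep_unit <- match.arg(timestep_unit)
  time_unit <- match.arg(time_unit)
  space_unit <- match.arg(space_unit)
  lines <- .vs_read_lines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    vs_error("empty normal-mode trajectory file", "vibspec_insufficient_data")

  frames <- list()
  nmodes0 <- NULL
  i <- 1L
  while (i <= length(nonblank)) {
    ln <- nonblank[i]
    count <- suppressWarnings(as.integer(.vs_tokens(lines[ln])[1]))
    if (is.na(count) || count < 1L)
      vs_error(sprintf("expected a mode count at line %d", ln),
               "vibspec_format_error")
    vals <- numeric(0)
    i <- i + 1L
    while (length(vals) < count) {
      if (i > length(nonblank))
        vs_error(sprintf("block %d declares %d momenta but the file ends early",
                         length(frames) + 1L, count), "vibspec_format_error")
      ln <- nonblank[i]
      vals <- c(vals, .vs_numeric(.vs_tokens(lines[ln]), ln))
      i <- i + 1L
    }
    if (length(vals) != count)
      vs_error(sprintf("block %d holds %d momenta where %d were declared",
                       length(frames) + 1L, length(vals), count),
               "vibspec_format_error")
    if (is.null(nmodes0)) nmodes0 <- count
    else if (count != nmodes0)
      vs_error(sprintf("block %d declares %d modes; block 1 declared %d",
                       length(frames) + 1L, count, nmodes0),
               "vibspec_format_error")
    frames[[length(frames) + 1L]] <- vals
  }
  if (length(frames) < 2L)
    vs_error("fewer than 2 blocks in normal-mode trajectory",
             "vibspec_insufficient_data")
  mom <- do.call(rbind, frames) * velocity_factor(space_unit, time_unit)
  nm_trajectory(mom, timestep = time_to_au(timestep, timestep_unit))
}

#' Write a normal-mode momentum trajectory
#'
#' Counterpart of [read_normal_mode_trajectory()]; writes atomic units at
#' full precision, wrapping long frames at 6 values per line.
#'
#' @param nm an [nm_trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_normal_mode_trajectory <- function(nm, path) {
  stopifnot(inherits(nm, "nm_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(nm$momenta))) {
    writeLines(as.character(nm$n_modes), con)
    vals <- sprintf("% .17g", nm$momenta[f, ])
    idx <- split(vals, ceiling(seq_along(vals) / 6))
    writeLines(vapply(idx, paste, "", collapse = " "), con)
  }
  invisible(path)
}

#' Read a Tinker velocity dump
#'
#' Per frame: a header line `natoms [title]`, then per atom a line
#' `index name vx vy vz` (extra trailing columns are ignored).  Fortran
#' `D`-exponent floats are accepted.  Tinker prints velocities in
#' Angstrom/ps; the units must still be declared explicitly.  The returned
#' trajectory has no positions, which restricts it to velocity-based
#' Cartesian spectra.
#'
#' @inheritParams read_block_trajectory
#' @return an [md_trajectory] with `positions = NULL`.
#' @export
read_tinker_velocities <- function(path, timestep,
                                   timestep_unit = c("au", "fs"),
                                   time_unit = "ps",
                                   space_unit = "angstrom") {
  timestep_unit <- match.arg(timestep_unit)
  time_unit <- match.arg(time_unit, c("au", "fs", "ps"))
  space_unit <- match.arg(space_unit, c("au", "nm", "angstrom"))
  lines <- .vs_read_lines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    vs_error("empty Tinker velocity file", "vibspec_insufficient_data")

  frames <- list()
  labels0 <- NULL
  i <- 1L
  while (i <= length(nonblank)) {
    ln <- nonblank[i]
    count <- suppressWarnings(as.integer(.vs_tokens(lines[ln])[1]))
    if (is.na(count) || count < 1L)
      vs_error(sprintf("expected 'natoms [title]' header at line %d", ln),
               "vibspec_format_error")
    if (i + count > length(nonblank))
      vs_error(sprintf("frame %d declares %d atoms but the file ends early",
                       length(frames) + 1L, count), "vibspec_format_error")
    lab <- character(count)
    vel <- matrix(NA_real_, count, 3L)
    for (a in seq_len(count)) {
      la <- nonblank[i + a]
      tok <- .vs_tokens(lines[la])
      if (length(tok) < 5L)
        vs_error(sprintf("line %d: expected 'index name vx vy vz'", la),
                 "vibspec_parse_error")
      idx <- suppressWarnings(as.integer(tok[1]))
      if (is.na(idx) || idx != a)
        vs_error(sprintf("line %d: atom index %s out of order (expected %d)",
                         la, tok[1], a), "vibspec_format_error")
      lab[a] <- tok[2]
      vel[a, ] <- .vs_numeric(tok[3:5], la)
    }
    if (is.null(labels0)) labels0 <- lab
    else if (length(lab) != length(labels0))
      vs_error(sprintf("frame %d: atom count differs from frame 1",
                       length(frames) + 1L), "vibspec_format_error")
    frames[[length(frames) + 1L]] <- as.vector(t(vel))
    i <- i + count + 1L
  }
  if (length(frames) < 2L)
    vs_error("fewer than 2 frames in Tinker velocity file",
             "vibspec_insufficient_data")
  vel <- do.call(rbind, frames) * velocity_factor(space_unit, time_unit)
  md_trajectory(labels = labels0, velocities = vel, positions = NULL,
                timestep = time_to_au(timestep, timestep_unit),
                source_units = list(time = time_unit, space = space_unit,
                                    dialect = "tinker"))
}

#' Write a Tinker-dialect velocity dump
#'
#' Used to build fixtures in the Tinker dialect; velocities are written in
#' Angstrom/ps, matching what Tinker prints.
#'
#' @param traj an [md_trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tinker_velocities <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  fac <- 1 / velocity_factor("angstrom", "ps")
  for (f in seq_len(nrow(traj$velocities))) {
    writeLines(sprintf("%d  generated frame", traj$n_atoms), con)
    v <- matrix(traj$velocities[f, ] * fac, ncol = 3L, byrow = TRUE)
    writeLines(sprintf("%6d  %-3s % .17g % .17g % .17g",
                       seq_len(traj$n_atoms), traj$labels,
                       v[, 1], v[, 2], v[, 3]), con)
  }
  invisible(path)
}

#' Write a power spectrum as whitespace-delimited text
#'
#' First column is the wavenumber in cm^-1; one further column per selected
#' mode, or a single summed column.  The header line names the columns.
#'
#' @param spectrum a [power_spectrum] object.
#' @param path output path.
#' @param selection `"all"` (every stored column), `"sum"` (one column
#'   holding the elementwise sum), or an integer vector of stored column
#'   indices.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, selection = "all") {
  stopifnot(inherits(spectrum, "power_spectrum"))
  I <- spectrum$intensities
  if (identical(selection, "sum")) {
    I <- matrix(rowSums(I), ncol = 1L, dimnames = list(NULL, "sum"))
  } else if (!identical(selection, "all")) {
    sel <- as.integer(selection)
    if (length(sel) == 0L)
      vs_error("empty mode selection", "vibspec_format_error")
    if (any(sel < 1L | sel > ncol(I)))
      vs_error(sprintf("selection out of range: valid columns are 1..%d",
                       ncol(I)), "vibspec_format_error")
    I <- I[, sel, drop = FALSE]
  }
  if (length(spectrum$frequencies) == 0L)
    vs_error("empty spectrum", "vibspec_format_error")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("# freq_cm-1", colnames(I)), collapse = " "), con)
  body <- cbind(spectrum$frequencies, I)
  writeLines(apply(body, 1L, function(r)
    paste(sprintf("% .10e", r), collapse = " ")), con)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path file path.
#' @return a [power_spectrum] object (metadata fields reconstructed from
#'   the file only).
#' @export
read_spectrum <- function(path) {
  lines <- .vs_read_lines(path)
  header <- .vs_tokens(sub("^#", "", lines[1]))
  dat <- do.call(rbind, lapply(lines[-1][nzchar(trimws(lines[-1]))],
                               function(l) .vs_numeric(.vs_tokens(l), NA)))
  new_power_spectrum(
    frequencies = dat[, 1],
    intensities = matrix(dat[, -1, drop = FALSE], ncol = ncol(dat) - 1L,
                         dimnames = list(NULL, header[-1])),
    total_time = NA_real_, window_meta = list(source = path))
}

#' Read a plain-text Hessian matrix
#'
#' Whitespace-delimited numbers forming a square 3N x 3N matrix (row-major;
#' line breaks are not significant), in atomic units (hartree/bohr^2).
#'
#' @param path file path.
#' @return a numeric square matrix.
#' @export
read_hessian <- function(path) {
  lines <- .vs_read_lines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  vals <- unlist(lapply(which(nzchar(trimws(lines))), function(i)
    .vs_numeric(.vs_tokens(lines[i]), i)))
  n <- round(sqrt(length(vals)))
  if (n * n != length(vals))
    vs_error(sprintf("Hessian file holds %d numbers, not a square matrix",
                     length(vals)), "vibspec_format_error")
  matrix(vals, n, n, byrow = TRUE)
}

#' Read a geometry file
#'
#' One line per atom: `label x y z`.
#'
#' @param path file path.
#' @param unit `"au"` (bohr) or `"angstrom"`.
#' @return a list with `labels` and `coords` (numeric 3N vector, bohr).
#' @export
read_geometry <- function(path, unit = c("au", "angstrom")) {
  unit <- match.arg(unit)
  lines <- .vs_read_lines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  labels <- character(0); coords <- numeric(0)
  for (i in keep) {
    tok <- .vs_tokens(lines[i])
    if (length(tok) < 4L)
      vs_error(sprintf("line %d: expected 'label x y z'", i),
               "vibspec_parse_error")
    labels <- c(labels, tok[1])
    coords <- c(coords, .vs_numeric(tok[2:4], i))
  }
  list(labels = labels, coords = coords * length_to_au(1, unit))
}
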