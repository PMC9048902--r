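# Text readers/writers: typed XYZ, GRO, LAMMPS data and dump.

#' Write / read typed XYZ
#'
#' Extended XYZ with the bead type label per line; a trajectory writes one
#' frame block per model. Coordinates are in Angstrom.
#'
#' @param obj a \code{cg_config} or \code{cg_traj}
#' @param path file path
#' @return \code{read_xyz} returns a list with \code{types} and a list of
#'   coordinate matrices \code{frames}
#' @export
write_xyz <- function(obj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(x, types, comment) {
    writeLines(as.character(nrow(x)), con)
    writeLines(comment, con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", types, x[, 1], x[, 2], x[, 3]), con)
  }
  if (inherits(obj, "cg_traj")) {
    types <- obj$config$type_names[obj$config$type]
    for (f in seq_along(obj$time)) {
      x <- matrix(obj$frames[, f], ncol = 3, byrow = TRUE)
      emit(x, types, sprintf("t= %.1f fs box= %.4f %.4f %.4f", obj$time[f],
                             obj$box[1], obj$box[2], obj$frame_lz[f]))
    }
  } else {
    emit(obj$x, obj$type_names[obj$type],
         sprintf("box= %.4f %.4f %.4f", obj$box[1], obj$box[2], obj$box[3]))
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  types <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    types <- vapply(parts, `[[`, "", 1)
    x <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- x
    i <- i + n + 2
  }
  list(types = types, frames = frames)
}

#' Write / read GRO
#'
#' Single-configuration GROMACS coordinate file (positions in nm; fixed
#' format, 3 decimals).
#'
#' @param config a \code{cg_config}
#' @param path file path
#' @return \code{read_gro} returns a list with \code{types}, \code{x} (A)
#'   and \code{box} (A)
#' @export
write_gro <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("coarse-grained membrane configuration", con)
  n <- nrow(config$x)
  writeLines(sprintf("%5d", n), con)
  tn <- config$type_names[config$type]
  res <- config$mol %% 100000
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     res, substr(config$group, 1, 5), tn,
                     seq_len(n) %% 100000,
                     config$x[, 1] / 10, config$x[, 2] / 10, config$x[, 3] / 10),
             con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", config$box[1] / 10,
                     config$box[2] / 10, config$box[3] / 10), con)
  invisible(path)
}

#' @rdname write_gro
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[2])
  at <- lines[3:(2 + n)]
  types <- trimws(substr(at, 11, 15))
  x <- cbind(as.numeric(substr(at, 21, 28)),
             as.numeric(substr(at, 29, 36)),
             as.numeric(substr(at, 37, 44))) * 10
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3] * 10
  list(types = types, x = x, box = box)
}

#' Write a LAMMPS data file
#'
#' Full-style data file (id mol type q x y z) with bond/angle/dihedral
#' sections and per-type coefficients in comments, for cross-checking the
#' parameterization against a reference engine.
#'
#' @param config a \code{cg_config}
#' @param path file path
#' @export
write_lammps_data <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(config$x)
  bt <- unique(data.frame(K = config$bond_k, r0 = config$bond_r0))
  bidx <- match(paste(config$bond_k, config$bond_r0),
                paste(bt$K, bt$r0))
  at <- unique(data.frame(t = config$angle_type, K = config$angle_k,
                          th = config$angle_theta0))
  aidx <- match(paste(config$angle_type, config$angle_k, config$angle_theta0),
                paste(at$t, at$K, at$th))
  w <- function(...) writeLines(sprintf(...), con)
  w("coarse-grained membrane data file")
  w("")
  w("%d atoms", n)
  w("%d bonds", NROW(config$bonds))
  w("%d angles", NROW(config$angles))
  w("%d dihedrals", NROW(config$dihedrals))
  w("%d atom types", length(config$type_names))
  w("%d bond types", nrow(bt))
  w("%d angle types", max(nrow(at), 0))
  w("%d dihedral types", as.integer(NROW(config$dihedrals) > 0))
  w("")
  w("0 %.6f xlo xhi", config$box[1])
  w("0 %.6f ylo yhi", config$box[2])
  w("0 %.6f zlo zhi", config$box[3])
  w("")
  w("Masses")
  w("")
  masses <- vapply(seq_along(config$type_names), function(t) {
    i <- which(config$type == t)[1]
    if (is.na(i)) .bead_types$mass[t] else config$mass[i]
  }, 0)
  for (t in seq_along(config$type_names))
    w("%d %.3f  # %s", t, masses[t], config$type_names[t])
  w("")
  w("Atoms  # full")
  w("")
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / 50000)))
    writeLines(sprintf("%d %d %d %.4f %.6f %.6f %.6f", chunk,
                       config$mol[chunk], config$type[chunk],
                       config$charge[chunk], config$x[chunk, 1],
                       config$x[chunk, 2], config$x[chunk, 3]), con)
  if (NROW(config$bonds)) {
    w("")
    w("Bonds")
    w("")
    writeLines(sprintf("%d %d %d %d  # K=%.3f r0=%.3f",
                       seq_len(nrow(config$bonds)), bidx,
                       config$bonds[, 1], config$bonds[, 2],
                       config$bond_k, config$bond_r0), con)
  }
  if (NROW(config$angles)) {
    w("")
    w("Angles")
    w("")
    writeLines(sprintf("%d %d %d %d %d", seq_len(nrow(config$angles)), aidx,
                       config$angles[, 1], config$angles[, 2],
                       config$angles[, 3]), con)
  }
  if (NROW(config$dihedrals)) {
    w("")
    w("Dihedrals")
    w("")
    writeLines(sprintf("%d 1 %d %d %d %d", seq_len(nrow(config$dihedrals)),
                       config$dihedrals[, 1], config$dihedrals[, 2],
                       config$dihedrals[, 3], config$dihedrals[, 4]), con)
  }
  invisible(path)
}

#' Write / read a LAMMPS-style dump trajectory
#'
#' Text dump with unwrapped coordinates (\code{xu yu zu}), one block per
#' frame.
#'
#' @param traj a \code{cg_traj}
#' @param path file path
#' @return \code{read_lammps_dump} returns a list with \code{frames} (3N x F
#'   matrix), \code{time} (fs, from timesteps times \code{dt}), \code{box}
#' @export
write_lammps_dump <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dt <- traj$settings$dt
  n <- nrow(traj$config$x)
  for (f in seq_along(traj$time)) {
    writeLines(c("ITEM: TIMESTEP", as.character(round(traj$time[f] / dt)),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.6f", traj$box[1]),
                 sprintf("0 %.6f", traj$box[2]),
                 sprintf("0 %.6f", traj$frame_lz[f]),
                 "ITEM: ATOMS id type xu yu zu"), con)
    x <- matrix(traj$frames[, f], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%d %d %.6f %.6f %.6f", seq_len(n),
                       traj$config$type[seq_len(n)], x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_lammps_dump
#' @export
read_lammps_dump <- function(path, dt = 10) {
  lines <- readLines(path)
  starts <- which(lines == "ITEM: TIMESTEP")
  frames <- NULL
  times <- numeric(0)
  lzs <- numeric(0)
  box <- NULL
  for (s in starts) {
    step <- as.numeric(lines[s + 1])
    n <- as.integer(lines[s + 3])
    bx <- vapply(lines[s + 5:7], function(l)
      diff(as.numeric(strsplit(trimws(l), "\\s+")[[1]])), 0)
    cols <- strsplit(sub("ITEM: ATOMS ", "", lines[s + 8]), "\\s+")[[1]]
    wrapped <- !all(c("xu", "yu", "zu") %in% cols)
    at <- lines[(s + 9):(s + 8 + n)]
    parts <- do.call(rbind, lapply(strsplit(trimws(at), "\\s+"), as.numeric))
    parts <- parts[order(parts[, 1]), , drop = FALSE]
    ci <- match(if (wrapped) c("x", "y", "z") else c("xu", "yu", "zu"), cols)
    xyz <- parts[, ci, drop = FALSE]
    col <- as.numeric(t(xyz))
    frames <- cbind(frames, col)
    times <- c(times, step * dt)
    lzs <- c(lzs, bx[3])
    box <- bx
    attr(frames, "wrapped") <- wrapped
  }
  list(frames = frames, time = times, frame_lz = lzs, box = unname(box),
       wrapped = isTRUE(attr(frames, "wrapped")))
}

#' Write the thermodynamic log as CSV
#'
#' @param traj a \code{cg_traj}
#' @param path file path
#' @export
write_thermo_csv <- function(traj, path) {
  write.csv(traj$thermo, path, row.names = FALSE)
  invisible(path)
}
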