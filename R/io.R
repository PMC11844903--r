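#' Write a configuration as a LAMMPS data file
#'
#' Atom style `full` (id mol type charge x y z) with harmonic bonds
#' between sequence neighbours; masses and types follow the model
#' alphabet.  Coordinates in nm (LAMMPS `units` are left to the run
#' script).
#'
#' @param conf a [configuration()].
#' @param model a [cg_model()].
#' @param path output file.
#' @export
write_lammps_data <- function(conf, model, path) {
  types <- bead_types(model, conf$residue) + 1L
  bonds <- bond_list(conf$chain) + 1L
  n <- nrow(conf$positions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("LAMMPS data file generated by cgphase", con)
  writeLines("", con)
  writeLines(sprintf("%d atoms", n), con)
  writeLines(sprintf("%d bonds", nrow(bonds)), con)
  writeLines(sprintf("%d atom types", length(model$alphabet)), con)
  writeLines("1 bond types", con)
  writeLines("", con)
  writeLines(sprintf("0.0 %.6f xlo xhi", conf$box[1]), con)
  writeLines(sprintf("0.0 %.6f ylo yhi", conf$box[2]), con)
  writeLines(sprintf("0.0 %.6f zlo zhi", conf$box[3]), con)
  writeLines("", con)
  writeLines("Masses", con)
  writeLines("", con)
  writeLines(sprintf("%d %.4f", seq_along(model$alphabet),
                     model$residues$mass), con)
  writeLines("", con)
  writeLines("Atoms", con)
  writeLines("", con)
  q <- model$residues$q[types]
  writeLines(sprintf("%d %d %d %.4f %.6f %.6f %.6f", seq_len(n),
                     conf$chain, types, q, conf$positions[, 1],
                     conf$positions[, 2], conf$positions[, 3]), con)
  if (nrow(bonds) > 0) {
    writeLines("", con)
    writeLines("Bonds", con)
    writeLines("", con)
    writeLines(sprintf("%d 1 %d %d", seq_len(nrow(bonds)), bonds[, 1],
                       bonds[, 2]), con)
  }
  invisible(path)
}

#' Write/read a trajectory as LAMMPS-style text dump frames
#'
#' Standard `ITEM:`-delimited dump with `id mol type x y z` columns;
#' the residue alphabet must be supplied on reading to map types back to
#' codes.
#'
#' @param traj a `cg_trajectory`.
#' @param model a [cg_model()].
#' @param path dump file.
#' @export
write_lammps_dump <- function(traj, model, path) {
  types <- bead_types(model, traj$residue) + 1L
  n <- length(traj$chain)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    writeLines("ITEM: TIMESTEP", con)
    writeLines(format(traj$times[k], digits = 10), con)
    writeLines("ITEM: NUMBER OF ATOMS", con)
    writeLines(as.character(n), con)
    writeLines("ITEM: BOX BOUNDS pp pp pp", con)
    writeLines(sprintf("0.0 %.6f", traj$box), con)
    writeLines("ITEM: ATOMS id mol type x y z", con)
    p <- traj$frames[[k]]
    writeLines(sprintf("%d %d %d %.6f %.6f %.6f", seq_len(n), traj$chain,
                       types, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_lammps_dump
#' @param alphabet residue codes indexed by LAMMPS type (reading).
#' @return `read_lammps_dump` returns a `cg_trajectory`.
#' @export
read_lammps_dump <- function(path, alphabet) {
  lines <- readLines(path)
  its <- which(lines == "ITEM: TIMESTEP")
  if (length(its) == 0) stop("no frames found in dump file: ", path)
  frames <- list()
  times <- numeric(0)
  chain <- NULL
  residue <- NULL
  box <- NULL
  for (s in its) {
    t <- as.numeric(lines[s + 1])
    n <- as.integer(lines[s + 3])
    box <- vapply(strsplit(lines[(s + 5):(s + 7)], "\\s+"),
                  function(v) as.numeric(v[2]), numeric(1))
    rows <- strsplit(lines[(s + 9):(s + 8 + n)], "\\s+")
    m <- do.call(rbind, lapply(rows, as.numeric))
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    frames[[length(frames) + 1]] <- m[, 4:6, drop = FALSE]
    times <- c(times, t)
    chain <- as.integer(m[, 2])
    residue <- alphabet[as.integer(m[, 3])]
  }
  conf <- configuration(frames[[1]], box, chain, residue)
  trajectory(frames, times, conf)
}

#' Write/read a trajectory in a columnar text format
#'
#' One row per bead per frame: frame, t, bead, chain, residue, x, y, z,
#' with the box in a commented header.
#'
#' @param traj a `cg_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# box %.8f %.8f %.8f", traj$box[1], traj$box[2],
                     traj$box[3]), con)
  n <- length(traj$chain)
  rows <- do.call(rbind, lapply(seq_along(traj$frames), function(k) {
    data.frame(frame = k, t = traj$times[k], bead = seq_len(n),
               chain = traj$chain, residue = traj$residue,
               x = traj$frames[[k]][, 1], y = traj$frames[[k]][, 2],
               z = traj$frames[[k]][, 3])
  }))
  write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @return `read_trajectory_csv` returns a `cg_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  box <- as.numeric(strsplit(sub("# box ", "", readLines(path, n = 1)),
                             " ")[[1]])
  d <- read.csv(path, comment.char = "#")
  ks <- sort(unique(d$frame))
  frames <- lapply(ks, function(k) {
    dk <- d[d$frame == k, ]
    dk <- dk[order(dk$bead), ]
    unname(as.matrix(dk[, c("x", "y", "z")]))
  })
  d1 <- d[d$frame == ks[1], ]
  d1 <- d1[order(d1$bead), ]
  conf <- configuration(frames[[1]], box, d1$chain, d1$residue)
  trajectory(frames, vapply(ks, function(k) d$t[d$frame == k][1],
                            numeric(1)), conf)
}
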