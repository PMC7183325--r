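# Trajectory readers/writers: XYZ, LAMMPS text dump ("ITEM: TIMESTEP" /
# "ITEM: ATOMS id type x y z" dialect) and multi-model PDB.

#' Read a trajectory
#'
#' @param path file path.
#' @param format one of `"xyz"`, `"lammps-dump"`, `"pdb-multi-model"`.
#' @param topology the matching [topology()]; per-frame atom counts must
#'   agree.
#' @param dt sampling interval in ps, used to synthesise times for formats
#'   that do not store them (XYZ, PDB).
#' @param box box edges (Angstrom) for formats that do not store them
#'   (XYZ, and PDB without CRYST1).
#' @param timestep_fs MD integration step in fs used to convert LAMMPS
#'   TIMESTEP counters to ps (default 2 fs, the conventional step).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = c("xyz", "lammps-dump",
                                             "pdb-multi-model"),
                            topology, dt = 10, box = NULL, timestep_fs = 2) {
  format <- match.arg(format)
  na <- n_atoms(topology)
  switch(format,
    "xyz" = {
      fr <- read_xyz_frames(path, box)
      check_frame_counts(fr, na)
      for (k in seq_along(fr)) fr[[k]]$time <- (k - 1) * dt
      trajectory(topology, fr, dt = dt)
    },
    "lammps-dump" = {
      parsed <- read_dump_frames(path)
      check_frame_counts(parsed$frames, na)
      times <- parsed$steps * timestep_fs / 1000
      if (any(diff(times) <= 0)) stop("non-monotone times in dump file")
      for (k in seq_along(parsed$frames)) parsed$frames[[k]]$time <- times[k]
      trajectory(topology, parsed$frames,
                 dt = if (length(times) > 1L) times[2] - times[1] else dt)
    },
    "pdb-multi-model" = {
      pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
      bx <- read_cryst1(path)
      if (is.null(bx)) bx <- box
      if (is.null(bx)) stop("PDB file has no CRYST1 record; supply box=")
      xyz <- pdb$xyz
      nfr <- nrow(xyz)
      fr <- lapply(seq_len(nfr), function(m) {
        X <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
        frame(X, bx, time = (m - 1) * dt)
      })
      check_frame_counts(fr, na)
      trajectory(topology, fr, dt = dt)
    })
}

check_frame_counts <- function(frames, na) {
  for (k in seq_along(frames))
    if (nrow(frames[[k]]$coords) != na)
      stop("atom-count mismatch at frame ", k, ": got ",
           nrow(frames[[k]]$coords), ", expected ", na)
  invisible(TRUE)
}

read_xyz_frames <- function(path, box) {
  if (is.null(box)) stop("XYZ stores no box; supply box=")
  ln <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(ln)) {
    if (!nzchar(trimws(ln[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(ln[i])))
    if (is.na(n)) stop("XYZ format error at line ", i, ": expected atom count")
    if (i + 1L + n > length(ln))
      stop("XYZ truncated in frame starting at line ", i)
    body <- ln[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(parts) < 4L))
      stop("XYZ format error near line ", i + 2L)
    X <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- frame(X, box)
    i <- i + 2L + n
  }
  frames
}

#' Write a trajectory to an XYZ file
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nm <- traj$topology$atoms$name
  for (f in seq_len(n_frames(traj))) {
    X <- traj$frames[[f]]$coords
    writeLines(as.character(nrow(X)), con)
    writeLines(sprintf("t= %.6f ps", traj$times[f]), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", nm, X[, 1], X[, 2], X[, 3]),
               con)
  }
  invisible(path)
}

read_dump_frames <- function(path) {
  ln <- readLines(path)
  frames <- list()
  steps <- integer()
  i <- 1L
  while (i <= length(ln)) {
    if (!startsWith(ln[i], "ITEM: TIMESTEP"))
      stop("dump format error at line ", i, ": expected 'ITEM: TIMESTEP'")
    step <- as.integer(trimws(ln[i + 1L]))
    if (!startsWith(ln[i + 2L], "ITEM: NUMBER OF ATOMS"))
      stop("dump format error at line ", i + 2L)
    n <- as.integer(trimws(ln[i + 3L]))
    if (!startsWith(ln[i + 4L], "ITEM: BOX BOUNDS"))
      stop("dump format error at line ", i + 4L)
    bb <- t(vapply(strsplit(trimws(ln[i + 5:7]), "[[:space:]]+"),
                   function(p) as.numeric(p[1:2]), numeric(2)))
    box <- bb[, 2] - bb[, 1]
    if (!startsWith(ln[i + 8L], "ITEM: ATOMS"))
      stop("dump format error at line ", i + 8L)
    cols <- strsplit(trimws(sub("ITEM: ATOMS", "", ln[i + 8L])),
                     "[[:space:]]+")[[1]]
    need <- match(c("id", "x", "y", "z"), cols)
    if (anyNA(need)) stop("dump ATOMS section must provide id x y z")
    body <- ln[(i + 9L):(i + 8L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(parts) < length(cols)))
      stop("dump format error in frame at line ", i)
    M <- t(vapply(parts, function(p) as.numeric(p[need]), numeric(4)))
    M <- M[order(M[, 1]), , drop = FALSE]
    frames[[length(frames) + 1L]] <- frame(M[, 2:4, drop = FALSE], box)
    steps <- c(steps, step)
    i <- i + 9L + n
  }
  list(frames = frames, steps = steps)
}

#' Write a trajectory as a LAMMPS text dump
#'
#' Emits the `ITEM: TIMESTEP` / `ITEM: ATOMS id type x y z` dialect; the
#' TIMESTEP counter is `time_ps * 1000 / timestep_fs`.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param timestep_fs integration step used for the counter (default 2).
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(traj, path, timestep_fs = 2) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- n_atoms(traj$topology)
  type <- as.integer(factor(traj$topology$atoms$name))
  for (f in seq_len(n_frames(traj))) {
    frm <- traj$frames[[f]]
    writeLines(c("ITEM: TIMESTEP",
                 as.character(round(traj$times[f] * 1000 / timestep_fs)),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("%.6f %.6f", 0, frm$box[1]),
                 sprintf("%.6f %.6f", 0, frm$box[2]),
                 sprintf("%.6f %.6f", 0, frm$box[3]),
                 "ITEM: ATOMS id type x y z"), con)
    writeLines(sprintf("%d %d %.6f %.6f %.6f", seq_len(n), type,
                       frm$coords[, 1], frm$coords[, 2], frm$coords[, 3]), con)
  }
  invisible(path)
}
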