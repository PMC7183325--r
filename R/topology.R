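# Domain containers: topology (atoms + strand/glycan/solvent assignment +
# bonds), frame (time, box, coords) and trajectory (topology + frames).

CELLULOSE_ATOM_NAMES <- c(
  "C1", "C2", "C3", "C4", "C5", "C6",
  "O1", "O2", "O3", "O4", "O5", "O6",
  "H1", "H2", "H3", "H4", "H5", "H61", "H62",
  "HO1", "HO2", "HO3", "HO4", "HO6"
)

# amu; standard atomic weights
ELEMENT_MASSES <- c(H = 1.008, C = 12.011, O = 15.999, P = 30.974, Cl = 35.453)

#' Infer the chemical element from an atom name
#'
#' Uses the naming scheme of the cellulose/TBP/water/chloride system: `Cl` is
#' chlorine, `P` phosphorus, names beginning `C` carbon, `O`/`Ow` oxygen and
#' everything beginning `H` hydrogen.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
element_from_name <- function(name) {
  out <- character(length(name))
  out[name == "Cl"] <- "Cl"
  out[name == "P"] <- "P"
  first <- substr(name, 1, 1)
  out[out == "" & first == "C"] <- "C"
  out[out == "" & first == "O"] <- "O"
  out[out == "" & first == "H"] <- "H"
  if (any(out == ""))
    stop("cannot infer element for atom name(s): ",
         paste(unique(name[out == ""]), collapse = ", "))
  out
}

#' Construct a topology
#'
#' A topology holds the atom table (one row per atom with name, element, mass,
#' optional charge), the strand/glycan assignment for cellulose atoms, the
#' solvent-molecule assignment (species and molecule id), and the covalent
#' bond list.  Every atom belongs to exactly one strand glycan or one solvent
#' molecule.
#'
#' @param atoms data.frame with columns `atom_id`, `name`, `element`, `mass`,
#'   `charge` (may be `NA`), `strand`, `glycan` (NA for solvent), `species`
#'   (`"cellulose"`, `"TBP"`, `"Cl"`, `"water"`), `mol_id` (NA for cellulose).
#' @param bonds two-column integer matrix of bonded atom-id pairs.
#' @param n_glycans glycans per strand (integer); 0 when no cellulose present.
#' @param layout optional cross-section layout (see [default_layout()]).
#' @return an object of class `"topology"`.
#' @export
topology <- function(atoms, bonds = NULL, n_glycans = 0L, layout = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("atom_id", "name", "element", "mass", "charge",
            "strand", "glycan", "species", "mol_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$atom_id)) stop("atom_id values must be unique")
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n_strands <- if (any(atoms$species == "cellulose"))
    max(atoms$strand[atoms$species == "cellulose"]) else 0L
  obj <- list(atoms = atoms, bonds = bonds,
              n_strands = as.integer(n_strands),
              n_glycans = as.integer(n_glycans),
              layout = layout)
  class(obj) <- "topology"
  obj
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms;",
      x$n_strands, "strands x", x$n_glycans, "glycans;",
      sum(x$atoms$species == "TBP" & !duplicated(x$atoms$mol_id) &
            x$atoms$species == "TBP"), "")
  tab <- table(x$atoms$species)
  cat(paste(names(tab), tab, collapse = ", "), "atoms by species\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology a [topology()] object.
#' @return integer atom count.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' Construct a single trajectory frame
#'
#' @param coords numeric matrix (n x 3) of coordinates in Angstrom.
#' @param box numeric 3-vector of orthorhombic box edge lengths in Angstrom.
#' @param time time stamp in ps.
#' @return an object of class `"frame"`.
#' @export
frame <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, length(box) == 3L)
  if (any(box <= 0)) stop("box edges must be positive")
  structure(list(coords = coords, box = as.numeric(box), time = as.numeric(time)),
            class = "frame")
}

#' Construct a trajectory
#'
#' @param topology a [topology()].
#' @param frames list of [frame()] objects with matching atom counts and
#'   strictly increasing times.
#' @param dt nominal sampling interval in ps (defaults to the first time
#'   difference, or 1 for single-frame trajectories).
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(topology, frames, dt = NULL) {
  stopifnot(inherits(topology, "topology"), length(frames) >= 1L)
  na <- n_atoms(topology)
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$coords) != na)
      stop("frame ", k, ": atom count ", nrow(frames[[k]]$coords),
           " does not match topology (", na, ")")
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(dt)) dt <- if (length(times) > 1L) times[2] - times[1] else 1
  if (dt <= 0) stop("dt must be positive")
  structure(list(topology = topology, frames = frames,
                 times = times, dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames,",
      n_atoms(x$topology), "atoms, t =", x$times[1], "..",
      x$times[length(x$times)], "ps (dt =", x$dt, "ps)\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

# atom indices (row numbers) helpers -------------------------------------

atoms_of_strand <- function(topology, strand) {
  which(topology$atoms$species == "cellulose" & topology$atoms$strand == strand)
}

atoms_of_glycan <- function(topology, strand, glycan) {
  which(topology$atoms$species == "cellulose" &
          topology$atoms$strand == strand & topology$atoms$glycan == glycan)
}

atoms_of_species <- function(topology, species) {
  which(topology$atoms$species == species)
}

# adjacency list (by atom row index == atom_id for package-built topologies)
bond_adjacency <- function(topology) {
  n <- n_atoms(topology)
  adj <- vector("list", n)
  b <- topology$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b[k, 1]; j <- b[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}
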