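# Pseudo-solvent molecule templates (TBP+, Cl-, water) and random packing.

# 53-atom pseudo-tetrabutylphosphonium: tetrahedral P with four all-anti
# butyl arms.  Only the topology (P + 16 C + 36 H) and rough sterics matter.
tbp_template <- function() {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  coords <- matrix(0, 53, 3)
  name <- character(53)
  bonds <- matrix(0L, 0, 2)
  coords[1, ] <- c(0, 0, 0)
  name[1] <- "P"
  k <- 1L
  hnames <- list(c("HP", "HP"), c("HC2", "HC2"), c("HC3", "HC3"),
                 c("HC4", "HC4", "HC4"))
  for (a in 1:4) {
    d <- dirs[a, ]
    # two perpendicular unit vectors for hydrogen placement
    u <- c(d[2], -d[1], 0); u <- u / sqrt(sum(u^2))
    v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
           d[1] * u[2] - d[2] * u[1])
    prev <- 1L
    for (ci in 1:4) {
      k <- k + 1L
      c_idx <- k
      coords[k, ] <- d * (1.85 + 1.54 * (ci - 1))
      name[k] <- "CT"
      bonds <- rbind(bonds, c(prev, c_idx))
      hs <- hnames[[ci]]
      for (hi in seq_along(hs)) {
        k <- k + 1L
        sgn <- if (hi == 1L) u else if (hi == 2L) -u else v
        coords[k, ] <- coords[c_idx, ] + 1.09 * sgn
        name[k] <- hs[hi]
        bonds <- rbind(bonds, c(c_idx, k))
      }
      prev <- c_idx
    }
  }
  list(coords = coords, name = name, bonds = bonds)
}

water_template <- function() {
  list(coords = rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.2400, 0.9266, 0)),
       name = c("Ow", "Hw", "Hw"),
       bonds = rbind(c(1L, 2L), c(1L, 3L)))
}

cl_template <- function() {
  list(coords = matrix(0, 1, 3), name = "Cl", bonds = matrix(0L, 0, 2))
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Delete solvent molecules overlapping the cellulose bundle
#'
#' Removes every solvent molecule having at least one atom within `cutoff`
#' (minimum image) of any cellulose atom — the standard insertion rule used
#' when a pre-equilibrated solvent box is combined with a cellulose bundle.
#'
#' @param topology combined topology (cellulose + solvent).
#' @param frm a [frame()] for the topology.
#' @param cutoff deletion distance in Angstrom (default 2).
#' @return list with the pruned `topology`, `frame` and `n_deleted` (named
#'   count of removed molecules by species).
#' @export
delete_overlapping_solvent <- function(topology, frm, cutoff = 2) {
  at <- topology$atoms
  cell <- which(at$species == "cellulose")
  solv <- which(at$species != "cellulose")
  if (!length(cell) || !length(solv))
    return(list(topology = topology, frame = frm,
                n_deleted = c(TBP = 0L, Cl = 0L, water = 0L)))
  hits <- neighbour_pairs(frm$coords[solv, , drop = FALSE],
                          frm$coords[cell, , drop = FALSE],
                          cutoff, frm$box)
  bad_atoms <- solv[unique(hits$i)]
  bad_mols <- unique(at$mol_id[bad_atoms])
  bad_mols <- bad_mols[!is.na(bad_mols)]
  keep <- is.na(at$mol_id) | !(at$mol_id %in% bad_mols)
  n_del <- c(
    TBP = length(unique(at$mol_id[!keep & at$species == "TBP"])),
    Cl = length(unique(at$mol_id[!keep & at$species == "Cl"])),
    water = length(unique(at$mol_id[!keep & at$species == "water"]))
  )
  sub <- subset_topology(topology, which(keep))
  list(topology = sub,
       frame = frame(frm$coords[keep, , drop = FALSE], frm$box, frm$time),
       n_deleted = n_del)
}

# keep a subset of atom rows, renumbering atom ids and remapping bonds
subset_topology <- function(topology, keep_idx) {
  at <- topology$atoms[keep_idx, , drop = FALSE]
  map <- integer(n_atoms(topology))
  map[keep_idx] <- seq_along(keep_idx)
  b <- topology$bonds
  if (nrow(b)) {
    ok <- map[b[, 1]] > 0L & map[b[, 2]] > 0L
    b <- cbind(map[b[ok, 1]], map[b[ok, 2]])
  }
  at$atom_id <- seq_len(nrow(at))
  rownames(at) <- NULL
  topology(at, b, n_glycans = topology$n_glycans, layout = topology$layout)
}

#' Pack pseudo-solvent molecules around a cellulose bundle
#'
#' Places `n_tbpcl` TBP/Cl ion pairs and `n_water` water molecules at random
#' positions and orientations in an orthorhombic box by rejection sampling
#' (molecule centres kept at least `min_sep` apart), then applies the 2 A
#' cellulose-overlap deletion rule of [delete_overlapping_solvent()].  This
#' is a geometric packing for estimator validation, not a physical
#' equilibration.
#'
#' @param comp list with counts `n_tbpcl` and `n_water`.
#' @param box 3-vector of box edges, Angstrom.
#' @param bundle optional list(topology, frame) from [build_ibeta_bundle()];
#'   when given, solvent is merged with the bundle and the deletion rule is
#'   applied.
#' @param seed optional integer seed for reproducible packing.
#' @param min_sep minimum centre-centre separation between solvent molecules
#'   (Angstrom, default 3).
#' @param max_tries placement attempts per molecule before a packing error.
#' @param delete_cutoff cellulose-overlap deletion distance (Angstrom).
#' @return list(topology, frame, n_requested, n_deleted, n_final) where the
#'   count vectors are named by species.
#' @export
pack_solvent <- function(comp, box, bundle = NULL, seed = NULL,
                         min_sep = 3, max_tries = 500L, delete_cutoff = 2) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n_tbpcl <- comp$n_tbpcl
  n_water <- comp$n_water
  stopifnot(n_tbpcl >= 0, n_water >= 0, all(box > 0))

  species_plan <- c(rep("TBP", n_tbpcl), rep("Cl", n_tbpcl), rep("water", n_water))
  tmpls <- list(TBP = tbp_template(), Cl = cl_template(), water = water_template())

  centres <- matrix(0, 0, 3)
  coords_list <- vector("list", length(species_plan))
  atoms_list <- vector("list", length(species_plan))
  bonds_list <- vector("list", length(species_plan))
  offset <- 0L
  for (m in seq_along(species_plan)) {
    sp <- species_plan[m]
    tmpl <- tmpls[[sp]]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ctr <- runif(3) * box
      if (nrow(centres)) {
        if (min(mic_dist_to(ctr, centres, box)) < min_sep) next
      }
      placed <- TRUE
      break
    }
    if (!placed)
      stop("packing error: could not place molecule ", m, " (", sp,
           ") after ", max_tries, " tries; placed ", m - 1L, " molecules")
    centres <- rbind(centres, ctr)
    xyz <- tmpl$coords %*% t(random_rotation())
    xyz <- sweep(xyz, 2L, ctr, "+")
    coords_list[[m]] <- xyz
    el <- element_from_name(tmpl$name)
    atoms_list[[m]] <- data.frame(
      atom_id = offset + seq_along(tmpl$name), name = tmpl$name, element = el,
      mass = unname(ELEMENT_MASSES[el]), charge = NA_real_,
      strand = NA_integer_, glycan = NA_integer_,
      species = sp, mol_id = m, stringsAsFactors = FALSE
    )
    if (nrow(tmpl$bonds)) bonds_list[[m]] <- tmpl$bonds + offset
    offset <- offset + length(tmpl$name)
  }
  solv_atoms <- do.call(rbind, atoms_list)
  solv_bonds <- do.call(rbind, bonds_list)
  solv_coords <- do.call(rbind, coords_list)
  if (is.null(solv_atoms))
    solv_atoms <- data.frame(atom_id = integer(), name = character(),
                             element = character(), mass = numeric(),
                             charge = numeric(), strand = integer(),
                             glycan = integer(), species = character(),
                             mol_id = integer(), stringsAsFactors = FALSE)

  n_req <- c(TBP = n_tbpcl, Cl = n_tbpcl, water = n_water)
  if (is.null(bundle)) {
    topo <- topology(solv_atoms, solv_bonds, n_glycans = 0L)
    frm <- frame(if (is.null(solv_coords)) matrix(0, 0, 3) else solv_coords, box)
    return(list(topology = topo, frame = frm, n_requested = n_req,
                n_deleted = c(TBP = 0L, Cl = 0L, water = 0L),
                n_final = n_req))
  }
  merged <- merge_topologies(bundle$topology, topology(solv_atoms, solv_bonds))
  coords <- rbind(bundle$frame$coords, solv_coords)
  frm <- frame(coords, box, bundle$frame$time)
  res <- delete_overlapping_solvent(merged, frm, cutoff = delete_cutoff)
  n_final <- n_req - res$n_deleted[names(n_req)]
  list(topology = res$topology, frame = res$frame, n_requested = n_req,
       n_deleted = res$n_deleted, n_final = n_final)
}

#' Merge two topologies
#'
#' Concatenates atom tables and bond lists, renumbering atom ids and solvent
#' molecule ids of the second topology.
#'
#' @param a,b [topology()] objects; cellulose metadata (glycan count,
#'   layout) is taken from `a`.
#' @return merged [topology()].
#' @export
merge_topologies <- function(a, b) {
  off <- n_atoms(a)
  bt <- b$atoms
  bt$atom_id <- bt$atom_id + off
  mol_off <- if (all(is.na(a$atoms$mol_id))) 0L else max(a$atoms$mol_id, na.rm = TRUE)
  bt$mol_id <- bt$mol_id + mol_off
  bonds <- rbind(a$bonds, if (nrow(b$bonds)) b$bonds + off)
  at <- rbind(a$atoms, bt)
  at$atom_id <- seq_len(nrow(at))
  rownames(at) <- NULL
  topology(at, bonds, n_glycans = a$n_glycans, layout = a$layout)
}
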