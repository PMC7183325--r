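# Geometric hydrogen-bond detection, classification, and per-glycan
# strand-class averaging.

#' Hydrogen-bond geometric criteria
#'
#' A donor-H...acceptor triple is a hydrogen bond when the H...A minimum
#' image distance is at most `d_ha_max`, the angle at the chosen vertex
#' between the D-H and D-A (or H-D and H-A) directions is at most
#' `angle_max`, and the donor-acceptor distance is at most `d_da_max`.
#'
#' @param d_ha_max maximum hydrogen-acceptor distance, Angstrom.
#' @param angle_max maximum angle, degrees.
#' @param d_da_max maximum donor-acceptor distance, Angstrom.
#' @param angle_vertex `"donor"` (default) measures the angle at the donor
#'   heavy atom between D->H and D->A; `"hydrogen"` measures the
#'   deviation-from-linearity angle at the hydrogen.
#' @return object of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(d_ha_max = 2.45, angle_max = 30, d_da_max = 3.5,
                           angle_vertex = c("donor", "hydrogen")) {
  stopifnot(d_ha_max > 0, angle_max > 0, d_da_max >= d_ha_max)
  structure(list(d_ha_max = d_ha_max, angle_max = angle_max,
                 d_da_max = d_da_max, angle_vertex = match.arg(angle_vertex)),
            class = "hbond_criteria")
}

# default donor heavy-atom names: oxygens that carry a bonded hydrogen
# (cellulose hydroxyls, chain caps, water); with include_ch, carbons too.
default_donor_names <- function(topology, include_ch = FALSE) {
  adj <- bond_adjacency(topology)
  at <- topology$atoms
  has_h <- vapply(seq_len(nrow(at)), function(i)
    any(at$element[adj[[i]]] == "H"), logical(1))
  el_ok <- at$element == "O" | (include_ch & at$element == "C")
  sort(unique(at$name[el_ok & has_h]))
}

default_acceptor_names <- function(topology) {
  at <- topology$atoms
  sort(unique(at$name[at$element %in% c("O", "Cl")]))
}

#' Detect hydrogen bonds in a frame
#'
#' Emits one record per donor-hydrogen-acceptor triple satisfying the
#' geometric criteria under the minimum-image convention.  A hydrogen may
#' bond several acceptors simultaneously (no exclusivity is imposed).
#' Output is ordered by donor id, then acceptor id.
#'
#' @param frm a [frame()].
#' @param topology matching [topology()] (bond list must cover the donor
#'   hydrogens).
#' @param criteria an [hbond_criteria()].
#' @param donors character vector of donor heavy-atom names; default is
#'   every oxygen with a bonded hydrogen.  Set `include_ch = TRUE` to add
#'   C-H donors.
#' @param acceptors character vector of acceptor atom names; default all
#'   oxygens and chloride.
#' @param include_ch include carbon donors in the default donor set.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   ids), `d_ha`, `d_da`, `angle`.
#' @export
detect_hbonds <- function(frm, topology, criteria = hbond_criteria(),
                          donors = NULL, acceptors = NULL,
                          include_ch = FALSE) {
  at <- topology$atoms
  if (is.null(donors)) donors <- default_donor_names(topology, include_ch)
  if (is.null(acceptors)) acceptors <- default_acceptor_names(topology)
  adj <- bond_adjacency(topology)

  d_idx <- which(at$name %in% donors)
  if (!length(d_idx)) return(empty_hbonds())
  # (donor, hydrogen) pairs; atoms of a donor name can lack a hydrogen in
  # some positions (e.g. bridging vs chain-terminating O4) and are skipped,
  # but a donor name with no bonded hydrogen anywhere is a topology error.
  dh <- do.call(rbind, lapply(d_idx, function(i) {
    hs <- adj[[i]][at$element[adj[[i]]] == "H"]
    if (!length(hs)) return(NULL)
    cbind(donor = i, hydrogen = hs)
  }))
  hopeless <- setdiff(intersect(donors, at$name),
                      if (is.null(dh)) character() else at$name[dh[, "donor"]])
  if (length(hopeless))
    stop("donor name(s) with no bonded hydrogen: ",
         paste(hopeless, collapse = ", "))
  if (is.null(dh)) return(empty_hbonds())
  a_idx <- which(at$name %in% acceptors)
  if (!length(a_idx)) return(empty_hbonds())

  X <- frm$coords
  cand <- neighbour_pairs(X[dh[, "hydrogen"], , drop = FALSE],
                          X[a_idx, , drop = FALSE],
                          criteria$d_ha_max, frm$box)
  if (!nrow(cand)) return(empty_hbonds())
  don <- dh[cand$i, "donor"]
  hyd <- dh[cand$i, "hydrogen"]
  acc <- a_idx[cand$j]
  keep <- acc != don & acc != hyd
  don <- don[keep]; hyd <- hyd[keep]; acc <- acc[keep]
  d_ha <- cand$d[keep]
  if (!length(don)) return(empty_hbonds())

  # donor-acceptor distance and the angle at the chosen vertex
  d_da <- vapply(seq_along(don), function(k)
    minimum_image_distance(X[don[k], ], X[acc[k], ], frm$box), numeric(1))
  ang <- vapply(seq_along(don), function(k) {
    if (criteria$angle_vertex == "donor") {
      v1 <- mic_displacement(rbind(X[hyd[k], ] - X[don[k], ]), frm$box)[1, ]
      v2 <- mic_displacement(rbind(X[acc[k], ] - X[don[k], ]), frm$box)[1, ]
    } else {
      v1 <- mic_displacement(rbind(X[don[k], ] - X[hyd[k], ]), frm$box)[1, ]
      v2 <- -mic_displacement(rbind(X[acc[k], ] - X[hyd[k], ]), frm$box)[1, ]
    }
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }, numeric(1))

  ok <- d_da <= criteria$d_da_max & ang <= criteria$angle_max
  out <- data.frame(donor = don[ok], hydrogen = hyd[ok], acceptor = acc[ok],
                    d_ha = d_ha[ok], d_da = d_da[ok], angle = ang[ok])
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

empty_hbonds <- function() {
  data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
             d_ha = numeric(), d_da = numeric(), angle = numeric())
}

#' Classify detected hydrogen bonds
#'
#' Partitions bonds into `intra_primary` (same strand, acceptor-donor named
#' pair O5...HO3-O3 or O6...HO2-O2), `intra_other` (same strand, any other
#' pair), `inter_strand` (different cellulose strands), `Cl_strand`,
#' `TBP_strand`, `water_strand` (one side solvent, one side cellulose) and
#' `solvent_solvent`.
#'
#' @param bonds data.frame from [detect_hbonds()].
#' @param topology matching [topology()].
#' @return `bonds` with an added `class` column (factor over the seven
#'   classes).
#' @export
classify_hbonds <- function(bonds, topology) {
  at <- topology$atoms
  lv <- c("intra_primary", "intra_other", "inter_strand",
          "Cl_strand", "TBP_strand", "water_strand", "solvent_solvent")
  if (!nrow(bonds)) {
    bonds$class <- factor(character(), levels = lv)
    return(bonds)
  }
  d_sp <- at$species[bonds$donor]
  a_sp <- at$species[bonds$acceptor]
  d_cell <- d_sp == "cellulose"
  a_cell <- a_sp == "cellulose"
  cls <- character(nrow(bonds))

  both <- d_cell & a_cell
  same <- both & at$strand[bonds$donor] == at$strand[bonds$acceptor]
  pair <- paste(at$name[bonds$acceptor], at$name[bonds$donor])
  primary <- pair %in% c("O5 O3", "O6 O2")
  cls[same & primary] <- "intra_primary"
  cls[same & !primary] <- "intra_other"
  cls[both & !same] <- "inter_strand"

  one_solv <- xor(d_cell, a_cell)
  solv_sp <- ifelse(d_cell, a_sp, d_sp)
  cls[one_solv] <- paste0(solv_sp[one_solv], "_strand")
  cls[!d_cell & !a_cell] <- "solvent_solvent"
  bonds$class <- factor(cls, levels = lv)
  bonds
}

#' Per-glycan hydrogen-bond averages by strand class
#'
#' Averages bond counts per glycan over a time window and over the strands
#' of each cross-section class.  `intra_primary` counts are normalised by
#' `g - 1` glycans (the last glycan has no junction partner); all other
#' classes by `g`.  Inter-strand bonds are credited to both participating
#' strands; solvent bonds to the cellulose strand.
#'
#' @param bonds data.frame with a `frame` column (1-based frame index) plus
#'   the [classify_hbonds()] columns, accumulated over a trajectory.
#' @param topology the [topology()].
#' @param class_map data.frame from [classify_strands()].
#' @param times frame times (ps), one per trajectory frame.
#' @param window numeric length-2, time window `[t0, t1]` in ps.
#' @return data.frame with columns `strand_class`, `bond_class`,
#'   `bonds_per_glycan`.
#' @export
per_glycan_class_average <- function(bonds, topology, class_map, times,
                                     window = range(times)) {
  in_win <- which(times >= window[1] & times <= window[2])
  if (!length(in_win)) stop("empty time window [", window[1], ", ", window[2], "] ps")
  g <- topology$n_glycans
  at <- topology$atoms
  strand_classes <- sort(unique(class_map$class))
  bond_classes <- c("intra_primary", "inter_strand",
                    "Cl_strand", "TBP_strand", "water_strand")
  # per-strand, per-bond-class total counts over the window
  counts <- matrix(0, topology$n_strands, length(bond_classes),
                   dimnames = list(NULL, bond_classes))
  b <- bonds[bonds$frame %in% in_win & bonds$class %in% bond_classes, , drop = FALSE]
  if (nrow(b)) {
    d_str <- at$strand[b$donor]
    a_str <- at$strand[b$acceptor]
    for (k in seq_len(nrow(b))) {
      cl <- as.character(b$class[k])
      ds <- d_str[k]; as_ <- a_str[k]
      if (cl == "inter_strand") {
        counts[ds, cl] <- counts[ds, cl] + 1
        counts[as_, cl] <- counts[as_, cl] + 1
      } else {
        s <- if (!is.na(ds)) ds else as_
        counts[s, cl] <- counts[s, cl] + 1
      }
    }
  }
  counts <- counts / length(in_win)  # time average
  basis <- c(intra_primary = g - 1, inter_strand = g,
             Cl_strand = g, TBP_strand = g, water_strand = g)
  rows <- list()
  for (sc in strand_classes) {
    strands <- class_map$strand[class_map$class == sc]
    for (bc in bond_classes) {
      rows[[length(rows) + 1L]] <- data.frame(
        strand_class = sc, bond_class = bc,
        bonds_per_glycan = mean(counts[strands, bc]) / basis[[bc]])
    }
  }
  do.call(rbind, rows)
}

#' Count solvent molecules near a target atom set
#'
#' Counts molecules of one species having at least one atom within `cutoff`
#' (minimum image) of at least one target atom — the display/selection rule
#' used for solvent shown near the inner glycans.
#'
#' @param frm a [frame()].
#' @param topology matching [topology()].
#' @param target integer atom indices of the target set.
#' @param cutoff Angstrom (default 3.5).
#' @param species one of `"TBP"`, `"Cl"`, `"water"`.
#' @return integer molecule count.
#' @export
solvent_proximity_count <- function(frm, topology, target, cutoff = 3.5,
                                    species = "water") {
  stopifnot(length(target) > 0)
  at <- topology$atoms
  sp_idx <- which(at$species == species)
  if (!length(sp_idx)) return(0L)
  hits <- neighbour_pairs(frm$coords[sp_idx, , drop = FALSE],
                          frm$coords[target, , drop = FALSE],
                          cutoff, frm$box)
  length(unique(at$mol_id[sp_idx[unique(hits$i)]]))
}

#' Census of the solvent pocket between two strands
#'
#' A molecule is in the pocket when it has at least one atom within `cutoff`
#' of each of the two strands.  Reports per-frame TBP and water counts over
#' a window plus the time-averaged TBP:water exchange ratio reduced to a
#' small integer ratio (one-decimal rounding), or `"-"` when undefined.
#'
#' @param traj a [trajectory()].
#' @param strand_a,strand_b distinct strand indices.
#' @param cutoff Angstrom (default 3.5).
#' @param window time window in ps (default all frames).
#' @return list(per_frame, mean_tbp, mean_water, ratio).
#' @export
pocket_census <- function(traj, strand_a, strand_b, cutoff = 3.5,
                          window = NULL) {
  if (strand_a == strand_b) stop("strands must be distinct")
  topo <- traj$topology
  at <- topo$atoms
  ia <- atoms_of_strand(topo, strand_a)
  ib <- atoms_of_strand(topo, strand_b)
  frames <- seq_len(n_frames(traj))
  if (!is.null(window))
    frames <- frames[traj$times >= window[1] & traj$times <= window[2]]
  res <- lapply(frames, function(f) {
    frm <- traj$frames[[f]]
    counts <- vapply(c("TBP", "water"), function(sp) {
      sp_idx <- which(at$species == sp)
      if (!length(sp_idx)) return(0L)
      near_a <- neighbour_pairs(frm$coords[sp_idx, , drop = FALSE],
                                frm$coords[ia, , drop = FALSE], cutoff, frm$box)
      near_b <- neighbour_pairs(frm$coords[sp_idx, , drop = FALSE],
                                frm$coords[ib, , drop = FALSE], cutoff, frm$box)
      ma <- unique(at$mol_id[sp_idx[unique(near_a$i)]])
      mb <- unique(at$mol_id[sp_idx[unique(near_b$i)]])
      length(intersect(ma, mb))
    }, integer(1))
    data.frame(frame = f, time = traj$times[f],
               n_TBP = counts[["TBP"]], n_water = counts[["water"]])
  })
  per_frame <- do.call(rbind, res)
  mt <- mean(per_frame$n_TBP)
  mw <- mean(per_frame$n_water)
  ratio <- if (mt == 0 && mw == 0) "-" else {
    lo <- min(mt[mt > 0], mw[mw > 0])
    r1 <- round(mt / lo, 1)
    r2 <- round(mw / lo, 1)
    fmt <- function(x) if (abs(x - round(x)) < 1e-9) as.character(round(x)) else
      format(x, nsmall = 1)
    paste0(fmt(r1), ":", fmt(r2))
  }
  list(per_frame = per_frame, mean_tbp = mt, mean_water = mw, ratio = ratio)
}

#' Hydrogen bonds over every frame of a trajectory
#'
#' Convenience wrapper: runs [detect_hbonds()] and [classify_hbonds()] per
#' frame and row-binds the results with a `frame` column.
#'
#' @inheritParams detect_hbonds
#' @param traj a [trajectory()].
#' @return classified bond table with `frame` first.
#' @export
detect_hbonds_trajectory <- function(traj, criteria = hbond_criteria(),
                                     donors = NULL, acceptors = NULL,
                                     include_ch = FALSE) {
  out <- lapply(seq_len(n_frames(traj)), function(f) {
    b <- detect_hbonds(traj$frames[[f]], traj$topology, criteria,
                       donors, acceptors, include_ch)
    b <- classify_hbonds(b, traj$topology)
    if (nrow(b)) cbind(frame = f, b) else cbind(frame = integer(), b)
  })
  do.call(rbind, out)
}
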