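# Group-group pairwise nonbonded energy decomposition: Lennard-Jones +
# truncated Coulomb with Lorentz-Berthelot mixing, bonded exclusions up to
# 1-4, and the peeling-strand conventions (1-5-or-further interactions
# retained within the strand; 20 A cutoffs; no long-range corrections).

COULOMB_CONSTANT <- 332.0636  # kcal A / (mol e^2)

#' Read a force-field parameter file
#'
#' Plain-text schema: comma- or whitespace-separated columns
#' `name charge epsilon sigma` (elementary charge, kcal/mol, Angstrom);
#' lines starting with `#` are comments.  One row per atom name.
#'
#' @param path file path.
#' @return data.frame(name, charge, epsilon, sigma).
#' @export
read_ff_params <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  parts <- strsplit(ln, "[,[:space:]]+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) stop("malformed parameter line ", bad[1], ": ", ln[bad[1]])
  out <- data.frame(
    name = vapply(parts, `[`, "", 1L),
    charge = as.numeric(vapply(parts, `[`, "", 2L)),
    epsilon = as.numeric(vapply(parts, `[`, "", 3L)),
    sigma = as.numeric(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$charge) | is.na(out$epsilon) | is.na(out$sigma)))
    stop("non-numeric parameter value in ", path)
  if (any(out$epsilon < 0) || any(out$sigma <= 0))
    stop("epsilon must be >= 0 and sigma > 0")
  out
}

#' Toy force-field parameters for the synthetic system
#'
#' Generic charges and Lennard-Jones constants for every atom name the
#' builders emit.  These are plausible-magnitude placeholders for exercising
#' the energy machinery on synthetic geometries, not a validated force
#' field.
#'
#' @return data.frame(name, charge, epsilon, sigma).
#' @export
toy_ff_params <- function() {
  tab <- rbind(
    # name    q      eps   sig
    c("C1",  0.30, 0.110, 3.40), c("C2", 0.25, 0.110, 3.40),
    c("C3",  0.25, 0.110, 3.40), c("C4", 0.25, 0.110, 3.40),
    c("C5",  0.25, 0.110, 3.40), c("C6", 0.20, 0.110, 3.40),
    c("O1", -0.60, 0.170, 3.00), c("O2", -0.60, 0.170, 3.00),
    c("O3", -0.60, 0.170, 3.00), c("O4", -0.40, 0.170, 3.00),
    c("O5", -0.40, 0.170, 3.00), c("O6", -0.60, 0.170, 3.00),
    c("H1",  0.05, 0.016, 2.50), c("H2", 0.05, 0.016, 2.50),
    c("H3",  0.05, 0.016, 2.50), c("H4", 0.05, 0.016, 2.50),
    c("H5",  0.05, 0.016, 2.50), c("H61", 0.05, 0.016, 2.50),
    c("H62", 0.05, 0.016, 2.50),
    c("HO1", 0.40, 0.000, 1.00), c("HO2", 0.40, 0.000, 1.00),
    c("HO3", 0.40, 0.000, 1.00), c("HO4", 0.40, 0.000, 1.00),
    c("HO6", 0.40, 0.000, 1.00),
    c("P",   0.80, 0.200, 3.74), c("CT", 0.00, 0.066, 3.50),
    c("HP",  0.05, 0.030, 2.50), c("HC2", 0.03, 0.030, 2.50),
    c("HC3", 0.03, 0.030, 2.50), c("HC4", 0.03, 0.030, 2.50),
    c("Cl", -1.00, 0.100, 4.40),
    c("Ow", -0.834, 0.152, 3.15), c("Hw", 0.417, 0.000, 1.00)
  )
  data.frame(name = tab[, 1], charge = as.numeric(tab[, 2]),
             epsilon = as.numeric(tab[, 3]), sigma = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
}

#' Build the bonded exclusion set
#'
#' Excludes every atom pair connected by a bonded path of length 1, 2 or 3
#' (1-2, 1-3 and 1-4 interactions), matching zeroed 1-2/1-3/1-4 scaling
#' factors; 1-5 and further pairs are retained.
#'
#' @param topology a [topology()] with a bond list.
#' @return list of integer vectors: `excl[[i]]` holds the partners excluded
#'   for atom `i` (symmetric).
#' @export
build_exclusions <- function(topology) {
  n <- n_atoms(topology)
  adj <- bond_adjacency(topology)
  excl <- vector("list", n)
  for (i in seq_len(n)) {
    d1 <- adj[[i]]
    d2 <- unique(unlist(adj[d1]))
    d3 <- unique(unlist(adj[d2]))
    e <- setdiff(unique(as.integer(c(d1, d2, d3))), i)
    excl[i] <- list(sort(e))  # keep empty entries (unbonded atoms)
  }
  excl
}

# per-atom parameter lookup, erroring on missing names
atom_params <- function(topology, params) {
  idx <- match(topology$atoms$name, params$name)
  if (anyNA(idx)) {
    miss <- unique(topology$atoms$name[is.na(idx)])
    stop("missing force-field parameters for atom name(s): ",
         paste(miss, collapse = ", "))
  }
  list(q = params$charge[idx], eps = params$epsilon[idx],
       sig = params$sigma[idx])
}

#' Pairwise nonbonded energy between two atom groups
#'
#' Sums `4 eps [(sig/r)^12 - (sig/r)^6] + C q1 q2 / r` over unexcluded atom
#' pairs within the minimum-image cutoff, with Lorentz-Berthelot mixing
#' (arithmetic sigma, geometric epsilon) and plain truncation at the cutoff
#' (no shifting, no long-range corrections).  When the two groups are
#' identical the internal energy over unique unexcluded pairs is returned.
#'
#' @param frm a [frame()].
#' @param topology matching [topology()].
#' @param params parameter table (see [read_ff_params()]).
#' @param group_a,group_b integer atom indices; disjoint, or identical for
#'   self-energy mode.
#' @param exclusions list from [build_exclusions()] (or `NULL` for none).
#' @param cutoff Angstrom (default 20).
#' @return named numeric: `lj`, `coulomb`, `total` (kcal/mol).
#' @export
pair_energy <- function(frm, topology, params, group_a, group_b,
                        exclusions = NULL, cutoff = 20) {
  ap <- atom_params(topology, params)
  self_mode <- length(group_a) == length(group_b) && all(group_a == group_b)
  if (!self_mode && length(intersect(group_a, group_b)))
    stop("groups must be disjoint or identical")
  if (!self_mode && min(group_b) < min(group_a)) {
    # canonical iteration order makes E(A,B) and E(B,A) bitwise identical
    tmp <- group_a; group_a <- group_b; group_b <- tmp
  }
  X <- frm$coords
  lj <- 0
  coul <- 0
  for (i in group_a) {
    partners <- if (self_mode) group_b[group_b > i] else group_b
    if (!is.null(exclusions) && length(exclusions[[i]]))
      partners <- partners[!(partners %in% exclusions[[i]])]
    if (!length(partners)) next
    r <- mic_dist_to(X[i, ], X[partners, , drop = FALSE], frm$box)
    sel <- r <= cutoff & r > 0
    if (!any(sel)) next
    r <- r[sel]
    p <- partners[sel]
    sig <- (ap$sig[i] + ap$sig[p]) / 2
    eps <- sqrt(ap$eps[i] * ap$eps[p])
    sr6 <- (sig / r)^6
    lj <- lj + sum(4 * eps * (sr6^2 - sr6))
    coul <- coul + sum(COULOMB_CONSTANT * ap$q[i] * ap$q[p] / r)
  }
  c(lj = lj, coulomb = coul, total = lj + coul)
}

#' Energy decomposition around a peeling strand
#'
#' Splits the nonbonded energy felt by one (peeling) strand into the
#' contributions of each solvent species (Cl, TBP, water), the rest of the
#' cellulose bundle, and the strand's own internal 1-5-or-further term
#' (bonded exclusions remove 1-2/1-3/1-4 pairs).  Each solvent species'
#' term is the full pair sum between that species' atoms and the strand.
#'
#' @param frm a [frame()].
#' @param topology matching [topology()].
#' @param params force-field parameter table.
#' @param strand peeling strand index.
#' @param exclusions from [build_exclusions()] (computed when `NULL`).
#' @param cutoff Angstrom (default 20).
#' @return data.frame(group, lj, coulomb, total); groups `Cl`, `TBP`,
#'   `water`, `bundle`, `intra_strand_15plus`.
#' @export
decompose_strand_energy <- function(frm, topology, params, strand,
                                    exclusions = NULL, cutoff = 20) {
  if (!strand %in% seq_len(topology$n_strands))
    stop("strand ", strand, " not present")
  if (is.null(exclusions)) exclusions <- build_exclusions(topology)
  at <- topology$atoms
  s_idx <- atoms_of_strand(topology, strand)
  groups <- list(
    Cl = which(at$species == "Cl"),
    TBP = which(at$species == "TBP"),
    water = which(at$species == "water"),
    bundle = which(at$species == "cellulose" & at$strand != strand)
  )
  rows <- lapply(names(groups), function(gn) {
    gi <- groups[[gn]]
    e <- if (length(gi))
      pair_energy(frm, topology, params, gi, s_idx, exclusions, cutoff)
    else c(lj = 0, coulomb = 0, total = 0)
    data.frame(group = gn, lj = e[["lj"]], coulomb = e[["coulomb"]],
               total = e[["total"]])
  })
  e_self <- pair_energy(frm, topology, params, s_idx, s_idx, exclusions, cutoff)
  rows[[length(rows) + 1L]] <- data.frame(
    group = "intra_strand_15plus", lj = e_self[["lj"]],
    coulomb = e_self[["coulomb"]], total = e_self[["total"]])
  do.call(rbind, rows)
}

#' Per-group energy time series over a trajectory
#'
#' Runs [decompose_strand_energy()] on every frame, optionally smoothing
#' each group's trace with [rolling_average()].
#'
#' @inheritParams decompose_strand_energy
#' @param traj a [trajectory()].
#' @param window,stride rolling-average parameters; `window = 1` disables
#'   smoothing.
#' @return data.frame(time, group, lj, coulomb, total); when smoothed, a
#'   data.frame(group, index, time, total_smoothed).
#' @export
energy_trace <- function(traj, params, strand, exclusions = NULL,
                         cutoff = 20, window = 1L, stride = 1L) {
  if (is.null(exclusions)) exclusions <- build_exclusions(traj$topology)
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    d <- decompose_strand_energy(traj$frames[[f]], traj$topology, params,
                                 strand, exclusions, cutoff)
    cbind(time = traj$times[f], d)
  })
  out <- do.call(rbind, rows)
  if (window <= 1L) return(out)
  sm <- lapply(split(out, out$group), function(gdf) {
    gdf <- gdf[order(gdf$time), ]
    ra <- rolling_average(gdf$total, window, stride)
    data.frame(group = gdf$group[1], index = ra$index,
               time = gdf$time[ra$index], total_smoothed = ra$value)
  })
  out <- do.call(rbind, sm)
  rownames(out) <- NULL
  out
}
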