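# Independent brute-force oracles and small fixture builders.  These are
# deliberately naive re-implementations (image enumeration, O(N^2) loops,
# alternative formulas) kept separate from the package's code paths.

# minimum-image distance by explicit enumeration of the 27 periodic images
oracle_min_image <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    bb <- b + c(ix, iy, iz) * box
    best <- min(best, sqrt(sum((bb - a)^2)))
  }
  best
}

# O(N^2) hydrogen-bond detector: loops over every (donor, H) pair and every
# acceptor, using oracle_min_image and an acos angle at the donor.
oracle_hbonds <- function(frm, topo, criteria, donors, acceptors) {
  at <- topo$atoms
  X <- frm$coords
  box <- frm$box
  adj <- vector("list", nrow(at))
  b <- topo$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  out <- list()
  for (d in which(at$name %in% donors)) {
    hs <- adj[[d]][at$element[adj[[d]]] == "H"]
    for (h in hs) for (a in which(at$name %in% acceptors)) {
      if (a == d || a == h) next
      d_ha <- oracle_min_image(X[h, ], X[a, ], box)
      if (d_ha > criteria$d_ha_max) next
      d_da <- oracle_min_image(X[d, ], X[a, ], box)
      if (d_da > criteria$d_da_max) next
      # wrapped bond vectors
      w <- function(v) v - box * round(v / box)
      v1 <- w(X[h, ] - X[d, ])
      v2 <- w(X[a, ] - X[d, ])
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang <= criteria$angle_max)
        out[[length(out) + 1L]] <- c(d, h, a)
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 3))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 3], m[, 2]), , drop = FALSE]
}

# O(N^2) pairwise nonbonded energy
oracle_pair_energy <- function(frm, topo, params, ga, gb, excl, cutoff) {
  at <- topo$atoms
  X <- frm$coords
  q <- params$charge[match(at$name, params$name)]
  eps <- params$epsilon[match(at$name, params$name)]
  sig <- params$sigma[match(at$name, params$name)]
  self <- identical(sort(ga), sort(gb))
  lj <- 0; coul <- 0
  for (i in ga) for (j in gb) {
    if (self && j <= i) next
    if (!is.null(excl) && j %in% excl[[i]]) next
    r <- oracle_min_image(X[i, ], X[j, ], frm$box)
    if (r > cutoff || r == 0) next
    s <- (sig[i] + sig[j]) / 2
    e <- sqrt(eps[i] * eps[j])
    lj <- lj + 4 * e * ((s / r)^12 - (s / r)^6)
    coul <- coul + 332.0636 * q[i] * q[j] / r
  }
  c(lj = lj, coulomb = coul, total = lj + coul)
}

# O(N^2) molecule proximity count
oracle_proximity <- function(frm, topo, target, cutoff, species) {
  at <- topo$atoms
  mols <- unique(at$mol_id[at$species == species])
  n <- 0L
  for (m in mols) {
    idx <- which(at$species == species & at$mol_id == m)
    hit <- FALSE
    for (i in idx) for (t in target) {
      if (oracle_min_image(frm$coords[i, ], frm$coords[t, ], frm$box) <= cutoff) {
        hit <- TRUE; break
      }
    }
    if (hit) n <- n + 1L
  }
  n
}

# dihedral by the projection formula (independent of the cross-product
# normal construction used in the package)
oracle_dihedral <- function(p) {
  # half-plane directions from the central bond towards atoms 1 and 4
  b2 <- p[3, ] - p[2, ]
  b2n <- b2 / sqrt(sum(b2^2))
  a1 <- p[1, ] - p[2, ]; a4 <- p[4, ] - p[3, ]
  u <- a1 - sum(a1 * b2n) * b2n
  v <- a4 - sum(a4 * b2n) * b2n
  cross <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                            a[1]*b[2]-a[2]*b[1])
  ang <- atan2(sum(cross(u, v) * b2n), sum(u * v)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# a box of randomly placed, randomly oriented waters
random_water_box <- function(n, box, seed) {
  set.seed(seed)
  res <- pack_solvent(list(n_tbpcl = 0L, n_water = n), box = box,
                      seed = seed, min_sep = 2.0)
  res
}

# tiny topology: one donor water (H aimed at the acceptor site) plus one
# acceptor water (hydrogens pointing away); the acceptor O sits at distance
# `d` along +x from the donor O.
two_water_fixture <- function(d, box = c(30, 30, 30)) {
  mk <- function(id0, mol, X) {
    data.frame(atom_id = id0 + 0:2, name = c("Ow", "Hw", "Hw"),
               element = c("O", "H", "H"),
               mass = c(15.999, 1.008, 1.008), charge = NA_real_,
               strand = NA_integer_, glycan = NA_integer_,
               species = "water", mol_id = mol, stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk(1L, 1L), mk(4L, 2L))
  bonds <- rbind(c(1L, 2L), c(1L, 3L), c(4L, 5L), c(4L, 6L))
  topo <- topology(atoms, bonds)
  coords <- rbind(
    c(5, 5, 5), c(5 + 0.9572, 5, 5), c(5 - 0.24, 5 + 0.9266, 5),  # donor
    c(5 + d, 5, 5), c(5 + d + 0.24, 5 + 0.9266, 5),
    c(5 + d + 0.24, 5 - 0.9266, 5))                                # acceptor
  list(topology = topo, frame = frame(coords, box))
}
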