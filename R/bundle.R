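# Ideal I-beta bundle builder and strand-class geometry.
#
# The glycan template is schematic: atom positions are hand-placed so that,
# under the geometric hydrogen-bond criteria (H...A <= 2.45 A, donor-vertex
# angle <= 30 deg, D...A <= 3.5 A), every glycosidic junction carries exactly
# the two primary intra-strand bonds (O5...HO3-O3 and O6...HO2-O2) and each
# pair of strands adjacent within a sheet shares one O3...HO6-O6 bond per
# glycan.  Bond lengths and a few non-bonded contacts are not physically
# accurate; the template is a controlled geometry for validating estimators,
# not a crystal structure.

# local template: 21 atoms per glycan, z along the strand axis.
glycan_template <- function() {
  m <- rbind(
    C1  = c( 0.90,  0.40,  3.95),
    C2  = c( 2.10,  1.00,  2.60),
    C3  = c( 1.45,  0.45,  1.35),
    C4  = c( 0.60, -0.35,  0.55),
    C5  = c( 0.05, -0.30,  1.70),
    C6  = c( 1.90,  0.20,  0.90),
    O2  = c( 3.40,  1.80,  3.30),
    O3  = c( 0.95,  0.30, -0.05),
    O4  = c(-0.35, -0.30,  4.85),
    O5  = c( 0.00,  0.00,  3.10),
    O6  = c( 3.60,  0.70,  1.15),
    H1  = c( 1.20, -0.55,  4.40),
    H2  = c( 2.30,  1.90,  3.15),
    H3  = c( 2.35, -0.15,  1.55),
    H4  = c( 0.00, -1.20,  0.70),
    H5  = c(-0.95, -0.70,  1.70),
    H61 = c( 2.15, -0.70,  0.40),
    H62 = c( 1.50,  0.75,  0.05),
    HO2 = c( 3.462, 1.460, 4.239),  # aimed at O6 of glycan j+1
    HO3 = c( 0.532, 0.168, -0.949), # aimed at O5 of glycan j-1
    HO6 = c( 4.481, 0.550, 0.700)   # aimed at O3 of the +x neighbour strand
  )
  colnames(m) <- c("x", "y", "z")
  m
}

# bonds within one glycan, by local atom index (template row order)
glycan_template_bonds <- function() {
  rbind(
    c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 10), c(10, 1),  # pyranose ring
    c(5, 6),                                                  # C5-C6
    c(2, 7), c(3, 8), c(1, 9), c(6, 11),                      # C-O
    c(1, 12), c(2, 13), c(3, 14), c(4, 15), c(5, 16),         # C-H
    c(6, 17), c(6, 18),
    c(7, 19), c(8, 20), c(11, 21)                             # O-H hydroxyls
  )
}

#' Default bundle cross-section layout
#'
#' Strand positions on an integer (row, col) grid, one row per strand in
#' strand order.  Defaults: 18 strands on a 3x6 grid, 88 strands on an 8x11
#' grid, otherwise a near-square row-major rectangle.  Strands adjacent along
#' a row (the col direction) form a hydrogen-bonded sheet.
#'
#' @param n_strands number of strands.
#' @return data.frame with columns `strand`, `row`, `col`.
#' @export
default_layout <- function(n_strands) {
  stopifnot(n_strands >= 1L)
  dims <- if (n_strands == 18L) c(3L, 6L)
  else if (n_strands == 88L) c(8L, 11L)
  else {
    w <- ceiling(sqrt(n_strands))
    c(as.integer(ceiling(n_strands / w)), as.integer(w))
  }
  g <- expand.grid(col = seq_len(dims[2]), row = seq_len(dims[1]))
  g <- g[seq_len(n_strands), ]
  data.frame(strand = seq_len(n_strands), row = g$row, col = g$col)
}

#' Build an ideal I-beta-like cellulose bundle
#'
#' Constructs an all-atom bundle with the standard cellulose atom naming
#' (C1-C6, O2-O6, HO2/HO3/HO6, H1-H5/H61/H62) on a rigid lattice: glycan
#' repeat `spacing["c"]` along z, strand spacing `spacing["a"]` within a
#' sheet (x) and `spacing["b"]` between sheets (y).  Each strand has
#' `21 * n_glycans + 3` atoms (the three extras cap the chain ends: O1/HO1 on
#' glycan 1 and HO4 on the last glycan).  Hydroxyl hydrogens are oriented so
#' the hydrogen-bond detector finds exactly two primary intra-strand bonds
#' per junction and one inter-strand bond per glycan between strands adjacent
#' within a sheet.
#'
#' @param n_strands number of strands (default 18).
#' @param n_glycans glycans per strand (default 12, must be >= 2).
#' @param layout cross-section layout as from [default_layout()].
#' @param spacing named numeric: `a` sheet spacing, `b` inter-sheet spacing,
#'   `c` glycan repeat, Angstrom.
#' @param box optional 3-vector box edges; default adds a 25 A vacuum margin
#'   on every side of the bundle.
#' @return list with elements `topology` and `frame`.
#' @examples
#' b <- build_ibeta_bundle(n_strands = 1, n_glycans = 2)
#' n_atoms(b$topology)  # 45
#' @export
build_ibeta_bundle <- function(n_strands = 18L, n_glycans = 12L,
                               layout = default_layout(n_strands),
                               spacing = c(a = 5.0, b = 5.0, c = 5.19),
                               box = NULL) {
  stopifnot(n_strands >= 1L, n_glycans >= 2L)
  if (nrow(layout) != n_strands)
    stop("layout has ", nrow(layout), " sites but n_strands is ", n_strands)
  tmpl <- glycan_template()
  tb <- glycan_template_bonds()
  g <- n_glycans
  per_strand <- 21L * g + 3L

  coords <- matrix(0, n_strands * per_strand, 3)
  name <- character(n_strands * per_strand)
  strand_id <- integer(n_strands * per_strand)
  glycan_id <- integer(n_strands * per_strand)
  bonds <- vector("list", n_strands)

  # per-strand layout: [O1, HO1, glycan 1 (21), ..., glycan g (21), HO4]
  # so residue numbers are monotone within a strand block
  for (s in seq_len(n_strands)) {
    x0 <- (layout$col[s] - 1) * spacing["a"]
    y0 <- (layout$row[s] - 1) * spacing["b"]
    base <- (s - 1L) * per_strand
    sb <- matrix(0L, 0, 2)
    gbase <- function(j) base + 2L + (j - 1L) * 21L
    for (j in seq_len(g)) {
      idx <- gbase(j) + 1:21
      coords[idx, ] <- sweep(tmpl, 2L, c(x0, y0, (j - 1) * spacing["c"]), "+")
      name[idx] <- rownames(tmpl)
      strand_id[idx] <- s
      glycan_id[idx] <- j
      sb <- rbind(sb, tb + gbase(j))
      if (j > 1L)  # glycosidic link O4(j-1)-C4(j)
        sb <- rbind(sb, c(gbase(j - 1L) + 9L, idx[4]))
    }
    # chain caps: O1/HO1 off C4 of glycan 1, HO4 on O4 of glycan g
    c4_1 <- coords[gbase(1L) + 4L, ]
    o1 <- c4_1 + c(-0.30, -0.65, -1.20)
    coords[base + 1L, ] <- o1
    coords[base + 2L, ] <- o1 + c(0, -0.406, -0.914)
    o4_g <- coords[gbase(g) + 9L, ]
    coords[base + per_strand, ] <- o4_g + c(-0.50, 0, 0.866)
    name[c(base + 1:2, base + per_strand)] <- c("O1", "HO1", "HO4")
    strand_id[c(base + 1:2, base + per_strand)] <- s
    glycan_id[c(base + 1:2, base + per_strand)] <- c(1L, 1L, g)
    sb <- rbind(sb,
                c(gbase(1L) + 4L, base + 1L), c(base + 1L, base + 2L),
                c(gbase(g) + 9L, base + per_strand))
    bonds[[s]] <- sb
  }

  el <- element_from_name(name)
  atoms <- data.frame(
    atom_id = seq_along(name), name = name, element = el,
    mass = unname(ELEMENT_MASSES[el]), charge = NA_real_,
    strand = strand_id, glycan = glycan_id,
    species = "cellulose", mol_id = NA_integer_,
    stringsAsFactors = FALSE
  )
  topo <- topology(atoms, do.call(rbind, bonds), n_glycans = g, layout = layout)

  if (is.null(box)) {
    span <- apply(coords, 2, function(v) diff(range(v)))
    box <- span + 50
    coords <- sweep(coords, 2L, apply(coords, 2, min) - 25, "-")
  }
  list(topology = topo, frame = frame(coords, box, time = 0))
}

#' Classify bundle strands by cross-section position
#'
#' Labels every strand of a cross-section layout as one of `corner`,
#' `first_layer`, `second_layer`, `above_corner` or `center`, matching the
#' solvent-exposure classes used when comparing hydrogen bonding across a
#' bundle.  Rules (deterministic given the layout): the boundary is the set
#' of sites missing at least one of their four orthogonal neighbours;
#' corners are the convex-hull vertices of the site set; the remaining
#' boundary is the first layer.  Among interior (eroded) sites:
#' `above_corner` sites touch a corner (orthogonally or diagonally),
#' `second_layer` is the boundary of the eroded set, and the rest is
#' `center`.  Degenerate case: when the eroded set has no interior of its
#' own, all its sites are `center`.
#'
#' @param layout data.frame with columns `strand`, `row`, `col`.
#' @return data.frame with columns `strand`, `row`, `col`, `class`,
#'   `mirror` (index of the strand at the centro-symmetric site, `NA` if
#'   that site is unoccupied).
#' @examples
#' classify_strands(default_layout(9))  # 3x3: 4 corner, 4 first_layer, 1 center
#' @export
classify_strands <- function(layout) {
  n <- nrow(layout)
  key <- paste(layout$row, layout$col)
  has <- function(r, c) paste(r, c) %in% key
  orth_n <- function(r, c) sum(has(r + 1, c), has(r - 1, c), has(r, c + 1), has(r, c - 1))
  cls <- rep(NA_character_, n)

  boundary <- vapply(seq_len(n),
                     function(i) orth_n(layout$row[i], layout$col[i]) < 4L,
                     logical(1))
  # convex-hull vertices of the site set = corners
  if (n == 1L) {
    corner <- TRUE
  } else if (n == 2L || length(unique(layout$row)) == 1L ||
             length(unique(layout$col)) == 1L) {
    # collinear: the two extremes are corners
    ord <- order(layout$row, layout$col)
    corner <- seq_len(n) %in% ord[c(1L, n)]
  } else {
    hull <- grDevices::chull(layout$col, layout$row)
    corner <- seq_len(n) %in% hull
  }
  cls[boundary & corner] <- "corner"
  cls[boundary & !corner] <- "first_layer"

  er <- which(!boundary)
  if (length(er)) {
    ekey <- paste(layout$row[er], layout$col[er])
    ehas <- function(r, c) paste(r, c) %in% ekey
    e_interior <- vapply(er, function(i) {
      r <- layout$row[i]; c <- layout$col[i]
      ehas(r + 1, c) && ehas(r - 1, c) && ehas(r, c + 1) && ehas(r, c - 1)
    }, logical(1))
    if (!any(e_interior)) {
      cls[er] <- "center"
    } else {
      corners <- which(cls == "corner")
      near_corner <- vapply(er, function(i) {
        any(abs(layout$row[i] - layout$row[corners]) <= 1 &
              abs(layout$col[i] - layout$col[corners]) <= 1)
      }, logical(1))
      e_boundary <- !vapply(seq_along(er), function(k) e_interior[k], logical(1))
      cls[er[near_corner]] <- "above_corner"
      cls[er[!near_corner & e_boundary]] <- "second_layer"
      cls[er[!near_corner & !e_boundary]] <- "center"
    }
  }

  # mirror pairs: centro-symmetric site in the layout
  rr <- max(layout$row) + min(layout$row)
  cc <- max(layout$col) + min(layout$col)
  mirror <- vapply(seq_len(n), function(i) {
    m <- which(layout$row == rr - layout$row[i] & layout$col == cc - layout$col[i])
    if (length(m) == 1L) layout$strand[m] else NA_integer_
  }, integer(1))

  data.frame(strand = layout$strand, row = layout$row, col = layout$col,
             class = cls, mirror = mirror, stringsAsFactors = FALSE)
}
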