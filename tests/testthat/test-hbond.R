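# Geometric hydrogen-bond detection, classification and averaging.

test_that("detection follows the distance and angle thresholds exactly", {
  # ideal linear O-H...O at d(H..A) = 1.8 A
  fx <- two_water_fixture(0.9572 + 1.8)
  hb <- detect_hbonds(fx$frame, fx$topology)
  expect_identical(nrow(hb), 1L)
  expect_equal(hb$d_ha, 1.8, tolerance = 1e-6)

  # d(H..A) = 2.50 A, otherwise ideal: rejected by the 2.45 A threshold
  fx2 <- two_water_fixture(0.9572 + 2.50)
  expect_identical(nrow(detect_hbonds(fx2$frame, fx2$topology)), 0L)

  # just inside: accepted
  fx3 <- two_water_fixture(0.9572 + 2.44)
  expect_identical(nrow(detect_hbonds(fx3$frame, fx3$topology)), 1L)
})

test_that("detector equals the all-pairs brute-force oracle on random boxes", {
  crit <- hbond_criteria()
  total <- 0L
  for (k in 1:60) {
    box <- c(14, 15, 13)
    res <- random_water_box(n = 25, box = box, seed = 100 + k)
    hb <- detect_hbonds(res$frame, res$topology, crit)
    want <- oracle_hbonds(res$frame, res$topology, crit,
                          donors = "Ow", acceptors = "Ow")
    got <- as.matrix(hb[, c("donor", "hydrogen", "acceptor")])
    got <- got[order(got[, 1], got[, 3], got[, 2]), , drop = FALSE]
    dimnames(got) <- NULL
    dimnames(want) <- NULL
    storage.mode(got) <- "integer"
    storage.mode(want) <- "integer"
    expect_equal(got, want)
    total <- total + nrow(want)
  }
  expect_gt(total, 0L)  # the comparison is not vacuous
})

test_that("classification is a partition consistent with atom ownership", {
  packed <- pack_solvent(list(n_tbpcl = 3L, n_water = 12L), box = c(42, 42, 46),
                         bundle = build_ibeta_bundle(4, 3, box = c(42, 42, 46)),
                         seed = 31)
  hb <- detect_hbonds(packed$frame, packed$topology)
  cls <- classify_hbonds(hb, packed$topology)
  expect_false(anyNA(cls$class))
  expect_identical(sum(table(cls$class)), nrow(hb))
  at <- packed$topology$atoms
  # named examples: same-strand O5/O3 junction pairs are primary
  ip <- cls[cls$class == "intra_primary", ]
  expect_true(all(paste(at$name[ip$acceptor], at$name[ip$donor]) %in%
                    c("O5 O3", "O6 O2")))
  # a chloride acceptor on a cellulose hydroxyl is Cl_strand
  chl <- cls[at$name[cls$acceptor] == "Cl" &
               at$species[cls$donor] == "cellulose", ]
  if (nrow(chl)) expect_true(all(chl$class == "Cl_strand"))
})

test_that("an O2...HO6-O6 style same-strand pair is intra_other, not primary", {
  # hand-built: donor O6-HO6 aimed at an O2 acceptor in the same strand
  b <- build_ibeta_bundle(1, 2)
  at <- b$topology$atoms
  X <- b$frame$coords
  o6 <- which(at$name == "O6" & at$glycan == 1)
  ho6 <- which(at$name == "HO6" & at$glycan == 1)
  o2 <- which(at$name == "O2" & at$glycan == 1)
  X[o2, ] <- X[o6, ] + c(2.8, 0, 0)
  X[ho6, ] <- X[o6, ] + c(1.0, 0, 0)
  frm <- frame(X, b$frame$box)
  hb <- classify_hbonds(detect_hbonds(frm, b$topology), b$topology)
  row <- hb[hb$donor == o6 & hb$acceptor == o2, ]
  expect_identical(nrow(row), 1L)
  expect_identical(as.character(row$class), "intra_other")
})

test_that("ideal static bundle averages 2 primary bonds per glycan in every class", {
  b <- build_ibeta_bundle(9, 4)  # 3x3 cross-section: three classes
  tr <- trajectory(b$topology, list(b$frame, frame(b$frame$coords, b$frame$box, 10)))
  bonds <- detect_hbonds_trajectory(tr)
  cm <- classify_strands(b$topology$layout)
  avg <- per_glycan_class_average(bonds, b$topology, cm, tr$times)
  ip <- avg[avg$bond_class == "intra_primary", ]
  expect_equal(ip$bonds_per_glycan, rep(2, nrow(ip)))
  # 12-glycan strands normalise the primary count by 11
  b12 <- build_ibeta_bundle(2, 12)
  tr12 <- trajectory(b12$topology, list(b12$frame))
  bonds12 <- detect_hbonds_trajectory(tr12)
  cm12 <- classify_strands(b12$topology$layout)
  avg12 <- per_glycan_class_average(bonds12, b12$topology, cm12, tr12$times)
  ip12 <- avg12[avg12$bond_class == "intra_primary", ]
  n_ip <- sum(bonds12$class == "intra_primary") / 2  # per strand
  expect_equal(unique(ip12$bonds_per_glycan), n_ip / 11)
  expect_equal(unique(ip12$bonds_per_glycan), 2)
  # no bonds at all: an all-zero table
  empty <- bonds12[0, ]
  avg0 <- per_glycan_class_average(empty, b12$topology, cm12, tr12$times)
  expect_true(all(avg0$bonds_per_glycan == 0))
})

test_that("criteria geometry: admissible bonds always satisfy the 3.5 A D-A bound", {
  # grid over d_HA <= 2.45 and donor-vertex angle <= 30 deg with d(D-H) = 1 A
  worst <- 0
  for (dha in seq(0.1, 2.45, length.out = 60)) {
    for (th in seq(0, 30, length.out = 61) * pi / 180) {
      # donor at origin, H at (1,0,0); acceptor on the cone at angle th from
      # D->H, at H-A distance dha: place A in the xz plane
      # A = D + t*(cos th, 0, sin th) with |A - H| = dha
      dir <- c(cos(th), 0, sin(th))
      # solve |t*dir - (1,0,0)| = dha for the largest root
      bq <- -2 * dir[1]
      cq <- 1 - dha^2
      disc <- bq^2 - 4 * cq
      if (disc < 0) next
      t1 <- (-bq + sqrt(disc)) / 2
      worst <- max(worst, t1)
    }
  }
  expect_lte(worst, 3.5)
  expect_gt(worst, 3.4)  # the bound is tight, not slack
})

test_that("proximity counts match the cutoff and the brute-force oracle", {
  fx <- two_water_fixture(3.4)  # acceptor O exactly 3.4 A from the target O
  n <- solvent_proximity_count(fx$frame, fx$topology, target = 4L,
                               cutoff = 3.5, species = "water")
  expect_identical(n, 2L)  # itself plus the donor water at 3.4 A
  fx2 <- two_water_fixture(3.6)
  # exclude the target molecule itself by counting around atom 1's molecule
  n2 <- solvent_proximity_count(fx2$frame, fx2$topology, target = 1L,
                                cutoff = 3.5, species = "water")
  expect_identical(n2, 1L)  # only its own molecule within 3.5 A

  for (k in 1:25) {
    res <- random_water_box(n = 20, box = c(16, 14, 15), seed = 400 + k)
    target <- 1:3
    got <- solvent_proximity_count(res$frame, res$topology, target,
                                   cutoff = 3.5, species = "water")
    expect_identical(got, oracle_proximity(res$frame, res$topology, target,
                                           3.5, "water"))
  }
})

test_that("pocket census reproduces planted TBP:water exchange ratios", {
  b <- build_ibeta_bundle(2, 3, box = c(60, 60, 60))
  # place 3 TBP and 1 water between strands 1 and 2 (gap at x ~ 2.5 + offset)
  mid <- (colMeans(b$frame$coords[cellsolv:::atoms_of_strand(b$topology, 1), ]) +
            colMeans(b$frame$coords[cellsolv:::atoms_of_strand(b$topology, 2), ])) / 2
  place <- function(template, centre, mol, id0, sp) {
    el <- element_from_name(template$name)
    at <- data.frame(atom_id = id0 + seq_along(template$name) - 1L,
                     name = template$name, element = el,
                     mass = unname(cellsolv:::ELEMENT_MASSES[el]),
                     charge = NA_real_, strand = NA_integer_,
                     glycan = NA_integer_, species = sp, mol_id = mol,
                     stringsAsFactors = FALSE)
    list(atoms = at, coords = sweep(template$coords, 2, centre, "+"),
         bonds = template$bonds + id0 - 1L)
  }
  tw <- cellsolv:::water_template()
  tt <- cellsolv:::tbp_template()
  parts <- list(place(tt, mid + c(0, 0, -4), 1L, 1L, "TBP"),
                place(tt, mid, 2L, 54L, "TBP"),
                place(tt, mid + c(0, 0, 4), 3L, 107L, "TBP"),
                place(tw, mid + c(0, 0, 8), 4L, 160L, "water"))
  solv_at <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  solv_x <- do.call(rbind, lapply(parts, `[[`, "coords"))
  solv_b <- do.call(rbind, lapply(parts, `[[`, "bonds"))
  solv <- topology(solv_at, solv_b)
  merged <- merge_topologies(b$topology, solv)
  frm <- frame(rbind(b$frame$coords, solv_x), b$frame$box)
  tr <- trajectory(merged, list(frm, frame(frm$coords, frm$box, 10)))
  pc <- pocket_census(tr, 1, 2, cutoff = 8)
  expect_identical(pc$ratio, "3:1")
  # 1 TBP : 2 water by construction
  parts2 <- list(place(tt, mid, 1L, 1L, "TBP"),
                 place(tw, mid + c(0, 0, 4), 2L, 54L, "water"),
                 place(tw, mid + c(0, 0, -4), 3L, 57L, "water"))
  solv_at2 <- do.call(rbind, lapply(parts2, `[[`, "atoms"))
  solv2 <- topology(solv_at2, do.call(rbind, lapply(parts2, `[[`, "bonds")))
  merged2 <- merge_topologies(b$topology, solv2)
  frm2 <- frame(rbind(b$frame$coords,
                      do.call(rbind, lapply(parts2, `[[`, "coords"))),
                b$frame$box)
  tr2 <- trajectory(merged2, list(frm2))
  pc2 <- pocket_census(tr2, 1, 2, cutoff = 8)
  expect_identical(pc2$ratio, "1:2")
  # empty pocket: undefined ratio rendered as "-"
  tr3 <- trajectory(b$topology, list(b$frame))
  pc3 <- pocket_census(tr3, 1, 2, cutoff = 3.5)
  expect_identical(pc3$ratio, "-")
  expect_error(pocket_census(tr3, 1, 1), "distinct")
})
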