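# Synthetic-data generators: bundle builder, strand classes, solvent
# packing, peeling kinematics and telegraph processes.

test_that("bundle atom counts follow the 21g+3 per-strand formula", {
  expect_identical(n_atoms(build_ibeta_bundle(18, 12)$topology), 4590L)
  expect_identical(n_atoms(build_ibeta_bundle(1, 2)$topology), 45L)
  # arbitrary sizes
  for (sz in list(c(2, 5), c(5, 3), c(9, 4))) {
    b <- build_ibeta_bundle(sz[1], sz[2])
    expect_identical(n_atoms(b$topology), as.integer(sz[1] * (21 * sz[2] + 3)))
  }
})

test_that("large-bundle dimensions give the published cellulose atom total", {
  b <- build_ibeta_bundle(88, 24)
  expect_identical(n_atoms(b$topology), 44616L)
  expect_identical(b$topology$n_strands, 88L)
})

test_that("a 2-glycan strand carries both primary bonds at its junction", {
  b <- build_ibeta_bundle(1, 2)
  hb <- classify_hbonds(detect_hbonds(b$frame, b$topology), b$topology)
  expect_identical(sum(hb$class == "intra_primary"), 2L)
  pairs <- paste(b$topology$atoms$name[hb$acceptor],
                 b$topology$atoms$name[hb$donor])[hb$class == "intra_primary"]
  expect_setequal(pairs, c("O5 O3", "O6 O2"))
})

test_that("ideal bundle: exactly 2 primary intra-strand bonds per glycan and
          positive inter-strand bonding for sheet neighbours", {
  b <- build_ibeta_bundle(6, 4)
  hb <- classify_hbonds(detect_hbonds(b$frame, b$topology), b$topology)
  g <- b$topology$n_glycans
  per_strand <- table(factor(b$topology$atoms$strand[hb$donor[hb$class == "intra_primary"]],
                             levels = 1:6))
  expect_true(all(per_strand == 2 * (g - 1)))
  inter <- hb[hb$class == "inter_strand", ]
  expect_gt(nrow(inter), 0)
  # inter-strand partners are adjacent within a sheet (adjacent columns)
  lay <- b$topology$layout
  ds <- b$topology$atoms$strand[inter$donor]
  as_ <- b$topology$atoms$strand[inter$acceptor]
  expect_true(all(abs(lay$col[ds] - lay$col[as_]) == 1 &
                    lay$row[ds] == lay$row[as_]))
})

test_that("strand classification matches the geometric rules", {
  c9 <- classify_strands(default_layout(9))  # 3x3
  expect_identical(as.integer(table(c9$class)[c("corner", "first_layer", "center")]),
                   c(4L, 4L, 1L))
  c1 <- classify_strands(default_layout(1))
  expect_identical(c1$class, "corner")
  c18a <- classify_strands(default_layout(18))
  c18b <- classify_strands(default_layout(18))
  expect_identical(c18a, c18b)              # deterministic
  expect_false(anyNA(c18a$class))           # every strand labelled
  c88 <- classify_strands(default_layout(88))
  expect_setequal(unique(c88$class),
                  c("corner", "first_layer", "second_layer", "above_corner",
                    "center"))
  # mirror pairing is an involution
  ok <- !is.na(c88$mirror)
  expect_identical(c88$mirror[c88$mirror[ok]], c88$strand[ok])
})

test_that("solvent packing honours counts and the 2 A deletion rule", {
  res <- pack_solvent(list(n_tbpcl = 0L, n_water = 10L), box = c(25, 25, 25),
                      seed = 3)
  expect_identical(n_atoms(res$topology), 30L)
  expect_identical(unname(res$n_deleted), c(0L, 0L, 0L))

  # one water placed 1.5 A from a cellulose atom is deleted
  b <- build_ibeta_bundle(1, 2)
  w <- water_near <- two_water_fixture(6)$topology
  near <- b$frame$coords[1, ] + c(1.5, 0, 0)
  at <- data.frame(atom_id = 1:3, name = c("Ow", "Hw", "Hw"),
                   element = c("O", "H", "H"), mass = c(15.999, 1.008, 1.008),
                   charge = NA_real_, strand = NA_integer_,
                   glycan = NA_integer_, species = "water", mol_id = 1L)
  wt <- topology(at, rbind(c(1L, 2L), c(1L, 3L)))
  merged <- merge_topologies(b$topology, wt)
  frm <- frame(rbind(b$frame$coords, rbind(near, near + c(0.96, 0, 0),
                                           near + c(-0.24, 0.93, 0))),
               b$frame$box)
  out <- delete_overlapping_solvent(merged, frm, cutoff = 2)
  expect_identical(out$n_deleted[["water"]], 1L)
  expect_identical(n_atoms(out$topology), n_atoms(b$topology))

  # post-condition scan: no remaining solvent atom within 2 A of cellulose
  packed <- pack_solvent(list(n_tbpcl = 3L, n_water = 20L), box = c(40, 40, 45),
                         bundle = build_ibeta_bundle(2, 3, box = c(40, 40, 45)),
                         seed = 11)
  at2 <- packed$topology$atoms
  ci <- which(at2$species == "cellulose")
  si <- which(at2$species != "cellulose")
  if (length(si)) {
    dmin <- min(cellsolv:::mic_dist_matrix(
      packed$frame$coords[si, , drop = FALSE],
      packed$frame$coords[ci, , drop = FALSE], packed$frame$box))
    expect_gt(dmin, 2)
  }
})

test_that("peeling trajectories follow the plan and are seed-reproducible", {
  b <- build_ibeta_bundle(4, 4)
  # zero displacement, zero noise: identical frames
  p0 <- peel_plan(1L, displacement = rep(0, 3), sigma = 0, seed = 5)
  tr0 <- generate_peeling_trajectory(b$topology, b$frame, p0, 3, dt = 10)
  for (f in 1:3) expect_equal(tr0$frames[[f]]$coords, b$frame$coords)

  # end-peel displacement: with the peel direction colinear with the
  # neighbour direction (two strands in one sheet), the end glycans' NN
  # rises by the full 10 A schedule
  b2 <- build_ibeta_bundle(2, 4)
  p1 <- peel_plan(1L, displacement = seq(0, 10, length.out = 5), sigma = 0,
                  profile = "end_peel", seed = 5)
  tr1 <- generate_peeling_trajectory(b2$topology, b2$frame, p1, 5, dt = 10)
  base <- matched_nn_profile(glycan_com(b2$frame, b2$topology), b2$frame$box)
  fin <- matched_nn_profile(glycan_com(tr1$frames[[5]], b2$topology),
                            tr1$frames[[5]]$box)
  expect_gte(max(fin$nn[1, c(1, 4)]), max(base$nn[1, c(1, 4)]) + 10 - 1e-6)
  # centre glycans move least under the end-peel profile
  expect_lt(min(fin$nn[1, 2:3]), max(fin$nn[1, c(1, 4)]))

  # bitwise reproducibility
  p2 <- peel_plan(2L, displacement = seq(0, 4, length.out = 4), sigma = 0.2,
                  seed = 99)
  a <- generate_peeling_trajectory(b$topology, b$frame, p2, 4, dt = 10)
  bb <- generate_peeling_trajectory(b$topology, b$frame, p2, 4, dt = 10)
  for (f in 1:4) expect_identical(a$frames[[f]]$coords, bb$frames[[f]]$coords)

  # schedule longer than n_frames is rejected
  expect_error(generate_peeling_trajectory(b$topology, b$frame, p1, 3),
               "longer than n_frames")
})

test_that("telegraph sojourns have the requested means and reproduce by seed", {
  tg <- generate_bond_telegraph(tau_bound = 5, tau_unbound = 3,
                                duration = 1e5, dt = 0.5, seed = 21)
  bound <- tg$sojourns$duration[tg$sojourns$state == 1L]
  expect_lt(abs(mean(bound) - 5) / 5, 0.05)
  unbound <- tg$sojourns$duration[tg$sojourns$state == 0L]
  expect_lt(abs(mean(unbound) - 3) / 3, 0.05)

  # enormous unbound lifetime: series is almost all zero after the first
  # unbinding event
  tg2 <- generate_bond_telegraph(2, 1e9, duration = 1e3, dt = 1, seed = 4)
  first0 <- which(tg2$series == 0L)[1]
  expect_true(all(tg2$series[first0:length(tg2$series)] == 0L))

  a <- generate_bond_telegraph(5, 3, 1e3, 0.5, seed = 8)
  b <- generate_bond_telegraph(5, 3, 1e3, 0.5, seed = 8)
  expect_identical(a$series, b$series)
})
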