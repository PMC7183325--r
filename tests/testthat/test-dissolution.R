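# Dissolution statistic: glycan COMs, matched nearest-neighbour profiles,
# threshold calibration, flags, rates and the radius of gyration.

test_that("glycan COMs are mass-weighted and unwrap across the box edge", {
  # two equal-mass atoms: COM at the midpoint
  at <- data.frame(atom_id = 1:2, name = c("C1", "C2"), element = "C",
                   mass = 12, charge = NA_real_, strand = 1L, glycan = 1L,
                   species = "cellulose", mol_id = NA_integer_)
  topo <- topology(at, n_glycans = 1L)
  frm <- frame(rbind(c(0, 0, 0), c(2, 0, 0)), c(10, 10, 10))
  expect_equal(glycan_com(frm, topo)[1, 1, ], c(1, 0, 0))
  # straddling the box edge: COM near the edge, not mid-box
  frm2 <- frame(rbind(c(9.5, 0, 0), c(0.5, 0, 0)), c(10, 10, 10))
  com2 <- glycan_com(frm2, topo)[1, 1, ]
  expect_equal(com2[1] %% 10, 0, tolerance = 1e-9)
  # ideal bundle: constant along-strand COM spacing across junctions
  b <- build_ibeta_bundle(1, 6)
  coms <- glycan_com(b$frame, b$topology)
  dz <- diff(coms[1, , 3])
  expect_equal(diff(dz[2:4]), c(0, 0), tolerance = 1e-9)  # interior spacing
})

test_that("matched NN profiles follow the lattice and react to displacement", {
  # two identical parallel strands 5 A apart: NN = 5 everywhere
  b <- build_ibeta_bundle(2, 4)
  coms <- glycan_com(b$frame, b$topology)
  prof <- matched_nn_profile(coms, b$frame$box)
  expect_equal(unname(prof$nn), matrix(5, 2, 4), tolerance = 1e-9)
  expect_equal(prof$max_nn, rep(5, 4), tolerance = 1e-9)
  # 18-strand bundle: maxNN equal across interior glycan numbers
  b18 <- build_ibeta_bundle(18, 6)
  p18 <- matched_nn_profile(glycan_com(b18$frame, b18$topology), b18$frame$box)
  expect_lt(diff(range(p18$max_nn[2:5])), 1e-9)
  # displacing one strand end glycan raises its NN; others unchanged
  X <- b18$frame$coords
  idx <- cellsolv:::atoms_of_glycan(b18$topology, 1, 1)
  X[idx, 2] <- X[idx, 2] - 5
  p2 <- matched_nn_profile(glycan_com(frame(X, b18$frame$box), b18$topology),
                           b18$frame$box)
  expect_gt(p2$nn[1, 1], p18$nn[1, 1] + 1)
  expect_equal(p2$nn[-1, ], p18$nn[-1, ], tolerance = 1e-9)
  expect_error(matched_nn_profile(coms[1, , , drop = FALSE]), "2 strands")
})

test_that("NN statistics are invariant to rigid motion and strand relabeling", {
  b <- build_ibeta_bundle(6, 4)
  coms <- glycan_com(b$frame, b$topology)
  prof <- matched_nn_profile(coms, b$frame$box)
  # rigid translation
  shift <- c(1.3, -2.1, 0.7)
  coms_t <- coms
  for (k in 1:3) coms_t[, , k] <- coms[, , k] + shift[k]
  expect_equal(matched_nn_profile(coms_t, b$frame$box)$nn, prof$nn,
               tolerance = 1e-9)
  # permuting strand labels permutes rows, leaves maxNN unchanged
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(matched_nn_profile(coms[perm, , ], b$frame$box)$max_nn,
               prof$max_nn, tolerance = 1e-9)
})

test_that("threshold calibration reproduces the printed control statistics", {
  # a pool synthesised to the printed control moments: mean 6.51, sd 0.16 A
  raw <- rep(c(-1, 1), 50)
  pool <- 6.51 + 0.16 * (raw - mean(raw)) / sd(raw)
  cal <- threshold_from_pool(pool, k = 4)
  expect_equal(cal$mean, 6.51, tolerance = 1e-12)
  expect_equal(cal$sd, 0.16, tolerance = 1e-12)
  expect_equal(cal$threshold, 7.15, tolerance = 0.0101)  # printed value 7.16
  # zero-variance pool: threshold equals the mean
  cal0 <- threshold_from_pool(rep(3, 10), k = 4)
  expect_equal(cal0$threshold, 3)
  expect_error(threshold_from_pool(6.51), "at least 2")
})

test_that("calibration recovers a known jitter scale from a synthetic control", {
  b <- build_ibeta_bundle(18, 12)
  sigma0 <- 0.2
  plan <- peel_plan(1L, displacement = rep(0, 8), sigma = sigma0, seed = 42)
  ctrl <- generate_peeling_trajectory(b$topology, b$frame, plan, 8, dt = 10)
  cal <- calibrate_threshold(ctrl, timepoints = c(0, 20, 40, 70), k = 4)
  # maxNN pool: 4 timepoints x 12 glycans
  expect_identical(length(cal$pool), 48L)
  expect_gt(cal$threshold, cal$mean)
  # COM jitter of a 21-atom glycan ~ sigma0/sqrt(n_eff); the pooled maxima
  # spread must sit on that scale (order-of-magnitude sanity, not equality)
  expect_lt(cal$sd, sigma0)
  expect_gt(cal$sd, 0.005)
})

test_that("dissolved flags use a strict threshold and rigid translation flags all", {
  b <- build_ibeta_bundle(4, 4)
  prof <- matched_nn_profile(glycan_com(b$frame, b$topology), b$frame$box)
  expect_identical(flag_dissolved(prof, 7.16)$n_dissolved, 0L)
  # translate strand 1 away by 12 A: all its glycans dissolve
  X <- b$frame$coords
  idx <- cellsolv:::atoms_of_strand(b$topology, 1)
  X[idx, 2] <- X[idx, 2] - 12
  p2 <- matched_nn_profile(glycan_com(frame(X, b$frame$box), b$topology),
                           b$frame$box)
  fl <- flag_dissolved(p2, 7.16)
  expect_true(all(fl$flags[1, ]))
  expect_false(any(fl$flags[-1, ]))
  # boundary: NN exactly at the threshold is not dissolved
  prof_exact <- list(nn = matrix(7.16, 1, 2))
  expect_identical(flag_dissolved(prof_exact, 7.16)$n_dissolved, 0L)
})

test_that("dissolution rate recovers planted slopes by OLS", {
  r <- dissolution_rate(c(0, 1e5, 2e5), c(0, 1, 2))
  expect_equal(r$slope_per_ns, 0.01, tolerance = 1e-9)
  rc <- dissolution_rate(c(0, 50, 100, 150), rep(2.5, 4))
  expect_equal(rc$slope_per_ns, 0, tolerance = 1e-12)
  expect_error(dissolution_rate(rep(5, 4), 1:4), "degenerate")
  # noisy linear series: true slope inside the fitted CI
  set.seed(12)
  t_ps <- seq(0, 1e5, length.out = 60)
  beta <- 0.035  # wt %/ns
  y <- beta * t_ps / 1000 + rnorm(60, 0, 0.3)
  fit <- dissolution_rate(t_ps, y)
  expect_gt(beta, fit$ci[1])
  expect_lt(beta, fit$ci[2])
})

test_that("wt % dissolved grows monotonically under a monotone peel", {
  b <- build_ibeta_bundle(4, 3)
  plan <- peel_plan(1L, displacement = seq(0, 14, length.out = 6), sigma = 0,
                    seed = 2)
  tr <- generate_peeling_trajectory(b$topology, b$frame, plan, 6, dt = 10)
  rep6 <- dissolution_report(tr, threshold = 7.16, n_tbpcl = 10, n_water = 20)
  expect_true(all(diff(rep6$wt_pct) >= 0))
  expect_true(all(rep6$wt_pct >= 0 & rep6$wt_pct <= 100))
})

test_that("radius of gyration follows its closed forms and invariances", {
  at <- data.frame(atom_id = 1:2, name = "C1", element = "C", mass = 1,
                   charge = NA_real_, strand = 1L, glycan = 1L,
                   species = "cellulose", mol_id = NA_integer_)
  topo <- topology(at, n_glycans = 1L)
  f1 <- frame(rbind(c(3, 3, 3), c(3, 3, 3)), c(10, 10, 10))
  expect_equal(radius_of_gyration(f1, topo, atoms = 1L), 0)
  f2 <- frame(rbind(c(0, 0, 0), c(2, 0, 0)), c(10, 10, 10))
  expect_equal(radius_of_gyration(f2, topo), 1)
  f3 <- frame(sweep(f2$coords, 2, c(1, 2, 3), "+"), c(10, 10, 10))
  expect_equal(radius_of_gyration(f3, topo), radius_of_gyration(f2, topo))
})

test_that("planted peels are flagged with full sensitivity and no false positives", {
  b <- build_ibeta_bundle(18, 12)
  sigma <- 0.3
  ctrl_plan <- peel_plan(1L, displacement = rep(0, 6), sigma = sigma, seed = 7)
  ctrl <- generate_peeling_trajectory(b$topology, b$frame, ctrl_plan, 6, dt = 10)
  cal <- calibrate_threshold(ctrl, timepoints = c(0, 20, 40, 50), k = 4)
  peeled <- c(4L, 18L)
  plan <- peel_plan(peeled, displacement = seq(0, 15, length.out = 6),
                    sigma = sigma, profile = "uniform", seed = 8)
  tr <- generate_peeling_trajectory(b$topology, b$frame, plan, 6, dt = 10)
  prof <- matched_nn_profile(glycan_com(tr$frames[[6]], b$topology),
                             tr$frames[[6]]$box)
  fl <- flag_dissolved(prof, cal)
  truth <- matrix(FALSE, 18, 12)
  truth[peeled, ] <- TRUE
  sens <- sum(fl$flags & truth) / sum(truth)
  fpr <- sum(fl$flags & !truth) / sum(!truth)
  expect_identical(sens, 1)
  expect_identical(fpr, 0)
})
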