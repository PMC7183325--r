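# Glycan centre-of-mass nearest-neighbour dissolution statistic,
# control-calibrated threshold, dissolved-mass accounting, rates, and the
# radius of gyration.

#' Glycan centres of mass
#'
#' Mass-weighted centre of each (strand, glycan) atom group.  Atom positions
#' are unwrapped within each glycan (every atom shifted to the periodic
#' image nearest the glycan's first atom) so a glycan straddling the box
#' edge gets a COM near the edge, not mid-box.
#'
#' @param frm a [frame()].
#' @param topology matching [topology()] with cellulose strands.
#' @return 3-d array `[strand, glycan, xyz]`.
#' @export
glycan_com <- function(frm, topology) {
  ns <- topology$n_strands
  g <- topology$n_glycans
  stopifnot(ns >= 1L, g >= 1L)
  at <- topology$atoms
  out <- array(NA_real_, c(ns, g, 3))
  for (s in seq_len(ns)) for (j in seq_len(g)) {
    idx <- atoms_of_glycan(topology, s, j)
    X <- frm$coords[idx, , drop = FALSE]
    ref <- X[1, ]
    D <- mic_displacement(sweep(X, 2L, ref), frm$box)
    m <- at$mass[idx]
    out[s, j, ] <- ref + colSums(D * m) / sum(m)
  }
  out
}

#' Matched-glycan nearest-neighbour profile
#'
#' For each strand `s` and glycan number `j`, the nearest-neighbour distance
#' `NN(s, j)` is the minimum over all other strands of the minimum-image
#' distance between the two strands' glycan-`j` centres of mass (matching
#' glycan numbers only).  `maxNN(j)` is the maximum of `NN(s, j)` over
#' strands: the strand-separation profile.
#'
#' @param coms array from [glycan_com()].
#' @param box box edges (Angstrom) for the minimum image, or `NULL`.
#' @return list(nn = matrix `[strand, glycan]`, max_nn = vector per glycan,
#'   nn_partner = matrix of the arg-min strand (lowest index on ties)).
#' @export
matched_nn_profile <- function(coms, box = NULL) {
  ns <- dim(coms)[1]
  g <- dim(coms)[2]
  if (ns < 2L) stop("nearest-neighbour profile needs at least 2 strands")
  nn <- matrix(NA_real_, ns, g)
  partner <- matrix(NA_integer_, ns, g)
  for (j in seq_len(g)) {
    P <- coms[, j, , drop = TRUE]
    if (is.null(dim(P))) P <- matrix(P, ns, 3)
    D <- mic_dist_matrix(P, P, box)
    diag(D) <- Inf
    nn[, j] <- apply(D, 1, min)
    partner[, j] <- apply(D, 1, which.min)  # lowest index on ties
  }
  list(nn = nn, max_nn = apply(nn, 2, max), nn_partner = partner)
}

#' Calibrate the dissolution threshold from a control trajectory
#'
#' Pools the per-glycan maximum nearest-neighbour distances `maxNN(j)` of a
#' non-dissolving control (e.g. pure water) at the listed timepoints and
#' sets the dissolution threshold at `mean + k * sd` of the pool.
#'
#' @param control a [trajectory()] of the control system.
#' @param timepoints times (ps) at which to sample the profile; the nearest
#'   stored frame is used.
#' @param k number of standard deviations (default 4).
#' @return object of class `"threshold_calibration"`: list(mean, max, sd,
#'   k, threshold, pool).
#' @export
calibrate_threshold <- function(control, timepoints, k = 4) {
  fr_idx <- vapply(timepoints, function(tp) which.min(abs(control$times - tp)),
                   integer(1))
  pool <- unlist(lapply(fr_idx, function(f) {
    coms <- glycan_com(control$frames[[f]], control$topology)
    matched_nn_profile(coms, control$frames[[f]]$box)$max_nn
  }))
  threshold_from_pool(pool, k)
}

#' Threshold from a pooled control sample
#'
#' @param pool numeric vector of pooled `maxNN` values (Angstrom).
#' @param k number of standard deviations above the mean (default 4).
#' @return `"threshold_calibration"` object.
#' @export
threshold_from_pool <- function(pool, k = 4) {
  if (length(pool) < 2L) stop("need at least 2 pooled values to calibrate")
  m <- mean(pool)
  s <- sd(pool)
  structure(list(mean = m, max = max(pool), sd = s, k = k,
                 threshold = m + k * s, pool = pool),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("dissolution threshold: %.2f A (mean %.2f + %g sd %.3f; pool max %.2f, n=%d)\n",
              x$threshold, x$mean, x$k, x$sd, x$max, length(x$pool)))
  invisible(x)
}

#' Flag dissolved glycans
#'
#' A glycan is dissolved when its nearest-neighbour distance strictly
#' exceeds the threshold (a value exactly at the threshold is not
#' dissolved).
#'
#' @param profile list from [matched_nn_profile()].
#' @param threshold Angstrom (a number or a `"threshold_calibration"`).
#' @return list(flags = logical matrix `[strand, glycan]`, n_dissolved).
#' @export
flag_dissolved <- function(profile, threshold) {
  if (inherits(threshold, "threshold_calibration")) threshold <- threshold$threshold
  stopifnot(threshold > 0)
  flags <- profile$nn > threshold
  list(flags = flags, n_dissolved = sum(flags))
}

#' Dissolution time series and wt \% for a trajectory
#'
#' Computes per-frame dissolved-glycan flags and the weight percent of
#' dissolved cellulose against the solvent masses of the composition.
#'
#' @param traj a [trajectory()].
#' @param threshold Angstrom or a `"threshold_calibration"`.
#' @param n_tbpcl,n_water solvent molecule counts for the wt \% denominator.
#' @return data.frame(time, n_dissolved, wt_pct).
#' @export
dissolution_report <- function(traj, threshold, n_tbpcl, n_water) {
  mm <- species_masses()
  m_solv_w <- n_water * mm[["water"]]
  m_solv_t <- n_tbpcl * mm[["TBPCl"]]
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    coms <- glycan_com(traj$frames[[f]], traj$topology)
    prof <- matched_nn_profile(coms, traj$frames[[f]]$box)
    fl <- flag_dissolved(prof, threshold)
    md <- dissolved_mass(fl$n_dissolved)
    data.frame(time = traj$times[f], n_dissolved = fl$n_dissolved,
               wt_pct = wt_percent_dissolved(md, m_solv_w, m_solv_t))
  })
  do.call(rbind, rows)
}

#' Dissolution rate by ordinary least squares
#'
#' Fits `wt_pct ~ time` and reports the slope in wt \%/ns with its
#' confidence interval.
#'
#' @param time_ps times in ps.
#' @param wt_pct dissolved weight percent at each time.
#' @param conf confidence level for the slope interval (default 0.95).
#' @return list(slope_per_ns, intercept, ci, residual_se, fit).
#' @export
dissolution_rate <- function(time_ps, wt_pct, conf = 0.95) {
  stopifnot(length(time_ps) == length(wt_pct), length(time_ps) >= 3L)
  if (diff(range(time_ps)) <= 0) stop("degenerate time axis")
  t_ns <- time_ps / 1000
  fit <- lm(wt_pct ~ t_ns)
  # exact linear inputs make lm's summary warn about a perfect fit
  ci <- suppressWarnings(confint(fit, "t_ns", level = conf))
  rse <- suppressWarnings(summary(fit)$sigma)
  list(slope_per_ns = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       ci = unname(ci), residual_se = rse, fit = fit)
}

#' Radius of gyration of an atom set
#'
#' Mass-weighted root-mean-square distance from the set's centre of mass
#' (coordinates used as stored; unwrap beforehand if the set spans the
#' periodic boundary).
#'
#' @param frm a [frame()].
#' @param topology matching [topology()].
#' @param atoms integer atom indices (default: all cellulose atoms).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frm, topology, atoms = NULL) {
  if (is.null(atoms)) atoms <- which(topology$atoms$species == "cellulose")
  stopifnot(length(atoms) >= 1L)
  X <- frm$coords[atoms, , drop = FALSE]
  m <- topology$atoms$mass[atoms]
  com <- colSums(X * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(X, 2L, com)^2)) / sum(m))
}
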