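# Kinematic peeling trajectories and two-state bond telegraph processes:
# synthetic dynamics with known ground truth for validating the estimators.

#' Define a strand-peeling plan
#'
#' @param strands integer indices of peeling strands.
#' @param displacement numeric vector, displacement magnitude (Angstrom) of
#'   the peeling strands at each frame; non-negative.
#' @param twist numeric vector (same length) of per-junction twist angles in
#'   degrees at each frame, or `NULL` for no twisting.
#' @param sigma isotropic Gaussian thermal-noise standard deviation per atom
#'   per frame, Angstrom.
#' @param profile `"uniform"` translates whole strands rigidly;
#'   `"end_peel"` weights the displacement linearly from 1 at the strand
#'   ends to 0 at the centre, emulating ends peeling first.
#' @param direction optional 3-vector displacement direction per peeling
#'   strand (rows); default points outward from the bundle axis in xy (+x
#'   when degenerate).
#' @param seed integer seed for the noise.
#' @return object of class `"peel_plan"`.
#' @export
peel_plan <- function(strands, displacement, twist = NULL, sigma = 0,
                      profile = c("uniform", "end_peel"), direction = NULL,
                      seed = 1L) {
  profile <- match.arg(profile)
  if (any(displacement < 0)) stop("displacement schedule must be non-negative")
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(twist) && length(twist) != length(displacement))
    stop("twist schedule must have the same length as the displacement schedule")
  structure(list(strands = as.integer(strands), displacement = displacement,
                 twist = twist, sigma = sigma, profile = profile,
                 direction = direction, seed = as.integer(seed)),
            class = "peel_plan")
}

# rotate points about an axis (point p0, unit direction u) by angle deg
rotate_about_axis <- function(X, p0, u, deg) {
  th <- deg * pi / 180
  u <- u / sqrt(sum(u^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(X, 2L, p0) %*% t(R), 2L, p0, "+")
}

#' Generate a kinematic peeling trajectory
#'
#' Starting from a static frame, every atom receives isotropic Gaussian
#' jitter of standard deviation `plan$sigma` each frame; the glycans of the
#' peeling strands are additionally translated along the plan's displacement
#' schedule (optionally weighted towards the strand ends) and twisted by
#' rotating each glycosidic junction's distal segment about the local
#' C1-O4 axis.  Reproducible given the plan's seed.
#'
#' @param topology bundle [topology()].
#' @param start starting [frame()].
#' @param plan a [peel_plan()].
#' @param n_frames number of frames to generate.
#' @param dt sampling interval, ps.
#' @return a [trajectory()]; attribute `"ground_truth"` holds the per-frame,
#'   per-glycan displacement applied to each peeling strand.
#' @export
generate_peeling_trajectory <- function(topology, start, plan, n_frames, dt = 10) {
  stopifnot(inherits(plan, "peel_plan"))
  if (length(plan$displacement) > n_frames)
    stop("displacement schedule (", length(plan$displacement),
         ") is longer than n_frames (", n_frames, ")")
  if (!all(plan$strands %in% seq_len(topology$n_strands)))
    stop("plan references strands not present in the topology")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(plan$seed)

  g <- topology$n_glycans
  disp <- c(plan$displacement, rep(tail(plan$displacement, 1),
                                   n_frames - length(plan$displacement)))
  twist <- if (is.null(plan$twist)) rep(0, n_frames)
  else c(plan$twist, rep(tail(plan$twist, 1), n_frames - length(plan$twist)))

  # outward displacement direction per peeling strand
  cell_idx <- which(topology$atoms$species == "cellulose")
  ctr <- colMeans(start$coords[cell_idx, , drop = FALSE])
  dirs <- matrix(0, length(plan$strands), 3)
  for (k in seq_along(plan$strands)) {
    if (!is.null(plan$direction)) {
      d <- plan$direction[k, ]
    } else {
      sc <- colMeans(start$coords[atoms_of_strand(topology, plan$strands[k]), ,
                                  drop = FALSE])
      d <- c(sc[1] - ctr[1], sc[2] - ctr[2], 0)
      if (sum(d^2) < 1e-8) d <- c(1, 0, 0)
    }
    dirs[k, ] <- d / sqrt(sum(d^2))
  }
  w <- if (plan$profile == "uniform") rep(1, g)
  else abs(seq_len(g) - (g + 1) / 2) / ((g - 1) / 2)

  glycan_atoms <- lapply(plan$strands, function(s)
    lapply(seq_len(g), function(j) atoms_of_glycan(topology, s, j)))

  frames <- vector("list", n_frames)
  truth <- array(0, dim = c(length(plan$strands), g, n_frames),
                 dimnames = list(strand = plan$strands, glycan = NULL, frame = NULL))
  for (f in seq_len(n_frames)) {
    xyz <- start$coords +
      matrix(rnorm(length(start$coords), 0, plan$sigma), ncol = 3)
    for (k in seq_along(plan$strands)) {
      s <- plan$strands[k]
      for (j in seq_len(g)) {
        idx <- glycan_atoms[[k]][[j]]
        dj <- disp[f] * w[j]
        xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2L, dirs[k, ] * dj, "+")
        truth[k, j, f] <- dj
      }
      if (twist[f] != 0) {
        at <- topology$atoms
        for (j in seq_len(g - 1L)) {
          o4 <- which(at$strand == s & at$glycan == j & at$name == "O4" &
                        at$species == "cellulose")[1]
          c1 <- which(at$strand == s & at$glycan == j & at$name == "C1" &
                        at$species == "cellulose")[1]
          distal <- which(at$species == "cellulose" & at$strand == s &
                            at$glycan > j)
          axis <- xyz[o4, ] - xyz[c1, ]
          xyz[distal, ] <- rotate_about_axis(xyz[distal, , drop = FALSE],
                                             xyz[o4, ], axis, twist[f])
        }
      }
    }
    frames[[f]] <- frame(xyz, start$box, time = (f - 1) * dt)
  }
  out <- trajectory(topology, frames, dt = dt)
  attr(out, "ground_truth") <- truth
  out
}

#' Generate a two-state bond telegraph process
#'
#' Alternating exponentially distributed bound/unbound sojourn times sampled
#' on a regular grid: the ground-truth process for validating hydrogen-bond
#' lifetime estimators.
#'
#' @param tau_bound mean bound lifetime, ps.
#' @param tau_unbound mean unbound lifetime, ps.
#' @param duration total duration, ps.
#' @param dt sampling interval, ps.
#' @param seed integer seed.
#' @param start_bound logical; start in the bound state (default TRUE).
#' @return list with `series` (integer 0/1 at each sample), `times` (ps),
#'   `dt`, and `sojourns` (data.frame of state + true duration, the ground
#'   truth).
#' @export
generate_bond_telegraph <- function(tau_bound, tau_unbound, duration, dt,
                                    seed = 1L, start_bound = TRUE) {
  stopifnot(tau_bound > 0, tau_unbound > 0, duration > 0, dt > 0, dt <= duration)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # draw alternating sojourns in blocks until the duration is covered
  st0 <- as.integer(start_bound)
  lens <- numeric(0)
  total <- 0
  while (total < duration) {
    block <- 2L * max(16L, ceiling(1.2 * (duration - total) /
                                     (tau_bound + tau_unbound)))
    odd <- rexp(block %/% 2L, rate = 1 / (if (st0 == 1L) tau_bound else tau_unbound))
    even <- rexp(block %/% 2L, rate = 1 / (if (st0 == 1L) tau_unbound else tau_bound))
    add <- as.vector(rbind(odd, even))
    if (length(lens) %% 2L == 1L) add <- as.vector(rbind(even, odd))
    lens <- c(lens, add)
    total <- total + sum(add)
  }
  states <- rep_len(if (st0 == 1L) c(1L, 0L) else c(0L, 1L), length(lens))
  edges <- cumsum(lens)
  keep <- seq_len(which(edges >= duration)[1])
  edges <- edges[keep]
  states <- states[keep]
  times <- seq(0, duration, by = dt)
  # state at each sample time: number of switches before t
  n_sw <- findInterval(times, edges)
  series <- as.integer((as.integer(start_bound) + n_sw) %% 2L == 1L)
  soj <- data.frame(state = states, duration = diff(c(0, edges)))
  list(series = series, times = times, dt = dt, sojourns = soj)
}
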