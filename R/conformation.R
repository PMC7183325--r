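# Glycosidic dihedral twist profiles and the rolling-average presentation
# transform.

#' Signed dihedral angle of four atoms
#'
#' Torsion about the 2-3 axis in the IUPAC sign convention, computed from
#' the cross products of the bond vectors.
#'
#' @param p 4 x 3 coordinate matrix (rows = the four atoms in order).
#' @return angle in degrees, in (-180, 180].
#' @export
dihedral <- function(p) {
  stopifnot(nrow(p) == 4L, ncol(p) == 3L)
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("collinear atoms: dihedral undefined")
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Glycosidic twist profile of a strand
#'
#' The dihedral measured, in order, from the O5-C1-O4-C4 atoms across each
#' glycosidic junction (O5, C1, O4 of glycan j; C4 of glycan j+1), reported
#' at the average glycan number j + 0.5, for every frame.
#'
#' @param traj a [trajectory()].
#' @param strand strand index.
#' @return data.frame(time, junction, angle) with `junction` = j + 0.5.
#' @export
twist_profile <- function(traj, strand) {
  topo <- traj$topology
  g <- topo$n_glycans
  if (g < 2L) stop("strand must have at least 2 glycans")
  at <- topo$atoms
  idx4 <- lapply(seq_len(g - 1L), function(j) {
    pick <- function(nm, jj) {
      i <- which(at$species == "cellulose" & at$strand == strand &
                   at$glycan == jj & at$name == nm)
      if (length(i) != 1L)
        stop("atom ", nm, " of strand ", strand, " glycan ", jj,
             " not resolvable in the topology")
      i
    }
    c(pick("O5", j), pick("C1", j), pick("O4", j), pick("C4", j + 1L))
  })
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    X <- traj$frames[[f]]$coords
    data.frame(time = traj$times[f],
               junction = seq_len(g - 1L) + 0.5,
               angle = vapply(idx4, function(ii) dihedral(X[ii, ]), numeric(1)))
  })
  do.call(rbind, rows)
}

#' Centred rolling average with decimation
#'
#' Centred moving mean with truncated windows at the series edges, followed
#' by keeping every `stride`-th point — the presentation transform used for
#' long noisy traces (average over 1000 points, plot every 100th).
#'
#' @param x numeric series.
#' @param window window width in points (default 1000).
#' @param stride decimation stride (default 100); 1 keeps every point.
#' @return data.frame(index, value) of the decimated smoothed series.
#' @export
rolling_average <- function(x, window = 1000L, stride = 100L) {
  n <- length(x)
  if (n == 0L) stop("empty series")
  stopifnot(window >= 1L, stride >= 1L)
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1L - half_lo
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  keep <- seq(1L, n, by = stride)
  data.frame(index = keep, value = sm[keep])
}
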