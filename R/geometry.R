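# Periodic-boundary geometry: orthorhombic minimum-image convention.

#' Minimum-image distance under an orthorhombic box
#'
#' Euclidean distance between two points under the minimum-image convention
#' for an orthorhombic (rectangular) periodic box.  With `box = NULL` the
#' plain (non-periodic) distance is returned.
#'
#' @param a,b numeric 3-vectors, Angstrom.
#' @param box numeric 3-vector of box edge lengths (Angstrom), or `NULL` for
#'   a non-periodic calculation.
#' @return distance in Angstrom.
#' @examples
#' minimum_image_distance(c(0, 0, 0), c(9, 0, 0), box = c(10, 10, 10)) # 1
#' @export
minimum_image_distance <- function(a, b, box = NULL) {
  d <- mic_displacement(rbind(b - a), box)
  sqrt(sum(d * d))
}

# Displacement matrix (n x 3) wrapped to the nearest periodic image.
mic_displacement <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  stopifnot(length(box) == 3L, all(box > 0))
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# Minimum-image distances from one point `a` to rows of matrix `X`.
mic_dist_to <- function(a, X, box = NULL) {
  d <- mic_displacement(sweep(X, 2L, a), box)
  sqrt(rowSums(d * d))
}

# All minimum-image distances between rows of X (n x 3) and rows of Y (m x 3);
# returns an n x m matrix.  Intended for modest n*m (tests, per-glycan COMs).
mic_dist_matrix <- function(X, Y, box = NULL) {
  n <- nrow(X)
  out <- matrix(0, n, nrow(Y))
  for (i in seq_len(n)) out[i, ] <- mic_dist_to(X[i, ], Y, box)
  out
}

# Cell-list neighbour search: for each row of `X`, indices of rows of `Y`
# within `cutoff` (minimum image).  Returns a data.frame(i, j, d).  Results
# are identical to the all-pairs computation; the grid only prunes
# candidates.  Falls back to brute force when the box is small relative to
# the cutoff or absent.
neighbour_pairs <- function(X, Y, cutoff, box = NULL) {
  if (nrow(X) == 0L || nrow(Y) == 0L)
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  use_cells <- !is.null(box) && all(box / cutoff >= 3)
  if (!use_cells) {
    hits <- vector("list", nrow(X))
    for (i in seq_len(nrow(X))) {
      d <- mic_dist_to(X[i, ], Y, box)
      j <- which(d <= cutoff)
      if (length(j)) hits[[i]] <- data.frame(i = i, j = j, d = d[j])
    }
    out <- do.call(rbind, hits)
    if (is.null(out)) out <- data.frame(i = integer(), j = integer(), d = numeric())
    return(out)
  }
  nc <- pmax(1L, as.integer(floor(box / cutoff)))
  cell_of <- function(P) {
    W <- P
    for (k in 1:3) {
      w <- P[, k] %% box[k]
      W[, k] <- pmin(as.integer(floor(w / (box[k] / nc[k]))), nc[k] - 1L)
    }
    W[, 1] + nc[1] * (W[, 2] + nc[2] * W[, 3]) + 1L
  }
  cy <- cell_of(Y)
  ybins <- split(seq_len(nrow(Y)), cy)
  # integer cell coordinates for X
  xw <- matrix(0L, nrow(X), 3)
  for (k in 1:3) {
    w <- X[, k] %% box[k]
    xw[, k] <- pmin(as.integer(floor(w / (box[k] / nc[k]))), nc[k] - 1L)
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  hits <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    cc <- sweep(offs, 2L, xw[i, ], "+")
    for (k in 1:3) cc[, k] <- cc[, k] %% nc[k]
    cc <- unique(cc)
    keys <- as.character(cc[, 1] + nc[1] * (cc[, 2] + nc[2] * cc[, 3]) + 1L)
    cand <- unlist(ybins[keys], use.names = FALSE)
    if (!length(cand)) next
    d <- mic_dist_to(X[i, ], Y[cand, , drop = FALSE], box)
    sel <- which(d <= cutoff)
    if (length(sel)) hits[[i]] <- data.frame(i = i, j = cand[sel], d = d[sel])
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) out <- data.frame(i = integer(), j = integer(), d = numeric())
  out[order(out$i, out$j), , drop = FALSE]
}
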