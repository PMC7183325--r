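# Hydrogen-bond lifetimes from existence autocorrelation, with the
# four-resolution cascade and censored (">") reporting.

#' Bond existence series from a trajectory
#'
#' Runs the hydrogen-bond detector on every frame and returns one binary
#' presence series per (donor, hydrogen, acceptor) triple that is bonded in
#' at least one frame, restricted to given donor/acceptor atom-name sets.
#'
#' @param traj a [trajectory()].
#' @param donor_names,acceptor_names atom-name sets defining the pair class
#'   (e.g. acceptor `"Cl"`, donors `"O2"`).
#' @param criteria an [hbond_criteria()].
#' @return list with `series` (0/1 matrix, one row per triple), `triples`
#'   (data.frame donor/hydrogen/acceptor) and `dt` (ps).  Empty matrix with
#'   a warning when no pair is ever bonded.
#' @export
existence_series <- function(traj, donor_names, acceptor_names,
                             criteria = hbond_criteria()) {
  nf <- n_frames(traj)
  keys <- list()
  per_frame <- vector("list", nf)
  for (f in seq_len(nf)) {
    b <- detect_hbonds(traj$frames[[f]], traj$topology, criteria,
                       donors = donor_names, acceptors = acceptor_names)
    per_frame[[f]] <- b
  }
  all_b <- do.call(rbind, per_frame)
  if (!nrow(all_b)) {
    warning("no bonded pairs found for the requested donor/acceptor names")
    return(list(series = matrix(0L, 0, nf), triples = empty_hbonds()[0, 1:3],
                dt = traj$dt))
  }
  trip <- unique(all_b[, c("donor", "hydrogen", "acceptor")])
  trip <- trip[order(trip$donor, trip$acceptor, trip$hydrogen), , drop = FALSE]
  rownames(trip) <- NULL
  key_of <- function(d) paste(d$donor, d$hydrogen, d$acceptor)
  tk <- key_of(trip)
  series <- matrix(0L, nrow(trip), nf)
  for (f in seq_len(nf)) {
    b <- per_frame[[f]]
    if (nrow(b)) series[match(key_of(b), tk), f] <- 1L
  }
  list(series = series, triples = trip, dt = traj$dt)
}

#' Existence autocorrelation of a binary bond series
#'
#' Continuous (survival) mode: probability that a bond present at a time
#' origin has remained unbroken through lag t, averaged over all bonded
#' origins.  Intermittent mode: probability of being bonded at lag t given
#' bonded at the origin, allowing re-formation.  Multiple series (rows of a
#' matrix) are pooled by summing numerators and denominators before the
#' ratio.
#'
#' @param series integer 0/1 vector, or a matrix with one series per row.
#' @param dt sampling interval, ps.
#' @param mode `"continuous"` or `"intermittent"`.
#' @return data.frame with columns `t` (ps, starting at 0) and `C`.
#' @export
hbond_acf <- function(series, dt, mode = c("continuous", "intermittent")) {
  mode <- match.arg(mode)
  if (is.vector(series)) series <- matrix(series, 1)
  n <- ncol(series)
  if (n < 2L) stop("series length must be >= 2")
  if (all(series == 0L)) stop("series never bonded: autocorrelation undefined")
  num <- numeric(n)
  den <- numeric(n)
  for (r in seq_len(nrow(series))) {
    s <- series[r, ]
    if (mode == "continuous") {
      # a bonded run of length L contributes origins with remaining
      # unbroken lengths L, L-1, ..., 1; so the tabulated remaining-length
      # distribution is the survival curve of the 1-run lengths
      r <- rle(s)
      runs1 <- r$lengths[r$values == 1L]
      tab <- rev(cumsum(rev(tabulate(runs1, nbins = n))))
      surv <- rev(cumsum(rev(tab)))       # surv[v] = #origins with run >= v
      num <- num + surv                   # lag k needs run >= k+1 samples
      cs <- cumsum(s)
      den <- den + cs[n:1]                 # bonded origins with i <= n-k
    } else {
      for (k in 0:(n - 1L)) {
        i <- seq_len(n - k)
        num[k + 1L] <- num[k + 1L] + sum(s[i] * s[i + k])
        den[k + 1L] <- den[k + 1L] + sum(s[i])
      }
    }
  }
  C <- ifelse(den > 0, num / den, 0)
  data.frame(t = (0:(n - 1L)) * dt, C = C)
}

#' Lifetime from an autocorrelation curve
#'
#' Integrates C(t) by the trapezoidal rule from 0 up to the first lag where
#' C drops to (numerically) zero; when C never reaches zero within the
#' window the integral over the whole window is reported as a censored
#' lower bound, rendered with a ">" prefix.
#'
#' @param acf data.frame from [hbond_acf()] (columns `t`, `C`, with
#'   `C[1] = 1`).
#' @param zero_tol C values at or below this count as zero (default 1e-3).
#' @param resolution_used optional sampling resolution tag (ps) carried into
#'   the result.
#' @return object of class `"lifetime_result"`: list(tau, censored,
#'   resolution_used).
#' @export
lifetime_from_acf <- function(acf, zero_tol = 1e-3, resolution_used = NA_real_) {
  stopifnot(nrow(acf) >= 1L, abs(acf$C[1] - 1) < 1e-9)
  hit <- which(acf$C <= zero_tol)
  if (length(hit)) {
    k <- hit[1]
    tau <- trapz(acf$t[1:k], acf$C[1:k])
    censored <- FALSE
  } else {
    tau <- trapz(acf$t, acf$C)
    censored <- TRUE
  }
  structure(list(tau = tau, censored = censored,
                 resolution_used = resolution_used),
            class = "lifetime_result")
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Render a lifetime in the censored reporting style
#'
#' Censored results carry a ">" prefix (e.g. `">31445"`).
#'
#' @param x a `"lifetime_result"`.
#' @param digits significant digits (default 3).
#' @return character scalar.
#' @export
format_lifetime <- function(x, digits = 3) {
  val <- signif(x$tau, digits)
  paste0(if (isTRUE(x$censored)) ">" else "", format(val, big.mark = ""))
}

#' @export
print.lifetime_result <- function(x, ...) {
  cat("lifetime:", format_lifetime(x), "ps",
      if (!is.na(x$resolution_used)) paste0("(resolution ", x$resolution_used, " ps)"),
      "\n")
  invisible(x)
}

#' Multi-resolution cascade lifetime
#'
#' Evaluates bond-existence series sampled at increasingly coarse
#' resolutions (canonically 0.01, 0.1, 1 and 10 ps with windows of 100,
#' 1000, 10000 ps and the full run) in order, returning the lifetime from
#' the first resolution whose autocorrelation decays to zero within its
#' window; if none does, the coarsest result is returned censored.
#'
#' @param series_list list of 0/1 vectors (or matrices), finest first.
#' @param dts sampling interval (ps) of each series.
#' @param mode autocorrelation mode (see [hbond_acf()]).
#' @param zero_tol zero threshold for the decay test.
#' @return `"lifetime_result"` with `resolution_used` set.
#' @export
cascade_lifetime <- function(series_list, dts, mode = "continuous",
                             zero_tol = 1e-3) {
  stopifnot(length(series_list) == length(dts), length(series_list) >= 1L)
  last <- NULL
  for (k in seq_along(series_list)) {
    acf <- hbond_acf(series_list[[k]], dts[k], mode)
    res <- lifetime_from_acf(acf, zero_tol, resolution_used = dts[k])
    last <- res
    if (!res$censored) return(res)
  }
  last
}

#' Average a lifetime over overlapping sample windows
#'
#' Splits a series into `n_samples` windows each covering `window_fraction`
#' of the run, with evenly spaced starting offsets, estimates the lifetime
#' in each, and reports mean and standard deviation.  The result is
#' censored when any sample is censored.
#'
#' @param series 0/1 vector (or matrix of pooled series).
#' @param dt sampling interval, ps.
#' @param n_samples number of windows (default 10).
#' @param window_fraction fraction of the run per window (default 0.8).
#' @param mode autocorrelation mode.
#' @param zero_tol zero threshold.
#' @return list(mean_tau, sd_tau, censored, taus, results).
#' @export
sample_average_lifetime <- function(series, dt, n_samples = 10L,
                                    window_fraction = 0.8,
                                    mode = "continuous", zero_tol = 1e-3) {
  if (is.vector(series)) series <- matrix(series, 1)
  n <- ncol(series)
  w <- floor(window_fraction * n)
  max_start <- n - w
  if (w < 2L || (n_samples > 1L && max_start < n_samples - 1L))
    stop("series too short for ", n_samples, " windows of ",
         window_fraction * 100, "%: need length >= ",
         ceiling((n_samples - 1) / (1 - window_fraction)))
  starts <- if (n_samples == 1L) 0L else
    round(seq(0, max_start, length.out = n_samples))
  results <- lapply(starts, function(s0) {
    sub <- series[, (s0 + 1):(s0 + w), drop = FALSE]
    lifetime_from_acf(hbond_acf(sub, dt, mode), zero_tol, resolution_used = dt)
  })
  taus <- vapply(results, function(r) r$tau, numeric(1))
  list(mean_tau = mean(taus), sd_tau = sd(taus),
       censored = any(vapply(results, function(r) r$censored, logical(1))),
       taus = taus, results = results)
}
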