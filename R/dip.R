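# Hartigan's dip statistic for unimodality, computed from the greatest
# convex minorant (GCM) and least concave majorant (LCM) of the empirical
# CDF. Works in observation-count units on the sorted sample, one index
# per observation (so ties are handled naturally): the GCM is fitted to
# the lower step corners (x_i, i - 1) and the LCM to the upper corners
# (x_i, i). The returned dip is half the maximal tube width, in
# probability units.

# lower convex hull indices of points (px, py), px non-decreasing
.lower_hull <- function(px, py) {
  h <- integer(0)
  for (i in seq_along(px)) {
    if (length(h) >= 1L && px[i] == px[h[length(h)]]) {
      if (py[i] >= py[h[length(h)]]) next # keep the lower point at this x
      h <- h[-length(h)]
    }
    while (length(h) >= 2L) {
      a <- h[length(h) - 1L]
      b <- h[length(h)]
      # pop b if it lies on or above segment a--i
      if ((px[i] - px[b]) * (py[b] - py[a]) >=
          (px[b] - px[a]) * (py[i] - py[b])) {
        h <- h[-length(h)]
      } else break
    }
    h <- c(h, i)
  }
  h
}

.upper_hull <- function(px, py) .lower_hull(px, -py)

# piecewise-linear fit through touchpoints, evaluated at indices `at`
.hull_fit <- function(touch, px, py, at) {
  if (length(touch) == 1L) return(rep(py[touch], length(at)))
  seg <- findInterval(at, touch)
  seg[seg < 1L] <- 1L
  seg[seg >= length(touch)] <- length(touch) - 1L
  a <- touch[seg]
  b <- touch[seg + 1L]
  dx <- px[b] - px[a]
  w <- ifelse(dx > 0, (px[at] - px[a]) / dx, 0)
  val <- py[a] + w * (py[b] - py[a])
  val[at %in% touch] <- py[at[at %in% touch]]
  val
}

#' Hartigan's dip statistic
#'
#' The dip is the smallest sup-norm distance between the empirical CDF
#' and any unimodal distribution function: large values indicate
#' departure from unimodality (e.g. bimodality). Computed by iteratively
#' shrinking a candidate modal interval and fitting the greatest convex
#' minorant / least concave majorant of the ECDF on it. Equally spaced
#' samples attain the minimum possible value `1 / (2 n)`.
#'
#' @param x numeric sample.
#' @return the dip statistic (scalar in `[1/(2n), 0.25]`).
#' @export
dip_stat <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 1L) stop("empty sample")
  if (n == 1L || x[n] == x[1L]) return(1 / (2 * n)) # degenerate floor
  # every observation is its own index: lower / upper ECDF step corners
  lcy <- 0:(n - 1L)
  ucy <- 1:n

  low <- 1L
  high <- n
  # A unimodal CDF may carry an atom at its mode, so even ties do not
  # force a dip beyond the minimal tube of one observation.
  dip <- 1

  repeat {
    idx <- low:high
    gcm <- idx[.lower_hull(x[idx], lcy[idx])]
    lcm <- idx[.upper_hull(x[idx], ucy[idx])]

    # maximal gap between the LCM and GCM curves, checked at touchpoints
    cand_l <- ucy[lcm] - .hull_fit(gcm, x, lcy, lcm) # at LCM touchpoints
    cand_g <- .hull_fit(lcm, x, ucy, gcm) - lcy[gcm] # at GCM touchpoints
    d <- max(cand_l, cand_g)
    if (d <= dip) break

    pt <- if (max(cand_l) >= max(cand_g)) {
      lcm[which.max(cand_l)]
    } else {
      gcm[which.max(cand_g)]
    }
    new_low <- max(gcm[gcm <= pt])
    new_high <- min(lcm[lcm >= pt])

    # deviations of the ECDF from the fits on the newly exposed tails
    jl <- low:new_low
    ju <- new_high:high
    dl <- max(ucy[jl] - .hull_fit(gcm, x, lcy, jl))
    du <- max(.hull_fit(lcm, x, ucy, ju) - lcy[ju])
    dip <- max(dip, dl, du)

    if (new_low == low && new_high == high) break
    low <- new_low
    high <- new_high
  }
  dip / (2 * n)
}

#' Bootstrap null distribution of the dip statistic
#'
#' Dip statistics of `n_boot` uniform samples of size `n`. Uniform
#' samples are the canonical least-favourable unimodal null for the dip
#' test.
#'
#' @param n sample size.
#' @param n_boot number of bootstrap draws.
#' @param seed optional integer seed.
#' @return numeric vector of `n_boot` dip statistics.
#' @export
dip_null_dist <- function(n, n_boot = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_boot), function(i) dip_stat(stats::runif(n)), 0)
}

#' Hartigan's dip test with bootstrap p-value
#'
#' Tests the null hypothesis of unimodality. The p-value is the fraction
#' of dip statistics from uniform null samples of the same size that
#' reach or exceed the observed dip (with a +1 continuity correction).
#' Passing a precomputed `null_dips` vector (from [dip_null_dist()])
#' makes repeated testing at a fixed `n` cheap.
#'
#' @param x numeric sample, n >= 4.
#' @param n_boot bootstrap draws when `null_dips` is not supplied.
#' @param seed optional integer seed for the bootstrap.
#' @param null_dips optional precomputed null dip distribution for
#'   samples of size `length(x)`.
#' @return a `stat_report` with `statistic` = dip, `p` the bootstrap
#'   p-value, and `n_boot` used.
#' @export
dip_test <- function(x, n_boot = 2000, seed = NULL, null_dips = NULL) {
  n <- length(x)
  if (n < 4L) stop("dip test requires n >= 4")
  d <- dip_stat(x)
  if (is.null(null_dips)) null_dips <- dip_null_dist(n, n_boot, seed = seed)
  p <- (sum(null_dips >= d - 1e-12) + 1) / (length(null_dips) + 1)
  stat_report("hartigan-dip", d, n, p, n_boot = length(null_dips))
}
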