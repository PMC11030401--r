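#' Rasterize one observer's boundary times onto a binary grid
#'
#' Each sample of a regular grid over one movie is set to 1 if it lies
#' within `window` seconds (inclusive, on either side) of any boundary the
#' observer marked, else 0. The grid has `round(duration / grid_step)`
#' samples at times `0, grid_step, 2 * grid_step, ...` relative to movie
#' onset.
#'
#' @param times numeric vector of boundary times, seconds from movie onset.
#' @param duration movie duration in seconds.
#' @param grid_step grid resolution in seconds (default 0.1, the resolution
#'   at which observers respond).
#' @param window inclusion half-window in seconds (default 1).
#' @return integer 0/1 vector of length `round(duration / grid_step)`.
#' @export
rasterize_observer <- function(times, duration, grid_step = 0.1, window = 1) {
  if (window < 0) stop("window must be >= 0")
  if (duration <= 0) stop("duration must be positive")
  if (length(times) && (any(times < 0) || any(times > duration)))
    stop("boundary times outside movie duration")
  n <- round(duration / grid_step)
  out <- integer(n)
  eps <- 1e-9
  for (t in times) {
    lo <- max(1L, as.integer(ceiling((t - window) / grid_step - eps)) + 1L)
    hi <- min(n, as.integer(floor((t + window) / grid_step + eps)) + 1L)
    if (lo <= hi) out[lo:hi] <- 1L
  }
  out
}

#' Across-observer agreement series for one movie
#'
#' Pointwise mean of observer rasters: the proportion of observers whose
#' (windowed) boundary marks cover each grid sample.
#'
#' @param rasters a list of equal-length 0/1 vectors (one per observer), or
#'   a matrix with observers in rows.
#' @return numeric vector in \[0, 1\].
#' @export
agreement_series <- function(rasters) {
  if (is.list(rasters)) {
    if (!length(rasters)) stop("need at least one observer")
    len <- lengths(rasters)
    if (length(unique(len)) != 1L) stop("mismatched raster lengths")
    rasters <- do.call(rbind, rasters)
  }
  colMeans(rasters)
}

#' Gaussian-weighted moving-average smoothing
#'
#' Smooths a series with a truncated Gaussian kernel of total width
#' `window` seconds (support \eqn{\pm} `window / 2`), standard deviation
#' `sigma` (default `window / 5`). Kernel weights are renormalized where
#' the window is clipped at the series edges, so a constant series is
#' returned unchanged and output length equals input length.
#'
#' @param x numeric series on a regular grid.
#' @param window total kernel width in seconds.
#' @param grid_step grid resolution in seconds.
#' @param sigma Gaussian standard deviation in seconds.
#' @return smoothed numeric series, same length as `x`.
#' @export
smooth_gaussian <- function(x, window = 2, grid_step = 0.1,
                            sigma = window / 5) {
  if (window <= 0) stop("window must be positive")
  if (window < grid_step) stop("window smaller than grid step")
  half <- floor(window / 2 / grid_step + 1e-9)
  off <- -half:half
  w <- stats::dnorm(off * grid_step, mean = 0, sd = sigma)
  n <- length(x)
  num <- numeric(n)
  den <- numeric(n)
  for (k in seq_along(off)) {
    d <- off[k]
    src <- seq_len(n) + d
    ok <- src >= 1L & src <= n
    num[ok] <- num[ok] + w[k] * x[src[ok]]
    den[ok] <- den[ok] + w[k]
  }
  num / den
}

#' Concatenate per-movie agreement series in layout order
#'
#' @param series_list named list of per-movie numeric series; names must
#'   cover every movie in `layout`.
#' @param layout a `session_layout`.
#' @param grid_step grid resolution in seconds.
#' @return An object of class `agreement_series`: list with `values`
#'   (concatenated series), `grid_step`, `movie_offsets` (named 0-based
#'   sample offsets) and `movie_id` per sample. Sample `i` (1-based)
#'   corresponds to global session time `(i - 1) * grid_step`.
#' @export
concat_movies <- function(series_list, layout, grid_step = 0.1) {
  stopifnot(inherits(layout, "session_layout"))
  ids <- layout$movies$movie_id
  missing <- setdiff(ids, names(series_list))
  if (length(missing)) stop("missing movie series: ",
                            paste(missing, collapse = ", "))
  lens <- round(layout$movies$duration_s / grid_step)
  for (i in seq_along(ids)) {
    if (length(series_list[[ids[i]]]) != lens[i])
      stop("series length does not match layout duration for ", ids[i])
  }
  values <- unlist(series_list[ids], use.names = FALSE)
  offsets <- c(0L, cumsum(lens))[seq_along(ids)]
  names(offsets) <- ids
  structure(list(
    values = values, grid_step = grid_step, movie_offsets = offsets,
    movie_id = rep(ids, lens)
  ), class = "agreement_series")
}

#' Agreement series from raw observer logs
#'
#' Convenience wrapper: rasterize every observer per movie, average into
#' per-movie agreement, smooth, and concatenate across movies in layout
#' order.
#'
#' @param logs data frame with columns `observer_id`, `movie_id`, `time_s`
#'   (seconds from movie onset).
#' @param layout a `session_layout`.
#' @param grid_step,window see [rasterize_observer()].
#' @param smooth_window Gaussian smoothing width in seconds; `NULL` or 0
#'   skips smoothing.
#' @return an `agreement_series` (see [concat_movies()]).
#' @export
observer_agreement <- function(logs, layout, grid_step = 0.1, window = 1,
                               smooth_window = 2) {
  stopifnot(all(c("observer_id", "movie_id", "time_s") %in% names(logs)))
  per_movie <- list()
  obs_ids <- unique(logs$observer_id)
  for (i in seq_len(nrow(layout$movies))) {
    mid <- layout$movies$movie_id[i]
    dur <- layout$movies$duration_s[i]
    ml <- logs[logs$movie_id == mid, , drop = FALSE]
    rasters <- lapply(obs_ids, function(o) {
      rasterize_observer(ml$time_s[ml$observer_id == o], dur,
                         grid_step = grid_step, window = window)
    })
    s <- agreement_series(rasters)
    if (!is.null(smooth_window) && smooth_window > 0) {
      s <- smooth_gaussian(s, window = smooth_window, grid_step = grid_step)
    }
    per_movie[[mid]] <- s
  }
  concat_movies(per_movie, layout, grid_step = grid_step)
}

#' Detect boundary peaks in a smoothed agreement series
#'
#' Thresholds the concatenated smoothed agreement series at a percentile of
#' all its samples (linear-interpolation percentile, zeros included) and
#' returns local maxima strictly above the threshold. Plateaus are reduced
#' to their earliest sample. Peaks closer than `min_peak_sep` seconds are
#' thinned by keeping the higher peak (earlier wins ties).
#'
#' @param agr an `agreement_series` (or a bare numeric series).
#' @param percentile threshold percentile in \[0, 100\].
#' @param min_peak_sep minimum separation between retained peaks, seconds.
#' @return data frame with columns `time_s` (global session seconds) and
#'   `agreement` (series value at the peak), sorted by time. Zero rows when
#'   no sample exceeds the threshold.
#' @export
detect_boundaries <- function(agr, percentile = 65, min_peak_sep = 1) {
  v <- if (inherits(agr, "agreement_series")) agr$values else agr
  grid_step <- if (inherits(agr, "agreement_series")) agr$grid_step else 0.1
  if (!length(v)) stop("empty series")
  thr <- stats::quantile(v, percentile / 100, names = FALSE, type = 7)

  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  prev <- c(-Inf, r$values[-k])
  nxt <- c(r$values[-1L], -Inf)
  is_peak <- r$values > thr & r$values > prev & r$values > nxt
  idx <- starts[is_peak] # plateau -> earliest sample

  if (!length(idx)) {
    return(data.frame(time_s = numeric(0), agreement = numeric(0)))
  }
  # minimum peak separation: greedily keep higher peaks (earlier on ties)
  ord <- order(-v[idx], idx)
  keep <- integer(0)
  for (i in idx[ord]) {
    if (!length(keep) ||
        all(abs(i - keep) * grid_step >= min_peak_sep - 1e-9)) {
      keep <- c(keep, i)
    }
  }
  keep <- sort(keep)
  data.frame(time_s = (keep - 1L) * grid_step, agreement = v[keep])
}

#' Bin detected boundaries into weak / moderate / strong
#'
#' Boundaries are sorted by agreement (ascending, ties keep time order) and
#' split into three equal-count bins; remainders go to the stronger bins,
#' so e.g. 10 boundaries split 3 / 3 / 4 (weak / moderate / strong) and 11
#' split 3 / 4 / 4.
#'
#' @param cand data frame with `time_s` and `agreement` columns (from
#'   [detect_boundaries()]).
#' @return the input with an added `category` factor
#'   (weak < moderate < strong), sorted by time.
#' @export
bin_strength <- function(cand) {
  n <- nrow(cand)
  if (n < 3L) stop("need at least 3 boundaries to bin")
  ord <- order(cand$agreement, cand$time_s)
  base <- n %/% 3L
  r <- n %% 3L
  sizes <- c(weak = base, moderate = base + (r == 2L), strong = base + (r >= 1L))
  cat_sorted <- rep(names(sizes), sizes)
  category <- character(n)
  category[ord] <- cat_sorted
  cand$category <- factor(category, levels = c("weak", "moderate", "strong"))
  cand[order(cand$time_s), , drop = FALSE]
}

#' Apply exclusion rules to a boundary set
#'
#' Flags (without removing) boundaries that should not enter fMRI analyses:
#' * `pair<6s`: every member of any pair closer than `min_sep` seconds
#'   (both members are flagged);
#' * `movie_onset`: boundaries inside a movie-title onset window
#'   `[title_onset, title_onset + title_duration + onset_pad]`;
#' * `last_in_run`: the final boundary of each run still retained after the
#'   two rules above.
#'
#' Strength categories are expected to be assigned *before* exclusion (see
#' [bin_strength()]), so exclusion removes members from bins rather than
#' re-binning.
#'
#' @param bnd data frame with `time_s` (global seconds), sorted by time.
#' @param layout a `session_layout`.
#' @param min_sep pair-exclusion distance, seconds.
#' @param last_per_run flag the last retained boundary of each run?
#' @param onset_pad extra padding after the title window, seconds.
#' @return the input with logical `excluded` and character `reason` columns
#'   (`NA` reason where retained).
#' @export
apply_exclusions <- function(bnd, layout, min_sep = 6, last_per_run = TRUE,
                             onset_pad = 1) {
  stopifnot(inherits(layout, "session_layout"))
  n <- nrow(bnd)
  excluded <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  if (n == 0L) {
    bnd$excluded <- excluded
    bnd$reason <- reason
    return(bnd)
  }
  if (is.unsorted(bnd$time_s)) stop("boundaries must be sorted by time")

  if (n >= 2L) {
    d <- diff(bnd$time_s)
    close_pair <- d < min_sep - 1e-9
    hit <- unique(c(which(close_pair), which(close_pair) + 1L))
    excluded[hit] <- TRUE
    reason[hit] <- "pair<6s"
  }

  m <- layout$movies
  for (i in seq_len(nrow(m))) {
    in_onset <- bnd$time_s >= m$title_onset_s[i] - 1e-9 &
      bnd$time_s <= m$title_end_s[i] + onset_pad + 1e-9
    new_hit <- in_onset & !excluded
    excluded[in_onset] <- TRUE
    reason[new_hit] <- "movie_onset"
  }

  if (last_per_run) {
    runs <- run_of_time(layout, bnd$time_s)
    for (r in unique(runs[!is.na(runs)])) {
      idx <- which(runs == r & !excluded)
      if (length(idx)) {
        last <- max(idx)
        excluded[last] <- TRUE
        reason[last] <- "last_in_run"
      }
    }
  }

  bnd$excluded <- excluded
  bnd$reason <- reason
  bnd
}

#' Map boundary times to HRF-shifted TR indices
#'
#' `tr_index = floor(time_s / TR) + hrf_shift` in run-global 0-based TR
#' coordinates (runs are contiguous, so the global TR grid applies). A
#' boundary whose shifted index falls at or beyond the end of its run is
#' flagged `run_end` and excluded from windowed analyses.
#'
#' @param bnd boundary data frame with `time_s` (global seconds).
#' @param layout a `session_layout`.
#' @param hrf_shift hemodynamic shift in TRs (default 3).
#' @return the input with an integer `tr_index` column (and updated
#'   `excluded` / `reason` where the shifted index leaves the run).
#' @export
to_tr_indices <- function(bnd, layout, hrf_shift = 3) {
  stopifnot(inherits(layout, "session_layout"))
  if (!nrow(bnd)) {
    bnd$tr_index <- integer(0)
    return(bnd)
  }
  base_tr <- time_to_tr(layout, bnd$time_s)
  tr_index <- base_tr + as.integer(hrf_shift)
  runs <- run_of_time(layout, bnd$time_s)
  ri <- match(runs, layout$runs$run)
  run_end_tr <- layout$runs$start_tr[ri] + layout$runs$n_tr[ri]
  beyond <- tr_index >= run_end_tr
  bnd$tr_index <- as.integer(tr_index)
  if (any(beyond)) {
    if (!"excluded" %in% names(bnd)) {
      bnd$excluded <- FALSE
      bnd$reason <- NA_character_
    }
    newly <- beyond & !bnd$excluded
    bnd$excluded[beyond] <- TRUE
    bnd$reason[newly] <- "run_end"
  }
  bnd
}

#' Segment-count allowance for a movie
#'
#' Observers segmenting a movie are asked for between `2k` and `4k`
#' segments, where `k` is the smallest integer greater than or equal to the
#' movie duration in minutes (target `3k`, plus or minus `k`).
#'
#' @param duration_s movie duration in seconds.
#' @return named integer vector `c(min = 2k, max = 4k)`.
#' @examples
#' segment_allowance(138) # c(min = 6, max = 12)
#' @export
segment_allowance <- function(duration_s) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration must be positive")
  k <- ceiling(duration_s / 60)
  c(min = 2L * as.integer(k), max = 4L * as.integer(k))
}

#' Validate agreement against independent strength ratings
#'
#' Each rater's 1--5 ratings are standardized (mean 0, sd 1), averaged
#' across raters, and rank-correlated (Spearman) with the boundary
#' agreement values. Raters with constant ratings are dropped with a
#' warning.
#'
#' @param ratings numeric matrix, raters in rows, boundaries in columns
#'   (integers 1--5).
#' @param agreement numeric vector of agreement values, one per boundary.
#' @return a `stat_report` (see [spearman_report()]) with fields `rho`,
#'   `n`, `p`, plus `n_raters` used.
#' @export
verify_ratings <- function(ratings, agreement) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L) stop("need at least 2 raters")
  if (ncol(ratings) != length(agreement))
    stop("ratings must cover all boundaries")
  if (!all(ratings %in% 1:5)) stop("ratings must be integers 1..5")
  sds <- apply(ratings, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " rater(s) with constant ratings dropped")
    ratings <- ratings[sds > 0, , drop = FALSE]
    if (nrow(ratings) < 2L) stop("fewer than 2 usable raters")
  }
  z <- t(scale(t(ratings)))
  mean_rating <- colMeans(z)
  rep <- spearman_report(mean_rating, agreement)
  rep$n_raters <- nrow(ratings)
  rep
}

#' Full segmentation pipeline: logs to analysed boundary set
#'
#' Runs rasterization, agreement averaging, smoothing, concatenation, peak
#' detection, strength binning, exclusion rules and TR mapping in order.
#'
#' @param logs observer log data frame (`observer_id`, `movie_id`,
#'   `time_s`).
#' @param layout a `session_layout`.
#' @param grid_step,window,smooth_window,percentile,min_peak_sep,min_sep,hrf_shift
#'   stage parameters; see the individual stage functions.
#' @return list with `agreement` (the smoothed `agreement_series`) and
#'   `boundaries` (data frame: time_s, agreement, category, excluded,
#'   reason, tr_index).
#' @export
segment_boundaries <- function(logs, layout, grid_step = 0.1, window = 1,
                               smooth_window = 2, percentile = 65,
                               min_peak_sep = 1, min_sep = 6,
                               hrf_shift = 3) {
  agr <- observer_agreement(logs, layout, grid_step = grid_step,
                            window = window, smooth_window = smooth_window)
  cand <- detect_boundaries(agr, percentile = percentile,
                            min_peak_sep = min_peak_sep)
  bnd <- bin_strength(cand)
  bnd <- apply_exclusions(bnd, layout, min_sep = min_sep)
  bnd <- to_tr_indices(bnd, layout, hrf_shift = hrf_shift)
  list(agreement = agr, boundaries = bnd)
}
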