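#' Build a session layout mapping movie time to fMRI TR indices
#'
#' A session layout describes how a set of movies, each preceded by a short
#' title screen, is laid out over one or more contiguous scanning runs. All
#' downstream stages use the layout to convert between seconds (observer
#' time, concatenated across movies) and 0-based TR indices (fMRI time).
#'
#' Movie durations are total interval lengths *including* the leading title
#' window, i.e. a 120 s movie with a 4 s title shows actual content during
#' seconds 4--120 of its interval. Runs must partition the movies into
#' contiguous, ordered blocks. Each run's duration must be an integer
#' multiple of `tr` (within tolerance); TR grids restart at run onsets.
#'
#' @param movie_durations numeric vector of per-movie durations in seconds
#'   (title included). Names, if present, are used as movie ids.
#' @param title_duration length of the title window at each movie onset,
#'   seconds.
#' @param tr repetition time in seconds.
#' @param runs integer vector, same length as `movie_durations`, assigning
#'   each movie to a run. Must be non-decreasing. Default: one run.
#' @return An object of class `session_layout`: a list with elements
#'   `tr`, `movies` (data frame: movie_id, run, onset_s, duration_s,
#'   title_onset_s, title_end_s), `runs` (data frame: run, start_s, end_s,
#'   start_tr, n_tr), `session_duration_s` and `n_tr_total`. All onsets are
#'   global (concatenated-session) seconds; `start_tr` is 0-based.
#' @examples
#' lay <- make_session_layout(c(120, 120), title_duration = 4, tr = 1.5)
#' lay$n_tr_total # 160
#' @export
make_session_layout <- function(movie_durations, title_duration = 4,
                                tr = 1.5, runs = NULL) {
  if (length(movie_durations) == 0L) stop("empty movie list")
  if (!is.numeric(movie_durations) || any(movie_durations <= 0))
    stop("movie durations must be positive")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a positive scalar")
  if (title_duration < 0 || title_duration >= min(movie_durations))
    stop("title_duration must be >= 0 and shorter than every movie")
  n <- length(movie_durations)
  if (is.null(runs)) runs <- rep(1L, n)
  runs <- as.integer(runs)
  if (length(runs) != n) stop("runs must have one entry per movie")
  if (any(diff(runs) < 0)) stop("runs must be non-decreasing (contiguous blocks)")

  ids <- names(movie_durations)
  if (is.null(ids)) ids <- sprintf("movie%02d", seq_len(n))
  onsets <- c(0, cumsum(movie_durations))[seq_len(n)]
  movies <- data.frame(
    movie_id = ids, run = runs, onset_s = onsets,
    duration_s = as.numeric(movie_durations),
    title_onset_s = onsets, title_end_s = onsets + title_duration,
    stringsAsFactors = FALSE
  )

  run_ids <- unique(runs)
  run_start <- vapply(run_ids, function(r) min(onsets[runs == r]), 0)
  run_end <- vapply(run_ids, function(r) {
    i <- runs == r
    max(onsets[i] + movie_durations[i])
  }, 0)
  n_tr <- (run_end - run_start) / tr
  if (any(abs(n_tr - round(n_tr)) > 1e-6)) {
    warning("run duration not an integer multiple of tr; truncating")
  }
  n_tr <- floor(n_tr + 1e-6)
  start_tr <- c(0L, cumsum(n_tr))[seq_along(run_ids)]
  runs_df <- data.frame(
    run = run_ids, start_s = run_start, end_s = run_end,
    start_tr = as.integer(start_tr), n_tr = as.integer(n_tr)
  )

  structure(list(
    tr = tr, title_duration = title_duration,
    movies = movies, runs = runs_df,
    session_duration_s = sum(movie_durations),
    n_tr_total = sum(n_tr)
  ), class = "session_layout")
}

#' @export
print.session_layout <- function(x, ...) {
  cat(sprintf(
    "<session_layout> %d movie(s), %d run(s), %.1f s, %d TRs (TR = %g s)\n",
    nrow(x$movies), nrow(x$runs), x$session_duration_s, x$n_tr_total, x$tr
  ))
  invisible(x)
}

#' Convert session seconds to 0-based TR indices
#'
#' Maps global session times to run-global 0-based TR indices:
#' `start_tr + floor((t - run_start) / tr)`. Times outside any run are an
#' error.
#'
#' @param layout a `session_layout`.
#' @param time_s numeric vector of global session times, seconds.
#' @return integer vector of 0-based TR indices.
#' @export
time_to_tr <- function(layout, time_s) {
  stopifnot(inherits(layout, "session_layout"))
  r <- run_of_time(layout, time_s)
  if (anyNA(r)) stop("time outside session runs")
  ri <- match(r, layout$runs$run)
  as.integer(layout$runs$start_tr[ri] +
               floor((time_s - layout$runs$start_s[ri]) / layout$tr + 1e-9))
}

#' Run membership of global session times
#'
#' @param layout a `session_layout`.
#' @param time_s numeric vector of global session times, seconds.
#' @return integer vector of run ids (NA where the time falls in no run).
#' @export
run_of_time <- function(layout, time_s) {
  out <- rep(NA_integer_, length(time_s))
  for (i in seq_len(nrow(layout$runs))) {
    sel <- time_s >= layout$runs$start_s[i] - 1e-9 &
      time_s < layout$runs$end_s[i] - 1e-9
    out[sel] <- layout$runs$run[i]
  }
  out
}

#' Run membership of 0-based TR indices
#'
#' @param layout a `session_layout`.
#' @param tr_index integer vector of 0-based TR indices.
#' @return integer vector of run ids (NA where out of range).
#' @export
run_of_tr <- function(layout, tr_index) {
  out <- rep(NA_integer_, length(tr_index))
  for (i in seq_len(nrow(layout$runs))) {
    sel <- tr_index >= layout$runs$start_tr[i] &
      tr_index < layout$runs$start_tr[i] + layout$runs$n_tr[i]
    out[sel] <- layout$runs$run[i]
  }
  out
}

#' Movie membership of global session times
#'
#' @param layout a `session_layout`.
#' @param time_s numeric vector of global session times, seconds.
#' @return character vector of movie ids (NA where outside all movies).
#' @export
movie_of_time <- function(layout, time_s) {
  out <- rep(NA_character_, length(time_s))
  m <- layout$movies
  for (i in seq_len(nrow(m))) {
    sel <- time_s >= m$onset_s[i] - 1e-9 &
      time_s < m$onset_s[i] + m$duration_s[i] - 1e-9
    out[sel] <- m$movie_id[i]
  }
  out
}

#' Run lengths in TRs, in run order
#' @param layout a `session_layout`.
#' @return integer vector of per-run TR counts.
#' @export
run_lengths <- function(layout) layout$runs$n_tr

#' Default ten-movie, two-run session layout
#'
#' A session mirroring the scale of a typical short-film fMRI stimulus set:
#' ten movies between 2.15 and 7.75 minutes, five per run, 4 s title
#' windows, TR 1.5 s.
#'
#' @param tr repetition time, seconds.
#' @return a `session_layout`.
#' @export
default_session_layout <- function(tr = 1.5) {
  mins <- c(2.15, 2.50, 3.10, 3.60, 4.20, 4.60, 5.20, 6.00, 7.00, 7.75)
  dur <- round(mins * 60 / tr) * tr # snap to TR grid
  names(dur) <- sprintf("movie%02d", 1:10)
  make_session_layout(dur, title_duration = 4, tr = tr,
                      runs = rep(1:2, each = 5))
}
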