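#' Ground truth for a synthetic segmentation study
#'
#' Bundles the planted event boundaries of a simulated session: their times
#' (global session seconds), strengths in \[0, 1\], and the response model
#' used to generate cortical data at those boundaries.
#'
#' In `graded` mode a parcel's latent pattern rotates at each boundary by
#' an amount that grows continuously with boundary strength; in `binary`
#' mode the pattern is fully replaced with probability
#' `detection_curve(strength)` and is otherwise unchanged (an all-or-none
#' "boundary detected" response).
#'
#' @param boundary_times strictly increasing numeric vector, global
#'   session seconds.
#' @param strength numeric vector in \[0, 1\], one per boundary.
#' @param profile_mode `"graded"` or `"binary"`.
#' @param detection_curve monotone non-decreasing function strength ->
#'   detection probability (binary mode). Default: identity.
#' @param shift_gain non-negative scalar scaling rotation magnitude
#'   (graded mode).
#' @param noise_sd non-negative additive voxel noise sd.
#' @param hrf_shift TR lag applied when planting neural pattern changes,
#'   so that the generated data carry the hemodynamic delay that the
#'   analysis pipeline removes (default 3).
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(boundary_times, strength,
                         profile_mode = c("graded", "binary"),
                         detection_curve = NULL, shift_gain = 1,
                         noise_sd = 0.1, hrf_shift = 3) {
  profile_mode <- match.arg(profile_mode)
  if (length(boundary_times) != length(strength))
    stop("boundary_times and strength must have equal length")
  if (is.unsorted(boundary_times, strictly = TRUE))
    stop("boundary_times must be strictly increasing")
  if (any(strength < 0 | strength > 1)) stop("strengths must lie in [0, 1]")
  if (shift_gain < 0) stop("shift_gain must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(detection_curve)) detection_curve <- function(s) s
  probe <- detection_curve(seq(0, 1, by = 0.05))
  if (any(diff(probe) < -1e-9))
    stop("detection_curve must be monotone non-decreasing")
  if (any(probe < -1e-9 | probe > 1 + 1e-9))
    stop("detection_curve must map into [0, 1]")
  structure(list(
    boundary_times = as.numeric(boundary_times),
    strength = as.numeric(strength),
    profile_mode = profile_mode, detection_curve = detection_curve,
    shift_gain = shift_gain, noise_sd = noise_sd,
    hrf_shift = as.integer(hrf_shift)
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d boundaries, %s profile, noise_sd = %g\n",
              length(x$boundary_times), x$profile_mode, x$noise_sd))
  invisible(x)
}

#' Sample plantable boundary times for a layout
#'
#' Draws boundary times uniformly inside movie intervals, avoiding title
#' windows (plus 1 s), the final `tail_excl` seconds of each run, and
#' keeping all pairs at least `min_gap` seconds apart so that planted
#' boundaries survive the 6 s pair-exclusion rule.
#'
#' @param layout a `session_layout`.
#' @param n_boundaries number of boundaries to plant.
#' @param min_gap minimum pairwise gap, seconds.
#' @param tail_excl excluded tail of each run, seconds.
#' @param seed optional integer seed.
#' @return sorted numeric vector of global session times (0.1 s grid).
#' @export
sample_boundary_times <- function(layout, n_boundaries = 130, min_gap = 8,
                                  tail_excl = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- layout$movies
  ri <- match(m$run, layout$runs$run)
  run_tail <- layout$runs$end_s[ri] - tail_excl
  lo <- pmin(m$title_end_s + 1.5, m$onset_s + m$duration_s)
  hi <- pmin(m$onset_s + m$duration_s - 1.5, run_tail)
  times <- numeric(0)
  tries <- 0L
  while (length(times) < n_boundaries) {
    tries <- tries + 1L
    if (tries > 50000L) stop("could not place boundaries; relax min_gap")
    i <- sample.int(nrow(m), 1L, prob = pmax(hi - lo, 0))
    t <- round(stats::runif(1, lo[i], hi[i]), 1)
    if (!length(times) || all(abs(t - times) >= min_gap)) {
      times <- c(times, t)
    }
  }
  sort(times)
}

#' Simulate observer segmentation logs
#'
#' Observer `o` marks planted boundary `i` with probability
#' `prob_fun(strength_i)` (default: the strength itself), at the true time
#' plus Gaussian jitter truncated to the movie interval. Optional false
#' alarms are placed uniformly inside movies at `false_alarm_rate` marks
#' per minute. With `enforce_allowance = TRUE`, per-observer per-movie
#' counts are clipped into the segment-allowance range
#' (see [segment_allowance()]): surplus marks are subsampled at random and
#' shortfalls are filled with uniform random marks.
#'
#' @param layout a `session_layout`.
#' @param truth a `ground_truth`.
#' @param n_observers number of observers (default 16).
#' @param jitter_sd Gaussian jitter sd, seconds (default 0.3).
#' @param seed optional integer seed.
#' @param prob_fun map strength -> marking probability.
#' @param false_alarm_rate spurious marks per minute of movie (default 0).
#' @param enforce_allowance clip counts into the allowance range?
#' @return data frame (`observer_id`, `movie_id`, `time_s`) with `time_s`
#'   in seconds from movie onset, rounded to 0.1 s.
#' @export
simulate_observers <- function(layout, truth, n_observers = 16,
                               jitter_sd = 0.3, seed = NULL,
                               prob_fun = NULL, false_alarm_rate = 0,
                               enforce_allowance = FALSE) {
  stopifnot(inherits(layout, "session_layout"),
            inherits(truth, "ground_truth"))
  if (n_observers < 1L) stop("need at least one observer")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(prob_fun)) prob_fun <- function(s) s

  m <- layout$movies
  b_movie <- movie_of_time(layout, truth$boundary_times)
  if (anyNA(b_movie)) stop("planted boundary outside movie intervals")
  mi <- match(b_movie, m$movie_id)
  rel_time <- truth$boundary_times - m$onset_s[mi]
  p_mark <- prob_fun(truth$strength)

  rows <- vector("list", n_observers)
  for (o in seq_len(n_observers)) {
    marked <- stats::runif(length(p_mark)) < p_mark
    t <- rel_time[marked]
    mid <- b_movie[marked]
    if (length(t) && jitter_sd > 0) {
      dur <- m$duration_s[match(mid, m$movie_id)]
      j <- stats::rnorm(length(t), 0, jitter_sd)
      t <- pmin(pmax(t + j, 0), dur - 0.1)
    }
    if (false_alarm_rate > 0) {
      for (i in seq_len(nrow(m))) {
        n_fa <- stats::rpois(1, false_alarm_rate * m$duration_s[i] / 60)
        if (n_fa > 0) {
          t <- c(t, stats::runif(n_fa, layout$title_duration,
                                 m$duration_s[i] - 0.1))
          mid <- c(mid, rep(m$movie_id[i], n_fa))
        }
      }
    }
    t <- round(t, 1)
    if (enforce_allowance && length(t)) {
      keep_t <- numeric(0)
      keep_m <- character(0)
      for (i in seq_len(nrow(m))) {
        sel <- mid == m$movie_id[i]
        ti <- t[sel]
        rng <- segment_allowance(m$duration_s[i])
        if (length(ti) > rng["max"]) {
          ti <- ti[sample.int(length(ti), rng["max"])]
        } else if (length(ti) < rng["min"]) {
          extra <- round(stats::runif(rng["min"] - length(ti),
                                      layout$title_duration,
                                      m$duration_s[i] - 0.1), 1)
          ti <- c(ti, extra)
        }
        keep_t <- c(keep_t, ti)
        keep_m <- c(keep_m, rep(m$movie_id[i], length(ti)))
      }
      t <- keep_t
      mid <- keep_m
    }
    rows[[o]] <- data.frame(
      observer_id = rep(sprintf("obs%02d", o), length(t)),
      movie_id = mid, time_s = t, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$observer_id, out$movie_id, out$time_s), ]
  rownames(out) <- NULL
  out
}

#' Default hierarchy specification for simulated cortical data
#'
#' @param n_parcels parcels per level.
#' @param n_voxels voxels per parcel.
#' @return named list, one entry per hierarchy level
#'   (`1_AUD`, `1_VIS`, `2`, `3`, `4`).
#' @export
default_levels_spec <- function(n_parcels = 2, n_voxels = 16) {
  lv <- c("1_AUD", "1_VIS", "2", "3", "4")
  stats::setNames(lapply(lv, function(l)
    list(n_parcels = n_parcels, n_voxels = n_voxels)), lv)
}

#' Default per-level strength responsiveness weights
#'
#' In graded mode a boundary of strength `s` rotates a level's latent
#' pattern by the fraction `shift_gain * weight * s`. Sensory levels
#' (weight 1) track boundary strength tightly; weights decrease up the
#' hierarchy, so high levels rotate less at weak boundaries and their
#' shift indicators fire progressively less often -- which is what gives
#' alignment scores their bottom-up nested structure.
#'
#' @return named numeric vector over hierarchy levels.
#' @export
default_level_weights <- function() {
  c("1_AUD" = 1, "1_VIS" = 1, "2" = 0.8, "3" = 0.6, "4" = 0.4)
}

# Rotate unit vector v toward a random direction by fraction f in [0, 1]:
# f = 0 keeps v, f = 1 lands on a direction orthogonal-in-expectation to v.
.rotate_latent <- function(v, f) {
  r <- stats::rnorm(length(v))
  r <- r - sum(r * v) * v # orthogonalize
  nr <- sqrt(sum(r^2))
  if (nr < 1e-12) return(v)
  r <- r / nr
  ang <- f * pi / 2
  w <- cos(ang) * v + sin(ang) * r
  w / sqrt(sum(w^2))
}

#' Simulate hierarchical multi-voxel cortical time series
#'
#' Within each event (the span between consecutive planted boundaries,
#' restarted at run onsets), a parcel's voxel pattern is a fixed latent
#' unit vector plus i.i.d. Gaussian noise. At each planted boundary
#' (HRF-shifted by `truth$hrf_shift` TRs) the latent vector changes:
#'
#' * `graded`: it rotates toward a new random direction by the fraction
#'   `clamp(shift_gain * w_l * strength, 0, 1)`, where `w_l` is the
#'   level's responsiveness weight -- the rotation grows continuously
#'   (proportionally) with strength;
#' * `binary`: it is fully replaced by a fresh random direction with
#'   probability `detection_curve(strength)`, else left unchanged.
#'   Detection is drawn independently per subject and boundary (shared
#'   across that subject's parcels), which is what makes between-subject
#'   variance peak at intermediate detection probabilities.
#'
#' In graded mode the latent sequence is shared by all subjects (a purely
#' stimulus-driven signal); only the noise is subject-specific.
#'
#' @param layout a `session_layout`.
#' @param truth a `ground_truth`.
#' @param levels_spec named list per level with `n_parcels`, `n_voxels`
#'   (see [default_levels_spec()]).
#' @param n_subjects number of subjects (default 17).
#' @param seed optional integer seed.
#' @param level_weights named responsiveness weights
#'   (see [default_level_weights()]).
#' @return list of subjects; each subject is a named list of levels; each
#'   level a list of `n_voxels x n_TR` matrices (one per parcel).
#' @export
simulate_cortex <- function(layout, truth, levels_spec = default_levels_spec(),
                            n_subjects = 17, seed = NULL,
                            level_weights = default_level_weights()) {
  stopifnot(inherits(layout, "session_layout"),
            inherits(truth, "ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  for (sp in levels_spec) {
    if (sp$n_voxels < 2L) stop("need at least 2 voxels per parcel")
  }
  lv <- names(levels_spec)
  if (!all(lv %in% names(level_weights)))
    stop("level_weights must cover every level in levels_spec")

  n_tr <- layout$n_tr_total
  b_tr <- time_to_tr(layout, truth$boundary_times) + truth$hrf_shift
  b_tr <- pmin(b_tr, n_tr - 1L)
  # event id per TR: segments cut at boundaries and at run onsets
  cuts <- sort(unique(c(layout$runs$start_tr, b_tr)))
  event_id <- findInterval(0:(n_tr - 1L), cuts)
  n_events <- max(event_id)
  # strength of the boundary opening each event (NA for run onsets)
  open_strength <- rep(NA_real_, n_events)
  open_detect_p <- rep(NA_real_, n_events)
  for (i in seq_along(b_tr)) {
    ev <- findInterval(b_tr[i], cuts)
    open_strength[ev] <- truth$strength[i]
    open_detect_p[ev] <- truth$detection_curve(truth$strength[i])
  }

  graded <- truth$profile_mode == "graded"

  # latent sequences shared across subjects in graded mode
  make_latents <- function(n_vox, w_l) {
    lat <- matrix(0, n_vox, n_events)
    v <- stats::rnorm(n_vox)
    v <- v / sqrt(sum(v^2))
    lat[, 1L] <- v
    for (ev in 2:max(2L, n_events)) {
      if (ev > n_events) break
      s <- open_strength[ev]
      if (is.na(s)) { # run onset: fresh context
        v <- stats::rnorm(n_vox)
        v <- v / sqrt(sum(v^2))
      } else if (graded) {
        f <- min(max(truth$shift_gain * w_l * s, 0), 1)
        v <- .rotate_latent(v, f)
      }
      lat[, ev] <- v
    }
    lat
  }

  subjects <- vector("list", n_subjects)
  if (graded) {
    latents <- lapply(lv, function(l) {
      sp <- levels_spec[[l]]
      lapply(seq_len(sp$n_parcels), function(p)
        make_latents(sp$n_voxels, level_weights[[l]]))
    })
    names(latents) <- lv
    for (s in seq_len(n_subjects)) {
      subjects[[s]] <- lapply(lv, function(l) {
        sp <- levels_spec[[l]]
        lapply(seq_len(sp$n_parcels), function(p) {
          lat <- latents[[l]][[p]]
          x <- lat[, event_id, drop = FALSE] * sqrt(sp$n_voxels)
          x + matrix(stats::rnorm(length(x), 0, truth$noise_sd),
                     nrow(x), ncol(x))
        })
      })
      names(subjects[[s]]) <- lv
    }
  } else {
    for (s in seq_len(n_subjects)) {
      # per-subject detection, shared across this subject's parcels
      detected <- !is.na(open_detect_p) &
        stats::runif(n_events) < ifelse(is.na(open_detect_p), 0, open_detect_p)
      subjects[[s]] <- lapply(lv, function(l) {
        sp <- levels_spec[[l]]
        lapply(seq_len(sp$n_parcels), function(p) {
          lat <- matrix(0, sp$n_voxels, n_events)
          v <- stats::rnorm(sp$n_voxels)
          v <- v / sqrt(sum(v^2))
          lat[, 1L] <- v
          for (ev in seq_len(n_events)[-1L]) {
            if (is.na(open_strength[ev]) || detected[ev]) {
              v <- stats::rnorm(sp$n_voxels)
              v <- v / sqrt(sum(v^2))
            }
            lat[, ev] <- v
          }
          x <- lat[, event_id, drop = FALSE] * sqrt(sp$n_voxels)
          x + matrix(stats::rnorm(length(x), 0, truth$noise_sd),
                     nrow(x), ncol(x))
        })
      })
      names(subjects[[s]]) <- lv
    }
  }
  subjects
}

#' Simulate boundary-locked hippocampal TR series
#'
#' `series = drift + sum_i amplitude_i * kernel(t - boundary_tr_i) + noise`
#' per subject, with subject-independent amplitudes and kernel and
#' i.i.d. Gaussian noise.
#'
#' @param layout a `session_layout`.
#' @param truth a `ground_truth` (its `hrf_shift` places the response).
#' @param amplitudes numeric vector, one per boundary; default
#'   `amplitude_rule(truth$strength)`.
#' @param amplitude_rule map strength -> amplitude (default identity);
#'   ignored when `amplitudes` is given.
#' @param kernel non-negative finite response kernel sampled at TR
#'   resolution, starting at lag 0. Default peaks 2 TRs after the
#'   (HRF-shifted) boundary.
#' @param noise_sd Gaussian noise sd.
#' @param n_subjects number of subjects.
#' @param seed optional integer seed.
#' @return numeric matrix `n_subjects x n_TR`.
#' @export
simulate_hippocampus <- function(layout, truth, amplitudes = NULL,
                                 amplitude_rule = identity,
                                 kernel = c(0.3, 0.8, 1, 0.7, 0.35, 0.15),
                                 noise_sd = 0.1, n_subjects = 17,
                                 seed = NULL) {
  stopifnot(inherits(layout, "session_layout"),
            inherits(truth, "ground_truth"))
  if (any(kernel < 0) || any(!is.finite(kernel)))
    stop("kernel must be non-negative and finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(amplitudes)) amplitudes <- amplitude_rule(truth$strength)
  if (length(amplitudes) != length(truth$boundary_times))
    stop("one amplitude per boundary required")
  n_tr <- layout$n_tr_total
  b_tr <- time_to_tr(layout, truth$boundary_times) + truth$hrf_shift
  base <- numeric(n_tr)
  for (i in seq_along(b_tr)) {
    idx <- b_tr[i] + seq_along(kernel) - 1L # lag 0 at boundary TR
    ok <- idx < n_tr
    base[idx[ok] + 1L] <- base[idx[ok] + 1L] + amplitudes[i] * kernel[ok]
  }
  out <- matrix(rep(base, each = n_subjects), n_subjects, n_tr)
  if (noise_sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), 0, noise_sd),
                        n_subjects, n_tr)
  }
  rownames(out) <- sprintf("sub%02d", seq_len(n_subjects))
  out
}

#' Simulate a complete synthetic study
#'
#' Bundles a layout, planted ground truth, observer logs, per-subject
#' cortical data and hippocampal series, mirroring the scale of the
#' analysed dataset by default (17 subjects, 16 observers, ~130
#' boundaries, TR 1.5 s).
#'
#' @param layout a `session_layout`
#'   (default [default_session_layout()]).
#' @param n_boundaries planted boundary count.
#' @param profile_mode `"graded"` or `"binary"`.
#' @param n_subjects,n_observers study sizes.
#' @param noise_sd,shift_gain,detection_curve response-model parameters
#'   (see [ground_truth()]).
#' @param levels_spec cortical hierarchy sizes
#'   (see [default_levels_spec()]).
#' @param seed integer seed driving every random stage.
#' @return list with `layout`, `truth`, `observer_logs`, `subject_data`,
#'   `hippocampus`, of class `simulated_study`.
#' @export
simulate_study <- function(layout = default_session_layout(),
                           n_boundaries = 130,
                           profile_mode = c("graded", "binary"),
                           n_subjects = 17, n_observers = 16,
                           noise_sd = 0.1, shift_gain = 1,
                           detection_curve = NULL,
                           levels_spec = default_levels_spec(),
                           seed = 1) {
  profile_mode <- match.arg(profile_mode)
  set.seed(seed)
  times <- sample_boundary_times(layout, n_boundaries)
  strength <- stats::runif(n_boundaries, 0.1, 1)
  truth <- ground_truth(times, strength, profile_mode = profile_mode,
                        detection_curve = detection_curve,
                        shift_gain = shift_gain, noise_sd = noise_sd)
  logs <- simulate_observers(layout, truth, n_observers = n_observers)
  subject_data <- simulate_cortex(layout, truth, levels_spec = levels_spec,
                                  n_subjects = n_subjects)
  hippo <- simulate_hippocampus(layout, truth, n_subjects = n_subjects)
  structure(list(layout = layout, truth = truth, observer_logs = logs,
                 subject_data = subject_data, hippocampus = hippo),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d subjects, %d observers, %d planted boundaries (%s)\n",
    length(x$subject_data), length(unique(x$observer_logs$observer_id)),
    length(x$truth$boundary_times), x$truth$profile_mode
  ))
  invisible(x)
}
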