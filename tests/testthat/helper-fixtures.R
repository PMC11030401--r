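# Shared fixture builders. All synthetic inputs are generated in code;
# seeds are fixed per test.

tiny_layout <- function() {
  make_session_layout(c(a = 120, b = 120), title_duration = 4, tr = 1.5)
}

two_run_layout <- function() {
  make_session_layout(c(a = 120, b = 120, c = 120, d = 120),
                      title_duration = 4, tr = 1.5, runs = c(1, 1, 2, 2))
}

# planted boundaries at fixed times with given strengths, inside `layout`
planted_truth <- function(layout, times, strength, ...) {
  ground_truth(times, strength, ...)
}

# brute-force agreement: double loop over observers and samples
brute_agreement <- function(times_list, duration, grid_step = 0.1,
                            window = 1) {
  n <- round(duration / grid_step)
  grid <- (seq_len(n) - 1) * grid_step
  acc <- numeric(n)
  for (times in times_list) {
    for (k in seq_len(n)) {
      hit <- FALSE
      for (t in times) {
        if (abs(grid[k] - t) <= window + 1e-9) hit <- TRUE
      }
      acc[k] <- acc[k] + as.numeric(hit)
    }
  }
  acc / length(times_list)
}

# naive per-TR pattern-shift recomputation
brute_shift_series <- function(x, run_lens, halfwin = 3) {
  out <- rep(NA_real_, ncol(x))
  off <- c(0L, cumsum(run_lens))
  for (r in seq_along(run_lens)) {
    for (t in seq_len(run_lens[r])) {
      if (t <= halfwin || t > run_lens[r] - halfwin) next
      col <- off[r] + t
      pre <- rowMeans(x[, off[r] + (t - halfwin):(t - 1), drop = FALSE])
      post <- rowMeans(x[, off[r] + (t + 1):(t + halfwin), drop = FALSE])
      if (stats::sd(pre) < 1e-12 || stats::sd(post) < 1e-12) next
      out[col] <- stats::cor(pre, post)
    }
  }
  out
}
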