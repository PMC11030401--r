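test_that("rasterization places inclusive 1 s windows on the 0.1 s grid", {
  r <- rasterize_observer(10.0, duration = 30)
  expect_equal(sum(r), 21) # samples 9.0 .. 11.0 inclusive
  expect_equal(which(r == 1L), 91:111)
  expect_equal(rasterize_observer(numeric(0), 30), integer(300))
  # overlapping windows merge
  r2 <- rasterize_observer(c(10, 11.5), 30)
  expect_equal(which(r2 == 1L), 91:126) # 9.0 .. 12.5
  expect_error(rasterize_observer(31, 30), "outside")
  expect_error(rasterize_observer(5, 30, window = -1), "window")
})

test_that("agreement equals the brute-force observer x sample loop", {
  set.seed(11)
  for (rep in 1:5) {
    dur <- 40
    times_list <- lapply(1:6, function(o)
      sort(round(runif(sample(0:5, 1), 0, dur), 1)))
    rasters <- lapply(times_list, rasterize_observer, duration = dur)
    expect_equal(agreement_series(rasters),
                 brute_agreement(times_list, dur))
  }
  # two observers with disjoint windows -> 0.5 on each window
  a <- agreement_series(list(rasterize_observer(5, 30),
                             rasterize_observer(20, 30)))
  expect_equal(unique(a[a > 0]), 0.5)
  expect_error(agreement_series(list(1:5, 1:4)), "mismatch")
})

test_that("Gaussian smoothing preserves constants and matches the kernel", {
  expect_equal(smooth_gaussian(rep(0.4, 100)), rep(0.4, 100))
  # symmetric input -> symmetric output
  x <- c(rep(0, 40), seq(0, 1, length.out = 11),
         seq(1, 0, length.out = 11)[-1], rep(0, 40))
  s <- smooth_gaussian(x)
  expect_equal(s, rev(s))
  # unit impulse reproduces the renormalized kernel weights
  imp <- c(rep(0, 50), 1, rep(0, 50))
  s <- smooth_gaussian(imp, window = 2, grid_step = 0.1)
  w <- dnorm((-10:10) * 0.1, 0, 0.4)
  expect_equal(s[41:61], w / sum(w), tolerance = 1e-12)
  expect_error(smooth_gaussian(1:10, window = 0.05, grid_step = 0.1),
               "smaller")
})

test_that("concatenation follows layout order and round-trips", {
  lay <- tiny_layout()
  sa <- runif(1200)
  sb <- runif(1200)
  agr <- concat_movies(list(b = sb, a = sa), lay)
  expect_equal(length(agr$values), 2400)
  expect_equal(agr$movie_offsets, c(a = 0L, b = 1200L))
  expect_equal(agr$values[1:1200], sa)
  expect_equal(agr$values[1201:2400], sb)
  expect_error(concat_movies(list(a = sa), lay), "missing")
  expect_error(concat_movies(list(a = sa[-1], b = sb), lay), "length")
})

test_that("peak detection thresholds, deduplicates plateaus, thins peaks", {
  # single triangular bump above threshold -> one boundary at the apex
  v <- c(rep(0, 200), seq(0, 1, length.out = 11),
         seq(1, 0, length.out = 11)[-1], rep(0, 200))
  b <- detect_boundaries(v, percentile = 65)
  expect_equal(nrow(b), 1L)
  expect_equal(b$time_s, 210 * 0.1)
  expect_equal(b$agreement, 1)
  # series entirely below threshold -> empty set, not an error
  expect_equal(nrow(detect_boundaries(rep(0.5, 100))), 0L)
  # plateau reduces to its earliest sample
  vp <- c(rep(0, 50), 0.2, rep(0.9, 5), 0.2, rep(0, 50))
  bp <- detect_boundaries(vp, percentile = 65)
  expect_equal(bp$time_s, 51 * 0.1)
  # two bumps 0.5 s apart -> only the higher peak survives
  v2 <- rep(0, 400)
  v2[101] <- 0.8
  v2[106] <- 0.6
  b2 <- detect_boundaries(v2, percentile = 65, min_peak_sep = 1)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$agreement, 0.8)
  # 1 s apart is allowed
  v3 <- rep(0, 400)
  v3[101] <- 0.8
  v3[111] <- 0.6
  expect_equal(nrow(detect_boundaries(v3, percentile = 65)), 2L)
})

test_that("strength binning is an equal split with remainders upward", {
  mk <- function(agree) data.frame(time_s = seq_along(agree), agreement = agree)
  b9 <- bin_strength(mk(seq(0.1, 0.9, by = 0.1)))
  expect_equal(as.vector(table(b9$category)), c(3, 3, 3))
  expect_equal(as.character(b9$category[b9$agreement > 0.6]),
               rep("strong", 3))
  b10 <- bin_strength(mk(seq(0.1, 1, by = 0.1)))
  expect_equal(as.vector(table(b10$category)), c(3, 3, 4))
  b11 <- bin_strength(mk(seq(0, 1, by = 0.1)))
  expect_equal(as.vector(table(b11$category)), c(3, 4, 4))
  # all-equal agreement: deterministic, sort-stable (earlier times weaker)
  be <- bin_strength(mk(rep(0.5, 6)))
  expect_equal(as.character(be$category), rep(c("weak", "moderate", "strong"),
                                              each = 2))
  expect_error(bin_strength(mk(c(0.1, 0.2))), "at least 3")
})

test_that("exclusion rules flag pairs, title onsets and run-final boundaries", {
  lay <- two_run_layout()
  mk <- function(t) data.frame(time_s = t, agreement = 0.5)
  # both members of a close pair are flagged
  b <- apply_exclusions(mk(c(10, 14)), lay, last_per_run = FALSE)
  expect_equal(b$excluded, c(TRUE, TRUE))
  expect_equal(b$reason, c("pair<6s", "pair<6s"))
  # boundary at a movie title onset window
  b2 <- apply_exclusions(mk(c(122, 200)), lay, last_per_run = FALSE)
  expect_equal(b2$excluded, c(TRUE, FALSE)) # 122 is in movie b's title+1s
  expect_equal(b2$reason[1], "movie_onset")
  # pair rule then last-in-run: of 10/14/30 nothing survives
  b3 <- apply_exclusions(mk(c(10, 14, 30)), lay)
  expect_equal(b3$excluded, rep(TRUE, 3))
  expect_equal(b3$reason, c("pair<6s", "pair<6s", "last_in_run"))
  # last retained boundary of EACH run is flagged
  b4 <- apply_exclusions(mk(c(30, 60, 300, 330)), lay)
  expect_equal(b4$excluded, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(b4$reason[c(2, 4)], c("last_in_run", "last_in_run"))
})

test_that("TR mapping applies the hemodynamic shift and flags run overruns", {
  lay <- two_run_layout()
  mk <- function(t) data.frame(time_s = t, agreement = 0.5)
  b <- to_tr_indices(mk(c(0, 30)), lay)
  expect_equal(b$tr_index, c(3L, 23L)) # floor(t/1.5) + 3
  # a time in run 2 is offset by run 1's TR count
  b2 <- to_tr_indices(mk(250.5), lay)
  expect_equal(b2$tr_index, 170L)
  # shifted index beyond the run end is flagged
  b3 <- to_tr_indices(mk(239.5), lay)
  expect_true(b3$excluded)
  expect_equal(b3$reason, "run_end")
})

test_that("segment allowance follows the ceil-minutes rule", {
  expect_equal(segment_allowance(138), c(min = 6L, max = 12L))
  expect_equal(segment_allowance(60), c(min = 2L, max = 4L))
  expect_equal(segment_allowance(465), c(min = 16L, max = 32L))
  expect_error(segment_allowance(0), "positive")
})

test_that("rating verification standardizes raters and rank-correlates", {
  agreement <- c(0.15, 0.3, 0.45, 0.62, 0.88)
  # perfectly rank-matching ratings -> rho = 1
  ratings <- rbind(1:5, 1:5)
  r <- verify_ratings(ratings, agreement)
  expect_equal(r$rho, 1)
  # reversed ranks -> rho = -1
  r2 <- verify_ratings(ratings[, 5:1, drop = FALSE], agreement)
  expect_equal(r2$rho, -1)
  # noisy ratings match the reference rank-correlation oracle
  set.seed(5)
  n <- 131
  agreement <- runif(n)
  ratings <- t(replicate(4, pmax(1, pmin(5, round(agreement * 4 + 1 +
                                                    rnorm(n, 0, 0.5))))))
  r3 <- verify_ratings(ratings, agreement)
  z <- t(scale(t(ratings)))
  ref <- cor(colMeans(z), agreement, method = "spearman")
  expect_equal(r3$rho, ref, tolerance = 1e-10)
  expect_gt(r3$rho, 0)
  # a constant rater is dropped with a warning
  ratings_c <- rbind(ratings, rep(3, n))
  expect_warning(r4 <- verify_ratings(ratings_c, agreement), "constant")
  expect_equal(r4$n_raters, 4)
})

test_that("planted boundaries are recovered from simulated observers", {
  # strengths {0.2, 0.5, 0.9}: detected within 1 s of truth and
  # Spearman(agreement, strength) > 0.8 in >= 95% of seeds
  lay <- default_session_layout()
  n_seeds <- 40
  ok <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    times <- sample_boundary_times(lay, n_boundaries = 90, min_gap = 10)
    strength <- rep(c(0.2, 0.5, 0.9), length.out = 90)
    truth <- ground_truth(times, strength)
    logs <- simulate_observers(lay, truth, n_observers = 16)
    seg <- segment_boundaries(logs, lay)
    kept <- seg$boundaries
    idx <- vapply(times, function(t) which.min(abs(kept$time_s - t)), 0L)
    matched <- abs(kept$time_s[idx] - times) <= 1
    rho <- suppressWarnings(cor(kept$agreement[idx][matched],
                                strength[matched], method = "spearman"))
    ok[s] <- mean(matched) >= 0.95 && rho > 0.8
  }
  expect_gte(mean(ok), 0.95)
})

test_that("the segmentation pipeline is idempotent on identical inputs", {
  lay <- tiny_layout()
  set.seed(3)
  times <- sample_boundary_times(lay, n_boundaries = 10, min_gap = 10)
  truth <- ground_truth(times, runif(10, 0.4, 1))
  logs <- simulate_observers(lay, truth, seed = 8)
  s1 <- segment_boundaries(logs, lay)
  s2 <- segment_boundaries(logs, lay)
  expect_identical(s1, s2)
})
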