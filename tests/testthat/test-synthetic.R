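test_that("ground truth validates its invariants", {
  expect_error(ground_truth(c(10, 5), c(0.5, 0.5)), "increasing")
  expect_error(ground_truth(c(5, 10), c(0.5, 1.5)), "0, 1")
  expect_error(ground_truth(5, 0.5, shift_gain = -1), "shift_gain")
  expect_error(ground_truth(5, 0.5, noise_sd = -1), "noise_sd")
  expect_error(ground_truth(5, 0.5, detection_curve = function(s) 1 - s),
               "monotone")
})

test_that("observer simulation honours degenerate probabilities", {
  lay <- tiny_layout()
  times <- c(20, 40, 60, 150, 180)
  # strength 1, no jitter: every observer marks every boundary exactly
  truth <- ground_truth(times, rep(1, 5))
  logs <- simulate_observers(lay, truth, n_observers = 4, jitter_sd = 0,
                             seed = 1)
  expect_equal(nrow(logs), 20L)
  got <- sort(logs$time_s[logs$observer_id == "obs01"])
  expect_equal(got, c(20, 40, 60, 30, 60)[order(c(20, 40, 60, 30, 60))])
  # strength 0: empty logs
  truth0 <- ground_truth(times, rep(0, 5))
  expect_equal(nrow(simulate_observers(lay, truth0, seed = 1)), 0L)
  expect_error(simulate_observers(lay, truth, jitter_sd = -1), "jitter")
})

test_that("marking fractions are binomially calibrated", {
  # strengths {0.2, 0.5, 0.9}, 16 observers, 200 seeds: empirical marking
  # fractions inside the binomial 95% band around the strengths
  lay <- tiny_layout()
  strength <- c(0.2, 0.5, 0.9)
  truth <- ground_truth(c(30, 90, 160), strength)
  marks <- matrix(0, 200, 3)
  for (s in 1:200) {
    logs <- simulate_observers(lay, truth, n_observers = 16, jitter_sd = 0,
                               seed = s)
    tt <- c(30, 90, 160 - 120) # movie-relative truth times
    mv <- c("a", "a", "b")
    marks[s, ] <- vapply(1:3, function(i)
      sum(logs$movie_id == mv[i] & abs(logs$time_s - tt[i]) < 0.05), 0)
  }
  frac <- colSums(marks) / (200 * 16)
  n_tot <- 200 * 16
  for (i in 1:3) {
    half <- 1.96 * sqrt(strength[i] * (1 - strength[i]) / n_tot)
    expect_lt(abs(frac[i] - strength[i]), half + 1e-12)
  }
})

test_that("allowance enforcement clips per-movie counts", {
  lay <- tiny_layout() # 120 s movies: k = 2, allowance 4..8
  times <- sort(c(seq(10, 115, by = 9), seq(130, 235, by = 9)))
  truth <- ground_truth(times, rep(1, length(times)))
  logs <- simulate_observers(lay, truth, n_observers = 3, jitter_sd = 0,
                             seed = 2, enforce_allowance = TRUE)
  counts <- table(logs$observer_id, logs$movie_id)
  expect_true(all(counts >= 4 & counts <= 8))
})

test_that("cortical generator respects the stated response profiles", {
  lay <- tiny_layout()
  spec <- default_levels_spec(n_parcels = 1, n_voxels = 12)["1_AUD"]
  # graded, strength 0, no noise: pattern identical across the boundary
  truth <- ground_truth(60, 0, profile_mode = "graded", noise_sd = 0)
  dat <- simulate_cortex(lay, truth, spec, n_subjects = 1, seed = 1)
  x <- dat[[1]][["1_AUD"]][[1]]
  btr <- time_to_tr(lay, 60) + 3
  expect_equal(x[, btr], x[, btr + 2]) # same latent both sides
  # binary with detection probability 1, no noise: pre/post patterns
  # uncorrelated in expectation (|mean cor| small over boundaries)
  truthb <- ground_truth(seq(30, 210, by = 20), rep(1, 10),
                         profile_mode = "binary", noise_sd = 0)
  cors <- c()
  for (s in 1:30) {
    datb <- simulate_cortex(lay, truthb, spec, n_subjects = 1, seed = s)
    xb <- datb[[1]][["1_AUD"]][[1]]
    for (t in time_to_tr(lay, truthb$boundary_times) + 3) {
      cors <- c(cors, cor(xb[, t - 1], xb[, t + 1]))
    }
  }
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("graded shift magnitude is ordered by planted strength", {
  # strengths {0.2, 0.5, 0.9}: mean pattern-shift magnitude strictly
  # ordered over 50 seeds (Monte Carlo on generator output)
  lay <- tiny_layout()
  spec <- default_levels_spec(n_parcels = 1, n_voxels = 12)["1_AUD"]
  strength <- rep(c(0.2, 0.5, 0.9), each = 4)
  times <- seq(25, 223, length.out = 12)
  truth <- ground_truth(times, strength, profile_mode = "graded",
                        noise_sd = 0.1)
  shift_mag <- matrix(0, 50, 3)
  for (s in 1:50) {
    dat <- simulate_cortex(lay, truth, spec, n_subjects = 1, seed = s)
    x <- dat[[1]][["1_AUD"]][[1]]
    btr <- time_to_tr(lay, times) + 3
    mag <- vapply(btr, function(t) 1 - cor(x[, t - 1], x[, t + 1]), 0)
    shift_mag[s, ] <- tapply(mag, strength, mean)
  }
  m <- colMeans(shift_mag)
  expect_true(m[1] < m[2] && m[2] < m[3])
})

test_that("hippocampal generator follows its additive model", {
  lay <- tiny_layout()
  truth <- ground_truth(c(60, 150), c(0.5, 1))
  # amplitude 0, noise 0: flat series
  h0 <- simulate_hippocampus(lay, truth, amplitudes = c(0, 0),
                             noise_sd = 0, n_subjects = 2, seed = 1)
  expect_equal(max(abs(h0)), 0)
  # single boundary, unit amplitude, delta kernel: unit spike at the
  # (HRF-shifted) boundary TR
  truth1 <- ground_truth(60, 1)
  h1 <- simulate_hippocampus(lay, truth1, amplitudes = 1, kernel = 1,
                             noise_sd = 0, n_subjects = 1, seed = 1)
  btr <- time_to_tr(lay, 60) + 3
  expect_equal(unname(h1[1, btr + 1]), 1)
  expect_equal(sum(h1), 1)
  expect_error(simulate_hippocampus(lay, truth, kernel = c(1, -1)),
               "kernel")
  # amplitudes proportional to strength: recovered 0-4 TR averages
  # ordered by strength over seeds
  strength <- rep(c(0.2, 0.5, 0.9), each = 4)
  times <- seq(25, 223, length.out = 12)
  truth3 <- ground_truth(times, strength)
  btr <- time_to_tr(lay, times) + 3
  avg <- matrix(0, 30, 3)
  for (s in 1:30) {
    h <- simulate_hippocampus(lay, truth3, noise_sd = 0.3,
                              n_subjects = 1, seed = s)
    resp <- vapply(btr, function(t) mean(h[1, t + 1 + 0:4]), 0)
    avg[s, ] <- tapply(resp, strength, mean)
  }
  m <- colMeans(avg)
  expect_true(m[1] < m[2] && m[2] < m[3])
})

test_that("generators are bitwise deterministic under a fixed seed", {
  lay <- tiny_layout()
  truth <- ground_truth(c(30, 90, 160), c(0.3, 0.6, 0.9))
  expect_identical(simulate_observers(lay, truth, seed = 42),
                   simulate_observers(lay, truth, seed = 42))
  spec <- default_levels_spec(n_parcels = 1, n_voxels = 6)
  expect_identical(simulate_cortex(lay, truth, spec, n_subjects = 2,
                                   seed = 42),
                   simulate_cortex(lay, truth, spec, n_subjects = 2,
                                   seed = 42))
  expect_identical(simulate_hippocampus(lay, truth, n_subjects = 2,
                                        seed = 42),
                   simulate_hippocampus(lay, truth, n_subjects = 2,
                                        seed = 42))
  s1 <- simulate_study(layout = lay, n_boundaries = 8, n_subjects = 2,
                       n_observers = 4,
                       levels_spec = default_levels_spec(1, 6), seed = 9)
  s2 <- simulate_study(layout = lay, n_boundaries = 8, n_subjects = 2,
                       n_observers = 4,
                       levels_spec = default_levels_spec(1, 6), seed = 9)
  expect_identical(s1, s2)
})
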