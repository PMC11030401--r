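test_that("Kruskal-Wallis matches the hand rank computation", {
  # ranks 1..9, rank sums 6 / 15 / 24 -> H = 7.2
  g <- rep(c("a", "b", "c"), each = 3)
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9), g)
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2L)
  # eta2 = (H - k + 1) / (N - k) = 5.2 / 6
  expect_equal(r$effect_size, 5.2 / 6, tolerance = 1e-12)
  expect_equal(r$p, pchisq(7.2, 2, lower.tail = FALSE))
  # invariant to within-group order
  r2 <- kruskal_wallis(c(3, 1, 2, 6, 4, 5, 9, 8, 7), g)
  expect_equal(r2$statistic, r$statistic)
  # agrees with the base implementation on tied data
  set.seed(41)
  v <- round(rnorm(30), 1)
  gg <- sample(c("a", "b", "c"), 30, replace = TRUE)
  mine <- kruskal_wallis(v, gg)
  ref <- kruskal.test(v, factor(gg))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_error(kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3)), "identical")
})

test_that("Dunn's Z uses tie-corrected pooled variance", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  d <- dunn_pairwise(v, g)
  # a vs c: mean ranks 2 and 8, variance (9*10/12)(2/3) = 5
  z_ac <- d$z[d$group1 == "a" & d$group2 == "c"]
  expect_equal(z_ac, -6 / sqrt(5), tolerance = 1e-12)
  expect_equal(d$p_corrected, pmin(1, d$p * 3))
  # identical groups: Z = 0, corrected p = 1
  d2 <- dunn_pairwise(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(d2$z, 0)
  expect_equal(d2$p_corrected, 1)
  # brute-force check with ties, n <= 12
  set.seed(42)
  v3 <- round(runif(12), 1)
  g3 <- rep(c("a", "b", "c"), 4)
  d3 <- dunn_pairwise(v3, g3)
  r <- rank(v3)
  tie <- sum(table(r)^3 - table(r)) / (12 * 11)
  for (q in seq_len(nrow(d3))) {
    i <- d3$group1[q]; j <- d3$group2[q]
    z <- (mean(r[g3 == i]) - mean(r[g3 == j])) /
      sqrt((12 * 13 / 12 - tie) * (1 / 4 + 1 / 4))
    expect_equal(d3$z[q], z, tolerance = 1e-12)
  }
})

test_that("Spearman correlation handles ties like the rank formula", {
  expect_equal(spearman_report(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_report(1:10, -(1:10))$rho, -1)
  set.seed(43)
  x <- round(rnorm(25), 1)
  y <- round(x + rnorm(25), 1)
  r <- spearman_report(x, y)
  expect_equal(r$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(r$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_report(rep(1, 5), 1:5), "constant")
})

test_that("the Shapiro gate flags clear deviations", {
  set.seed(44)
  expect_equal(shapiro_gate(rnorm(100))$verdict, "normal")
  expect_equal(shapiro_gate(rexp(100))$verdict, "non-normal")
  expect_error(shapiro_gate(c(1, 2)), "n")
})

test_that("between-subject variance matches brute force", {
  m <- rbind(c(1, 1, 1), c(1, 3, NA), c(2, NA, NA))
  v <- between_subject_variance(m)
  expect_equal(v[1], 0)
  expect_equal(v[2], 2) # (1-3)^2 / 2
  expect_true(is.na(v[3]))
  set.seed(45)
  mm <- matrix(rnorm(40), 8, 5)
  expect_equal(between_subject_variance(mm), apply(mm, 1, var))
})

test_that("repeated-measures ANOVA matches the reference implementation", {
  # frozen oracle values computed with pingouin.rm_anova on this table
  tab <- rbind(c(1, 2, 4), c(2, 4, 3), c(5, 6, 9), c(3, 3, 5))
  r <- rm_anova(tab)
  expect_equal(r$statistic, 7.125, tolerance = 1e-8)
  expect_equal(r$p, 0.026012294874, tolerance = 1e-8)
  expect_equal(r$effect_size, 0.248772504092, tolerance = 1e-8)
  expect_equal(r$df, c(2L, 6L))
  # zero condition effect -> F = 0
  tab0 <- matrix(rep(c(1, 2, 3), 3), 3, byrow = FALSE)
  expect_equal(rm_anova(cbind(tab0[, 1], tab0[, 1], tab0[, 1]))$statistic, 0)
  # adding a constant to one subject's row leaves F unchanged
  tab2 <- tab
  tab2[2, ] <- tab2[2, ] + 100
  expect_equal(rm_anova(tab2)$statistic, r$statistic, tolerance = 1e-8)
  expect_error(rm_anova(rbind(c(1, NA), c(2, 3))), "missing")
})

test_that("paired t matches the textbook formula on a 5-pair fixture", {
  x <- c(2.1, 3.4, 2.8, 4.0, 3.3)
  y <- c(1.9, 2.8, 2.9, 3.1, 2.7)
  r <- paired_t(x, y, comparisons = 3)
  d <- x - y
  t_ref <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(r$statistic, t_ref, tolerance = 1e-12)
  expect_equal(r$df, 4L)
  expect_equal(r$p_corrected, min(1, r$p * 3))
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  # identical pairs are flagged as an error
  expect_error(paired_t(x, x), "zero-variance")
  # consistent positive differences with tiny noise -> large positive t
  set.seed(46)
  xx <- rnorm(10)
  expect_gt(paired_t(xx + 1 + rnorm(10, 0, 0.01), xx)$statistic, 50)
})

test_that("non-boundary sampling respects every constraint", {
  lay <- default_session_layout()
  set.seed(47)
  times <- sample_boundary_times(lay, n_boundaries = 60, min_gap = 12)
  bnd <- data.frame(time_s = times, excluded = FALSE)
  pts <- sample_non_boundaries(lay, bnd, seed = 48)
  expect_length(pts, 44) # 22 per run
  runs <- run_of_time(lay, pts)
  expect_equal(as.vector(table(runs)), c(22L, 22L))
  # pairwise gaps >= 6 s within each run (and globally, runs are far apart)
  expect_true(all(diff(pts) >= 6 - 1e-9))
  # at least 6 s from every retained boundary
  expect_true(all(vapply(pts, function(p) min(abs(p - times)), 0) >= 6 - 1e-9))
  # never inside a title window nor in the last 10 s of a run
  m <- lay$movies
  for (p in pts) {
    mi <- which(p >= m$onset_s & p < m$onset_s + m$duration_s)
    expect_gte(p, m$title_end_s[mi])
  }
  expect_true(all(vapply(seq_along(pts), function(i)
    lay$runs$end_s[match(runs[i], lay$runs$run)] - pts[i], 0) >= 10 - 1e-9))
  # unsatisfiable constraints raise after bounded retries
  expect_error(sample_non_boundaries(tiny_layout(), per_run = 60,
                                     max_tries = 500, seed = 1),
               "unsatisfiable")
})

test_that("dip statistic reproduces frozen reference values", {
  # reference values frozen from the published algorithm's implementation
  expect_equal(dip_stat(1:4), 0.125, tolerance = 1e-12)
  expect_equal(dip_stat(c(1, 2, 3, 4, 10, 11, 12)), 0.160714285714286,
               tolerance = 1e-12)
  x3 <- c(0.12, 0.15, 0.2, 0.3, 0.31, 0.31, 0.5, 0.55, 0.7, 0.74, 0.76,
          0.8, 0.81, 0.9, 0.95, 1.0, 1.4, 1.41, 1.5, 2.0)
  expect_equal(dip_stat(x3), 0.0844827586206896, tolerance = 1e-12)
  # equally spaced samples attain the theoretical minimum 1/(2n)
  for (n in c(4, 7, 25)) {
    expect_equal(dip_stat(seq_len(n)), 1 / (2 * n), tolerance = 1e-12)
  }
  # scale and shift invariance
  set.seed(51)
  z <- rnorm(40)
  expect_equal(dip_stat(z), dip_stat(3 * z - 7), tolerance = 1e-12)
})

test_that("dip test separates unimodal from strongly bimodal samples", {
  set.seed(52)
  null_200 <- dip_null_dist(200, n_boot = 500)
  # unimodal normal: large p
  p_uni <- dip_test(rnorm(200), null_dips = null_200)$p
  expect_gt(p_uni, 0.05)
  # far-separated mixture: tiny p
  bim <- c(rnorm(100, -5, 0.1), rnorm(100, 5, 0.1))
  expect_lt(dip_test(bim, null_dips = null_200)$p, 0.01)
  expect_error(dip_test(1:3), "n >= 4")
})

test_that("JZS Bayes factor matches frozen reference values", {
  # frozen from a reference JZS ANOVA implementation (rscaleFixed = 0.5)
  y <- c(0.214, 0.48, 0.088, 0.444, -0.363, 0.123, -0.864, 0.49, -0.364,
         -1.294, -0.746, 0.922, 0.75, -2.509, -3.041, 0, -0.394, -1.745)
  g <- factor(rep(c("a", "b", "c"), each = 6))
  r1 <- bayes_anova_bf01(y, g)
  expect_equal(r1$statistic, 0.883672529569, tolerance = 1e-5)
  y2 <- y + rep(c(0, 1.5, 3), each = 6)
  r2 <- bayes_anova_bf01(y2, g)
  expect_equal(r2$statistic, 0.42854265666, tolerance = 1e-5)
  # BF01 x BF10 = 1 by definition
  expect_equal(r1$statistic * r1$bf10, 1, tolerance = 1e-10)
  # posterior summaries cover each group's sample mean
  post <- bayes_anova_bf01(y2, g, seed = 1)$posterior
  mns <- tapply(y2, g, mean)
  expect_true(all(post$lower < mns & mns < post$upper))
})

test_that("Bayes factor separates null from large group effects", {
  set.seed(53)
  # well-separated groups (d = 3): strong evidence against the null
  y <- c(rnorm(40), rnorm(40, 3), rnorm(40, 6))
  g <- rep(c("a", "b", "c"), each = 40)
  expect_lt(bayes_anova_bf01(y, g)$statistic, 0.1)
})
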