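# Group- and individual-level statistics for cross-boundary correlations.
# All tests return a plain "stat_report" list so results serialize to JSON
# without surprises.

stat_report <- function(test, statistic, df, p, p_corrected = p,
                        effect_size = NA_real_, effect_name = NA_character_,
                        ...) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 p_corrected = p_corrected, effect_size = effect_size,
                 effect_name = effect_name, ...),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  dfs <- paste(unlist(x$df), collapse = ", ")
  cat(sprintf("<stat_report> %s: stat = %.4g, df = (%s), p = %.4g",
              x$test, x$statistic, dfs, x$p))
  if (!is.na(x$effect_size))
    cat(sprintf(", %s = %.4g", x$effect_name, x$effect_size))
  cat("\n")
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Records whether a sample deviates from normality at `alpha`. Used to
#' log the rationale for using rank-based tests; the pipeline runs
#' Kruskal-Wallis regardless of the outcome.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @param alpha decision level (default 0.05).
#' @return a `stat_report` with an added `verdict` field
#'   (`"normal"` / `"non-normal"`).
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- stats::shapiro.test(x)
  stat_report("shapiro-wilk", unname(sw$statistic), n, sw$p.value,
              verdict = if (sw$p.value < alpha) "non-normal" else "normal")
}

.rank_tie_term <- function(r) {
  t_ <- table(r)
  sum(t_^3 - t_)
}

#' Kruskal-Wallis rank test with tie correction
#'
#' H with tie correction, chi-square p with k - 1 df, and the rank
#' epsilon-squared-style effect size `eta2 = (H - k + 1) / (N - k)`.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @return a `stat_report` (fields: statistic = H, df = k - 1, p,
#'   effect_size = eta2, plus per-group `summary` data frame).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n_j <- tabulate(groups)
  N <- length(values)
  if (k < 2L) stop("need at least 2 groups")
  if (any(n_j < 1L) || N < 3L) stop("each group needs n >= 1, total >= 3")
  if (length(unique(values)) == 1L) stop("all values identical")
  r <- rank(values)
  R_j <- tapply(r, groups, sum)
  H <- 12 / (N * (N + 1)) * sum(R_j^2 / n_j) - 3 * (N + 1)
  tie <- 1 - .rank_tie_term(r) / (N^3 - N)
  H <- H / tie
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  eta2 <- (H - k + 1) / (N - k)
  summ <- data.frame(
    group = levels(groups), n = n_j,
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, stats::sd)),
    mean_rank = as.numeric(R_j / n_j)
  )
  stat_report("kruskal-wallis", H, k - 1L, p, effect_size = eta2,
              effect_name = "eta2", summary = summ)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' For groups i, j:
#' `Z_ij = (meanrank_i - meanrank_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' with tie term `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided p-values are
#' Bonferroni-multiplied by the number of pairs and capped at 1.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return data frame: `group1`, `group2`, `z`, `p`, `p_corrected`.
#' @export
dunn_pairwise <- function(values, groups, correction = c("bonferroni",
                                                         "none")) {
  correction <- match.arg(correction)
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  n_j <- tabulate(groups)
  if (any(n_j == 0L)) stop("empty group")
  N <- length(values)
  r <- rank(values)
  mr <- tapply(r, groups, mean)
  tie <- .rank_tie_term(r) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    se <- sqrt((N * (N + 1) / 12 - tie) * (1 / n_j[i] + 1 / n_j[j]))
    z <- (mr[[i]] - mr[[j]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = levels(groups)[i], group2 = levels(groups)[j],
               z = z, p = p,
               p_corrected = if (correction == "bonferroni")
                 min(1, p * m) else p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; `t = rho * sqrt((n - 2) / (1 - rho^2))` with
#' n - 2 df, two-sided.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return a `stat_report` with fields `rho` (= statistic), `n`, `p`.
#' @export
spearman_report <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("need equal-length vectors, n >= 3")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3L) stop("fewer than 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant input")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  rep <- stat_report("spearman", rho, n - 2L, p)
  rep$rho <- rho
  rep$n <- n
  rep
}

#' Between-subject variance of cross-boundary correlation
#'
#' Unbiased sample variance across subjects, per boundary. Boundaries with
#' fewer than two defined subject values get `NA`.
#'
#' @param cbc_by_subject numeric matrix, boundaries in rows, subjects in
#'   columns.
#' @return numeric vector of per-boundary variances.
#' @export
between_subject_variance <- function(cbc_by_subject) {
  apply(cbc_by_subject, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else stats::var(v)
  })
}

#' One-way repeated-measures ANOVA with generalized eta squared
#'
#' Complete balanced subject x condition table. F has
#' `(k - 1, (k - 1)(n - 1))` degrees of freedom; the effect size is
#' generalized eta squared
#' `SS_cond / (SS_cond + SS_subj + SS_error)`.
#'
#' @param tab numeric matrix, subjects in rows, conditions in columns; no
#'   missing cells.
#' @return a `stat_report` (statistic = F, df = c(df1, df2), p,
#'   effect_size = ges).
#' @export
rm_anova <- function(tab) {
  tab <- as.matrix(tab)
  if (anyNA(tab)) stop("missing cells in repeated-measures table")
  n <- nrow(tab); k <- ncol(tab)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  grand <- mean(tab)
  ss_cond <- n * sum((colMeans(tab) - grand)^2)
  ss_subj <- k * sum((rowMeans(tab) - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err < 1e-300) {
    if (ms_cond < 1e-300) 0 else Inf
  } else ms_cond / ms_err
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  ges <- ss_cond / (ss_cond + ss_subj + ss_err)
  stat_report("rm-anova", f, c(df1, df2), p, effect_size = ges,
              effect_name = "ges",
              ss = c(cond = ss_cond, subj = ss_subj, error = ss_err))
}

#' Paired t-test with Bonferroni-style correction
#'
#' @param x,y equal-length paired samples.
#' @param comparisons number of comparisons in the family (the corrected
#'   p is `min(1, p * comparisons)`).
#' @return a `stat_report` (statistic = t, df = n - 1).
#' @export
paired_t <- function(x, y, comparisons = 1) {
  n <- length(x)
  if (length(y) != n || n < 2L) stop("need equal-length pairs, n >= 2")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d < 1e-300) stop("zero-variance differences")
  tstat <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  stat_report("paired-t", tstat, n - 1L, p,
              p_corrected = min(1, p * comparisons),
              mean_diff = mean(d))
}

#' Sample non-boundary control time points
#'
#' Pseudo-random time points inside movie playback, used as a
#' no-boundary control set: excluded are title windows, the final
#' `tail_excl` seconds of every run, any point closer than `min_sep`
#' seconds to an already drawn point, and (by default) any point closer
#' than `min_sep` to a retained event boundary. Exactly `per_run` points
#' are drawn per run.
#'
#' @param layout a `session_layout`.
#' @param boundaries boundary data frame with `time_s` (and optionally
#'   `excluded`); only retained boundaries constrain the draw.
#' @param per_run points per run (default 22).
#' @param min_sep minimum separation, seconds (default 6).
#' @param tail_excl excluded run tail, seconds (default 10).
#' @param exclude_near_boundaries also stay `min_sep` away from retained
#'   boundaries? (default TRUE)
#' @param seed optional integer seed.
#' @param max_tries rejection-sampling budget per run.
#' @return sorted numeric vector of global session times (0.1 s grid),
#'   length `per_run * n_runs`.
#' @export
sample_non_boundaries <- function(layout, boundaries = NULL, per_run = 22,
                                  min_sep = 6, tail_excl = 10,
                                  exclude_near_boundaries = TRUE,
                                  seed = NULL, max_tries = 20000) {
  stopifnot(inherits(layout, "session_layout"))
  if (!is.null(seed)) set.seed(seed)
  b_times <- numeric(0)
  if (exclude_near_boundaries && !is.null(boundaries) && nrow(boundaries)) {
    keep <- if ("excluded" %in% names(boundaries)) !boundaries$excluded
    else rep(TRUE, nrow(boundaries))
    b_times <- boundaries$time_s[keep]
  }
  m <- layout$movies
  out <- numeric(0)
  for (ri in seq_len(nrow(layout$runs))) {
    run <- layout$runs$run[ri]
    run_cut <- layout$runs$end_s[ri] - tail_excl
    mm <- m[m$run == run, , drop = FALSE]
    lo <- mm$title_end_s
    hi <- pmin(mm$onset_s + mm$duration_s, run_cut)
    w <- pmax(hi - lo, 0)
    if (sum(w) <= 0) stop("no valid sampling time in run ", run)
    drawn <- numeric(0)
    tries <- 0L
    while (length(drawn) < per_run) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("non-boundary sampling constraints unsatisfiable in run ", run)
      i <- sample.int(nrow(mm), 1L, prob = w)
      t <- round(stats::runif(1, lo[i], hi[i]), 1)
      if (length(drawn) && any(abs(t - drawn) < min_sep)) next
      if (length(b_times) && any(abs(t - b_times) < min_sep)) next
      drawn <- c(drawn, t)
    }
    out <- c(out, drawn)
  }
  sort(out)
}
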