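#' Shift-indicator matrix across hierarchy levels
#'
#' Builds, per boundary, the vector of shift indicators over hierarchy
#' levels 1--4 from group-level cross-boundary correlations (shift =
#' cbc strictly below zero). Level 1 combines the auditory and visual
#' sensory streams: with `level1_mode = "either"` (default) a shift in
#' either `1_AUD` or `1_VIS` counts, with `"both"` both streams must
#' shift. Boundaries with an undefined cbc at any assessed level are
#' dropped with a reason.
#'
#' @param cbc data frame from [cbc_table()] (columns `boundary_id`,
#'   `level`, `cbc`) at the group level.
#' @param level1_mode `"either"` or `"both"`.
#' @return list with `indicators` (logical matrix, boundaries x levels
#'   `L1`..`L4`), `boundary_id`, and `dropped` (data frame of excluded
#'   boundaries with reasons).
#' @export
indicator_matrix <- function(cbc, level1_mode = c("either", "both")) {
  level1_mode <- match.arg(level1_mode)
  need <- c("1_AUD", "1_VIS", "2", "3", "4")
  have <- unique(cbc$level)
  if (!all(need %in% have)) {
    # tolerate a collapsed level 1 named "1"
    if (!all(c("1", "2", "3", "4") %in% have))
      stop("cbc table must cover hierarchy levels 1-4")
    need <- c("1", "2", "3", "4")
  }
  wide <- lapply(need, function(lv) {
    sub <- cbc[cbc$level == lv, ]
    sub$cbc[order(sub$boundary_id)]
  })
  ids <- sort(unique(cbc$boundary_id))
  m <- do.call(cbind, wide)
  if (length(need) == 5L) {
    l1 <- if (level1_mode == "either") {
      pmin(m[, 1], m[, 2]) # shift if either stream is below zero
    } else {
      pmax(m[, 1], m[, 2])
    }
    m <- cbind(l1, m[, 3:5])
  }
  colnames(m) <- paste0("L", 1:4)
  ok <- stats::complete.cases(m)
  ind <- m[ok, , drop = FALSE] < 0
  rownames(ind) <- ids[ok]
  dropped <- data.frame(
    boundary_id = ids[!ok],
    reason = rep("undefined cbc at an assessed level", sum(!ok))
  )
  list(indicators = ind, boundary_id = ids[ok], dropped = dropped)
}

.prefix_score <- function(ind) {
  # length of the initial all-TRUE run, provided no TRUE occurs above a
  # FALSE (otherwise the bottom-up nested structure is absent -> NA)
  s <- match(FALSE, ind, nomatch = length(ind) + 1L) - 1L
  if (any(ind[seq_along(ind) > s])) return(NA_integer_)
  s
}

#' Strict-nesting alignment score (levels 1--4)
#'
#' Scores the bottom-up nesting of pattern shifts over all four hierarchy
#' levels: a boundary whose indicator vector is 1 at levels 1..s and 0
#' above scores `s` (0--4). Any shift above a non-shifting level breaks
#' the nested structure and the score is undefined (`NA`).
#'
#' @param ind logical vector of length 4 (levels 1--4), or a matrix with
#'   4 columns (boundaries in rows).
#' @return integer score(s) in 0..4 or `NA`.
#' @export
score_strict_nesting <- function(ind) {
  if (is.matrix(ind)) return(apply(ind, 1L, score_strict_nesting))
  stopifnot(length(ind) == 4L, !anyNA(ind))
  .prefix_score(ind)
}

#' Nesting alignment score (levels 2--4)
#'
#' As [score_strict_nesting()] but assessed over levels 2--4 only
#' (score 0--3), ignoring the modality-specific sensory level.
#'
#' @param ind logical vector of length 3 (levels 2--4), or a matrix with
#'   3 or 4 columns (4 columns: the first is dropped).
#' @return integer score(s) in 0..3 or `NA`.
#' @export
score_nesting <- function(ind) {
  if (is.matrix(ind)) {
    if (ncol(ind) == 4L) ind <- ind[, 2:4, drop = FALSE]
    return(apply(ind, 1L, score_nesting))
  }
  if (length(ind) == 4L) ind <- ind[2:4]
  stopifnot(length(ind) == 3L, !anyNA(ind))
  .prefix_score(ind)
}

#' Summation alignment score (levels 2--4)
#'
#' Count of levels 2--4 exhibiting a shift, with no nesting requirement
#' (always defined, 0--3).
#'
#' @param ind logical vector of length 3 (levels 2--4), or a matrix with
#'   3 or 4 columns (4 columns: the first is dropped).
#' @return integer score(s) in 0..3.
#' @export
score_summation <- function(ind) {
  if (is.matrix(ind)) {
    if (ncol(ind) == 4L) ind <- ind[, 2:4, drop = FALSE]
    return(apply(ind, 1L, score_summation))
  }
  if (length(ind) == 4L) ind <- ind[2:4]
  stopifnot(length(ind) == 3L, !anyNA(ind))
  sum(ind)
}

#' Alignment table: indicators and all three scores per boundary
#'
#' @param cbc group-level cbc table (see [indicator_matrix()]).
#' @param level1_mode see [indicator_matrix()].
#' @return data frame: `boundary_id`, `L1`..`L4` indicators, `strict`,
#'   `nesting`, `summation` scores (NA where undefined).
#' @export
alignment_table <- function(cbc, level1_mode = "either") {
  im <- indicator_matrix(cbc, level1_mode = level1_mode)
  ind <- im$indicators
  data.frame(
    boundary_id = im$boundary_id,
    L1 = ind[, 1], L2 = ind[, 2], L3 = ind[, 3], L4 = ind[, 4],
    strict = score_strict_nesting(ind),
    nesting = score_nesting(ind),
    summation = score_summation(ind),
    row.names = NULL
  )
}

#' Correlate alignment scores with boundary agreement
#'
#' Spearman rank correlation over boundaries with a defined score
#' (undefined scores are excluded, shrinking the df, never imputed).
#'
#' @param scores numeric/integer score vector (NA = undefined).
#' @param agreement agreement values, same length.
#' @return a `stat_report` from [spearman_report()].
#' @export
alignment_vs_agreement <- function(scores, agreement) {
  ok <- !is.na(scores)
  if (sum(ok) < 3L) stop("fewer than 3 boundaries with defined scores")
  spearman_report(scores[ok], agreement[ok])
}

#' Mean ROI time series from a voxel array and mask
#'
#' Standardizes voxels within each run, then averages over in-mask
#' voxels per TR.
#'
#' @param x `n_voxels x n_TR` matrix, or a 4D array (x, y, z, t).
#' @param mask logical vector over voxels (or logical 3D array matching
#'   the spatial grid of `x`).
#' @param run_lens per-run TR counts.
#' @param standardize z-score voxels within run first? (default TRUE)
#' @return numeric TR series.
#' @export
roi_series <- function(x, mask, run_lens = NULL, standardize = TRUE) {
  if (length(dim(x)) == 4L) {
    nt <- dim(x)[4]
    x <- matrix(x, ncol = nt)
    mask <- as.logical(mask)
  }
  stopifnot(is.matrix(x), length(mask) == nrow(x))
  if (!any(mask)) stop("empty mask")
  if (is.null(run_lens)) run_lens <- ncol(x)
  xm <- x[mask, , drop = FALSE]
  if (standardize) xm <- standardize_voxels(xm, run_lens)
  colMeans(xm)
}

#' Boundary-locked response windows with baseline subtraction
#'
#' For each boundary, extracts the ROI series from `pre` TRs before to
#' `post` TRs after the boundary TR, subtracts the mean of the `baseline`
#' TRs immediately preceding the boundary, and summarizes as the mean of
#' the baseline-subtracted values over `summary_win` TRs after boundary
#' onset. Boundaries whose full window (including the baseline span)
#' leaves their run are dropped with a reason.
#'
#' @param series numeric TR series (runs concatenated).
#' @param boundary_trs integer 0-based boundary TR indices (HRF-shifted).
#' @param run_lens per-run TR counts.
#' @param pre,post window extent in TRs around the boundary (default 2
#'   and 10).
#' @param baseline number of pre-boundary TRs averaged as baseline
#'   (2, or 10 for comparison with longer-baseline conventions).
#' @param summary_win TR offsets averaged into the summary (default 0:4).
#' @return list with `response` (matrix boundaries x window TRs, rows NA
#'   where dropped), `summary` (numeric per boundary), `offsets`, and
#'   `kept` (logical).
#' @export
boundary_locked <- function(series, boundary_trs, run_lens = length(series),
                            pre = 2, post = 10, baseline = 2,
                            summary_win = 0:4) {
  offs <- (-pre):post
  run_of <- rep(seq_along(run_lens), run_lens)
  nb <- length(boundary_trs)
  resp <- matrix(NA_real_, nb, length(offs))
  summ <- rep(NA_real_, nb)
  kept <- logical(nb)
  lo_needed <- -max(pre, baseline)
  for (i in seq_len(nb)) {
    tr <- boundary_trs[i]
    idx0 <- tr + c(lo_needed:-1, offs[offs >= 0])
    if (any(idx0 < 0L) || any(idx0 >= length(series))) next
    if (length(unique(run_of[tr + c(lo_needed, post) + 1L])) != 1L) next
    base <- mean(series[tr - seq_len(baseline) + 1L])
    vals <- series[tr + offs + 1L] - base
    resp[i, ] <- vals
    summ[i] <- mean(vals[match(summary_win, offs)])
    kept[i] <- TRUE
  }
  colnames(resp) <- offs
  list(response = resp, summary = summ, offsets = offs, kept = kept)
}

#' Group tests on boundary-locked responses
#'
#' Averages each subject's response summaries within boundary groups
#' (alignment score or strength category), then runs a paired t-test
#' (exactly two groups) or a one-way repeated-measures ANOVA (more than
#' two). Subjects lacking boundaries in some group are dropped with a
#' warning.
#'
#' @param summaries data frame with columns `subject`, `group`,
#'   `summary` (one row per subject x boundary).
#' @param comparisons Bonferroni family size for the paired t (default
#'   1).
#' @return a `stat_report`; the per-subject group means are attached as
#'   `table`.
#' @export
grouped_response_tests <- function(summaries, comparisons = 1) {
  stopifnot(all(c("subject", "group", "summary") %in% names(summaries)))
  summaries <- summaries[!is.na(summaries$summary), , drop = FALSE]
  tab <- tapply(summaries$summary,
                list(summaries$subject, summaries$group), mean)
  complete <- stats::complete.cases(tab)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) without data in every group dropped")
    tab <- tab[complete, , drop = FALSE]
  }
  if (ncol(tab) < 2L) stop("need at least 2 groups")
  if (nrow(tab) < 2L) stop("need at least 2 complete subjects")
  rep <- if (ncol(tab) == 2L) {
    paired_t(tab[, 2], tab[, 1], comparisons = comparisons)
  } else {
    rm_anova(tab)
  }
  rep$table <- tab
  rep
}
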