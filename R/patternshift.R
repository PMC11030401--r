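#' Z-score voxel time series within each scanning run
#'
#' Each voxel's series is standardized to mean 0, sd 1 separately within
#' every run (sample sd). Constant voxels are set to zeros with a warning.
#'
#' @param x `n_voxels x n_TR` matrix, runs concatenated along columns.
#' @param run_lens integer vector of per-run TR counts summing to
#'   `ncol(x)`.
#' @return standardized matrix, same shape.
#' @export
standardize_voxels <- function(x, run_lens = ncol(x)) {
  stopifnot(is.matrix(x), sum(run_lens) == ncol(x))
  off <- c(0L, cumsum(run_lens))
  n_const <- 0L
  for (r in seq_along(run_lens)) {
    if (run_lens[r] < 2L) stop("each run needs at least 2 TRs")
    cols <- (off[r] + 1L):off[r + 1L]
    xr <- x[, cols, drop = FALSE]
    mu <- rowMeans(xr)
    sd_ <- sqrt(rowSums((xr - mu)^2) / (length(cols) - 1L))
    const <- sd_ < 1e-12
    n_const <- n_const + sum(const)
    sd_[const] <- 1
    xr <- (xr - mu) / sd_
    xr[const, ] <- 0
    x[, cols] <- xr
  }
  if (n_const > 0L)
    warning(n_const, " constant voxel run(s) set to zeros")
  x
}

#' Voxelwise group average across subjects
#'
#' @param subject_arrays list of identically shaped matrices.
#' @return their elementwise mean.
#' @export
group_average <- function(subject_arrays) {
  if (!length(subject_arrays)) stop("no subjects")
  d <- dim(subject_arrays[[1]])
  for (a in subject_arrays) {
    if (!identical(dim(a), d)) stop("shape mismatch across subjects")
  }
  Reduce(`+`, subject_arrays) / length(subject_arrays)
}

#' Multi-voxel pattern-shift correlation time series
#'
#' At each TR `t`, the pre-pattern is the voxelwise mean over TRs
#' `t-halfwin .. t-1` and the post-pattern the mean over
#' `t+1 .. t+halfwin` (the focal TR itself is excluded from both
#' windows); the series value at `t` is the Pearson correlation between
#' the two patterns across voxels. TRs whose window leaves the run are
#' undefined (`NA`), i.e. the first and last `halfwin` TRs of every run.
#' Zero-variance window patterns also give `NA`.
#'
#' @param x `n_voxels x n_TR` matrix (typically standardized; runs
#'   concatenated along columns).
#' @param run_lens per-run TR counts summing to `ncol(x)`.
#' @param halfwin window half-width in TRs (default 3).
#' @return numeric vector of length `ncol(x)` with `NA` at undefined TRs.
#' @export
shift_series <- function(x, run_lens = ncol(x), halfwin = 3) {
  stopifnot(is.matrix(x), sum(run_lens) == ncol(x))
  if (any(run_lens <= 2 * halfwin))
    stop("each run must be longer than 2 * halfwin TRs")
  out <- rep(NA_real_, ncol(x))
  off <- c(0L, cumsum(run_lens))
  for (r in seq_along(run_lens)) {
    cols <- (off[r] + 1L):off[r + 1L]
    xr <- x[, cols, drop = FALSE]
    L <- ncol(xr)
    # windowed sums via cumulative sums over columns
    cs <- cbind(0, t(apply(xr, 1L, cumsum)))
    ts_ <- (halfwin + 1L):(L - halfwin)
    pre <- (cs[, ts_] - cs[, ts_ - halfwin]) / halfwin
    post <- (cs[, ts_ + halfwin + 1L] - cs[, ts_ + 1L]) / halfwin
    pre <- pre - rep(colMeans(pre), each = nrow(pre))
    post <- post - rep(colMeans(post), each = nrow(post))
    num <- colSums(pre * post)
    den <- sqrt(colSums(pre^2) * colSums(post^2))
    v <- num / den
    v[den < 1e-12] <- NA_real_
    out[off[r] + ts_] <- v
  }
  out
}

#' Normalize a pattern-shift series across runs
#'
#' Concatenated shift series are z-scored over all *defined* samples
#' (mean 0, sd 1); undefined (`NA`) samples stay undefined.
#'
#' @param series numeric vector with `NA` at undefined TRs.
#' @return z-scored series, same length and `NA` mask.
#' @export
normalize_shift <- function(series) {
  ok <- !is.na(series)
  if (sum(ok) < 2L) stop("need at least 2 defined values")
  mu <- mean(series[ok])
  sd_ <- stats::sd(series[ok])
  if (sd_ < 1e-12) stop("constant shift series cannot be normalized")
  (series - mu) / sd_
}

#' Average normalized shift series across parcels within a level
#'
#' Pointwise mean of z-scored parcel series; an `NA` in any parcel makes
#' the pooled sample `NA` (no partial windows).
#'
#' @param series_list non-empty list of equal-length numeric vectors.
#' @return pooled numeric vector.
#' @export
level_average <- function(series_list) {
  if (!length(series_list)) stop("empty level")
  len <- lengths(series_list)
  if (length(unique(len)) != 1L) stop("series lengths differ")
  rowMeans(do.call(cbind, series_list))
}

#' Per-level pattern-shift series for one subject (or the group)
#'
#' Standardizes each parcel's voxels within run, computes the shift
#' series, z-scores it across runs, and averages parcels within each
#' hierarchy level.
#'
#' @param level_data named list (levels) of lists of `n_voxels x n_TR`
#'   parcel matrices.
#' @param run_lens per-run TR counts.
#' @param halfwin shift-window half-width in TRs.
#' @param standardize z-score voxels within run first? (default TRUE)
#' @return named list of per-level numeric series (z-values, `NA` edges).
#' @export
level_shift_series <- function(level_data, run_lens, halfwin = 3,
                               standardize = TRUE) {
  lapply(level_data, function(parcels) {
    zs <- lapply(parcels, function(p) {
      if (standardize) p <- standardize_voxels(p, run_lens)
      normalize_shift(shift_series(p, run_lens, halfwin = halfwin))
    })
    level_average(zs)
  })
}

#' Cross-boundary correlation at one boundary
#'
#' Arithmetic mean of the shift series over the TRs `tr_index - win ..
#' tr_index + win`. Undefined (`NA`) whenever any TR in the window is
#' undefined or the window leaves the boundary's run.
#'
#' @param series numeric shift series (z-values, `NA` edges).
#' @param tr_index 0-based boundary TR index (already HRF-shifted).
#' @param win window half-width in TRs (default 1).
#' @param run_lens per-run TR counts (used to reject windows that span a
#'   run break); default: one run.
#' @return scalar mean, or `NA`.
#' @export
cross_boundary <- function(series, tr_index, win = 1,
                           run_lens = length(series)) {
  idx0 <- tr_index + (-win):win # 0-based
  if (any(idx0 < 0L) || any(idx0 >= length(series))) return(NA_real_)
  run_of <- rep(seq_along(run_lens), run_lens)
  if (length(unique(run_of[idx0 + 1L])) != 1L) return(NA_real_)
  vals <- series[idx0 + 1L]
  if (anyNA(vals)) return(NA_real_)
  mean(vals)
}

#' Shift indicator from a cross-boundary correlation
#'
#' A pattern shift is present iff the cross-boundary correlation is
#' strictly below zero.
#'
#' @param cbc numeric vector of cross-boundary correlations.
#' @return logical vector (`NA` where `cbc` is undefined).
#' @export
label_shift <- function(cbc) {
  ifelse(is.na(cbc), NA, cbc < 0)
}

#' Cross-boundary correlation table over levels and boundaries
#'
#' @param level_series named list of per-level shift series (z-values).
#' @param boundaries boundary data frame with `tr_index` (0-based) and
#'   optionally `excluded`; excluded boundaries are skipped.
#' @param run_lens per-run TR counts.
#' @param win cross-boundary window half-width in TRs.
#' @return data frame: `boundary_id` (row index into the retained
#'   boundaries), `level`, `cbc`, `shift`.
#' @export
cbc_table <- function(level_series, boundaries, run_lens, win = 1) {
  keep <- if ("excluded" %in% names(boundaries)) !boundaries$excluded
  else rep(TRUE, nrow(boundaries))
  b <- boundaries[keep, , drop = FALSE]
  rows <- list()
  for (lv in names(level_series)) {
    cbc <- vapply(b$tr_index, function(tr)
      cross_boundary(level_series[[lv]], tr, win = win,
                     run_lens = run_lens), 0)
    rows[[lv]] <- data.frame(
      boundary_id = seq_len(nrow(b)), level = lv, cbc = cbc,
      shift = label_shift(cbc), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
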