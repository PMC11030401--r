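#' Inter-subject correlation (ISC) of voxel time courses
#'
#' Leave-one-out ISC: for each voxel, every subject's time course is
#' correlated with the mean time course of all other subjects, and the
#' correlations are averaged over subjects. A pairwise alternative
#' (mean over all subject-pair correlations) is available.
#'
#' Voxels for which any subject has a constant (zero-variance) series get
#' `NA`, which downstream labelling treats as `unlabeled`.
#'
#' @param subject_series list of `n_voxels x n_TR` matrices, one per
#'   subject (equal dimensions).
#' @param method `"loo"` (leave-one-out, default) or `"pairwise"`.
#' @return numeric vector of per-voxel ISC values in \[-1, 1\] (or `NA`).
#' @export
compute_isc <- function(subject_series, method = c("loo", "pairwise")) {
  method <- match.arg(method)
  n_sub <- length(subject_series)
  if (n_sub < 2L) stop("need at least 2 subjects")
  dims <- vapply(subject_series, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all subjects must have identical series dimensions")
  n_vox <- dims[1, 1]

  row_cor <- function(a, b) {
    a <- a - rowMeans(a)
    b <- b - rowMeans(b)
    num <- rowSums(a * b)
    den <- sqrt(rowSums(a^2) * rowSums(b^2))
    out <- num / den
    out[den < 1e-12] <- NA_real_
    out
  }

  if (method == "loo") {
    total <- Reduce(`+`, subject_series)
    acc <- matrix(0, n_vox, n_sub)
    for (s in seq_len(n_sub)) {
      others <- (total - subject_series[[s]]) / (n_sub - 1)
      acc[, s] <- row_cor(subject_series[[s]], others)
    }
    rowMeans(acc) # NA propagates: any undefined correlation flags the voxel
  } else {
    pairs <- utils::combn(n_sub, 2)
    acc <- matrix(0, n_vox, ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      acc[, k] <- row_cor(subject_series[[pairs[1, k]]],
                          subject_series[[pairs[2, k]]])
    }
    rowMeans(acc)
  }
}

#' ISC table across scrambling conditions
#'
#' @param intact,fine,coarse per-condition lists of subject matrices (see
#'   [compute_isc()]): the intact movie, fine temporal scrambling and
#'   coarse temporal scrambling conditions.
#' @param method ISC method, see [compute_isc()].
#' @return data frame with per-voxel `r_intact`, `r_fine`, `r_coarse`.
#' @export
isc_table <- function(intact, fine, coarse, method = "loo") {
  data.frame(
    r_intact = compute_isc(intact, method = method),
    r_fine = compute_isc(fine, method = method),
    r_coarse = compute_isc(coarse, method = method)
  )
}

#' Label voxels by processing timescale from scrambling-condition ISC
#'
#' A voxel is `short` if its ISC exceeds `thr` in all three conditions;
#' `medium` if it exceeds `thr` in the intact and coarse-scramble
#' conditions but not the fine-scramble condition; `long` if only the
#' intact condition exceeds `thr`. Any other pattern (including `NA`) is
#' `unlabeled`.
#'
#' @param r_intact,r_fine,r_coarse per-voxel ISC values (vectors).
#' @param thr ISC threshold (default 0.2).
#' @return character vector over
#'   `c("short", "medium", "long", "unlabeled")`.
#' @export
label_voxel <- function(r_intact, r_fine, r_coarse, thr = 0.2) {
  n <- length(r_intact)
  stopifnot(length(r_fine) == n, length(r_coarse) == n)
  i <- !is.na(r_intact) & r_intact > thr
  f <- !is.na(r_fine) & r_fine > thr
  c_ <- !is.na(r_coarse) & r_coarse > thr
  out <- rep("unlabeled", n)
  out[i & f & c_] <- "short"
  out[i & !f & c_] <- "medium"
  out[i & !f & !c_] <- "long"
  out
}

#' Assign one parcel to a cortical hierarchy level
#'
#' A parcel is `rejected` when fewer than half of its voxels carry any
#' timescale label. Otherwise its timescale is the majority label (ties go
#' to the longer timescale), and short-timescale parcels are subdivided:
#' `1_VIS` if more than half the voxels overlap early visual cortex
#' (retinotopic probability >= `retino_thr`), `1_AUD` if the parcel id is
#' in the hand-selected auditory list, else level `2`. Medium maps to `3`,
#' long to `4`.
#'
#' @param labels character vector of voxel labels (from [label_voxel()]).
#' @param retino_prob per-voxel probability of falling in areas V1--V4.
#' @param parcel_id parcel identifier (matched against `auditory_ids`).
#' @param auditory_ids vector of auditory parcel ids.
#' @param retino_thr probability threshold for a voxel to count as early
#'   visual (default 0.25).
#' @param reject_frac minimum labelled-voxel fraction (default 0.5).
#' @return list with `level` (one of `1_AUD`, `1_VIS`, `2`, `3`, `4`,
#'   `rejected`), `overlap_fraction`, and `label_counts`.
#' @export
assign_parcel <- function(labels, retino_prob = NULL, parcel_id = NULL,
                          auditory_ids = character(0), retino_thr = 0.25,
                          reject_frac = 0.5) {
  if (!length(labels)) stop("empty parcel")
  counts <- c(short = sum(labels == "short"),
              medium = sum(labels == "medium"),
              long = sum(labels == "long"))
  frac <- sum(counts) / length(labels)
  if (frac < reject_frac) {
    return(list(level = "rejected", overlap_fraction = frac,
                label_counts = counts))
  }
  # majority; ties broken toward the longer timescale
  order_pref <- c("long", "medium", "short")
  winner <- order_pref[which.max(counts[order_pref])]
  if (winner == "medium") {
    level <- "3"
  } else if (winner == "long") {
    level <- "4"
  } else {
    is_vis <- !is.null(retino_prob) &&
      mean(retino_prob >= retino_thr) > 0.5
    is_aud <- !is.null(parcel_id) && parcel_id %in% auditory_ids
    if (is_vis && is_aud)
      stop("parcel ", parcel_id,
           " matches both the auditory list and the visual overlap rule")
    level <- if (is_vis) "1_VIS" else if (is_aud) "1_AUD" else "2"
  }
  list(level = level, overlap_fraction = frac, label_counts = counts)
}

#' Assign every parcel of a parcellation to a hierarchy level
#'
#' @param voxel_labels character vector of voxel timescale labels.
#' @param parcellation vector of parcel ids, one per voxel.
#' @param retino_prob per-voxel early-visual probability (optional).
#' @param auditory_ids vector of auditory parcel ids.
#' @param retino_thr,reject_frac see [assign_parcel()].
#' @return data frame: `parcel_id`, `level`, `overlap_fraction`,
#'   `n_short`, `n_medium`, `n_long`.
#' @export
build_hierarchy <- function(voxel_labels, parcellation, retino_prob = NULL,
                            auditory_ids = character(0), retino_thr = 0.25,
                            reject_frac = 0.5) {
  stopifnot(length(voxel_labels) == length(parcellation))
  ids <- unique(parcellation)
  rows <- lapply(ids, function(pid) {
    sel <- parcellation == pid
    a <- assign_parcel(voxel_labels[sel],
                       retino_prob = if (is.null(retino_prob)) NULL
                       else retino_prob[sel],
                       parcel_id = pid, auditory_ids = auditory_ids,
                       retino_thr = retino_thr, reject_frac = reject_frac)
    data.frame(parcel_id = pid, level = a$level,
               overlap_fraction = a$overlap_fraction,
               n_short = a$label_counts[["short"]],
               n_medium = a$label_counts[["medium"]],
               n_long = a$label_counts[["long"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
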