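# Plain-text I/O. TSV is the canonical tabular format, JSON is used for
# reports and ground truth, YAML for run configuration. Imaging-style
# arrays are serialized as TSV matrices with a small header line, which
# keeps fixtures human-readable and diffable.

#' Write / read observer segmentation logs (TSV)
#'
#' Columns: `observer_id`, `movie_id`, `time_s`.
#'
#' @param logs data frame of observer logs.
#' @param path file path.
#' @return `read_observer_logs` returns the data frame.
#' @export
write_observer_logs <- function(logs, path) {
  stopifnot(all(c("observer_id", "movie_id", "time_s") %in% names(logs)))
  utils::write.table(logs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_observer_logs
#' @export
read_observer_logs <- function(path) {
  logs <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  stopifnot(all(c("observer_id", "movie_id", "time_s") %in% names(logs)))
  logs
}

#' Write / read a boundary set (TSV)
#'
#' @param bnd boundary data frame (`time_s`, `agreement`, `category`,
#'   `excluded`, `reason`, `tr_index`).
#' @param path file path.
#' @return `read_boundaries` returns the data frame with `category`
#'   restored as an ordered factor.
#' @export
write_boundaries <- function(bnd, path) {
  utils::write.table(bnd, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundaries
#' @export
read_boundaries <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if ("category" %in% names(b))
    b$category <- factor(b$category, levels = c("weak", "moderate", "strong"))
  b
}

#' Write / read a numeric matrix as TSV with a shape header
#'
#' The first line is a comment `# rows cols`; data follow as plain TSV.
#' Used for simulated voxel-by-TR arrays and masks.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d", nrow(m), ncol(m)), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  hdr <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  shape <- as.integer(hdr[2:3])
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1,
                                   header = FALSE))
  dimnames(m) <- NULL
  stopifnot(identical(dim(m), shape))
  m
}

#' Serialize / restore a session layout (JSON)
#'
#' @param layout a `session_layout`.
#' @param path file path.
#' @return `read_layout` returns the rebuilt `session_layout`.
#' @export
write_layout <- function(layout, path) {
  obj <- list(
    tr = layout$tr, title_duration = layout$title_duration,
    movie_id = layout$movies$movie_id,
    duration_s = layout$movies$duration_s,
    run = layout$movies$run
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dur <- obj$duration_s
  names(dur) <- obj$movie_id
  make_session_layout(dur, title_duration = obj$title_duration,
                      tr = obj$tr, runs = obj$run)
}

#' Default run configuration
#'
#' All tunables of the pipeline with their defaults; values can be
#' overridden from a YAML file via [read_config()].
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    grid_step = 0.1, window = 1, smooth_window = 2, percentile = 65,
    min_peak_sep = 1, min_sep = 6, hrf_shift = 3, halfwin = 3, win = 1,
    isc_thr = 0.2, retino_thr = 0.25, level1_mode = "either",
    baseline = 2, pre = 2, post = 10, nonboundary_per_run = 22,
    nonboundary_tail = 10, seed = 1,
    n_subjects = 17, n_observers = 16, n_boundaries = 130,
    noise_sd = 0.1, shift_gain = 1, profile_mode = "graded"
  )
}

#' Read a YAML run configuration
#'
#' Unknown keys are an error; missing keys fall back to
#' [default_config()].
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return named list of parameters.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  utils::modifyList(cfg, user)
}

#' Write a run configuration to YAML
#'
#' @param cfg named list (see [default_config()]).
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
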