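#' Run the full analysis pipeline on a simulated study
#'
#' Executes segmentation -> pattern shift -> group statistics ->
#' alignment -> hippocampal response in order, writing TSV/JSON outputs
#' and a provenance record when `out_dir` is given.
#'
#' @param study a `simulated_study` (see [simulate_study()]), or `NULL`
#'   to simulate one from `config`.
#' @param config parameter list (see [default_config()]).
#' @param out_dir optional output directory (created if needed).
#' @return list with `boundaries`, `level_series`, `cbc`, `alignment`,
#'   `group_stats` (per-level Kruskal-Wallis), `align_cor`, `hippo`
#'   (grouped hippocampal test) and `non_boundaries`.
#' @export
run_pipeline <- function(study = NULL, config = default_config(),
                         out_dir = NULL) {
  if (is.null(study)) {
    study <- simulate_study(
      n_boundaries = config$n_boundaries,
      profile_mode = config$profile_mode,
      n_subjects = config$n_subjects, n_observers = config$n_observers,
      noise_sd = config$noise_sd, shift_gain = config$shift_gain,
      seed = config$seed
    )
  }
  layout <- study$layout
  rl <- run_lengths(layout)

  seg <- with_stage("segmentation", function()
    segment_boundaries(study$observer_logs, layout,
                       grid_step = config$grid_step, window = config$window,
                       smooth_window = config$smooth_window,
                       percentile = config$percentile,
                       min_peak_sep = config$min_peak_sep,
                       min_sep = config$min_sep,
                       hrf_shift = config$hrf_shift))
  bnd <- seg$boundaries
  kept <- bnd[!bnd$excluded, , drop = FALSE]

  shift <- with_stage("patternshift", function() {
    group <- group_level_data(study$subject_data)
    series <- level_shift_series(group, rl, halfwin = config$halfwin)
    cbc <- cbc_table(series, bnd, rl, win = config$win)
    list(series = series, cbc = cbc)
  })

  stats_out <- with_stage("stats", function() {
    per_level <- lapply(names(shift$series), function(lv) {
      sub <- shift$cbc[shift$cbc$level == lv, ]
      ok <- !is.na(sub$cbc)
      kruskal_wallis(sub$cbc[ok], kept$category[sub$boundary_id[ok]])
    })
    names(per_level) <- names(shift$series)
    per_level
  })

  have_levels <- unique(shift$cbc$level)
  full_hierarchy <- all(c("2", "3", "4") %in% have_levels) &&
    (all(c("1_AUD", "1_VIS") %in% have_levels) || "1" %in% have_levels)
  align <- if (full_hierarchy) {
    with_stage("alignment", function() {
      at <- alignment_table(shift$cbc, level1_mode = config$level1_mode)
      ok <- !is.na(at$nesting)
      # degenerate score distributions (e.g. every boundary fully
      # aligned in a small study) yield no correlation, not an error
      cor_rep <- if (sum(ok) >= 3L) {
        tryCatch(
          alignment_vs_agreement(at$nesting,
                                 kept$agreement[at$boundary_id]),
          error = function(e) NULL
        )
      } else NULL
      list(table = at, cor = cor_rep)
    })
  } else {
    # studies without the full four-level hierarchy (e.g. miniature
    # fixtures) skip alignment scoring
    list(table = NULL, cor = NULL)
  }

  hippo <- with_stage("hippocampus", function() {
    # group boundaries by nesting alignment score when available, else
    # by strength category
    if (!is.null(align$table)) {
      b_id <- align$table$boundary_id
      grp <- align$table$nesting
    } else {
      b_id <- seq_len(nrow(kept))
      grp <- as.character(kept$category)
    }
    sub_ids <- rownames(study$hippocampus)
    if (is.null(sub_ids))
      sub_ids <- sprintf("sub%02d", seq_len(nrow(study$hippocampus)))
    rows <- list()
    for (s in seq_len(nrow(study$hippocampus))) {
      bl <- boundary_locked(study$hippocampus[s, ], kept$tr_index[b_id],
                            rl, pre = config$pre, post = config$post,
                            baseline = config$baseline)
      rows[[s]] <- data.frame(subject = sub_ids[s], boundary_id = b_id,
                              group = grp, summary = bl$summary)
    }
    df <- do.call(rbind, rows)
    df <- df[!is.na(df$group), , drop = FALSE]
    test <- tryCatch(grouped_response_tests(df),
                     error = function(e) NULL)
    list(summaries = df, test = test)
  })

  nb <- with_stage("nonboundary", function()
    sample_non_boundaries(layout, kept,
                          per_run = config$nonboundary_per_run,
                          min_sep = config$min_sep,
                          tail_excl = config$nonboundary_tail,
                          seed = config$seed))

  res <- list(boundaries = bnd, level_series = shift$series,
              cbc = shift$cbc, alignment = align$table,
              group_stats = stats_out, align_cor = align$cor,
              hippo = hippo, non_boundaries = nb)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_boundaries(bnd, file.path(out_dir, "boundaries.tsv"))
    utils::write.table(shift$cbc, file.path(out_dir, "cbc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(align$table))
      utils::write.table(align$table, file.path(out_dir, "alignment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(hippo$summaries,
                       file.path(out_dir, "hippocampus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prov <- list(
      package = "eventshift",
      version = as.character(utils::packageVersion("eventshift")),
      config = config[order(names(config))],
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

# propagate stage errors with the stage name attached
with_stage <- function(stage, fn) {
  tryCatch(fn(), error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Group-average a per-subject nested data structure
#'
#' @param subject_data list of subjects, each a named list of levels of
#'   parcel matrices (as produced by [simulate_cortex()]).
#' @return one nested structure of the same shape holding voxelwise
#'   means across subjects.
#' @export
group_level_data <- function(subject_data) {
  lv <- names(subject_data[[1]])
  out <- lapply(lv, function(l) {
    np <- length(subject_data[[1]][[l]])
    lapply(seq_len(np), function(p)
      group_average(lapply(subject_data, function(s) s[[l]][[p]])))
  })
  names(out) <- lv
  out
}

#' Write a miniature on-disk synthetic study
#'
#' Generates a small (two runs, four short movies, three hierarchy
#' levels, four subjects) study and writes it as plain-text files:
#' observer logs and ground truth, layout JSON, per-subject parcel
#' matrices and hippocampal series as TSV. Deterministic given `seed`
#' and small enough for test fixtures.
#'
#' @param dir output directory (created).
#' @param seed integer seed.
#' @return invisibly, the directory path.
#' @export
make_fixture <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dur <- c(a = 60, b = 58.5, c = 60, d = 58.5)
  layout <- make_session_layout(dur, title_duration = 4, tr = 1.5,
                                runs = c(1, 1, 2, 2))
  set.seed(seed)
  times <- sample_boundary_times(layout, n_boundaries = 12, min_gap = 8)
  strength <- stats::runif(12, 0.2, 1)
  truth <- ground_truth(times, strength, noise_sd = 0.1)
  spec <- default_levels_spec(n_parcels = 1, n_voxels = 8)[c("1_AUD", "2", "4")]
  logs <- simulate_observers(layout, truth, n_observers = 8)
  cortex <- simulate_cortex(layout, truth, levels_spec = spec,
                            n_subjects = 4)
  hip <- simulate_hippocampus(layout, truth, n_subjects = 4)

  write_layout(layout, file.path(dir, "layout.json"))
  write_observer_logs(logs, file.path(dir, "observer_logs.tsv"))
  jsonlite::write_json(
    list(boundary_times = truth$boundary_times, strength = truth$strength,
         profile_mode = truth$profile_mode, noise_sd = truth$noise_sd,
         seed = seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE,
    pretty = TRUE
  )
  for (s in seq_along(cortex)) {
    for (lv in names(cortex[[s]])) {
      for (p in seq_along(cortex[[s]][[lv]])) {
        write_matrix_tsv(cortex[[s]][[lv]][[p]],
                         file.path(dir, sprintf("sub%02d_level%s_parcel%d.tsv",
                                                s, lv, p)))
      }
    }
  }
  write_matrix_tsv(hip, file.path(dir, "hippocampus.tsv"))
  invisible(dir)
}

#' Load a fixture written by [make_fixture()]
#'
#' @param dir fixture directory.
#' @return a `simulated_study`-shaped list (`layout`, `truth`,
#'   `observer_logs`, `subject_data`, `hippocampus`).
#' @export
read_fixture <- function(dir) {
  layout <- read_layout(file.path(dir, "layout.json"))
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE)
  truth <- ground_truth(truth_raw$boundary_times, truth_raw$strength,
                        profile_mode = truth_raw$profile_mode,
                        noise_sd = truth_raw$noise_sd)
  logs <- read_observer_logs(file.path(dir, "observer_logs.tsv"))
  files <- list.files(dir, pattern = "^sub\\d+_level.*_parcel\\d+\\.tsv$")
  subs <- sort(unique(sub("_level.*$", "", files)))
  subject_data <- lapply(subs, function(sid) {
    sf <- files[startsWith(files, sid)]
    lvs <- unique(sub("^.*_level(.*)_parcel.*$", "\\1", sf))
    out <- lapply(lvs, function(lv) {
      pf <- sort(sf[grepl(sprintf("_level%s_parcel", lv), sf, fixed = TRUE)])
      lapply(pf, function(f) read_matrix_tsv(file.path(dir, f)))
    })
    names(out) <- lvs
    out
  })
  hip <- read_matrix_tsv(file.path(dir, "hippocampus.tsv"))
  structure(list(layout = layout, truth = truth, observer_logs = logs,
                 subject_data = subject_data, hippocampus = hip),
            class = "simulated_study")
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a fixture study), `segment` (observer
#' logs -> boundary TSV), `all` (full pipeline on a simulated study).
#' Global options: `--seed <int>`, `--config <yaml>`, `--out <dir>`.
#'
#' @param args character vector of command-line arguments (default: the
#'   actual command line).
#' @return exit status, invisibly (0 on success).
#' @export
eventshift_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: eventshift <simulate|segment|all> [--seed N] [--config FILE]",
    "[--out DIR] [--logs FILE] [--layout FILE]"
  )
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list(seed = 1L, config = NULL, out = "eventshift_out",
              logs = NULL, layout = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option: ", args[i])
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- read_config(opt$config)
  cfg$seed <- as.integer(opt$seed)

  if (cmd == "simulate") {
    make_fixture(opt$out, seed = cfg$seed)
    message("fixture written to ", opt$out)
  } else if (cmd == "segment") {
    if (is.null(opt$logs) || is.null(opt$layout))
      stop("segment needs --logs and --layout")
    layout <- read_layout(opt$layout)
    logs <- read_observer_logs(opt$logs)
    seg <- segment_boundaries(logs, layout,
                              grid_step = cfg$grid_step,
                              window = cfg$window,
                              smooth_window = cfg$smooth_window,
                              percentile = cfg$percentile,
                              min_sep = cfg$min_sep,
                              hrf_shift = cfg$hrf_shift)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    write_boundaries(seg$boundaries,
                     file.path(opt$out, "boundaries.tsv"))
    message("boundaries written to ", file.path(opt$out, "boundaries.tsv"))
  } else if (cmd == "all") {
    run_pipeline(config = cfg, out_dir = opt$out)
    message("pipeline outputs written to ", opt$out)
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
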