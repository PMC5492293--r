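#' Read one sensor recording from CSV
#'
#' Expects a header `time_s, ax, ay, az` with axes ordered vertical, ML, AP.
#' The site is taken from the filename suffix `_{LB|LS|RS}.csv` unless given.
#'
#' @param path CSV path.
#' @param site Optional site override.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, site = NULL) {
  df <- utils::read.csv(path)
  if (!identical(names(df)[1:4], c("time_s", "ax", "ay", "az")))
    stop("expected header time_s, ax, ay, az in ", path, call. = FALSE)
  bad <- which(!stats::complete.cases(df) |
                 !apply(df, 1, function(r) all(is.finite(as.numeric(r)))))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  if (is.null(site)) {
    m <- regmatches(path, regexpr("_(LB|LS|RS)\\.csv$", path))
    if (!length(m)) stop("cannot infer site from filename: ", path,
                         call. = FALSE)
    site <- sub("^_", "", sub("\\.csv$", "", m))
  }
  raw_recording(site, df$time_s, cbind(df$ax, df$ay, df$az))
}

#' @rdname read_recording
#' @param rec A `raw_recording` to write.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time_s = rec$time_s, ax = rec$accel[, "V"],
                   ay = rec$accel[, "ML"], az = rec$accel[, "AP"])
  utils::write.csv(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic session to disk
#'
#' One CSV per sensor site (`{id}_{site}.csv`) plus a JSON sidecar
#' (`{id}_truth.json`) with the label and planted ground truth.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if missing).
#' @param id Participant id used in filenames.
#' @return Invisibly, the written paths.
#' @export
write_session <- function(session, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(session$recordings), function(s) {
    p <- file.path(dir, sprintf("%s_%s.csv", id, s))
    write_recording(session$recordings[[s]], p)
    p
  }, character(1))
  truth_path <- file.path(dir, sprintf("%s_truth.json", id))
  truth <- session$truth
  truth$turn_intervals <- apply(truth$turn_intervals, 1, identity,
                                simplify = FALSE)
  jsonlite::write_json(list(label = session$label, truth = truth),
                       truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth_path))
}

#' Read a session (three site CSVs + truth JSON) back from disk
#'
#' @param dir Directory written by [write_session()].
#' @param id Participant id.
#' @return A `synthetic_session`.
#' @export
read_session <- function(dir, id) {
  recs <- lapply(c(LB = "LB", LS = "LS", RS = "RS"), function(s)
    read_recording(file.path(dir, sprintf("%s_%s.csv", id, s))))
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_truth.json", id)),
                              simplifyVector = TRUE)
  truth <- meta$truth
  if (is.list(truth$turn_intervals))
    truth$turn_intervals <- do.call(rbind, truth$turn_intervals)
  structure(list(recordings = recs, label = meta$label, truth = truth),
            class = "synthetic_session")
}

#' Write segments as a BED-like TSV
#'
#' Columns: `kind, start_s, end_s, n_steps`.
#'
#' @param segments List of `walk_segment`.
#' @param session The `session` the indices refer to.
#' @param path Output TSV path.
#' @export
write_segments <- function(segments, session, path) {
  df <- if (length(segments)) data.frame(
    kind = vapply(segments, function(s) s$kind, character(1)),
    start_s = session$time_s[vapply(segments, function(s) s$start_idx,
                                    numeric(1))],
    end_s = session$time_s[pmin(vapply(segments, function(s) s$end_idx,
                                       numeric(1)), length(session$time_s))],
    n_steps = vapply(segments, function(s) length(s$steps), integer(1))
  ) else data.frame(kind = character(0), start_s = numeric(0),
                    end_s = numeric(0), n_steps = integer(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a cohort feature matrix as CSV
#'
#' Header: `participant_id`, `label`, then the canonical
#' `agg|site|feature|axis` feature names.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(participant_id = fm$participants,
                   label = as.character(fm$labels), check.names = FALSE)
  df <- cbind(df, as.data.frame(fm$x, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$participant_id
  structure(list(x = x, labels = factor(df$label, levels = c("NF", "PF")),
                 participants = df$participant_id),
            class = "feature_matrix")
}

#' Default run configuration
#'
#' All tunable knobs of the pipeline with their defaults. `run_config()`
#' merges overrides into the defaults and rejects unknown keys.
#'
#' @param ... Named overrides of the default keys.
#' @return Named list of configuration values.
#' @export
run_config <- function(...) {
  defaults <- list(
    n_nf = 43, n_pf = 28, duration = 360,
    sync_prominence = 1.0,
    turn_theta = 0.7, turn_window_s = 1.0, turn_min_run_s = 0.5,
    step_prominence = 0.3, step_min_separation = 0.3,
    buffer_s = 0.2,
    reoh_normalized = TRUE, n_harmonics = 20,
    k_features = 5, alpha = 0.05,
    n_iter = 2500, test_frac = 0.2, mfo_threshold = 250,
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaults, overrides)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `segment` (segment one
#' session's CSVs), `extract` (cohort feature matrices), `evaluate` (run the
#' protocol and write a JSON report). Invoked by the thin wrapper script in
#' `inst/cli/turngait.R`; returns an exit status instead of calling `quit()`
#' so it is testable in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success).
#' @export
tg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: turngait <simulate|segment|extract|evaluate|report> [options]",
    "  simulate --out DIR [--n-nf N] [--n-pf N] [--duration S] [--seed N]",
    "  segment  --dir DIR --id ID --out TSV",
    "  extract  --dir DIR --out-prefix PFX",
    "  evaluate --dir DIR --out JSON [--n-iter N] [--seed N]",
    "  report   --in JSON",
    sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    args[i[1] + 1L]
  }
  tryCatch({
    if (!length(args)) stop(usage, call. = FALSE)
    cmd <- args[1]
    if (cmd == "simulate") {
      out <- opt("--out"); if (is.null(out)) stop(usage, call. = FALSE)
      cohort <- simulate_cohort(
        n_nf = as.integer(opt("--n-nf", "6")),
        n_pf = as.integer(opt("--n-pf", "4")),
        duration = as.numeric(opt("--duration", "360")),
        seed = as.integer(opt("--seed", "1")))
      for (id in names(cohort)) write_session(cohort[[id]], out, id)
      message("wrote ", length(cohort), " sessions to ", out)
    } else if (cmd == "segment") {
      dir <- opt("--dir"); id <- opt("--id"); out <- opt("--out")
      if (is.null(dir) || is.null(id) || is.null(out))
        stop(usage, call. = FALSE)
      sess <- read_session(dir, id)
      pp <- preprocess_session(sess$recordings)
      write_segments(c(pp$turns, pp$straights), pp$session, out)
      message(length(pp$turns), " turns, ", length(pp$straights),
              " straights -> ", out)
    } else if (cmd == "extract") {
      dir <- opt("--dir"); pfx <- opt("--out-prefix")
      if (is.null(dir) || is.null(pfx)) stop(usage, call. = FALSE)
      ids <- unique(sub("_truth\\.json$", "",
                        basename(list.files(dir, "_truth\\.json$"))))
      cohort <- lapply(stats::setNames(ids, ids),
                       function(i) read_session(dir, i))
      fms <- cohort_features(cohort)
      write_feature_matrix(fms$straight, paste0(pfx, "_straight.csv"))
      write_feature_matrix(fms$turn, paste0(pfx, "_turn.csv"))
      write_feature_matrix(fms$combined, paste0(pfx, "_combined.csv"))
      message("wrote feature matrices with prefix ", pfx)
    } else if (cmd == "evaluate") {
      dir <- opt("--dir"); out <- opt("--out")
      if (is.null(dir) || is.null(out)) stop(usage, call. = FALSE)
      ids <- unique(sub("_truth\\.json$", "",
                        basename(list.files(dir, "_truth\\.json$"))))
      cohort <- lapply(stats::setNames(ids, ids),
                       function(i) read_session(dir, i))
      fms <- cohort_features(cohort)
      rep <- run_protocol(fms$straight, fms$turn, fms$combined,
                          n_iter = as.integer(opt("--n-iter", "100")),
                          seed = as.integer(opt("--seed", "1")))
      jsonlite::write_json(list(
        best_turn = rep$test2$best_turn,
        best_straight = rep$test2$best_straight,
        turn_means = as.data.frame(rep$test2$turn$means),
        straight_means = as.data.frame(rep$test2$straight$means),
        welch_p = lapply(rep$welch, function(w) w$p)),
        out, auto_unbox = TRUE, digits = NA)
      message("report -> ", out)
    } else if (cmd == "report") {
      path <- opt("--in"); if (is.null(path)) stop(usage, call. = FALSE)
      rep <- jsonlite::read_json(path, simplifyVector = TRUE)
      cat("best turn combination:     ", rep$best_turn, "\n")
      cat("best straight combination: ", rep$best_straight, "\n\n")
      cat("turn metric means:\n")
      print(round(as.data.frame(rep$turn_means), 3))
      cat("\nstraight metric means:\n")
      print(round(as.data.frame(rep$straight_means), 3))
      cat("\nWelch p (turn vs straight, per metric):\n")
      print(signif(unlist(rep$welch_p), 3))
    } else stop(usage, call. = FALSE)
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
}
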