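# Cohort serialization (one child per line, JSON), feature tables and the
# printed-summary-table reader.
#
# The raw storage schema is an invention of this package (no public schema
# exists for such session data); it is versioned via `format_version`.

COHORT_FORMAT_VERSION <- 1L

# ---- wire conversion --------------------------------------------------------

df_to_wire <- function(df) as.list(df)

num <- function(x) as.numeric(unlist(x) %||% numeric(0))
int <- function(x) as.integer(round(num(x)))
chr <- function(x) as.character(unlist(x) %||% character(0))
lgl <- function(x) as.logical(unlist(x) %||% logical(0))

task_to_wire <- function(name, task) {
  switch(name,
    preferential = lapply(task, function(tr) list(
      social_on_left = tr$social_on_left,
      frames = df_to_wire(tr$frames))),
    button = df_to_wire(task),
    wheel = lapply(task, function(tr) list(
      completed = tr$completed,
      play_duration_s = tr$play_duration_s,
      max_duration_s = tr$max_duration_s,
      face_frames = df_to_wire(tr$face_frames))),
    motor = lapply(task, function(tr) list(
      target = df_to_wire(tr$target),
      touch = df_to_wire(tr$touch))),
    bubble = df_to_wire(task),
    colouring = lapply(task, function(ss) list(
      figure_outline = list(x = ss$figure_outline[, 1],
                            y = ss$figure_outline[, 2]),
      screen_px = ss$screen_px,
      brush_radius_px = ss$brush_radius_px,
      strokes = lapply(ss$strokes, df_to_wire))),
    questionnaire = task,
    pci = task,
    stopf("unknown task '%s'", name))
}

wire_to_task <- function(name, w) {
  switch(name,
    preferential = lapply(w, function(tr) list(
      social_on_left = lgl(tr$social_on_left),
      frames = data.frame(t_ms = int(tr$frames$t_ms),
                          eye_detected = lgl(tr$frames$eye_detected),
                          gaze = chr(tr$frames$gaze)))),
    button = data.frame(completed = lgl(w$completed), choice = chr(w$choice)),
    wheel = lapply(w, function(tr) list(
      completed = lgl(tr$completed),
      play_duration_s = num(tr$play_duration_s),
      max_duration_s = num(tr$max_duration_s),
      face_frames = data.frame(t_ms = int(tr$face_frames$t_ms),
                               face_detected = lgl(tr$face_frames$face_detected),
                               distance_mm = num_na(tr$face_frames$distance_mm),
                               gaze_on_wheel = lgl(tr$face_frames$gaze_on_wheel)))),
    motor = lapply(w, function(tr) list(
      target = data.frame(t_ms = int(tr$target$t_ms), x_px = num(tr$target$x_px),
                          y_px = num(tr$target$y_px)),
      touch = if (length(tr$touch$t_ms)) {
        data.frame(t_ms = int(tr$touch$t_ms), x_px = num(tr$touch$x_px),
                   y_px = num(tr$touch$y_px), pressure = num(tr$touch$pressure))
      } else {
        data.frame(t_ms = integer(0), x_px = numeric(0), y_px = numeric(0),
                   pressure = numeric(0))
      })),
    bubble = data.frame(bubble_x = num(w$bubble_x), bubble_y = num(w$bubble_y),
                        touch_x = num(w$touch_x), touch_y = num(w$touch_y),
                        pressure = num(w$pressure), popped = lgl(w$popped)),
    colouring = lapply(w, function(ss) list(
      figure_outline = cbind(num(ss$figure_outline$x), num(ss$figure_outline$y)),
      screen_px = num(ss$screen_px),
      brush_radius_px = num(ss$brush_radius_px),
      strokes = lapply(ss$strokes, function(st) data.frame(
        t_ms = int(st$t_ms), x_px = num(st$x_px), y_px = num(st$y_px),
        pressure = num(st$pressure))))),
    questionnaire = list(items = chr(w$items), reverse_coded = int(w$reverse_coded)),
    pci = lapply(w, function(cd) list(
      coder_id = chr(cd$coder_id),
      child_initiation_prop = num(cd$child_initiation_prop),
      caregiver_sync_prop = num(cd$caregiver_sync_prop),
      child_opportunities = int(cd$child_opportunities),
      caregiver_opportunities = int(cd$caregiver_opportunities))),
    stopf("unknown task '%s'", name))
}

num_na <- function(x) {
  x <- unlist(lapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v)))
  if (is.null(x)) numeric(0) else x
}

child_to_json <- function(rec) {
  tasks <- rec$tasks[intersect(TASK_NAMES, names(rec$tasks))]  # stable key order
  wire <- list(
    child_id = rec$child_id, group = rec$group,
    age_years = rec$age_years, sex = rec$sex,
    tasks = mapply(task_to_wire, names(tasks), tasks, SIMPLIFY = FALSE))
  jsonlite::toJSON(wire, auto_unbox = TRUE, digits = NA, na = "null", null = "null")
}

json_to_child <- function(line) {
  w <- jsonlite::fromJSON(line, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  unknown <- setdiff(names(w$tasks), TASK_NAMES)
  if (length(unknown)) stopf("unknown task name(s): %s", paste(unknown, collapse = ", "))
  tasks <- mapply(wire_to_task, names(w$tasks), w$tasks, SIMPLIFY = FALSE)
  child_record(w$child_id, w$group, w$age_years, w$sex, tasks)
}

# ---- cohort files -----------------------------------------------------------

#' Write a cohort to a line-delimited session file
#'
#' One JSON header line (`format_version`, record count) followed by one JSON
#' record per child with a stable key order, so repeated writes of the same
#' cohort are byte-identical and `read_cohort()` is an exact inverse.
#'
#' @param cohort a list of `start_child` records.
#' @param path output file path (UTF-8).
#' @param config battery configuration used for validation.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = start_config()) {
  validate_cohort(cohort, config)
  header <- jsonlite::toJSON(
    list(format_version = COHORT_FORMAT_VERSION, type = "start_cohort",
         n = length(cohort)),
    auto_unbox = TRUE)
  lines <- c(header, vapply(cohort, child_to_json, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort from a line-delimited session file
#'
#' @param path file written by [write_cohort()].
#' @param config battery configuration used for validation.
#' @return A validated `start_cohort` (list of `start_child` records).
#'   Malformed lines raise a parse error naming the line; duplicated
#'   `child_id`s raise a validation error naming the id.
#' @export
read_cohort <- function(path, config = start_config()) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), class = "start_cohort"))
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]),
                  error = function(e) stopf("parse error at line 1: %s", conditionMessage(e)))
  body <- lines
  if (identical(hdr$type, "start_cohort")) {
    if (!identical(as.integer(hdr$format_version), COHORT_FORMAT_VERSION)) {
      stopf("unsupported cohort format_version %s", hdr$format_version)
    }
    body <- lines[-1]
    offset <- 1L
  } else {
    offset <- 0L  # headerless files are tolerated
  }
  cohort <- vector("list", length(body))
  for (i in seq_along(body)) {
    cohort[[i]] <- tryCatch(
      json_to_child(body[i]),
      error = function(e) stopf("parse error at line %d: %s", i + offset,
                                conditionMessage(e)))
    validate_child_record(cohort[[i]], config,
                          context = sprintf("line %d (child '%s')", i + offset,
                                            cohort[[i]]$child_id))
  }
  validate_cohort(cohort, config)
  structure(cohort, class = "start_cohort")
}

# ---- feature tables ---------------------------------------------------------

#' Write a feature table
#'
#' Comma-separated, header `child_id,group,<16 feature slots>`; missing values
#' are rendered as empty fields.
#'
#' @param features a data frame as returned by [extract_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  cols <- c("child_id", "group", FEATURE_SLOTS)
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols)) stopf("feature table lacks column(s): %s",
                                  paste(missing_cols, collapse = ", "))
  utils::write.table(features[, cols, drop = FALSE], path, sep = ",",
                     na = "", row.names = FALSE, col.names = TRUE, qmethod = "double")
  invisible(path)
}

#' Read a feature table
#'
#' @param path file written by [write_feature_table()].
#' @return A data frame of class `start_features`; empty fields become `NA`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(child_id = "character", group = "character"))
  for (s in FEATURE_SLOTS) df[[s]] <- as.numeric(df[[s]])
  class(df) <- c("start_features", "data.frame")
  df
}

# ---- printed group-summary tables -------------------------------------------

#' Read a group summary table
#'
#' Reads a delimited table of printed group summaries with columns
#' `measure,group,n,mean,sd` (one row per measure x group) such as the
#' participant-characteristics and group-comparison tables shipped in
#' `inst/extdata/`.
#'
#' @param path CSV file path.
#' @return A named list of `start_summary` objects, one per measure, each
#'   holding `measure` and a data frame `groups` (rows TD, AS, ID) with
#'   columns `group`, `n`, `mean`, `sd`.
#' @export
read_summary_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("measure", "group", "n", "mean", "sd")
  if (!all(need %in% names(df))) {
    stopf("summary table must have columns %s", paste(need, collapse = ","))
  }
  out <- list()
  for (m in unique(df$measure)) {
    sub <- df[df$measure == m, ]
    if (!setequal(sub$group, GROUP_LEVELS)) {
      stopf("measure '%s' must list exactly the groups %s", m,
            paste(GROUP_LEVELS, collapse = ", "))
    }
    sub <- sub[match(GROUP_LEVELS, sub$group), ]
    if (any(sub$n <= 1)) stopf("measure '%s': group n must exceed 1", m)
    if (any(sub$sd < 0)) stopf("measure '%s': sd must be non-negative", m)
    out[[m]] <- structure(
      list(measure = m,
           groups = data.frame(group = sub$group, n = as.integer(sub$n),
                               mean = sub$mean, sd = sub$sd)),
      class = "start_summary")
  }
  out
}

#' @export
print.start_summary <- function(x, ...) {
  cat(sprintf("<start_summary> %s\n", x$measure))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

# ---- pipeline ---------------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Chains the pipeline stages `simulate` (synthetic cohort), `extract`
#' (feature table + filter report), `stats` (group-comparison table) and
#' `classify` (per-block and best-combination cross-validated accuracy),
#' writing one artifact file per stage into `out_dir`. The same configuration
#' and seed always produce identical artifacts.
#'
#' @param config a list with elements `stages` (character vector, in order),
#'   `seed` (integer), `out_dir` (directory, created if needed), and optional
#'   overrides `n_per_group`, `cv_folds`, `cv_repeats`, `classifier`, plus any
#'   [start_config()] field under `battery`.
#' @param log_file optional path; log lines go to stderr and, if set, there.
#' @return Invisibly, a named list of stage outputs and artifact paths.
#' @export
run_pipeline <- function(config, log_file = NULL) {
  stages <- config$stages %||% c("simulate", "extract", "stats", "classify")
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "."
  unknown <- setdiff(stages, c("simulate", "extract", "stats", "classify"))
  if (length(unknown)) stopf("unknown pipeline stage(s): %s",
                             paste(unknown, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  battery <- do.call(start_config, config$battery %||% list())
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    message(line)
    if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  }
  out <- list()
  run_stage <- function(name, fn) {
    logf("stage %s: start", name)
    res <- tryCatch(fn(), error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    logf("stage %s: done", name)
    res
  }
  cohort <- NULL
  features <- NULL
  for (st in stages) {
    if (st == "simulate") {
      out$cohort_path <- file.path(out_dir, "cohort.jsonl")
      cohort <- run_stage("simulate", function() {
        sc <- sim_config(seed = seed,
                         n_per_group = config$n_per_group %||% c(TD = 40, AS = 48, ID = 43),
                         battery = battery)
        co <- simulate_cohort(sc)
        write_cohort(co, out$cohort_path, battery)
        co
      })
      out$cohort <- cohort
    } else if (st == "extract") {
      out$features_path <- file.path(out_dir, "features.csv")
      out$filters_path <- file.path(out_dir, "filters.csv")
      features <- run_stage("extract", function() {
        if (is.null(cohort)) cohort <<- read_cohort(out$cohort_path %||%
                                                      file.path(out_dir, "cohort.jsonl"), battery)
        ex <- extract_cohort(cohort, battery, seed = mix_seed(seed, 4242))
        write_feature_table(ex$features, out$features_path)
        utils::write.csv(ex$filters, out$filters_path, row.names = FALSE)
        ex$features
      })
      out$features <- features
    } else if (st == "stats") {
      out$stats_path <- file.path(out_dir, "group_table.csv")
      out$group_table <- run_stage("stats", function() {
        if (is.null(features)) features <<- read_feature_table(out$features_path %||%
                                                                 file.path(out_dir, "features.csv"))
        gt <- group_table(features)
        utils::write.csv(as.data.frame(gt), out$stats_path, row.names = FALSE)
        gt
      })
    } else if (st == "classify") {
      out$classify_path <- file.path(out_dir, "classification.csv")
      out$classification <- run_stage("classify", function() {
        if (is.null(features)) features <<- read_feature_table(out$features_path %||%
                                                                 file.path(out_dir, "features.csv"))
        cv <- cv_config(folds = config$cv_folds %||% 5,
                        repeats = config$cv_repeats %||% 20,
                        seed = mix_seed(seed, 777),
                        classifier = config$classifier %||% "logistic_regression")
        blocks <- feature_blocks()
        rows <- lapply(names(blocks), function(b) {
          as.data.frame(evaluate_blocks(features, b, cv))
        })
        combo <- as.data.frame(evaluate_blocks(features, best_combination(), cv))
        tab <- do.call(rbind, c(rows, list(combo)))
        utils::write.csv(tab, out$classify_path, row.names = FALSE)
        tab
      })
    }
  }
  invisible(out)
}
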