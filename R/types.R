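# Domain types: raw session records, feature vectors and their validators.

#' @name startpheno-types
#' @title Session record structure
#'
#' @description
#' A cohort is a list of child records (class `start_cohort`). Each child
#' record (class `start_child`) holds an opaque `child_id`, a `group` label
#' (`"TD"`, `"AS"` or `"ID"`), `age_years`, `sex` (`"F"`/`"M"`) and a named
#' `tasks` list holding any subset of the eight raw task sub-records:
#'
#' * `preferential`: list of trials, each `list(social_on_left, frames)` where
#'   `frames` is a data frame `t_ms`, `eye_detected`, `gaze` (one of
#'   `social_side`, `nonsocial_side`, `elsewhere_on_tablet`, `off_tablet`,
#'   `undetected`).
#' * `button`: data frame `completed`, `choice` (`social`/`nonsocial`/`none`).
#' * `wheel`: list of trials `list(completed, play_duration_s, max_duration_s,
#'   face_frames)`; `face_frames` is a data frame `t_ms`, `face_detected`,
#'   `distance_mm` (present iff detected), `gaze_on_wheel`.
#' * `motor`: list of trials `list(target, touch)`, both time-ordered data
#'   frames of `t_ms`, `x_px`, `y_px` (+ `pressure` for `touch`).
#' * `bubble`: data frame `bubble_x`, `bubble_y`, `touch_x`, `touch_y`,
#'   `pressure`, `popped`.
#' * `colouring`: list of sessions `list(figure_outline, screen_px,
#'   brush_radius_px, strokes)`; `strokes` is a list of time-ordered data
#'   frames of `t_ms`, `x_px`, `y_px`, `pressure`.
#' * `questionnaire`: `list(items, reverse_coded)` with 14 `"yes"`/`"no"`
#'   items and the indices of the 8 reverse-coded items.
#' * `pci`: list of codings `list(coder_id, child_initiation_prop,
#'   caregiver_sync_prop, child_opportunities, caregiver_opportunities)`.
#'
#' Coordinates are screen pixels with the origin at the top-left corner, x
#' rightward, y downward; timestamps are integer milliseconds.
NULL

GROUP_LEVELS <- c("TD", "AS", "ID")
GAZE_LEVELS <- c("social_side", "nonsocial_side", "elsewhere_on_tablet",
                 "off_tablet", "undetected")
TASK_NAMES <- c("preferential", "button", "wheel", "motor", "bubble",
                "colouring", "questionnaire", "pci")

#' Feature slot names
#'
#' The 16 per-child derived metrics, in canonical column order.
#' @export
FEATURE_SLOTS <- c(
  "social_preference", "social_choice",
  "wheel_looking", "wheel_dist_min", "wheel_dist_max",
  "motor_rmse", "fft_gain_x", "fft_gain_y", "jerk",
  "pop_force", "pop_dist_x", "pop_dist_y",
  "colour_crossings",
  "pci_child_init", "pci_caregiver_sync",
  "questionnaire_score"
)

FILTER_REASONS <- c(
  "ok", "missing_task", "eye_detection_below_half",
  "gaze_on_tablet_below_half", "fewer_than_half_trials",
  "fewer_than_two_trials", "face_detection_at_or_below_quarter",
  "no_bubbles_popped", "coverage_below_threshold", "degenerate"
)

#' Construct a child record
#'
#' @param child_id opaque identifier, unique within a cohort.
#' @param group one of `"TD"`, `"AS"`, `"ID"`.
#' @param age_years chronological age in years.
#' @param sex `"F"` or `"M"`.
#' @param tasks named list of raw task sub-records (any subset of the eight
#'   task names); see [startpheno-types].
#' @return An object of class `start_child`.
#' @export
child_record <- function(child_id, group, age_years, sex, tasks = list()) {
  rec <- structure(
    list(child_id = as.character(child_id), group = as.character(group),
         age_years = as.numeric(age_years), sex = as.character(sex),
         tasks = tasks),
    class = "start_child")
  rec
}

#' Validate a child record
#'
#' Checks every structural invariant of the session schema (label levels,
#' value ranges, time ordering, task-specific field constraints) and fails
#' with an informative error on the first violation.
#'
#' @param rec a `start_child` record.
#' @param config battery configuration, see [start_config()].
#' @param context string prefixed to error messages (e.g. a line number).
#' @return `rec`, invisibly.
#' @export
validate_child_record <- function(rec, config = start_config(), context = NULL) {
  ctx <- if (is.null(context)) sprintf("child '%s'", rec$child_id %||% "?")
         else context
  fail <- function(fmt, ...) stopf("%s: %s", ctx, sprintf(fmt, ...))
  if (is.null(rec$child_id) || !nzchar(rec$child_id)) fail("missing child_id")
  if (!rec$group %in% GROUP_LEVELS) fail("invalid group '%s'", rec$group)
  if (!rec$sex %in% c("F", "M")) fail("invalid sex '%s'", rec$sex)
  ar <- config$age_range
  if (!is.finite(rec$age_years) || rec$age_years < ar[1] || rec$age_years > ar[2]) {
    fail("age %.2f outside configured range [%g, %g]", rec$age_years, ar[1], ar[2])
  }
  unknown <- setdiff(names(rec$tasks), TASK_NAMES)
  if (length(unknown)) fail("unknown task name(s): %s", paste(unknown, collapse = ", "))
  W <- config$screen_px[1]; H <- config$screen_px[2]
  chk_xy <- function(x, y, what) {
    if (any(!is.finite(x)) || any(!is.finite(y)) ||
        any(x < 0 | x > W) || any(y < 0 | y > H)) {
      fail("%s coordinates outside screen bounds %dx%d", what, W, H)
    }
  }
  chk_t <- function(t, what, strict = TRUE) {
    if (length(t) && (any(t < 0) || any(!is.finite(t)))) fail("%s has invalid t_ms", what)
    if (length(t) > 1) {
      d <- diff(t)
      if (strict && any(d <= 0)) fail("%s t_ms not strictly increasing", what)
      if (!strict && any(d < 0)) fail("%s t_ms not non-decreasing", what)
    }
  }
  tk <- rec$tasks
  if (!is.null(tk$preferential)) {
    for (tr in tk$preferential) {
      if (!is.logical(tr$social_on_left)) fail("preferential trial lacks social_on_left flag")
      fr <- tr$frames
      chk_t(fr$t_ms, "preferential frames")
      if (!all(fr$gaze %in% GAZE_LEVELS)) fail("invalid gaze label")
      if (any((fr$gaze == "undetected") != !fr$eye_detected)) {
        fail("gaze 'undetected' must coincide with eye_detected == FALSE")
      }
    }
  }
  if (!is.null(tk$button)) {
    bt <- tk$button
    if (!all(bt$choice %in% c("social", "nonsocial", "none"))) fail("invalid button choice")
    if (any((bt$choice == "none") != !bt$completed)) {
      fail("button choice 'none' must coincide with completed == FALSE")
    }
  }
  if (!is.null(tk$wheel)) {
    for (tr in tk$wheel) {
      if (tr$play_duration_s < 0 || tr$play_duration_s > tr$max_duration_s + 1e-9) {
        fail("wheel play_duration_s outside [0, max_duration_s]")
      }
      ff <- tr$face_frames
      chk_t(ff$t_ms, "wheel face frames")
      has_d <- !is.na(ff$distance_mm)
      if (any(has_d != ff$face_detected)) {
        fail("wheel distance_mm must be present iff face_detected")
      }
      if (any(ff$distance_mm[has_d] <= 0)) fail("wheel distance_mm must be positive")
    }
  }
  if (!is.null(tk$motor)) {
    for (tr in tk$motor) {
      chk_t(tr$target$t_ms, "motor target")
      chk_t(tr$touch$t_ms, "motor touch")
      chk_xy(tr$touch$x_px, tr$touch$y_px, "motor touch")
      if (!is.null(tr$touch$pressure) && length(tr$touch$pressure) &&
          any(tr$touch$pressure < 0 | tr$touch$pressure > 1)) {
        fail("motor touch pressure outside [0, 1]")
      }
    }
  }
  if (!is.null(tk$bubble)) {
    bb <- tk$bubble
    if (nrow(bb) && any(bb$pressure < 0 | bb$pressure > 1)) fail("bubble pressure outside [0, 1]")
    if (nrow(bb)) chk_xy(bb$touch_x, bb$touch_y, "bubble touch")
  }
  if (!is.null(tk$colouring)) {
    for (ss in tk$colouring) {
      po <- ss$figure_outline
      if (!is.matrix(po) || ncol(po) != 2 || nrow(po) < 3) fail("colouring outline is not a polygon")
      if (ss$brush_radius_px <= 0) fail("brush radius must be positive")
      for (st in ss$strokes) chk_t(st$t_ms, "colouring stroke", strict = FALSE)
    }
  }
  if (!is.null(tk$questionnaire)) {
    q <- tk$questionnaire
    if (length(q$items) != 14 || !all(q$items %in% c("yes", "no"))) {
      fail("questionnaire must have exactly 14 yes/no items")
    }
    if (length(unique(q$reverse_coded)) != 8 ||
        !all(q$reverse_coded %in% 1:14)) {
      fail("questionnaire must mark exactly 8 reverse-coded item indices")
    }
  }
  if (!is.null(tk$pci)) {
    for (cd in tk$pci) {
      pr <- c(cd$child_initiation_prop, cd$caregiver_sync_prop)
      if (any(pr < 0 | pr > 1)) fail("interaction proportions outside [0, 1]")
      if (cd$child_opportunities <= 0 || cd$caregiver_opportunities <= 0) {
        fail("interaction opportunity counts must be positive")
      }
    }
  }
  invisible(rec)
}

#' Validate a cohort
#'
#' Validates every record and checks cohort-level invariants (unique
#' `child_id`).
#'
#' @param cohort list of `start_child` records.
#' @inheritParams validate_child_record
#' @return `cohort`, invisibly, with class `start_cohort`.
#' @export
validate_cohort <- function(cohort, config = start_config()) {
  ids <- vapply(cohort, function(r) r$child_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopf("duplicate child_id: %s", paste(dup, collapse = ", "))
  for (i in seq_along(cohort)) {
    validate_child_record(cohort[[i]], config,
                          context = sprintf("record %d (child '%s')", i, ids[i]))
  }
  class(cohort) <- "start_cohort"
  invisible(cohort)
}

#' @export
print.start_cohort <- function(x, ...) {
  grp <- table(factor(vapply(x, function(r) r$group, character(1)), GROUP_LEVELS))
  cat(sprintf("<start_cohort> %d children (%s)\n", length(x),
              paste(sprintf("%s=%d", names(grp), grp), collapse = ", ")))
  invisible(x)
}

#' Battery configuration
#'
#' Default geometry, timing and analysis parameters of the task battery.
#' Trial counts follow the battery design (8 preferential-looking trials,
#' 8 button trials, 5 wheel trials of at most 15 s, 4 motor-following trials,
#' 6 bubble trials presenting 1..6 bubbles, 2 colouring trials); the screen is
#' a 2560x1600 px tablet sampled at 20 Hz.
#'
#' @param ... named overrides of any default listed below.
#' @return A list of configuration values (class `start_config`).
#' @details Analysis parameters:
#' * `fft_band`: frequency band (Hz) for the motor frequency gain, weighted
#'   by frequency within the band.
#' * `fft_dt_s`: uniform resampling step for spectra (50 ms).
#' * `coverage_threshold`, `coverage_mode`: colouring inclusion rule; the
#'   denominator is all screen pixels (`"screen"`, the printed rule) or the
#'   figure interior (`"figure"`).
#' * `coverage_grid_step`: integer pixel-grid decimation used when measuring
#'   painted coverage (1 = every pixel).
#' @export
start_config <- function(...) {
  cfg <- list(
    screen_px = c(2560, 1600),
    fps = 20,
    age_range = c(2, 7.99),
    preferential_trials = 8,
    preferential_trial_s = 7.5,
    button_trials = 8,
    wheel_trials = 5,
    wheel_trial_s = 15,
    motor_trials = 4,
    motor_trial_s = 30,
    motor_velocity_range = c(45, 105),
    motor_lag_ms = 120,
    bubble_trials = 6,
    colouring_trials = 2,
    brush_radius_px = 40,
    coverage_threshold = 0.25,
    coverage_mode = "screen",
    coverage_grid_step = 4,
    fft_band = c(0.2, 5),
    fft_dt_s = 0.05,
    min_trial_overlap = 0.5
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "start_config")
}
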