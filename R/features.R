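# Per-task inclusion filters and dependent-variable computations.
#
# Each task operation returns list(value = <numeric or named numerics>,
# outcome = filter_outcome(...)). Filters follow the battery's pre-set
# exclusion criteria: "at least 50%" rules are inclusive (>= half counts as
# in), while the wheel face-detection rule excludes at exactly 25% ("25% or
# fewer ... were excluded").

filter_outcome <- function(task, included, reason) {
  stopifnot(reason %in% FILTER_REASONS)
  data.frame(task = task, included = included, reason = reason,
             stringsAsFactors = FALSE)
}

excluded <- function(task, reason, slots) {
  v <- rep(NA_real_, length(slots))
  names(v) <- slots
  list(value = v, outcome = filter_outcome(task, FALSE, reason))
}

ok <- function(task, value) list(value = value, outcome = filter_outcome(task, TRUE, "ok"))

#' Social preference from preferential-looking trials
#'
#' Inclusion requires eye detection on at least half of all frames and gaze
#' anywhere on the tablet (either stimulus side or elsewhere on the screen)
#' on at least half of all frames. The value is the fraction of on-stimulus
#' frames spent on the social side: social / (social + nonsocial).
#'
#' @param trials list of preferential-looking trials (see [startpheno-types]).
#' @return list(value, outcome): `value` is a named numeric
#'   (`social_preference`), `NA` when excluded; `outcome` a one-row filter
#'   report.
#' @export
social_preference <- function(trials) {
  slots <- "social_preference"
  if (is.null(trials) || !length(trials)) return(excluded("preferential", "missing_task", slots))
  gaze <- unlist(lapply(trials, function(tr) tr$frames$gaze))
  n <- length(gaze)
  if (!n) return(excluded("preferential", "missing_task", slots))
  detected <- gaze != "undetected"
  if (mean(detected) < 0.5) return(excluded("preferential", "eye_detection_below_half", slots))
  on_tablet <- gaze %in% c("social_side", "nonsocial_side", "elsewhere_on_tablet")
  if (mean(on_tablet) < 0.5) return(excluded("preferential", "gaze_on_tablet_below_half", slots))
  n_soc <- sum(gaze == "social_side")
  n_non <- sum(gaze == "nonsocial_side")
  if (n_soc + n_non == 0) return(excluded("preferential", "degenerate", slots))
  ok("preferential", c(social_preference = n_soc / (n_soc + n_non)))
}

#' Social choice proportion from button trials
#'
#' Children completing fewer than half of the scheduled trials are excluded;
#' the value is social choices / completed trials.
#'
#' @param trials data frame of button trials (`completed`, `choice`).
#' @param scheduled number of scheduled trials (default 8).
#' @return list(value, outcome) as in [social_preference()].
#' @export
button_social_choice <- function(trials, scheduled = 8) {
  slots <- "social_choice"
  if (is.null(trials) || !nrow(trials)) return(excluded("button", "missing_task", slots))
  ncomp <- sum(trials$completed)
  if (ncomp < 0.5 * scheduled) return(excluded("button", "fewer_than_half_trials", slots))
  ok("button", c(social_choice = sum(trials$choice == "social") / ncomp))
}

wheel_included <- function(trials) {
  if (is.null(trials) || !length(trials)) return("missing_task")
  if (sum(vapply(trials, function(tr) tr$completed, logical(1))) < 2) {
    return("fewer_than_two_trials")
  }
  det <- unlist(lapply(trials, function(tr) tr$face_frames$face_detected))
  if (!length(det) || mean(det) <= 0.25) return("face_detection_at_or_below_quarter")
  "ok"
}

#' Wheel-task looking time
#'
#' Inclusion requires at least two completed trials and face detection on
#' more than a quarter of all video frames. Looking time is summed over the
#' frames of completed trials on which gaze was on the wheel and divided by
#' the maximum possible viewing duration of the completed trials.
#'
#' @param trials list of wheel trials.
#' @return list(value, outcome); `value` is `wheel_looking` in \[0, 1\].
#' @export
wheel_looking <- function(trials) {
  slots <- "wheel_looking"
  reason <- wheel_included(trials)
  if (reason != "ok") return(excluded("wheel", reason, slots))
  comp <- Filter(function(tr) tr$completed, trials)
  look_s <- vapply(comp, function(tr) {
    fr <- tr$face_frames
    if (nrow(fr) < 1) return(0)
    dt <- if (nrow(fr) > 1) diff(fr$t_ms) else 50
    dt <- c(dt, stats::median(dt)) / 1000
    sum(dt[fr$gaze_on_wheel])
  }, numeric(1))
  denom <- sum(vapply(comp, function(tr) tr$max_duration_s, numeric(1)))
  ok("wheel", c(wheel_looking = clamp(sum(look_s) / denom, 0, 1)))
}

#' Wheel-task face distance range
#'
#' Minimum and maximum face-tablet distance (mm) over the face-detected
#' frames of completed trials, under the same inclusion rule as
#' [wheel_looking()].
#'
#' @param trials list of wheel trials.
#' @return list(value, outcome); `value` holds `wheel_dist_min`,
#'   `wheel_dist_max`.
#' @export
wheel_face_distance <- function(trials) {
  slots <- c("wheel_dist_min", "wheel_dist_max")
  reason <- wheel_included(trials)
  if (reason != "ok") return(excluded("wheel", reason, slots))
  comp <- Filter(function(tr) tr$completed, trials)
  d <- unlist(lapply(comp, function(tr) {
    fr <- tr$face_frames
    fr$distance_mm[fr$face_detected]
  }))
  d <- d[!is.na(d)]
  if (!length(d)) return(excluded("wheel", "degenerate", slots))
  ok("wheel", c(wheel_dist_min = min(d), wheel_dist_max = max(d)))
}

# ---- motor following --------------------------------------------------------

motor_trial_valid <- function(trial, min_overlap = 0.5) {
  tg <- trial$target; tc <- trial$touch
  if (is.null(tc) || !nrow(tc) || nrow(tg) < 2) return(FALSE)
  span <- range(tg$t_ms)
  lo <- max(span[1], min(tc$t_ms)); hi <- min(span[2], max(tc$t_ms))
  (hi - lo) / diff(span) >= min_overlap
}

motor_overlap_grid <- function(trial) {
  tg <- trial$target; tc <- trial$touch
  lo <- max(min(tg$t_ms), min(tc$t_ms))
  hi <- min(max(tg$t_ms), max(tc$t_ms))
  tg$t_ms[tg$t_ms >= lo & tg$t_ms <= hi]
}

#' Root-mean-square trajectory error of one motor-following trial
#'
#' The touch trajectory is linearly interpolated onto the target's timestamps
#' within their overlapping time support; the value is the root mean square
#' Euclidean distance between the two trajectories over those timestamps.
#'
#' @param trial a motor trial (`target`, `touch` data frames).
#' @return RMSE in pixels, or `NA` for an invalid trial (empty touch or
#'   touch covering less than half the target's time support).
#' @export
motor_rmse <- function(trial) {
  if (!motor_trial_valid(trial)) return(NA_real_)
  tt <- motor_overlap_grid(trial)
  cx <- interp1(trial$touch$t_ms, trial$touch$x_px, tt)
  cy <- interp1(trial$touch$t_ms, trial$touch$y_px, tt)
  keep <- !is.na(cx) & !is.na(cy)
  if (!any(keep)) return(NA_real_)
  dx <- cx[keep] - interp1(trial$target$t_ms, trial$target$x_px, tt)[keep]
  dy <- cy[keep] - interp1(trial$target$t_ms, trial$target$y_px, tt)[keep]
  sqrt(mean(dx^2 + dy^2))
}

# Resample a series to a uniform dt grid over the overlap window (endpoint
# excluded so the FFT length matches the window duration exactly), linearly
# detrend, Hann-window, and return the one-sided magnitude spectrum.
spectrum_mag <- function(t_ms, v, t0, t1, dt_s) {
  tt <- seq(t0, t1, by = dt_s * 1000)
  if (length(tt) > 1 && tt[length(tt)] >= t1) tt <- tt[-length(tt)]
  x <- interp1(t_ms, v, tt)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) return(NULL)
  # endpoint-matching detrend: removes the jump of the periodic extension
  # (a least-squares line is not orthogonal to low-frequency content and
  # would leak broadband power into the band)
  i <- seq_len(n) - 1
  x <- x - (x[1] + (x[n] - x[1]) * i / (n - 1))
  x <- (x - mean(x)) * hann_window(n)
  mag <- Mod(stats::fft(x))
  f <- (seq_len(n) - 1) / (n * dt_s)
  half <- f <= 1 / (2 * dt_s)
  list(f = f[half], mag = mag[half])
}

#' Frequency gain of one motor-following trial
#'
#' Target and touch series on one axis are resampled to a uniform grid,
#' linearly detrended and Hann-windowed; the gain is the ratio of their
#' frequency-weighted magnitude spectra summed over the band (default
#' 0.2-5 Hz, weight w(f) = f). Perfect tracking gives a gain of 1; power
#' added by the child inside the band raises it.
#'
#' @param trial a motor trial.
#' @param axis `"x"` or `"y"`.
#' @param band frequency band in Hz.
#' @param dt_s uniform resampling step (default 50 ms).
#' @return The gain (>= 0), or `NA` for an invalid trial or an all-zero
#'   target spectrum in the band.
#' @export
motor_frequency_gain <- function(trial, axis = c("x", "y"), band = c(0.2, 5),
                                 dt_s = 0.05) {
  axis <- match.arg(axis)
  if (!motor_trial_valid(trial)) return(NA_real_)
  col <- paste0(axis, "_px")
  tt <- motor_overlap_grid(trial)
  t0 <- min(tt); t1 <- max(tt)
  st <- spectrum_mag(trial$target$t_ms, trial$target[[col]], t0, t1, dt_s)
  sc <- spectrum_mag(trial$touch$t_ms, trial$touch[[col]], t0, t1, dt_s)
  if (is.null(st) || is.null(sc)) return(NA_real_)
  inb <- st$f >= band[1] & st$f <= band[2]
  denom <- sum(st$f[inb] * st$mag[inb])
  if (denom <= 0) return(NA_real_)
  inbc <- sc$f >= band[1] & sc$f <= band[2]
  sum(sc$f[inbc] * sc$mag[inbc]) / denom
}

#' Jerk of one motor-following trial
#'
#' Mean magnitude of the discrete third difference of the touch trajectory
#' divided by the cube of the sampling step, normalised by the screen
#' diagonal per second cubed to a dimensionless smoothness index (0 for any
#' constant-velocity straight line).
#'
#' @param trial a motor trial.
#' @param screen_px screen size in pixels (for the diagonal).
#' @return Dimensionless jerk (>= 0); `NA` with fewer than 4 touch samples.
#' @export
motor_jerk <- function(trial, screen_px = c(2560, 1600)) {
  tc <- trial$touch
  if (is.null(tc) || nrow(tc) < 4) return(NA_real_)
  dt <- stats::median(diff(tc$t_ms)) / 1000
  d3x <- diff(tc$x_px, differences = 3)
  d3y <- diff(tc$y_px, differences = 3)
  diag_px <- sqrt(sum(screen_px^2))
  mean(sqrt(d3x^2 + d3y^2)) / dt^3 / diag_px
}

motor_features <- function(trials, config) {
  slots <- c("motor_rmse", "fft_gain_x", "fft_gain_y", "jerk")
  if (is.null(trials) || !length(trials)) return(excluded("motor", "missing_task", slots))
  valid <- Filter(function(tr) motor_trial_valid(tr, config$min_trial_overlap), trials)
  if (length(valid) < 2) return(excluded("motor", "fewer_than_two_trials", slots))
  mfun <- function(f) {
    v <- vapply(valid, f, numeric(1))
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }
  ok("motor", c(
    motor_rmse = mfun(motor_rmse),
    fft_gain_x = mfun(function(tr) motor_frequency_gain(tr, "x", config$fft_band, config$fft_dt_s)),
    fft_gain_y = mfun(function(tr) motor_frequency_gain(tr, "y", config$fft_band, config$fft_dt_s)),
    jerk = mfun(function(tr) motor_jerk(tr, config$screen_px))))
}

# ---- bubble popping ---------------------------------------------------------

#' Bubble-popping force and targeting offsets
#'
#' Children who popped at least one bubble are included. Force is the mean
#' touch pressure over popped bubbles; the offsets are the mean absolute
#' horizontal and vertical distances between the touch point and the bubble
#' centre at touch time.
#'
#' @param touches data frame of bubble touches.
#' @return list(value, outcome); `value` holds `pop_force`, `pop_dist_x`,
#'   `pop_dist_y`.
#' @export
bubble_features <- function(touches) {
  slots <- c("pop_force", "pop_dist_x", "pop_dist_y")
  if (is.null(touches) || !nrow(touches)) return(excluded("bubble", "missing_task", slots))
  pop <- touches[touches$popped, , drop = FALSE]
  if (!nrow(pop)) return(excluded("bubble", "no_bubbles_popped", slots))
  ok("bubble", c(pop_force = mean(pop$pressure),
                 pop_dist_x = mean(abs(pop$touch_x - pop$bubble_x)),
                 pop_dist_y = mean(abs(pop$touch_y - pop$bubble_y))))
}

# ---- colouring --------------------------------------------------------------

#' Outline crossings of one colouring session
#'
#' Each consecutive pair of samples within a stroke whose inside/outside
#' classifications (even-odd point-in-polygon; points on the outline count as
#' inside) differ adds one crossing. Stroke boundaries never generate
#' crossings.
#'
#' @param session a colouring session.
#' @return Integer crossing count (this session only, no inclusion filter).
#' @export
colouring_crossings <- function(session) {
  total <- 0L
  for (st in session$strokes) {
    if (nrow(st) < 2) next
    inside <- point_in_polygon(st$x_px, st$y_px, session$figure_outline)
    total <- total + sum(inside[-1] != inside[-length(inside)])
  }
  total
}

#' Painted coverage of one or more colouring sessions
#'
#' Fraction of pixels lying within the brush radius of any stroke sample,
#' measured on an integer pixel grid (optionally decimated by `grid_step`
#' for speed). With `mode = "screen"` the denominator is every screen pixel
#' (the battery's printed inclusion rule); `mode = "figure"` restricts both
#' numerator and denominator to the figure interior.
#'
#' @param sessions a colouring session or list of sessions sharing a screen.
#' @param grid_step integer grid decimation (1 = every pixel).
#' @param mode `"screen"` or `"figure"`.
#' @return Coverage in \[0, 1\].
#' @export
colouring_coverage <- function(sessions, grid_step = 1, mode = c("screen", "figure")) {
  mode <- match.arg(mode)
  if (!is.null(sessions$strokes)) sessions <- list(sessions)
  scr <- sessions[[1]]$screen_px
  gw <- max(1L, floor(scr[1] / grid_step))
  gh <- max(1L, floor(scr[2] / grid_step))
  painted <- logical(gw * gh)
  for (ss in sessions) {
    r <- ss$brush_radius_px / grid_step
    ri <- ceiling(r)
    offs <- expand.grid(dx = -ri:ri, dy = -ri:ri)
    offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, , drop = FALSE]
    off_lin <- offs$dy * gw + offs$dx
    for (st in ss$strokes) {
      if (!nrow(st)) next
      # disc stamping in linear indices; points are clamped >= ri+1 cells
      # from the border so offsets cannot wrap across rows
      gx <- pmin(pmax(round(st$x_px / grid_step), ri + 1L), gw - ri)
      gy <- pmin(pmax(round(st$y_px / grid_step), ri + 1L), gh - ri)
      lin <- unique((gy - 1L) * gw + gx)
      painted[as.vector(outer(lin, off_lin, "+"))] <- TRUE
    }
  }
  painted <- matrix(painted, nrow = gw)
  if (mode == "screen") {
    mean(painted)
  } else {
    cx <- (seq_len(gw) - 0.5) * grid_step
    cy <- (seq_len(gh) - 0.5) * grid_step
    grid <- expand.grid(x = cx, y = cy)
    infig <- matrix(point_in_polygon(grid$x, grid$y, sessions[[1]]$figure_outline),
                    nrow = gw)
    sum(painted & infig) / max(sum(infig), 1L)
  }
}

colouring_features <- function(sessions, config) {
  slots <- "colour_crossings"
  if (is.null(sessions) || !length(sessions)) return(excluded("colouring", "missing_task", slots))
  if (!any(vapply(sessions, function(s) length(s$strokes) > 0, logical(1)))) {
    return(excluded("colouring", "missing_task", slots))
  }
  cov <- colouring_coverage(sessions, grid_step = config$coverage_grid_step,
                            mode = config$coverage_mode)
  if (cov < config$coverage_threshold) {
    return(excluded("colouring", "coverage_below_threshold", slots))
  }
  ok("colouring", c(colour_crossings = sum(vapply(sessions, colouring_crossings, numeric(1)))))
}

# ---- questionnaire and interaction ------------------------------------------

#' Questionnaire severity score
#'
#' Fourteen binary items; six direct items score 1 for "yes" and the eight
#' reverse-coded items score 1 for "no". The score is the item sum, 0-14,
#' higher meaning more red-flag signs.
#'
#' @param resp `list(items, reverse_coded)`.
#' @return Integer score in 0..14.
#' @export
questionnaire_score <- function(resp) {
  if (length(resp$items) != 14) stopf("questionnaire must have 14 items, got %d",
                                      length(resp$items))
  if (length(unique(resp$reverse_coded)) != 8) stopf("exactly 8 items must be reverse-coded")
  rev <- seq_along(resp$items) %in% resp$reverse_coded
  sum(ifelse(rev, resp$items == "no", resp$items == "yes"))
}

#' Interaction features from coded caregiver-child play
#'
#' When several coders rated the same video, one coder is selected uniformly
#' at random (reproducibly under `seed`) and their two proportions returned.
#'
#' @param codings list of coder records.
#' @param seed integer seed for the coder draw.
#' @return list(value, outcome); `value` holds `pci_child_init`,
#'   `pci_caregiver_sync`.
#' @export
pci_features <- function(codings, seed = 1L) {
  slots <- c("pci_child_init", "pci_caregiver_sync")
  if (is.null(codings) || !length(codings)) return(excluded("pci", "missing_task", slots))
  idx <- if (length(codings) == 1) 1L else with_seed(seed, function() sample.int(length(codings), 1))
  cd <- codings[[idx]]
  ok("pci", c(pci_child_init = cd$child_initiation_prop,
              pci_caregiver_sync = cd$caregiver_sync_prop))
}

# ---- whole-record extraction ------------------------------------------------

#' Extract the feature vector of one child
#'
#' Applies every task operation and its inclusion filter; absent tasks yield
#' missing slots with reason `missing_task`. The outcome table always covers
#' all eight tasks.
#'
#' @param record a `start_child` record.
#' @param config battery configuration.
#' @param seed seed for the (only) stochastic step, the interaction coder
#'   draw.
#' @return `list(features, outcomes)`: a named numeric over the 16 slots
#'   (with `questionnaire_score` as an integer count) and the filter-outcome
#'   data frame.
#' @export
extract_features <- function(record, config = start_config(), seed = 1L) {
  tk <- record$tasks
  parts <- list(
    social_preference(tk$preferential),
    button_social_choice(tk$button, config$button_trials),
    wheel_looking(tk$wheel),
    wheel_face_distance(tk$wheel),
    motor_features(tk$motor, config),
    bubble_features(tk$bubble),
    colouring_features(tk$colouring, config),
    if (is.null(tk$questionnaire)) {
      excluded("questionnaire", "missing_task", "questionnaire_score")
    } else {
      ok("questionnaire", c(questionnaire_score = questionnaire_score(tk$questionnaire)))
    },
    pci_features(tk$pci, seed = seed)
  )
  feats <- unlist(lapply(parts, function(p) p$value))
  feats <- feats[FEATURE_SLOTS]
  names(feats) <- FEATURE_SLOTS
  outcomes <- do.call(rbind, lapply(parts, function(p) p$outcome))
  # wheel contributes two operations under one filter; report the task once
  outcomes <- outcomes[!duplicated(outcomes$task), , drop = FALSE]
  rownames(outcomes) <- NULL
  list(features = feats, outcomes = outcomes)
}

#' Extract a feature table for a whole cohort
#'
#' @param cohort a `start_cohort`.
#' @param config battery configuration.
#' @param seed base seed for per-child coder draws.
#' @return `list(features, filters)`: a `start_features` data frame (one row
#'   per child: `child_id`, `group`, the 16 slots) and a tidy per-child,
#'   per-task filter report (`child_id`, `task`, `included`, `reason`).
#' @export
extract_cohort <- function(cohort, config = start_config(), seed = 1L) {
  rows <- vector("list", length(cohort))
  filt <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    ex <- extract_features(rec, config, seed = mix_seed(seed, i))
    rows[[i]] <- data.frame(child_id = rec$child_id, group = rec$group,
                            as.list(ex$features), stringsAsFactors = FALSE)
    filt[[i]] <- data.frame(child_id = rec$child_id, ex$outcomes,
                            stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, rows)
  class(features) <- c("start_features", "data.frame")
  list(features = features, filters = do.call(rbind, filt))
}
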